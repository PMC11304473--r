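# Builders and an independent brute-force oracle for the descriptor engine.

make_series <- function(levels, field_id = "F1",
                        start = as.Date("2022-07-01")) {
  tibble::tibble(
    field_id = field_id,
    date = start + seq_along(levels) - 1,
    level_cm = levels,
    censored = levels <= -15,
    observed = TRUE
  )
}

# toy 10-day series used across tests (frozen hand-enumerated descriptors)
s1_levels <- c(3, 6, 11, 0, -4, -8, -12, 6, -6, -2)

random_series <- function(n_days, field_id = "R1") {
  make_series(round(runif(n_days, -15, 20), 1), field_id = field_id)
}

# Naive day-by-day reference implementation, written independently of the
# package internals: explicit loops, no rle/segmentation helpers.
oracle_descriptors <- function(levels) {
  n <- length(levels)
  flooded <- logical(n)
  fband <- dband <- character(n)
  for (i in seq_len(n)) {
    l <- levels[i]
    if (l > 0) {
      flooded[i] <- TRUE
      fband[i] <- if (l > 10) "gt10" else if (l > 5) "b510" else "b05"
    } else {
      dband[i] <- if (l >= -5) "d05" else if (l >= -10) "d510" else "dlt10"
    }
  }
  nf <- sum(flooded)
  nd <- n - nf
  pct <- function(x, base) if (base > 0) 100 * x / base else 0

  # walk flood runs
  fl_dur <- integer(0)
  i <- 1
  while (i <= n) {
    if (flooded[i]) {
      j <- i
      while (j < n && flooded[j + 1]) j <- j + 1
      fl_dur <- c(fl_dur, j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  # walk dry runs, collect duration per min-level band
  dry_dur <- list(d05 = integer(0), d510 = integer(0), dlt10 = integer(0))
  i <- 1
  while (i <= n) {
    if (!flooded[i]) {
      j <- i
      while (j < n && !flooded[j + 1]) j <- j + 1
      m <- min(levels[i:j])
      b <- if (m >= -5) "d05" else if (m >= -10) "d510" else "dlt10"
      dry_dur[[b]] <- c(dry_dur[[b]], j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  c2 <- c3 <- 0
  for (i in seq_len(n - 1)) {
    if (levels[i] >= 5 && levels[i + 1] <= -5) c2 <- c2 + 1
    if (levels[i] - levels[i + 1] > 10) c3 <- c3 + 1
  }
  mean0 <- function(x) if (length(x)) mean(x) else 0
  c(
    A1 = pct(nf, n),
    A2 = pct(sum(fband == "b05"), nf),
    A3 = pct(sum(fband == "b510"), nf),
    A4 = pct(sum(fband == "gt10"), nf),
    A5 = pct(sum(fl_dur == 1), length(fl_dur)),
    A6 = pct(sum(fl_dur >= 2 & fl_dur <= 7), length(fl_dur)),
    A7 = pct(sum(fl_dur >= 8 & fl_dur <= 30), length(fl_dur)),
    A8 = pct(sum(fl_dur > 30), length(fl_dur)),
    B1 = pct(sum(dband == "d05"), nd),
    B2 = pct(sum(dband == "d510"), nd),
    B3 = pct(sum(dband == "dlt10"), nd),
    B4 = mean0(dry_dur$d05),
    B5 = mean0(dry_dur$d510),
    B6 = mean0(dry_dur$dlt10),
    C1 = length(fl_dur),
    C2 = c2,
    C3 = c3
  )
}

# descriptor tibble with A1 driving structure; remaining 16 are iid noise
synthetic_descriptor_table <- function(n, a1) {
  stopifnot(length(a1) == n)
  out <- tibble::tibble(field_id = sprintf("F%03d", seq_len(n)), A1 = a1)
  for (nm in setdiff(paddyghg:::DESCRIPTOR_NAMES, "A1")) {
    out[[nm]] <- rnorm(n)
  }
  out
}
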