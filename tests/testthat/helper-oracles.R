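# Independent brute-force oracles and small fixture builders. The oracles
# deliberately re-derive each rule with plain loops so they share no code
# with the implementation they check.

# flat curve with optional overrides: flat_curve(`50` = 200) sets channel 50
flat_curve <- function(level = 100, ...) {
  ch <- rep(level, 200)
  over <- list(...)
  for (nm in names(over)) ch[as.integer(nm)] <- over[[nm]]
  glow_curve(ch)
}

# triple-condition spike scan, one explicit loop per condition
oracle_spike_positions <- function(ch, s) {
  ch <- as.numeric(ch)
  f <- (100 + s) / 100
  hits <- integer(0)
  for (i in 1:197) {
    c1 <- ch[i + 1] > ch[i] * f
    c2 <- ch[i + 1] > ch[i + 2] * f
    c3 <- ch[i + 2] > ch[i + 3] * f
    if (c1 && (c2 || c3)) hits <- c(hits, i)
  }
  hits
}

# merged-event count from raw firing positions
oracle_spike_events <- function(positions) {
  if (!length(positions)) return(0L)
  sum(c(TRUE, diff(positions) > 1L))
}

# exhaustive ratio-table scan: every row, every computable ratio
oracle_ratio_match <- function(doses, tab, tol) {
  n <- length(doses)
  ratio <- function(num, den) {
    if (num > n || den > n) return(NA_real_)
    if (doses[den] == 0) {
      if (doses[num] == 0) NA_real_ else Inf
    } else doses[num] / doses[den]
  }
  r <- c(ratio(4, 3), ratio(3, 1), ratio(3, 2), ratio(1, 4))
  hits <- character(0)
  for (i in seq_len(nrow(tab))) {
    vals <- c(tab$l4_over_l3[i], tab$l3_over_l1[i], tab$l3_over_l2[i],
              tab$l1_over_l4[i])
    ok <- TRUE
    for (k in 1:4) {
      if (is.na(r[k])) next
      if (is.infinite(r[k])) {
        if (!(is.finite(vals[k]) && tol > 0 && vals[k] > 1 / tol)) ok <- FALSE
      } else if (abs(r[k] - vals[k]) > tol) ok <- FALSE
    }
    if (ok) hits <- c(hits, tab$beam[i])
  }
  hits
}

# intensity-weighted moments by direct summation
oracle_moments <- function(ch) {
  ch <- as.numeric(ch)
  p <- ch / sum(ch)
  i <- 1:200
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  c(skew = sum((i - mu)^3 * p) / v^1.5, kurt = sum((i - mu)^4 * p) / v^2)
}

make_record <- function(doses = c(30, 30, 30, 30), id = "T001",
                        read = "2024-02-01", prev = "2024-01-01",
                        curves = NULL) {
  if (is.null(curves))
    curves <- lapply(seq_along(doses), function(i)
      generate_normal_gc(seed = i, noise_cv = 0))
  dosimeter_record(id, "RD01", curves, doses, read, prev)
}
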