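# Independent brute-force oracles, written as plain double loops so they
# share no code with the package implementation.

# Seasonal Mann-Kendall by direct enumeration over all within-season
# pairs. `t_mon` are integer month indices, `x` the values.
smk_brute <- function(t_mon, x, period = 12) {
  ok <- !is.na(x)
  t_mon <- t_mon[ok]
  x <- x[ok]
  s_total <- 0
  var_total <- 0
  slopes <- c()
  for (s in 0:(period - 1)) {
    idx <- which(t_mon %% period == s)
    n <- length(idx)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- idx[i]
        b <- idx[j]
        if (t_mon[b] < t_mon[a]) { tmp <- a; a <- b; b <- tmp }
        d <- x[b] - x[a]
        s_total <- s_total + sign(d)
        if (t_mon[b] != t_mon[a]) {
          slopes <- c(slopes, d / (t_mon[b] - t_mon[a]))
        }
      }
    }
    tie_counts <- as.vector(table(x[idx]))
    var_total <- var_total +
      (n * (n - 1) * (2 * n + 5) -
         sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  }
  list(s = s_total, var_s = var_total,
       sen_per_year = if (length(slopes)) median(slopes) * 12 else 0)
}

# Spearman's rho by explicit average-rank computation.
spearman_brute <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Screening fate classes by direct arithmetic, independent of the
# package's case_when path.
screen_brute <- function(k_rxn, c_ss, tau_years) {
  sec_month <- 86400 * 30.44
  t_half <- log(2) / (k_rxn * c_ss) / sec_month
  r <- log10(t_half / (tau_years * 12))
  out <- character(length(r))
  for (i in seq_along(r)) {
    out[i] <- if (r[i] < 0) "faster_than_flushing"
              else if (r[i] < 1) "comparable" else "slower"
  }
  out
}

monthly_dates <- function(n, start = "2000-01-01") {
  seq(as.Date(start), by = "month", length.out = n)
}
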