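# Shared fixture builders and independent oracle helpers.

# small dosage panel built directly (no simulator)
make_panel <- function(dosages, maf = NULL, quality = NULL,
                       chrom = NULL, pos = NULL, ref = "A", alt = "G") {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  variants <- data.frame(
    chrom = if (is.null(chrom)) rep("1", n) else chrom,
    pos = if (is.null(pos)) seq_len(n) * 100L else pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    maf = if (is.null(maf)) rep(0.25, n) else maf,
    quality = if (is.null(quality)) rep(0.95, n) else quality,
    stringsAsFactors = FALSE)
  dosage_panel(variants, dosages)
}

# textbook Pearson correlation, written independently of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Spearman via the no-tie rank-difference formula
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# grid search of the (unweighted, no-ties) Cox partial likelihood over a
# single covariate; vectorized over the beta grid
grid_cox_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  o <- order(time, decreasing = TRUE)   # risk sets are prefixes
  x_s <- x[o]; e_s <- event[o]
  E <- exp(outer(x_s, grid))            # n x G
  S0 <- apply(E, 2, cumsum)             # risk-set sums at each position
  ev <- which(e_s)
  ll <- colSums(outer(x_s[ev], grid)) - colSums(log(S0[ev, , drop = FALSE]))
  grid[which.max(ll)]
}

# O(n^2) concordance oracle written differently from harrell_c
c_index_oracle <- function(lp, time, event) {
  n <- length(time)
  conc <- comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # order the pair so 'a' has the earlier time
      a <- if (time[i] <= time[j]) i else j
      b <- if (time[i] <= time[j]) j else i
      if (!event[a]) next
      if (time[a] == time[b] && event[b]) next  # tied event times: not comparable
      comp <- comp + 1
      if (lp[a] > lp[b]) conc <- conc + 1
      else if (lp[a] == lp[b]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# a no-ties all-events single-covariate survival fixture
random_cox_fixture <- function(n, beta = 0.5) {
  x <- rnorm(n)
  time <- rexp(n, rate = exp(beta * x))
  while (anyDuplicated(time)) time <- rexp(n, rate = exp(beta * x))
  list(time = time, event = rep(TRUE, n), x = x)
}

# two columns with exact sample correlation rho
exact_cor_columns <- function(n, rho, seed = 1) {
  set.seed(seed)
  a <- scale(rnorm(n))[, 1]
  b <- residuals(lm(rnorm(n) ~ a))
  b <- b / sd(b)
  a <- a / sd(a)
  cbind(a, rho * a + sqrt(1 - rho^2) * b)
}
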