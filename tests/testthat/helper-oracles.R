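# Independent oracles, written from the defining formulas and kept free of
# package internals so estimator tests are genuine dual-route checks.

oracle_ivw_fixed <- function(beta_exp, beta_out, se_out) {
  ratio <- beta_out / beta_exp
  w <- (beta_exp / se_out)^2
  list(beta = sum(w * ratio) / sum(w), se = sqrt(1 / sum(w)))
}

# Weighted least squares with intercept by explicit normal equations
# (solve(), not the closed-form sums the implementation uses), with the
# same residual-variance floor.
oracle_wls_egger <- function(beta_exp, beta_out, se_out) {
  sgn <- ifelse(beta_exp < 0, -1, 1)
  x <- beta_exp * sgn
  y <- beta_out * sgn
  w <- 1 / se_out^2
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% coefs
  sigma2 <- sum(w * resid^2) / (length(y) - 2)
  vcv <- solve(XtWX) * max(1, sigma2)
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = sqrt(vcv[1, 1]), se_slope = sqrt(vcv[2, 2]))
}

# Brute-force cumulative-weight interpolation at probability one half.
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  b <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  j <- max(which(s < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

oracle_sobel <- function(b1, s1, b2, s2) {
  se <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  z <- b1 * b2 / se
  list(se = se, z = z, p = 2 * pnorm(-abs(z)))
}

# Random small harmonized instance for estimator equivalence sweeps.
random_harmonized <- function(k, seed) {
  withr::with_seed(seed, {
    be <- runif(k, 0.02, 0.2) * sample(c(-1, 1), k, replace = TRUE)
    mrmediation:::harmonized_set(
      variant_id = paste0("rs", seq_len(k)),
      beta_exp = be,
      se_exp = runif(k, 0.005, 0.02),
      beta_out = 0.3 * be + rnorm(k, 0, 0.02),
      se_out = runif(k, 0.005, 0.03),
      n_exp = 30000L, n_out = 30000L
    )
  })
}

make_table <- function(df, ...) sumstats(df, ...)

# Minimal well-formed record collection used across the format tests.
example_records <- function() {
  tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1000L, 2000L, 3000L),
    effect_allele = c("A", "C", "T"),
    other_allele = c("G", "T", "C"),
    eaf = c(0.2, 0.5, 0.8),
    beta = c(0.1, -0.2, 0.05),
    se = c(0.02, 0.04, 0.01),
    pval = c(1e-7, 2e-6, 1e-5),
    n = c(10000L, 10000L, 12000L)
  )
}
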