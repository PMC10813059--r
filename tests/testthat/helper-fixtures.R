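# Shared fixtures and independent oracles.

GROUPS <- c("WT-CTRL", "WT-OE", "TG-CTRL", "TG-OE")

balanced_design <- function(n = 3, sexes = c("female", "male")) {
  nn <- stats::setNames(rep(n, 4), GROUPS)
  make_design(n_female = if ("female" %in% sexes) nn else NULL,
              n_male = if ("male" %in% sexes) nn else NULL)
}

# Straight-line, package-independent evaluation of the empirical-Bayes
# moderated t closed form. The prior degrees of freedom are found by
# root-bracketing (uniroot) rather than Newton iteration so the oracle does
# not share numerical code with the implementation under test.
oracle_moderated_t <- function(mat, idA, idB) {
  A <- mat[, idA, drop = FALSE]
  B <- mat[, idB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  df <- nA + nB - 2
  mA <- apply(A, 1, mean); mB <- apply(B, 1, mean)
  s2 <- (apply(A, 1, function(v) sum((v - mean(v))^2)) +
         apply(B, 1, function(v) sum((v - mean(v))^2))) / df
  x <- pmax(s2, 1e-5 * stats::median(s2))
  e <- log(x) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df / 2)
  if (evar > 0) {
    half_d0 <- stats::uniroot(function(v) trigamma(v) - evar,
                              c(1e-8, 1e10), tol = 1e-14)$root
    d0 <- 2 * half_d0
    s2_prior <- exp(emean + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- Inf
    s2_prior <- mean(x)
  }
  s2_post <- if (is.infinite(d0)) rep(s2_prior, length(s2))
             else (d0 * s2_prior + df * s2) / (d0 + df)
  tt <- (mA - mB) / sqrt(s2_post * (1 / nA + 1 / nB))
  df_total <- min(df + d0, df * nrow(mat))
  list(d0 = d0, s2_prior = s2_prior, t = tt,
       p = 2 * stats::pt(-abs(tt), df = df_total))
}

# Exhaustive hypergeometric oracle: probability that a uniformly drawn
# subset of size `size_b` from 1..N intersects `set_a` in >= k elements.
oracle_hyper_p <- function(N, set_a, size_b, k) {
  draws <- utils::combn(N, size_b)
  mean(apply(draws, 2, function(b) sum(b %in% set_a)) >= k)
}
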