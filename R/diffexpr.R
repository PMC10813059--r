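# Sex-stratified pairwise differential analysis with empirical-Bayes
# variance moderation (the Smyth 2004 hierarchical model, closed-form
# moment estimation of the prior via trigamma inversion).

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` for `x > 0`, used by the
#' moment-matching estimator of the variance-prior degrees of freedom.
#' @param y positive numeric vector.
#' @return x with `trigamma(x) = y` (elementwise).
#' @export
trigamma_inverse <- function(y) {
  out <- y
  big <- y > 1e7
  small <- y < 1e-6
  out[big] <- 1 / sqrt(y[big])
  out[small] <- 1 / y[small]
  mid <- which(!big & !small)
  if (length(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Moment-match a scaled inverse-chi-square variance prior
#'
#' Given per-feature sample variances `s2` on a common `df`, estimates the
#' prior degrees of freedom `d0` and prior variance `s2_prior` by matching
#' the mean and variance of `log(s2)` against the scaled-F marginal implied
#' by the hierarchical model. If the empirical variance of `log(s2)` does
#' not exceed its sampling component, `d0 = Inf` (all variances shrunk to
#' the prior).
#'
#' @param s2 positive sample variances (non-positive values are excluded
#'   from estimation).
#' @param df residual degrees of freedom shared by all features.
#' @return list with `d0` and `s2_prior`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 >= 0
  x <- s2[ok]
  if (length(x) < 2)
    stop("need at least 2 features with finite variance to fit the prior")
  m <- stats::median(x)
  if (m == 0)
    stop("more than half of the residual variances are exactly zero")
  x <- pmax(x, 1e-5 * m)  # offset exact zeros away from log(0)
  e <- log(x) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s2_prior <- mean(x)
  }
  list(d0 = d0, s2_prior = s2_prior)
}

#' Moderated two-sample t-test per feature
#'
#' For each feature of a complete log2 matrix, computes the group-mean
#' difference (`log2FC = mean(A) - mean(B)`), the pooled within-group sample
#' variance on `nA + nB - 2` degrees of freedom, the empirical-Bayes
#' posterior variance
#' `s2_post = (d0 * s2_prior + df * s2) / (d0 + df)` with `(d0, s2_prior)`
#' from [fit_variance_prior()], the moderated statistic
#' `t = log2FC / sqrt(s2_post * (1/nA + 1/nB))`, and a two-sided p-value on
#' `df + d0` total degrees of freedom (capped at the pooled residual df of
#' the whole matrix). BH-adjusted q-values are computed across all features
#' of the contrast.
#'
#' @param mat complete numeric matrix, features x samples (log2 scale).
#' @param design sample design covering the columns of `mat`.
#' @param groupA,groupB group labels contrasted as A - B.
#' @param sex optional `"female"` or `"male"` filter: the contrast is
#'   computed within that stratum only.
#' @return a `data.frame` (class `diff_table`) with columns `feature_id`,
#'   `log2FC`, `t`, `df_total`, `p`, `q` and attribute `"fit"` holding
#'   `d0`, `s2_prior`, `s2_post`, `nA`, `nB`.
#' @export
fit_moderated_t <- function(mat, design, groupA, groupB, sex = NULL) {
  design <- validate_design(design)
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("female", "male"))
    design <- design[design$sex == sex, , drop = FALSE]
  }
  design <- design[design$sample_id %in% colnames(mat), , drop = FALSE]
  idA <- design$sample_id[design$group == groupA]
  idB <- design$sample_id[design$group == groupB]
  nA <- length(idA); nB <- length(idB)
  if (nA < 2 || nB < 2)
    stop("need >= 2 samples per group (got ", nA, " vs ", nB, ")")
  if (nrow(mat) < 10)
    stop("need >= 10 features to estimate the variance prior")
  if (anyNA(mat)) stop("matrix must be complete (impute first)")

  A <- mat[, idA, drop = FALSE]
  B <- mat[, idB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2)
  ssB <- rowSums((B - mB)^2)
  df <- nA + nB - 2
  s2 <- (ssA + ssB) / df
  if (all(s2 == 0)) stop("zero variance in every feature")

  prior <- tryCatch(fit_variance_prior(s2, df), error = function(e) NULL)
  if (is.null(prior)) {
    warning("variance prior could not be estimated; using ordinary t")
    prior <- list(d0 = 0, s2_prior = 0)
  }
  d0 <- prior$d0; s2_prior <- prior$s2_prior
  s2_post <- if (is.infinite(d0)) rep(s2_prior, length(s2))
             else (d0 * s2_prior + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  logfc <- mA - mB
  tstat <- ifelse(se > 0, logfc / se, 0)
  df_total <- min(df + d0, df * nrow(mat))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- stats::p.adjust(p, method = "BH")

  out <- data.frame(feature_id = rownames(mat), log2FC = logfc, t = tstat,
                    df_total = df_total, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diff_table", "data.frame")
  attr(out, "fit") <- list(d0 = d0, s2_prior = s2_prior, s2_post = s2_post,
                           nA = nA, nB = nB, df = df)
  attr(out, "contrast") <- paste(groupA, "vs", groupB)
  attr(out, "sex") <- if (is.null(sex)) "both" else sex
  out
}

#' Call an up/down signature from a differential table
#'
#' A feature is `up` when its (nominal or BH-adjusted) p-value is strictly
#' below `alpha` and `log2FC > 0`; `down` symmetrically. Features at exactly
#' `alpha`, or significant with a zero fold change, are not called.
#'
#' @param dt a `diff_table` from [fit_moderated_t()].
#' @param alpha significance threshold in (0, 1).
#' @param use_adjusted use the BH q-value instead of the nominal p.
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
call_signature <- function(dt, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  pv <- if (use_adjusted) dt$q else dt$p
  sig <- pv < alpha
  n_degen <- sum(sig & dt$log2FC == 0)
  if (n_degen > 0)
    message(n_degen, " significant feature(s) with zero fold change left uncalled")
  list(up = dt$feature_id[sig & dt$log2FC > 0],
       down = dt$feature_id[sig & dt$log2FC < 0])
}

#' Run the two study contrasts in each sex
#'
#' Convenience wrapper computing the disease contrast (TG-CTRL vs WT-CTRL,
#' "5xFADvsWT") and the treatment contrast (TG-OE vs TG-CTRL,
#' "5xFAD-DUSP4vs5xFAD") within each sex present in the design.
#'
#' @param mat complete log2 matrix.
#' @param design sample design.
#' @param alpha,use_adjusted passed to [call_signature()].
#' @return nested list `result[[sex]][[contrast]]` with elements `table`
#'   (diff_table) and `signature` (up/down sets).
#' @export
run_contrasts <- function(mat, design, alpha = 0.05, use_adjusted = FALSE) {
  design <- validate_design(design)
  contrasts <- list("5xFADvsWT" = c("TG-CTRL", "WT-CTRL"),
                    "5xFAD-DUSP4vs5xFAD" = c("TG-OE", "TG-CTRL"))
  out <- list()
  for (sx in unique(design$sex)) {
    out[[sx]] <- list()
    for (cn in names(contrasts)) {
      cc <- contrasts[[cn]]
      dt <- fit_moderated_t(mat, design, cc[1], cc[2], sex = sx)
      out[[sx]][[cn]] <- list(table = dt,
                              signature = call_signature(dt, alpha, use_adjusted))
    }
  }
  out
}
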