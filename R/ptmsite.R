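# Phosphosite-centric analysis: DEPTM -> DPP collapse, sample-wise site-set
# enrichment scoring (kernel-ECDF random walk, GSVA-style), and differential
# analysis of the enrichment scores.

#' Parse canonical site ids
#'
#' Canonical form: `GENE;<S|T|Y><position>` (e.g. `"APP;S441"`).
#' @param ids character vector of site ids.
#' @return data.frame with `site_id`, `gene`, `residue`, `position`;
#'   unparseable ids yield `NA` fields.
#' @export
parse_site_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+);([STY])([0-9]+)$", ids))
  pick <- function(i) vapply(m, function(x) x[i], character(1))  # NA when unmatched
  data.frame(
    site_id = ids,
    gene = pick(2),
    residue = pick(3),
    position = suppressWarnings(as.integer(pick(4))),
    stringsAsFactors = FALSE)
}

#' Collapse differential sites to differentially phosphorylated proteins
#'
#' A protein is a DPP when at least one of its sites is a differential site.
#' Proteins carrying differential sites in both directions appear in both
#' lists and are flagged ambivalent.
#'
#' @param deptm_up,deptm_down character vectors of canonical site ids.
#' @return list with protein sets `up`, `down` and `ambivalent`; the count
#'   of unparseable ids is attached as attribute `"skipped"`.
#' @export
collapse_to_dpp <- function(deptm_up, deptm_down) {
  pu <- parse_site_id(deptm_up)
  pd <- parse_site_id(deptm_down)
  skipped <- sum(is.na(pu$gene)) + sum(is.na(pd$gene))
  if (skipped > 0)
    message(skipped, " unparseable site id(s) skipped")
  up <- unique(stats::na.omit(pu$gene))
  down <- unique(stats::na.omit(pd$gene))
  amb <- intersect(up, down)
  out <- list(up = up, down = down, ambivalent = amb)
  attr(out, "skipped") <- skipped
  out
}

#' Enrichment-score random walk over a fixed ranking
#'
#' Given features already ordered by decreasing rank statistic, walks down
#' the list adding normalized in-set increments `|r|^tau / sum_in_set |r|^tau`
#' and subtracting `1/(P - m)` for out-of-set features; the enrichment score
#' is the sum of the largest positive and largest negative deviations of the
#' running sum ("maxdiff" convention), bounded in [-1, 1].
#'
#' @param r rank statistic in walk order (length P).
#' @param inset logical vector in walk order marking set membership.
#' @param tau exponent on the rank statistic (default 1).
#' @return the enrichment score (scalar).
#' @export
es_walk <- function(r, inset, tau = 1) {
  P <- length(r)
  m <- sum(inset)
  if (m == 0) stop("empty set in walk")
  if (m == P) stop("set covers all features; out-of-set step undefined")
  w <- abs(r)^tau
  denom <- sum(w[inset])
  steps <- ifelse(inset, if (denom > 0) w / denom else 1 / m, -1 / (P - m))
  # denom == 0 can only happen when every in-set weight is 0 (flat statistic);
  # fall back to uniform in-set increments
  if (denom > 0) steps[inset] <- w[inset] / denom
  cs <- cumsum(steps)
  max(cs, 0) + min(cs, 0)
}

#' Sample-wise site-set enrichment scores
#'
#' GSVA-style scoring: each feature's expression is first transformed to a
#' kernel-ECDF statistic `z_ij = mean_k Phi((x_ij - x_ik) / h_i)` with
#' Gaussian kernel bandwidth `h_i = sd_i / 4`; per sample, features are
#' ranked by `z` (descending) and weighted by the symmetric rank statistic
#' `|P/2 - rank|`; the set score is the [es_walk()] over that ranking.
#' Because the bandwidth is proportional to the per-feature sd, the scores
#' are invariant to per-feature positive affine transforms of the input.
#'
#' Sets may carry per-site expected directions (attribute `"direction"`,
#' named vector of +1/-1): a site annotated -1 contributes its reflected
#' statistic (`z -> 1 - z`) before ranking.
#'
#' @param mat complete numeric matrix (sites x samples, post-imputation
#'   log2 scale). Constant rows are excluded with a warning.
#' @param sets named list of character vectors of site ids (a
#'   `SiteSetCollection`), e.g. from [read_gmt()] with `directional = TRUE`.
#' @param tau rank-weight exponent.
#' @param min_overlap minimum matched sites for a set to be scored.
#' @return matrix of enrichment scores, scored sets x samples, with
#'   attribute `"n_matched"` (matched-site counts per scored set).
#' @export
site_set_scores <- function(mat, sets, tau = 1, min_overlap = 5) {
  stopifnot(is.matrix(mat), !anyNA(mat), min_overlap >= 3)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) excluded from ranking")
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  P <- nrow(mat); n <- ncol(mat)
  if (P < min_overlap) stop("too few variable features")

  h <- sds / 4
  z <- matrix(0, P, n, dimnames = dimnames(mat))
  for (i in seq_len(P)) {
    xi <- mat[i, ]
    # outer(xi, xi, "-")[j, k] = x_ij - x_ik, so row means give z_ij
    z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h[i]))
  }

  matched <- lapply(sets, function(s) {
    ids <- as.character(s)
    dirs <- attr(s, "direction")
    ix <- match(ids, rownames(mat))
    keep <- !is.na(ix)
    list(idx = ix[keep],
         dir = if (is.null(dirs)) rep(1, sum(keep)) else dirs[keep])
  })
  n_match <- vapply(matched, function(m) length(m$idx), integer(1))
  scored <- n_match >= min_overlap
  if (any(n_match == P))
    stop("a set covers every feature; out-of-set step undefined")
  if (!any(scored)) {
    warning("no set matched >= min_overlap sites")
    return(matrix(numeric(0), 0, n, dimnames = list(NULL, colnames(mat))))
  }
  matched <- matched[scored]

  rstat <- abs(P / 2 - seq_len(P))
  base_ord <- apply(z, 2, order, decreasing = TRUE)
  es <- matrix(NA_real_, length(matched), n,
               dimnames = list(names(matched), colnames(mat)))
  for (s in seq_along(matched)) {
    idx <- matched[[s]]$idx
    dir <- matched[[s]]$dir
    reflect <- idx[dir < 0]
    inset_row <- rep(FALSE, P)
    inset_row[idx] <- TRUE
    for (j in seq_len(n)) {
      if (length(reflect)) {
        zj <- z[, j]
        zj[reflect] <- 1 - zj[reflect]
        ord <- order(zj, decreasing = TRUE)
      } else ord <- base_ord[, j]
      es[s, j] <- es_walk(rstat, inset_row[ord], tau)
    }
  }
  attr(es, "n_matched") <- vapply(matched, function(m) length(m$idx), integer(1))
  es
}

#' Differential analysis of enrichment scores
#'
#' Applies the moderated t machinery ([fit_moderated_t()]) to a set-by-sample
#' enrichment-score matrix, reporting BH-adjusted q-values across sets.
#'
#' @param es enrichment-score matrix from [site_set_scores()].
#' @inheritParams fit_moderated_t
#' @return a `diff_table` over sets.
#' @export
differential_scores <- function(es, design, groupA, groupB, sex = NULL) {
  fit_moderated_t(es, design, groupA, groupB, sex = sex)
}
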