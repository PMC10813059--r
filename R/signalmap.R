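# Target-centric signaling map: Fisher-exact enrichment of the positive and
# negative network signatures against a curated disease gene-set collection,
# scored as -log10(FDR) and filtered at FDR < 0.05.

#' Build a signaling map
#'
#' For every gene set, tests the positively- and negatively-associated
#' signatures separately with a one-sided Fisher exact test
#' (enrichment, 2x2 over the background), BH-adjusts across the pooled
#' (set x sign) family, keeps connections with FDR below `fdr_cut`, and
#' scores each kept connection as `-log10(FDR)`. Each set additionally gets
#' a `sign_class`: `positive-only`, `negative-only`, or `both`, according to
#' which signatures retain a connection to it.
#'
#' @param pos_genes,neg_genes disjoint character vectors (e.g. the positive
#'   and negative neighbourhoods of a target-centric network).
#' @param ad_sets named list of gene sets (a curated disease collection).
#' @param background background universe.
#' @param set_categories optional named character vector mapping set name to
#'   a parent category for rendering.
#' @param fdr_cut connection filter (default 0.05).
#' @param pooled_bh BH family: pooled across sets and both signs (default)
#'   or per sign.
#' @return list with `edges` (kept connections: `set`, `category`, `sign`,
#'   `k`, `FE`, `p`, `q`, `score`, `sign_class`) and `all` (every test).
#' @export
build_signal_map <- function(pos_genes, neg_genes, ad_sets, background,
                             set_categories = NULL, fdr_cut = 0.05,
                             pooled_bh = TRUE) {
  if (length(intersect(pos_genes, neg_genes)))
    stop("pos_genes and neg_genes must be disjoint")
  N <- length(unique(background))
  sig_list <- list(positive = intersect(unique(pos_genes), background),
                   negative = intersect(unique(neg_genes), background))
  rows <- list()
  for (sgn in names(sig_list)) {
    sig <- sig_list[[sgn]]
    m <- length(sig)
    for (nm in names(ad_sets)) {
      s <- intersect(unique(as.character(ad_sets[[nm]])), background)
      n <- length(s)
      k <- length(intersect(sig, s))
      if (m == 0 || n == 0) { p <- NA_real_; fe <- NA_real_ }
      else {
        tab <- matrix(c(k, m - k, n - k, N - m - n + k), 2, 2)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        fe <- k * N / (m * n)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, sign = sgn, k = k, FE = fe, p = p,
        stringsAsFactors = FALSE)
    }
  }
  all_tab <- do.call(rbind, rows)
  all_tab$q <- NA_real_
  if (pooled_bh) {
    ok <- !is.na(all_tab$p)
    all_tab$q[ok] <- stats::p.adjust(all_tab$p[ok], method = "BH")
  } else {
    for (sgn in names(sig_list)) {
      ix <- all_tab$sign == sgn & !is.na(all_tab$p)
      all_tab$q[ix] <- stats::p.adjust(all_tab$p[ix], method = "BH")
    }
  }
  all_tab$category <- if (is.null(set_categories)) NA_character_
                      else unname(set_categories[all_tab$set])

  kept <- all_tab[!is.na(all_tab$q) & all_tab$q < fdr_cut, , drop = FALSE]
  kept$score <- -log10(kept$q)
  cls <- tapply(kept$sign, kept$set, function(s) {
    if (all(c("positive", "negative") %in% s)) "both"
    else if ("positive" %in% s) "positive-only" else "negative-only"
  })
  kept$sign_class <- unname(cls[kept$set])
  rownames(kept) <- NULL
  list(edges = kept[order(-kept$score), , drop = FALSE], all = all_tab)
}
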