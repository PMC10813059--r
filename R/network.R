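# Target-centric consensus co-expression network across cohorts:
# per-dataset FDR-thresholded correlations, directional voting, and the
# frequency-thresholded network with sex-specific signature projection.

#' Correlate every gene with a target gene
#'
#' Pearson correlation of each gene against the target across samples, with
#' two-sided p-values from the t transform `t = r * sqrt((n-2)/(1-r^2))` and
#' BH adjustment within the dataset. Constant genes are excluded; Spearman
#' is available by flag.
#'
#' @param mat gene x sample numeric matrix containing the target row.
#' @param target_gene rowname of the target.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame `gene`, `r`, `p`, `q` (target row excluded).
#' @export
correlate_with_target <- function(mat, target_gene,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!target_gene %in% rownames(mat)) stop("target gene not in matrix")
  if (ncol(mat) < 10) stop("need >= 10 samples")
  x <- mat[target_gene, ]
  if (stats::sd(x) == 0) stop("target gene is constant")
  others <- mat[setdiff(rownames(mat), target_gene), , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  others <- others[sds > 0, , drop = FALSE]
  if (method == "spearman") {
    x <- rank(x)
    others <- t(apply(others, 1, rank))
  }
  n <- ncol(mat)
  r <- as.vector(stats::cor(t(others), x))
  r <- pmax(pmin(r, 1), -1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(gene = rownames(others), r = r, p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Directional voting across datasets
#'
#' Counts, per gene, the datasets in which it is significantly positively
#' (`q < fdr_cut`, `r > 0`) or negatively correlated with the target; the
#' net sign is `sign(n_pos - n_neg)` (ties give 0 and are excluded from
#' networks downstream).
#'
#' @param tables list of per-dataset data.frames from
#'   [correlate_with_target()].
#' @param fdr_cut per-dataset FDR threshold.
#' @return data.frame `gene`, `n_pos`, `n_neg`, `net_sign`, restricted to
#'   genes with at least one significant vote; attribute `"k"` records the
#'   number of datasets.
#' @export
directional_vote <- function(tables, fdr_cut = 0.05) {
  stopifnot(length(tables) >= 1)
  votes <- list()
  for (tab in tables) {
    sig <- tab[!is.na(tab$q) & tab$q < fdr_cut, , drop = FALSE]
    for (dir in c(1, -1)) {
      g <- sig$gene[sign(sig$r) == dir]
      if (length(g))
        votes[[length(votes) + 1L]] <- data.frame(gene = g, dir = dir)
    }
  }
  if (!length(votes)) {
    out <- data.frame(gene = character(0), n_pos = integer(0),
                      n_neg = integer(0), net_sign = integer(0))
    attr(out, "k") <- length(tables)
    return(out)
  }
  v <- do.call(rbind, votes)
  pos <- table(v$gene[v$dir == 1])
  neg <- table(v$gene[v$dir == -1])
  genes <- sort(unique(v$gene))
  n_pos <- as.integer(pos[genes]); n_pos[is.na(n_pos)] <- 0L
  n_neg <- as.integer(neg[genes]); n_neg[is.na(n_neg)] <- 0L
  out <- data.frame(gene = genes, n_pos = n_pos, n_neg = n_neg,
                    net_sign = sign(n_pos - n_neg),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- length(tables)
  out
}

#' Build the target-centric network at a frequency threshold
#'
#' Keeps genes whose dominant vote count reaches `threshold_n` with a
#' non-tied net sign; edges carry the net sign and the dominant frequency.
#' Nodes are annotated by membership in the sex-specific treatment-contrast
#' signatures: `shared` (both sexes), `female_specific`, `male_specific`,
#' or `unaffected`.
#'
#' @param votes vote table from [directional_vote()].
#' @param threshold_n frequency threshold in 1..k.
#' @param dep_female,dep_male character vectors of genes in the female/male
#'   signatures (up and down combined).
#' @param target target gene name (annotation only).
#' @return object of class `centric_network`: list with `target`,
#'   `threshold` and `edges` (data.frame `gene`, `sign`, `frequency`,
#'   `annotation`).
#' @export
build_centric_network <- function(votes, threshold_n, dep_female = character(0),
                                  dep_male = character(0), target = "TARGET") {
  k <- attr(votes, "k")
  if (!is.null(k) && threshold_n > k)
    stop("threshold_n exceeds the number of datasets (", k, ")")
  if (threshold_n < 1) stop("threshold_n must be >= 1")
  freq <- pmax(votes$n_pos, votes$n_neg)
  keep <- freq >= threshold_n & votes$net_sign != 0
  edges <- data.frame(gene = votes$gene[keep],
                      sign = votes$net_sign[keep],
                      frequency = freq[keep],
                      stringsAsFactors = FALSE)
  in_f <- edges$gene %in% dep_female
  in_m <- edges$gene %in% dep_male
  edges$annotation <- ifelse(in_f & in_m, "shared",
                        ifelse(in_f, "female_specific",
                          ifelse(in_m, "male_specific", "unaffected")))
  structure(list(target = target, threshold = threshold_n, edges = edges),
            class = "centric_network")
}

#' @export
print.centric_network <- function(x, ...) {
  cat(sprintf("%s-centric network (threshold n = %d): %d genes (%d+, %d-)\n",
              x$target, x$threshold, nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  if (nrow(x$edges))
    print(table(x$edges$annotation))
  invisible(x)
}

#' Run the consensus-network pipeline over a cohort panel
#'
#' @param datasets list of gene x sample matrices sharing the target.
#' @param target_gene target gene name.
#' @param fdr_cut per-dataset FDR threshold for voting.
#' @param threshold_n frequency threshold for the reported network.
#' @inheritParams correlate_with_target
#' @inheritParams build_centric_network
#' @return list with `tables`, `votes` and `network`.
#' @export
consensus_network <- function(datasets, target_gene, fdr_cut = 0.05,
                              threshold_n = 4, dep_female = character(0),
                              dep_male = character(0),
                              method = "pearson") {
  tables <- lapply(datasets, correlate_with_target, target_gene = target_gene,
                   method = method)
  votes <- directional_vote(tables, fdr_cut = fdr_cut)
  net <- build_centric_network(votes, threshold_n, dep_female, dep_male,
                               target = target_gene)
  list(tables = tables, votes = votes, network = net)
}
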