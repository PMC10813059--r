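# Gene-set collections: GMT I/O, hypergeometric overrepresentation, ranked
# (GSEA-style) enrichment with a permutation null, and projection of signed
# signatures onto annotated co-expression modules.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. With `directional = TRUE`, member suffixes `";u"` / `";d"` are
#' stripped and recorded as a per-member `direction` attribute (+1 / -1),
#' the convention used by signed phosphosite signature databases.
#'
#' @param path GMT file path.
#' @param directional parse `";u"`/`";d"` member suffixes.
#' @return named list of member vectors; descriptions in attribute
#'   `"description"`, directions (if requested) as per-set attributes.
#' @export
read_gmt <- function(path, directional = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) next
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (directional) {
      dir <- rep(1, length(members))
      dir[grepl(";d$", members)] <- -1
      ids <- sub(";[ud]$", "", members)
      members <- ids
      attr(members, "direction") <- stats::setNames(dir, ids)
    }
    sets[[parts[1]]] <- members
    descs[parts[1]] <- parts[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of member vectors (optionally with `direction`
#'   attributes, written as `";u"`/`";d"` suffixes).
#' @param path output path.
#' @param descriptions optional named character vector.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    members <- sets[[nm]]
    dir <- attr(members, "direction")
    ids <- as.character(members)
    if (!is.null(dir))
      ids <- paste0(ids, ifelse(dir[ids] < 0, ";d", ";u"))
    desc <- if (!is.null(descriptions) && !is.na(descriptions[nm]))
      descriptions[nm] else "na"
    paste(c(nm, desc, ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Overrepresentation test of a signature against a collection
#'
#' One-sided hypergeometric test per set, after intersecting each set with
#' the background universe; BH adjustment across sets. Fold enrichment is
#' `k * N / (m * n)` with `m` the signature size and `n` the in-background
#' set size.
#'
#' @param signature character vector (subset of `background`).
#' @param sets named list of member vectors.
#' @param background background universe.
#' @return data.frame `set`, `set_size`, `k`, `FE`, `p`, `q`, sorted by p.
#' @export
overrep_test <- function(signature, sets, background) {
  signature <- intersect(unique(signature), background)
  N <- length(unique(background))
  if (length(signature) == 0)
    return(data.frame(set = character(0), set_size = integer(0),
                      k = integer(0), FE = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  m <- length(signature)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(as.character(sets[[nm]])), background)
    n <- length(s)
    k <- length(intersect(signature, s))
    data.frame(set = nm, set_size = n, k = k,
               FE = if (n > 0) k * N / (m * n) else NA_real_,
               p = if (n > 0) stats::phyper(k - 1, m, N - m, n,
                                            lower.tail = FALSE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out[order(out$p), , drop = FALSE]
}

.gsea_es <- function(ord_w, inset_ord, P, m) {
  denom <- sum(ord_w[inset_ord])
  steps <- numeric(P)
  steps[inset_ord] <- if (denom > 0) ord_w[inset_ord] / denom else 1 / m
  steps[!inset_ord] <- -1 / (P - m)
  cs <- cumsum(steps)
  mx <- max(cs); mn <- min(cs)
  if (mx >= -mn) mx else mn
}

#' Ranked (GSEA-style) enrichment with a permutation null
#'
#' Features are ordered by decreasing score; the running sum gains
#' weight-normalized increments at set members and loses `1/(P - m)`
#' elsewhere; the enrichment score is the extreme deviation (positive =
#' activated, negative = suppressed). The null distribution is obtained by
#' re-drawing the set positions: exhaustively over all `choose(P, m)`
#' placements when feasible, otherwise by `n_perm` random draws.
#' NES divides ES by the mean |null ES| of matching sign.
#'
#' @param scores named numeric vector (no duplicated names, all finite).
#' @param sets named list of member vectors; sets with fewer than 3 matched
#'   features are skipped.
#' @param n_perm random permutations when exhaustive enumeration is not used.
#' @param seed integer seed for the permutation draw.
#' @param weight_mode `"score"` (hit weights `|score|^tau`, the classic
#'   weighted statistic) or `"rank"` (symmetric rank weights
#'   `|P/2 - rank|^tau`, invariant to monotone score transforms).
#' @param tau weight exponent.
#' @param exact_limit enumerate all placements when `choose(P, m)` is at
#'   most this.
#' @return data.frame `set`, `n_matched`, `ES`, `NES`, `p`, `status`
#'   (activated/suppressed), `exact` (logical).
#' @export
ranked_enrichment <- function(scores, sets, n_perm = 1999, seed = 1L,
                              weight_mode = c("score", "rank"), tau = 1,
                              exact_limit = 20000) {
  weight_mode <- match.arg(weight_mode)
  if (anyDuplicated(names(scores))) stop("duplicated feature names")
  if (any(!is.finite(scores))) stop("scores must be finite")
  P <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  feats_ord <- names(scores)[ord]
  w <- switch(weight_mode,
              score = abs(scores[ord])^tau,
              rank = abs(P / 2 - seq_len(P))^tau)
  if (all(w == 0)) message("flat score vector; unweighted statistic used")
  set.seed(as.integer(seed))

  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(as.character(sets[[nm]]), names(scores))
    m <- length(members)
    if (m < 3) next
    if (m == P) next  # degenerate: set covers the whole ranking
    inset <- feats_ord %in% members
    es <- .gsea_es(w, inset, P, m)

    n_comb <- choose(P, m)
    exact <- is.finite(n_comb) && n_comb <= exact_limit
    if (exact) {
      combs <- utils::combn(P, m)
      null_es <- apply(combs, 2, function(ix) {
        ins <- rep(FALSE, P); ins[ix] <- TRUE
        .gsea_es(w, ins, P, m)
      })
      hits <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
      p <- hits / length(null_es)
    } else {
      null_es <- vapply(seq_len(n_perm), function(b) {
        ins <- rep(FALSE, P); ins[sample.int(P, m)] <- TRUE
        .gsea_es(w, ins, P, m)
      }, numeric(1))
      hits <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
      p <- (1 + hits) / (1 + n_perm)
    }
    same_sign <- null_es[sign(null_es) == sign(es) & null_es != 0]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    rows[[nm]] <- data.frame(
      set = nm, n_matched = m, ES = es, NES = nes, p = p,
      status = if (es >= 0) "activated" else "suppressed",
      exact = exact, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set = character(0), n_matched = integer(0),
                      ES = numeric(0), NES = numeric(0), p = numeric(0),
                      status = character(0), exact = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Map mouse symbols to human symbols
#'
#' Default mapping is case-based uppercasing (`Apoe -> APOE`); an explicit
#' two-column data.frame (`mouse`, `human`) overrides it.
#' @param genes character vector of mouse symbols.
#' @param mapping optional data.frame with columns `mouse` and `human`.
#' @return character vector of human symbols (unmapped genes are uppercased).
#' @export
map_mouse_to_human <- function(genes, mapping = NULL) {
  if (is.null(mapping)) return(toupper(genes))
  ix <- match(genes, mapping$mouse)
  out <- mapping$human[ix]
  out[is.na(ix)] <- toupper(genes[is.na(ix)])
  out
}

#' Project signed signatures onto ranked co-expression modules
#'
#' Runs [overrep_test()] of each signature against each module (after
#' mouse-to-human mapping) and reports a signatures x modules matrix of
#' `-log10(q)`, with module ranking classes (Top10/Top20/Top30 by the
#' supplied module ranks) and dominant cell types carried through.
#'
#' @param signatures named list of signed signature gene vectors (e.g.
#'   `female.up`, `female.down`, ...), in mouse symbols.
#' @param modules named list of module member vectors (human symbols).
#' @param module_meta data.frame with columns `module`, `rank` and
#'   optionally `cell_type`.
#' @param background background universe in human symbols.
#' @param mapping optional mouse-to-human mapping data.frame.
#' @return list with `scores` (signature x module matrix of -log10(q)),
#'   `q` (raw q matrix) and `module_meta` (with a `rank_class` column).
#' @export
project_onto_modules <- function(signatures, modules, module_meta,
                                 background, mapping = NULL) {
  mapped <- lapply(signatures, map_mouse_to_human, mapping = mapping)
  if (!any(unlist(mapped) %in% background))
    stop("no identifier overlap between signatures and background after ",
         "mapping; supply an explicit mouse-human mapping file")
  scores <- q <- matrix(NA_real_, length(signatures), length(modules),
                        dimnames = list(names(signatures), names(modules)))
  for (i in seq_along(signatures)) {
    tab <- overrep_test(mapped[[i]], modules, background)
    q[i, tab$set] <- tab$q
    scores[i, tab$set] <- -log10(tab$q)
  }
  mm <- module_meta
  mm$rank_class <- cut(mm$rank, c(0, 10, 20, 30, Inf),
                       labels = c("Top10", "Top20", "Top30", "other"))
  list(scores = scores, q = q, module_meta = mm)
}
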