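# Signed-overlap statistics between signature pairs and the reversal
# fraction of disease-contrast signatures under treatment.

.overlap_one <- function(a, b, N) {
  m <- length(a); n <- length(b)
  k <- length(intersect(a, b))
  if (m == 0 || n == 0)
    return(list(k = 0L, FE = NA_real_, p = NA_real_, members = character(0)))
  list(k = k, FE = k * N / (m * n),
       p = stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE),
       members = intersect(a, b))
}

#' Signed overlap between two up/down signature pairs
#'
#' Tests the four signed intersections (upA&upB, upA&downB, downA&upB,
#' downA&downB) against the hypergeometric null on a background of
#' `background_size` features. Fold enrichment is
#' `FE = k * N / (|A| * |B|)`; the p-value is the upper tail
#' `P(X >= k)`; BH adjustment is applied across the four tests.
#'
#' @param upA,downA,upB,downB character vectors of feature ids (each a
#'   subset of the background universe).
#' @param background_size number of features in the tested universe (the
#'   features that passed QC and entered the contrasts).
#' @return data.frame with one row per signed pair: `pair`, `k`, `FE`, `p`,
#'   `q`, and a list-column `members`.
#' @export
signed_overlap <- function(upA, downA, upB, downB, background_size) {
  N <- background_size
  sizes <- c(length(upA), length(downA), length(upB), length(downB))
  if (N < length(union(c(upA, downA), c(upB, downB))))
    stop("background_size smaller than the union of the signatures")
  pairs <- list(up_up = list(upA, upB), up_down = list(upA, downB),
                down_up = list(downA, upB), down_down = list(downA, downB))
  res <- lapply(pairs, function(pp) .overlap_one(pp[[1]], pp[[2]], N))
  out <- data.frame(
    pair = names(pairs),
    k = vapply(res, function(r) as.integer(r$k), integer(1)),
    FE = vapply(res, function(r) r$FE, numeric(1)),
    p = vapply(res, function(r) r$p, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$members <- I(lapply(res, function(r) r$members))
  attr(out, "background_size") <- N
  out
}

#' Reversal fraction of a disease signature under treatment
#'
#' A disease-contrast feature is reversed when the treatment contrast calls
#' it in the opposite direction:
#' `reversed = (fad_up & oe_down) | (fad_down & oe_up)`.
#'
#' @param fad_up,fad_down disjoint up/down sets from the disease contrast.
#' @param oe_up,oe_down up/down sets from the treatment contrast.
#' @return list with `fraction` (`|reversed| / (|fad_up| + |fad_down|)`) and
#'   the `reversed` feature set.
#' @export
reversal_fraction <- function(fad_up, fad_down, oe_up, oe_down) {
  if (length(intersect(fad_up, fad_down)))
    stop("fad_up and fad_down must be disjoint")
  n_fad <- length(fad_up) + length(fad_down)
  if (n_fad == 0) stop("empty disease signature")
  reversed <- union(intersect(fad_up, oe_down), intersect(fad_down, oe_up))
  list(fraction = length(reversed) / n_fad, reversed = reversed)
}
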