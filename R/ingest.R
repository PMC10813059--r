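# Readers and QC filters for MaxQuant-dialect protein-group and phosphosite
# tables, plus the matching writers used by the synthetic generators so the
# ingest path can be exercised end-to-end.

.flag_col <- function(df, name) {
  if (is.null(df[[name]])) rep(FALSE, nrow(df))
  else !is.na(df[[name]]) & trimws(as.character(df[[name]])) == "+"
}

.sample_cols <- function(header, prefix, design) {
  wanted <- paste(prefix, design$sample_id)
  miss <- design$sample_id[!(wanted %in% header)]
  if (length(miss))
    stop("design sample(s) with no matching '", prefix, "' column: ",
         paste(miss, collapse = ", "))
  wanted
}

#' Read a sample design file
#'
#' @param path TSV with header `sample_id`, `sex`, `genotype`, `treatment`.
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d)
}

#' Write a sample design file
#' @param design a design data.frame
#' @param path output TSV path
#' @export
write_design <- function(design, path) {
  utils::write.table(design[c("sample_id", "sex", "genotype", "treatment")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MaxQuant proteinGroups-style table
#'
#' Expects one `LFQ intensity <sample_id>` column per design sample plus the
#' flag columns `Potential contaminant`, `Reverse` and
#' `Only identified by site` ("+" marks). Zero intensities are recoded as
#' missing (the LFQ non-detection convention). Feature ids are taken from
#' `Gene names`, falling back to `Majority protein IDs`, and made unique.
#'
#' @param path path to the tab-separated table.
#' @param design a validated sample design.
#' @return a protein-type [intensity_table()].
#' @export
read_protein_table <- function(path, design) {
  design <- validate_design(design)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- .sample_cols(names(df), "LFQ intensity", design)
  mat <- as.matrix(df[, cols, drop = FALSE])
  mode(mat) <- "double"
  mat[mat == 0] <- NA_real_
  colnames(mat) <- design$sample_id

  ids <- df[["Gene names"]]
  if (is.null(ids)) ids <- df[["Majority protein IDs"]]
  if (is.null(ids)) ids <- sprintf("row%05d", seq_len(nrow(df)))
  ids <- as.character(ids)
  fallback <- df[["Majority protein IDs"]]
  if (!is.null(fallback)) {
    blank <- is.na(ids) | ids == ""
    ids[blank] <- as.character(fallback)[blank]
  }
  ids[is.na(ids) | ids == ""] <- sprintf("row%05d", which(is.na(ids) | ids == ""))
  ids <- make.unique(ids)
  rownames(mat) <- ids

  features <- data.frame(
    feature_id = ids,
    contaminant = .flag_col(df, "Potential contaminant"),
    reverse = .flag_col(df, "Reverse"),
    only_site = .flag_col(df, "Only identified by site"),
    stringsAsFactors = FALSE)
  intensity_table(mat, features, "protein")
}

#' QC-filter a protein table
#'
#' Removes potential contaminants, reverse decoys and proteins only
#' identified by site, then keeps proteins observed in more than half of the
#' samples (strictly greater than N/2; a protein observed in exactly half is
#' dropped).
#'
#' @param t a protein [intensity_table()].
#' @return the filtered table. Dropped-row counts are attached as attribute
#'   `"qc_dropped"`.
#' @export
qc_filter_proteins <- function(t) {
  stopifnot(inherits(t, "intensity_table"))
  fl <- t$features
  flagged <- fl$contaminant | fl$reverse | fl$only_site
  n <- ncol(t$mat)
  covered <- observed_counts(t$mat) > n / 2
  keep <- !flagged & covered
  if (!any(keep)) warning("QC removed every protein")
  out <- intensity_table(t$mat[keep, , drop = FALSE],
                         fl[keep, , drop = FALSE], t$type)
  attr(out, "qc_dropped") <- c(flagged = sum(flagged),
                               low_coverage = sum(!covered & !flagged))
  out
}

#' Read a MaxQuant Phospho(STY)Sites-style table
#'
#' Expects `Gene names`, `Amino acid`, `Position` and one
#' `Intensity <sample_id>` column per design sample, plus the usual flag
#' columns. Zeros are recoded as missing.
#'
#' @inheritParams read_protein_table
#' @return a site-type [intensity_table()] with `gene`, `residue`,
#'   `position` feature columns (rows not yet keyed/summarized; see
#'   [qc_filter_sites()]).
#' @export
read_site_table <- function(path, design) {
  design <- validate_design(design)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    mat <- matrix(numeric(0), 0, nrow(design),
                  dimnames = list(NULL, design$sample_id))
    # zero-row tables need explicit empty rownames to satisfy the container
    rownames(mat) <- character(0)
    features <- data.frame(feature_id = character(0), gene = character(0),
                           residue = character(0), position = integer(0),
                           contaminant = logical(0), reverse = logical(0),
                           only_site = logical(0), stringsAsFactors = FALSE)
    return(intensity_table(mat, features, "site"))
  }
  cols <- .sample_cols(names(df), "Intensity", design)
  mat <- as.matrix(df[, cols, drop = FALSE])
  mode(mat) <- "double"
  mat[mat == 0] <- NA_real_
  colnames(mat) <- design$sample_id
  rownames(mat) <- sprintf("siterow%05d", seq_len(nrow(df)))

  gene <- if (is.null(df[["Gene names"]])) rep("", nrow(df))
          else as.character(df[["Gene names"]])
  pos <- suppressWarnings(as.integer(as.character(df[["Position"]])))
  res <- if (is.null(df[["Amino acid"]])) rep("", nrow(df))
         else as.character(df[["Amino acid"]])
  features <- data.frame(
    feature_id = rownames(mat), gene = gene, residue = res, position = pos,
    contaminant = .flag_col(df, "Potential contaminant"),
    reverse = .flag_col(df, "Reverse"),
    only_site = .flag_col(df, "Only identified by site"),
    stringsAsFactors = FALSE)
  intensity_table(mat, features, "site")
}

#' QC-filter and summarize a phosphosite table
#'
#' Removes reverse/contaminant rows and rows lacking a gene name or an
#' integer position, then summarizes intensities per canonical site key
#' `GENE;<residue><position>` (uppercase gene, 1-based position). Rows
#' mapping to the same key — e.g. MaxQuant multiplicity rows — are collapsed
#' by summing raw intensities (configurable to the median).
#'
#' @param t a site [intensity_table()] from [read_site_table()].
#' @param summarize `"sum"` (default, additive-abundance convention) or
#'   `"median"`.
#' @return a site [intensity_table()] keyed by canonical site id; the count
#'   of rows dropped for missing annotation is attached as attribute
#'   `"qc_dropped"`.
#' @export
qc_filter_sites <- function(t, summarize = c("sum", "median")) {
  stopifnot(inherits(t, "intensity_table"))
  summarize <- match.arg(summarize)
  fl <- t$features
  flagged <- fl$contaminant | fl$reverse | fl$only_site
  bad_annot <- is.na(fl$gene) | fl$gene == "" | is.na(fl$position) |
    fl$position < 1 | !(fl$residue %in% c("S", "T", "Y"))
  keep <- !flagged & !bad_annot
  n_bad <- sum(bad_annot & !flagged)
  if (n_bad > 0)
    message(n_bad, " site row(s) dropped for missing/malformed annotation")
  if (!any(keep)) {
    out <- intensity_table(t$mat[keep, , drop = FALSE],
                           fl[keep, , drop = FALSE], "site")
    attr(out, "qc_dropped") <- c(flagged = sum(flagged), no_annot = n_bad)
    return(out)
  }
  fl <- fl[keep, , drop = FALSE]
  m <- t$mat[keep, , drop = FALSE]
  key <- paste0(toupper(fl$gene), ";", fl$residue, fl$position)

  mm <- m
  mm[is.na(mm)] <- 0
  if (summarize == "sum") {
    agg <- rowsum(mm, key, reorder = FALSE)
  } else {
    agg <- do.call(rbind, lapply(split(seq_along(key), factor(key, unique(key))),
      function(ix) apply(mm[ix, , drop = FALSE], 2, stats::median)))
    rownames(agg) <- unique(key)
  }
  agg[agg == 0] <- NA_real_  # all-missing cells back to NA
  first <- !duplicated(key)
  features <- data.frame(
    feature_id = rownames(agg),
    gene = toupper(fl$gene)[first][match(rownames(agg), key[first])],
    residue = fl$residue[first][match(rownames(agg), key[first])],
    position = fl$position[first][match(rownames(agg), key[first])],
    contaminant = FALSE, reverse = FALSE, only_site = FALSE,
    stringsAsFactors = FALSE)
  # a site never observed in any sample carries no quantitative information
  never_obs <- rowSums(!is.na(agg)) == 0
  if (any(never_obs))
    message(sum(never_obs), " site(s) with no observed intensity dropped")
  agg <- agg[!never_obs, , drop = FALSE]
  features <- features[!never_obs, , drop = FALSE]
  out <- intensity_table(agg, features, "site")
  attr(out, "qc_dropped") <- c(flagged = sum(flagged), no_annot = n_bad,
                               collapsed = sum(duplicated(key)),
                               unobserved = sum(never_obs))
  out
}

#' Write an intensity table in the MaxQuant proteinGroups dialect
#'
#' Missing intensities are written as 0 and flags as "+"/"" so the result is
#' readable by [read_protein_table()].
#' @param t a protein [intensity_table()].
#' @param path output path.
#' @export
write_protein_groups <- function(t, path) {
  stopifnot(inherits(t, "intensity_table"))
  m <- t$mat
  m[is.na(m)] <- 0
  df <- data.frame(
    `Majority protein IDs` = t$features$feature_id,
    `Gene names` = t$features$feature_id,
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m)))
    df[[paste("LFQ intensity", colnames(m)[j])]] <- m[, j]
  df[["Potential contaminant"]] <- ifelse(t$features$contaminant, "+", "")
  df[["Reverse"]] <- ifelse(t$features$reverse, "+", "")
  df[["Only identified by site"]] <- ifelse(t$features$only_site, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a site table in the MaxQuant Phospho(STY)Sites dialect
#' @param t a site [intensity_table()].
#' @param path output path.
#' @export
write_site_table <- function(t, path) {
  stopifnot(inherits(t, "intensity_table"), t$type == "site")
  m <- t$mat
  m[is.na(m)] <- 0
  df <- data.frame(
    `Gene names` = t$features$gene,
    `Amino acid` = t$features$residue,
    `Position` = t$features$position,
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m)))
    df[[paste("Intensity", colnames(m)[j])]] <- m[, j]
  df[["Potential contaminant"]] <- ifelse(t$features$contaminant, "+", "")
  df[["Reverse"]] <- ifelse(t$features$reverse, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
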