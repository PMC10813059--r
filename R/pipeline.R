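# End-to-end orchestration: ingest/simulate -> QC -> preprocess ->
# sex-stratified contrasts -> signed overlaps and reversal -> phosphosite
# stages -> gene-set projections -> consensus network -> signaling map,
# with a provenance manifest and, in synthetic mode, truth-based evaluation.

#' Run the full analysis pipeline
#'
#' The configuration is a nested list. Supply either file paths
#' (`config$proteome$path`, `config$design$path`, optional
#' `config$phospho$path`) or synthetic-mode parameter lists
#' (`config$design$synth`, `config$proteome$synth`, `config$phospho$synth`
#' passed to [make_design()], [simulate_proteome()], [simulate_phospho()]).
#' Optional stages run when their inputs are present:
#' `config$marker_sets` (named list of marker gene sets) drives cell-type
#' overrepresentation of each signature; `config$ptm_sets` drives site-set
#' enrichment scoring and differential scores; `config$panel` (a cohort
#' panel or `config$panel$synth` parameters) drives the consensus network;
#' `config$ad_sets` (+ optional `config$ad_categories`) drives the
#' signaling map.
#'
#' @param config nested configuration list. Scalar options: `alpha`
#'   (default 0.05), `use_adjusted` (FALSE), `knn_k` (10), `lowrank_rank`
#'   (NULL = automatic), `threshold_n` (4), `fdr_cut` (0.05), `seed` (1).
#' @return list of stage results plus a `manifest`; in synthetic mode also
#'   an `evaluation` (per-sex sensitivity, empirical FDR, reversal
#'   recovery).
#' @export
run_pipeline <- function(config = list()) {
  alpha <- config$alpha %||d% 0.05
  use_adjusted <- config$use_adjusted %||d% FALSE
  knn_k <- config$knn_k %||d% 10
  threshold_n <- config$threshold_n %||d% 4
  fdr_cut <- config$fdr_cut %||d% 0.05
  seed <- as.integer(config$seed %||d% 1L)

  dropped <- list()

  # --- design -------------------------------------------------------------
  if (!is.null(config$design$path)) {
    design <- read_design(config$design$path)
  } else {
    design <- do.call(make_design, c(config$design$synth %||d% list(),
                                     list(seed = seed)))
  }

  # --- proteome ingest / simulation ---------------------------------------
  truth <- NULL
  if (!is.null(config$proteome$path)) {
    prot <- read_protein_table(config$proteome$path, design)
  } else {
    sim <- do.call(simulate_proteome,
                   c(list(design = design), config$proteome$synth %||d% list(),
                     list(seed = seed)))
    prot <- sim$table
    truth <- sim$truth
  }
  prot_qc <- qc_filter_proteins(prot)
  dropped$proteome <- attr(prot_qc, "qc_dropped")
  pmat <- preprocess_proteome(prot_qc, k = knn_k)

  # --- sex-stratified contrasts and signatures ----------------------------
  contrasts <- run_contrasts(pmat, design, alpha = alpha,
                             use_adjusted = use_adjusted)
  background <- rownames(pmat)

  overlaps <- list()
  reversal <- list()
  for (sx in names(contrasts)) {
    fad <- contrasts[[sx]][["5xFADvsWT"]]$signature
    oe <- contrasts[[sx]][["5xFAD-DUSP4vs5xFAD"]]$signature
    overlaps[[sx]] <- signed_overlap(fad$up, fad$down, oe$up, oe$down,
                                     background_size = length(background))
    if (length(fad$up) + length(fad$down) > 0)
      reversal[[sx]] <- reversal_fraction(fad$up, fad$down, oe$up, oe$down)
  }

  # --- cell-type / gene-set projection ------------------------------------
  celltype <- NULL
  if (!is.null(config$marker_sets)) {
    celltype <- list()
    for (sx in names(contrasts)) {
      for (cn in names(contrasts[[sx]])) {
        sig <- contrasts[[sx]][[cn]]$signature
        for (dir in c("up", "down")) {
          nm <- paste(sx, cn, dir, sep = ".")
          celltype[[nm]] <- overrep_test(sig[[dir]], config$marker_sets,
                                         background)
        }
      }
    }
  }

  # --- phosphoproteome ----------------------------------------------------
  phospho <- NULL
  if (!is.null(config$phospho)) {
    ph_truth <- NULL
    if (!is.null(config$phospho$path)) {
      site_raw <- read_site_table(config$phospho$path, design)
    } else {
      if (is.null(truth)) stop("phospho synthesis needs a proteome truth table")
      phsim <- do.call(simulate_phospho,
                       c(list(design = design, proteome_truth = truth),
                         config$phospho$synth %||d% list(), list(seed = seed + 1L)))
      site_raw <- phsim$table
      ph_truth <- phsim$truth
    }
    site_qc <- qc_filter_sites(site_raw)
    dropped$phospho <- attr(site_qc, "qc_dropped")
    smat <- preprocess_phospho(site_qc, rank = config$lowrank_rank %||d% NULL)
    ph_contrasts <- run_contrasts(smat, design, alpha = alpha,
                                  use_adjusted = use_adjusted)
    dpp <- lapply(ph_contrasts, function(bysex)
      lapply(bysex, function(cc)
        collapse_to_dpp(cc$signature$up, cc$signature$down)))
    es <- diff_es <- NULL
    if (!is.null(config$ptm_sets)) {
      es <- site_set_scores(smat, config$ptm_sets,
                            min_overlap = config$min_overlap %||d% 5)
      if (nrow(es) >= 10)
        diff_es <- run_contrasts(es, design, alpha = alpha,
                                 use_adjusted = TRUE)
    }
    phospho <- list(matrix = smat, contrasts = ph_contrasts, dpp = dpp,
                    es = es, differential_es = diff_es, truth = ph_truth)
  }

  # --- consensus network --------------------------------------------------
  network <- NULL
  if (!is.null(config$panel)) {
    panel <- if (!is.null(config$panel$datasets)) config$panel
             else do.call(simulate_cohort_panel,
                          c(config$panel$synth %||d% list(),
                            list(seed = seed + 2L)))
    dep_f <- dep_m <- character(0)
    if ("female" %in% names(contrasts)) {
      s <- contrasts$female[["5xFAD-DUSP4vs5xFAD"]]$signature
      dep_f <- toupper(c(s$up, s$down))
    }
    if ("male" %in% names(contrasts)) {
      s <- contrasts$male[["5xFAD-DUSP4vs5xFAD"]]$signature
      dep_m <- toupper(c(s$up, s$down))
    }
    network <- consensus_network(panel$datasets, panel$target_gene,
                                 fdr_cut = fdr_cut, threshold_n = threshold_n,
                                 dep_female = dep_f, dep_male = dep_m)
  }

  # --- signaling map ------------------------------------------------------
  signal_map <- NULL
  if (!is.null(config$ad_sets) && !is.null(network)) {
    ed <- network$network$edges
    signal_map <- build_signal_map(
      pos_genes = ed$gene[ed$sign > 0], neg_genes = ed$gene[ed$sign < 0],
      ad_sets = config$ad_sets,
      background = unique(unlist(lapply(network$tables, function(t) t$gene))),
      set_categories = config$ad_categories %||d% NULL,
      fdr_cut = fdr_cut)
  }

  # --- truth evaluation (synthetic mode) ----------------------------------
  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- list()
    tr <- truth[!truth$is_decoy, , drop = FALSE]
    de_true <- tr$feature_id[tr$genotype_effect != 0]
    for (sx in names(contrasts)) {
      fad <- contrasts[[sx]][["5xFADvsWT"]]$signature
      called <- c(fad$up, fad$down)
      tp <- length(intersect(called, de_true))
      evaluation[[sx]] <- list(
        sensitivity = if (length(de_true)) tp / length(de_true) else NA_real_,
        fdr = if (length(called)) 1 - tp / length(called) else NA_real_,
        reversal_estimate = if (!is.null(reversal[[sx]]))
          reversal[[sx]]$fraction else NA_real_)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("proteosig")),
    seed = seed, alpha = alpha, use_adjusted = use_adjusted,
    knn_k = knn_k, threshold_n = threshold_n, fdr_cut = fdr_cut,
    n_samples = nrow(design), n_features_qc = length(background),
    dropped = dropped, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  list(design = design, matrix = pmat, contrasts = contrasts,
       overlaps = overlaps, reversal = reversal, celltype = celltype,
       phospho = phospho, network = network, signal_map = signal_map,
       evaluation = evaluation, truth = truth, manifest = manifest)
}

# default-or-value helper for nested config access
`%||d%` <- function(a, b) if (is.null(a)) b else a
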