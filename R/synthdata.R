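# Synthetic-data generators with planted ground truth.
#
# The generators emulate the statistical structure the downstream analysis
# assumes: a 4-group (genotype x treatment) by 2-sex design, log-normal LFQ
# intensity baselines, planted genotype effects of which a fraction is
# reversed by the treatment, intensity-dependent (MNAR) plus random (MCAR)
# missingness, MaxQuant-style decoy rows, ~3 phosphosites per parent protein,
# and a multi-cohort panel with signed correlates of a target gene.

#' Build a synthetic sample design
#'
#' Creates a sample design for a genotype (WT/TG) x treatment (CTRL/OE)
#' factorial, optionally for both sexes. The default cell counts reproduce a
#' 46-sample hippocampal study layout (female 5/5/7/7 and male 7/6/5/4 for
#' WT-CTRL/WT-OE/TG-CTRL/TG-OE).
#'
#' @param n_female,n_male named integer vectors of per-group sample counts;
#'   names must be the group labels WT-CTRL, WT-OE, TG-CTRL, TG-OE. Pass
#'   `NULL` to omit a sex entirely.
#' @param seed integer seed (the design itself is deterministic; the seed is
#'   recorded for provenance).
#' @return a design data.frame (`sample_id`, `sex`, `genotype`, `treatment`,
#'   `group`).
#' @export
make_design <- function(n_female = c("WT-CTRL" = 5, "WT-OE" = 5,
                                     "TG-CTRL" = 7, "TG-OE" = 7),
                        n_male = c("WT-CTRL" = 7, "WT-OE" = 6,
                                   "TG-CTRL" = 5, "TG-OE" = 4),
                        seed = 1L) {
  cells <- list(female = n_female, male = n_male)
  cells <- cells[!vapply(cells, is.null, logical(1))]
  if (!length(cells)) stop("at least one sex must have counts")
  rows <- list()
  for (sx in names(cells)) {
    nn <- cells[[sx]]
    bad <- setdiff(names(nn), group_levels())
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    if (any(nn < 2))
      stop("every requested (sex, group) cell needs n >= 2 ",
           "(within-group variance is required)")
    idx <- 0L
    for (g in names(nn)) {
      gt <- sub("-.*", "", g); tr <- sub(".*-", "", g)
      for (i in seq_len(nn[[g]])) {
        idx <- idx + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s%02d", toupper(substr(sx, 1, 1)), idx),
          sex = sx, genotype = gt, treatment = tr,
          stringsAsFactors = FALSE)
      }
    }
  }
  design <- do.call(rbind, rows)
  design <- validate_design(design)
  attr(design, "seed") <- seed
  design
}

#' Simulate a label-free proteome with planted effects
#'
#' Raw-scale intensities are `2^(baseline + effects + noise)` with per-feature
#' log2 baselines drawn from Normal(25, 2) to mimic LFQ intensity ranges.
#' A fraction `de_frac` of features receives a genotype (TG vs WT) effect;
#' of those, `reversal_frac` additionally receive the opposing effect in
#' treated TG samples (TG-OE), modelling treatment-driven reversal. One
#' designated feature `"TARGET"` carries a large overexpression effect in
#' treated samples of both genotypes (default `log2(22.8)`). Missingness is
#' intensity-dependent, `P(missing) = logistic(-steepness * (x - q20))` with
#' `q20` the per-sample 20th percentile of log2 intensity, plus a uniform
#' MCAR component. Decoy rows (flagged contaminant or reverse, MaxQuant "+"
#' dialect when written to disk) are appended on top of `n_features`.
#'
#' @param design a design from [make_design()].
#' @param n_features number of genuine (non-decoy) features (>= 100).
#' @param de_frac fraction of features given a genotype effect.
#' @param reversal_frac fraction of genotype-affected features whose effect is
#'   reversed under treatment.
#' @param effect_mean,effect_sd log2 magnitude distribution of planted
#'   effects (signs are assigned separately).
#' @param noise_sd residual log2 standard deviation.
#' @param mnar_steepness steepness of the logistic intensity-dependent
#'   missingness; 0 disables MNAR.
#' @param mcar_frac completely-at-random missingness fraction.
#' @param decoy_frac decoy rows appended, as a fraction of `n_features`.
#' @param target_fc raw-scale fold change planted on the `"TARGET"` feature
#'   in treated samples.
#' @param cell_types optional `c(up = "...", down = "...")` labels; when
#'   given, `cell_type_frac` of up- (down-)regulated features are labelled
#'   with the corresponding cell type, so marker-enrichment recovery can be
#'   evaluated downstream.
#' @param cell_type_frac fraction of directional features labelled.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @return list with `table` (an [intensity_table()] of raw intensities) and
#'   `truth` (data.frame: `feature_id`, `genotype_effect`, `treatment_effect`,
#'   `reversed`, `cell_type_label`, `is_decoy`).
#' @export
simulate_proteome <- function(design, n_features = 3600, de_frac = 0.2,
                              reversal_frac = 0.25,
                              effect_mean = 1, effect_sd = 0.3,
                              noise_sd = 0.5, mnar_steepness = 0.8,
                              mcar_frac = 0.02, decoy_frac = 0.05,
                              target_fc = 22.8,
                              cell_types = NULL, cell_type_frac = 0.8,
                              seed = 1L) {
  design <- validate_design(design)
  stopifnot(n_features >= 100,
            de_frac >= 0, de_frac <= 1,
            reversal_frac >= 0, reversal_frac <= 1,
            mcar_frac >= 0, mcar_frac <= 1,
            decoy_frac >= 0, decoy_frac <= 1)
  if (reversal_frac > 0 && de_frac == 0)
    stop("reversal_frac > 0 requires de_frac > 0")
  set.seed(as.integer(seed))

  ns <- nrow(design)
  ids <- c("TARGET", sprintf("GENE%04d", seq_len(n_features - 1)))
  n_decoy <- round(decoy_frac * n_features)
  decoy_ids <- if (n_decoy > 0) sprintf("DECOY%04d", seq_len(n_decoy)) else character(0)

  geno_eff <- treat_eff <- numeric(n_features)
  reversed <- logical(n_features)
  cell_lab <- rep(NA_character_, n_features)

  n_de <- round(de_frac * n_features)
  de_idx <- if (n_de > 0) sample(2:n_features, n_de) else integer(0)
  if (n_de > 0) {
    mag <- abs(stats::rnorm(n_de, effect_mean, effect_sd))
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    geno_eff[de_idx] <- sgn * mag
    n_rev <- round(reversal_frac * n_de)
    rev_idx <- if (n_rev > 0) sample(de_idx, n_rev) else integer(0)
    reversed[rev_idx] <- TRUE
    treat_eff[rev_idx] <- -geno_eff[rev_idx]
    if (!is.null(cell_types)) {
      up_i <- de_idx[geno_eff[de_idx] > 0]
      dn_i <- de_idx[geno_eff[de_idx] < 0]
      lab_up <- sample(up_i, round(cell_type_frac * length(up_i)))
      lab_dn <- sample(dn_i, round(cell_type_frac * length(dn_i)))
      cell_lab[lab_up] <- cell_types[["up"]]
      cell_lab[lab_dn] <- cell_types[["down"]]
    }
  }
  treat_eff[1] <- log2(target_fc)  # TARGET: OE effect in both genotypes

  is_tg <- design$genotype == "TG"
  is_oe <- design$treatment == "OE"
  baseline <- stats::rnorm(n_features, 25, 2)
  x <- matrix(baseline, n_features, ns)
  x <- x + outer(geno_eff, as.numeric(is_tg))
  # reversal effects act in treated TG samples; the TARGET overexpression
  # effect acts in treated samples of both genotypes
  treat_mask <- outer(reversed, is_tg & is_oe, "&")
  treat_mask[1, ] <- is_oe
  x <- x + treat_eff * treat_mask
  x <- x + matrix(stats::rnorm(n_features * ns, 0, noise_sd), n_features, ns)

  if (n_decoy > 0) {
    xd <- matrix(stats::rnorm(n_decoy, 23, 2), n_decoy, ns) +
      matrix(stats::rnorm(n_decoy * ns, 0, noise_sd), n_decoy, ns)
    x <- rbind(x, xd)
  }
  all_ids <- c(ids, decoy_ids)
  rownames(x) <- all_ids
  colnames(x) <- design$sample_id

  miss <- .plant_missingness(x, mnar_steepness, mcar_frac)
  raw <- 2^x
  raw[miss] <- NA_real_

  n_all <- n_features + n_decoy
  is_decoy <- c(rep(FALSE, n_features), rep(TRUE, n_decoy))
  decoy_kind <- character(n_decoy)
  if (n_decoy > 0)
    decoy_kind <- sample(c("contaminant", "reverse", "only_site"), n_decoy,
                         replace = TRUE, prob = c(0.5, 0.3, 0.2))
  features <- data.frame(
    feature_id = all_ids,
    contaminant = c(rep(FALSE, n_features), decoy_kind == "contaminant"),
    reverse = c(rep(FALSE, n_features), decoy_kind == "reverse"),
    only_site = c(rep(FALSE, n_features), decoy_kind == "only_site"),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    feature_id = all_ids,
    genotype_effect = c(geno_eff, rep(0, n_decoy)),
    treatment_effect = c(treat_eff, rep(0, n_decoy)),
    reversed = c(reversed, rep(FALSE, n_decoy)),
    cell_type_label = c(cell_lab, rep(NA_character_, n_decoy)),
    is_decoy = is_decoy,
    stringsAsFactors = FALSE)

  list(table = intensity_table(raw, features, "protein"), truth = truth,
       params = list(n_features = n_features, de_frac = de_frac,
                     reversal_frac = reversal_frac, noise_sd = noise_sd,
                     mnar_steepness = mnar_steepness, mcar_frac = mcar_frac,
                     decoy_frac = decoy_frac, seed = seed))
}

# logical missingness mask for a log2 intensity matrix
.plant_missingness <- function(x, mnar_steepness, mcar_frac) {
  p_mnar <- matrix(0, nrow(x), ncol(x))
  if (mnar_steepness > 0) {
    q20 <- apply(x, 2, stats::quantile, probs = 0.2)
    p_mnar <- stats::plogis(-mnar_steepness * sweep(x, 2, q20))
  }
  miss <- matrix(stats::runif(length(x)) < p_mnar, nrow(x), ncol(x))
  if (mcar_frac > 0)
    miss <- miss | matrix(stats::runif(length(x)) < mcar_frac,
                          nrow(x), ncol(x))
  miss
}

#' Expected marginal missingness of a simulated table
#'
#' Computes, from the complete latent log2 matrix that a given simulation
#' would produce, the expected marginal missingness rate
#' (MCAR + MNAR, with overlap accounted for). Used by calibration checks.
#' @param x complete log2 matrix
#' @inheritParams simulate_proteome
#' @return expected fraction of missing cells
#' @export
expected_missing_rate <- function(x, mnar_steepness, mcar_frac) {
  p_mnar <- 0
  if (mnar_steepness > 0) {
    q20 <- apply(x, 2, stats::quantile, probs = 0.2)
    p_mnar <- stats::plogis(-mnar_steepness * sweep(x, 2, q20))
  }
  mean(1 - (1 - p_mnar) * (1 - mcar_frac))
}

#' Simulate a phosphosite table from proteome ground truth
#'
#' Each parent protein (non-decoy row of the proteome truth table) spawns
#' `1 + Poisson(mean - 1)` phosphosites named `GENE;<S|T|Y><position>`
#' (residues sampled S:T:Y at 86:12:2, positions uniform on 1..2000, unique
#' within a protein). Site effects inherit the parent's planted direction
#' scaled by a positive site-level jitter; missingness is drawn
#' independently of the proteome.
#'
#' @param design a design from [make_design()].
#' @param proteome_truth truth data.frame from [simulate_proteome()]; decoy
#'   rows are ignored. Subset it to control the number of parent proteins.
#' @param sites_per_protein_mean mean sites per protein (>= 1).
#' @param jitter_sd sd of the multiplicative effect jitter.
#' @inheritParams simulate_proteome
#' @return list with `table` (site-type [intensity_table()]) and `truth`
#'   (site-level truth with a `gene` column naming the parent).
#' @export
simulate_phospho <- function(design, proteome_truth,
                             sites_per_protein_mean = 3.2,
                             jitter_sd = 0.25, noise_sd = 0.5,
                             mnar_steepness = 0.8, mcar_frac = 0.02,
                             seed = 1L) {
  design <- validate_design(design)
  stopifnot(sites_per_protein_mean >= 1)
  if (!all(c("feature_id", "genotype_effect", "treatment_effect",
             "reversed", "is_decoy") %in% names(proteome_truth)))
    stop("`proteome_truth` does not look like a proteome truth table")
  set.seed(as.integer(seed))

  parents <- proteome_truth[!proteome_truth$is_decoy, , drop = FALSE]
  if (!nrow(parents)) stop("no non-decoy parent proteins")
  n_sites_per <- 1L + stats::rpois(nrow(parents), sites_per_protein_mean - 1)
  parent_idx <- rep(seq_len(nrow(parents)), n_sites_per)
  n_sites <- length(parent_idx)

  residues <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                     prob = c(0.86, 0.12, 0.02))
  positions <- unlist(lapply(n_sites_per, function(k) sample.int(2000, k)),
                      use.names = FALSE)
  gene <- parents$feature_id[parent_idx]
  site_id <- paste0(toupper(gene), ";", residues, positions)

  jit <- pmax(0.1, stats::rnorm(n_sites, 1, jitter_sd))
  geno_eff <- parents$genotype_effect[parent_idx] * jit
  treat_eff <- parents$treatment_effect[parent_idx] * jit
  reversed <- parents$reversed[parent_idx]
  is_target <- gene == "TARGET"

  ns <- nrow(design)
  is_tg <- design$genotype == "TG"
  is_oe <- design$treatment == "OE"
  baseline <- stats::rnorm(n_sites, 25, 2)
  x <- matrix(baseline, n_sites, ns)
  x <- x + outer(geno_eff, as.numeric(is_tg))
  treat_mask <- outer(reversed, is_tg & is_oe, "&")
  treat_mask[is_target, ] <- matrix(is_oe, sum(is_target), ns, byrow = TRUE)
  x <- x + treat_eff * treat_mask
  x <- x + matrix(stats::rnorm(n_sites * ns, 0, noise_sd), n_sites, ns)
  rownames(x) <- site_id
  colnames(x) <- design$sample_id

  miss <- .plant_missingness(x, mnar_steepness, mcar_frac)
  raw <- 2^x
  raw[miss] <- NA_real_

  features <- data.frame(
    feature_id = site_id, gene = toupper(gene), residue = residues,
    position = positions, contaminant = FALSE, reverse = FALSE,
    only_site = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(
    feature_id = site_id, gene = toupper(gene),
    genotype_effect = geno_eff, treatment_effect = treat_eff,
    reversed = reversed, is_decoy = FALSE, stringsAsFactors = FALSE)

  list(table = intensity_table(raw, features, "site"), truth = truth,
       params = list(sites_per_protein_mean = sites_per_protein_mean,
                     seed = seed))
}

#' Simulate a multi-cohort expression panel around a target gene
#'
#' Builds `k_datasets` gene-by-sample matrices sharing a `"TARGET"` gene.
#' Designated positive/negative correlates are generated as
#' `sign * rho * target + sqrt(1 - rho^2) * noise` in exactly `support`
#' randomly chosen datasets each, and as independent noise elsewhere; all
#' other genes are independent standard normals.
#'
#' @param k_datasets number of datasets (>= 1).
#' @param n_genes number of non-target genes per dataset.
#' @param n_samples_per samples per dataset (>= 10).
#' @param pos_correlates,neg_correlates numbers of planted signed correlates.
#' @param support number of datasets (<= `k_datasets`) in which each planted
#'   correlate is active.
#' @param rho planted correlation magnitude, |rho| < 1.
#' @param seed integer seed.
#' @return list with `datasets` (list of gene x sample matrices),
#'   `target_gene` and `planted_sign` (genes x datasets matrix of -1/0/+1).
#' @export
simulate_cohort_panel <- function(k_datasets = 8, n_genes = 1000,
                                  n_samples_per = 50, pos_correlates = 10,
                                  neg_correlates = 10, support = 6,
                                  rho = 0.8, seed = 1L) {
  stopifnot(k_datasets >= 1, n_samples_per >= 10,
            support >= 1, support <= k_datasets, abs(rho) < 1)
  if (pos_correlates + neg_correlates >= n_genes)
    stop("pos_correlates + neg_correlates must be < n_genes")
  set.seed(as.integer(seed))

  genes <- sprintf("G%04d", seq_len(n_genes))
  pos_genes <- genes[seq_len(pos_correlates)]
  neg_genes <- genes[pos_correlates + seq_len(neg_correlates)]
  planted <- matrix(0L, n_genes, k_datasets,
                    dimnames = list(genes, paste0("ds", seq_len(k_datasets))))
  for (g in c(pos_genes, neg_genes)) {
    ds <- sample.int(k_datasets, support)
    planted[g, ds] <- if (g %in% pos_genes) 1L else -1L
  }

  datasets <- vector("list", k_datasets)
  for (d in seq_len(k_datasets)) {
    tgt <- stats::rnorm(n_samples_per)
    m <- matrix(stats::rnorm(n_genes * n_samples_per), n_genes, n_samples_per,
                dimnames = list(genes, sprintf("s%03d", seq_len(n_samples_per))))
    act <- which(planted[, d] != 0L)
    for (g in act)
      m[g, ] <- planted[g, d] * rho * tgt + sqrt(1 - rho^2) * m[g, ]
    datasets[[d]] <- rbind(TARGET = tgt, m)
  }
  names(datasets) <- colnames(planted)
  list(datasets = datasets, target_gene = "TARGET", planted_sign = planted)
}

#' Derive cell-type marker sets from a proteome truth table
#'
#' Collects features per planted `cell_type_label` into a marker collection,
#' optionally padded with additional decoy marker sets of unaffected features
#' so that enrichment ranking is non-trivial.
#'
#' @param truth truth table from [simulate_proteome()].
#' @param n_extra_sets number of decoy marker sets drawn from unlabelled,
#'   unaffected features.
#' @param set_size size of each decoy set.
#' @param seed integer seed for the decoy draw.
#' @return named list of marker gene vectors.
#' @export
marker_sets_from_truth <- function(truth, n_extra_sets = 4, set_size = 50,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  labs <- unique(stats::na.omit(truth$cell_type_label))
  sets <- lapply(labs, function(l)
    truth$feature_id[!is.na(truth$cell_type_label) & truth$cell_type_label == l])
  names(sets) <- labs
  pool <- truth$feature_id[is.na(truth$cell_type_label) & !truth$is_decoy &
                             truth$genotype_effect == 0]
  for (i in seq_len(n_extra_sets)) {
    sets[[paste0("other", i)]] <- sample(pool, min(set_size, length(pool)))
  }
  sets
}
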