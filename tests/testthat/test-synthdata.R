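# Synthetic generators: design construction, planted effects, missingness,
# phosphosite spawning, cohort panels.

test_that("design construction matches the requested cell counts", {
  d <- make_design(
    n_female = c("TG-OE" = 7, "TG-CTRL" = 7, "WT-CTRL" = 5, "WT-OE" = 5),
    n_male = c("TG-OE" = 4, "TG-CTRL" = 5, "WT-CTRL" = 7, "WT-OE" = 6))
  expect_equal(nrow(d), 46)
  expect_equal(sum(d$sex == "female"), 24)
  expect_true(all(d$group %in% GROUPS))
  expect_false(anyDuplicated(d$sample_id) > 0)

  d2 <- balanced_design(3)
  expect_equal(nrow(d2), 24)

  expect_error(make_design(n_female = c("WT-CTRL" = 1, "TG-CTRL" = 3),
                           n_male = NULL), "n >= 2")
  expect_error(make_design(n_female = c(bogus = 3), n_male = NULL), "group label")
})

test_that("null configuration yields a complete matrix with no effects", {
  d <- balanced_design(3, "female")
  sim <- simulate_proteome(d, n_features = 150, de_frac = 0, reversal_frac = 0,
                           mnar_steepness = 0, mcar_frac = 0, decoy_frac = 0,
                           seed = 11)
  expect_false(anyNA(sim$table$mat))
  nondecoy <- sim$truth[!sim$truth$is_decoy & sim$truth$feature_id != "TARGET", ]
  expect_true(all(nondecoy$genotype_effect == 0))
  expect_true(all(nondecoy$treatment_effect == 0))
  expect_error(simulate_proteome(d, 150, de_frac = 0, reversal_frac = 0.2),
               "reversal_frac")
})

test_that("planted effect bookkeeping is exact", {
  d <- balanced_design(3, "female")
  sim <- simulate_proteome(d, n_features = 2000, de_frac = 0.2,
                           reversal_frac = 0.25, seed = 5)
  tr <- sim$truth[!sim$truth$is_decoy, ]
  expect_equal(sum(tr$genotype_effect != 0), 400)
  expect_equal(sum(tr$reversed), 100)
  expect_true(all(sign(tr$treatment_effect[tr$reversed]) ==
                    -sign(tr$genotype_effect[tr$reversed])))
  expect_true(all(tr$genotype_effect[tr$reversed] != 0))
  expect_true(all(sim$truth$genotype_effect[sim$truth$is_decoy] == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  d <- balanced_design(2)
  a <- simulate_proteome(d, n_features = 120, seed = 42)
  b <- simulate_proteome(d, n_features = 120, seed = 42)
  expect_identical(a$table$mat, b$table$mat)
  expect_identical(a$truth, b$truth)
  c <- simulate_proteome(d, n_features = 120, seed = 43)
  expect_false(identical(a$table$mat, c$table$mat))
})

test_that("marginal missingness matches its analytic expectation", {
  d <- balanced_design(3)
  for (pars in list(c(0.8, 0.02), c(0, 0.1), c(1.5, 0))) {
    sim <- simulate_proteome(d, n_features = 2000, de_frac = 0,
                             reversal_frac = 0, decoy_frac = 0,
                             mnar_steepness = pars[1], mcar_frac = pars[2],
                             seed = 7)
    # twin run without missingness exposes the identical latent matrix
    sim0 <- simulate_proteome(d, n_features = 2000, de_frac = 0,
                              reversal_frac = 0, decoy_frac = 0,
                              mnar_steepness = 0, mcar_frac = 0, seed = 7)
    latent <- log2(sim0$table$mat)
    expected <- expected_missing_rate(latent, pars[1], pars[2])
    observed <- mean(is.na(sim$table$mat))
    expect_lt(abs(observed - expected), 0.02)
  }
})

test_that("the overexpressed target recovers its planted fold change", {
  d <- make_design()  # full two-sex study layout
  sim <- simulate_proteome(d, n_features = 500, noise_sd = 0.5,
                           mnar_steepness = 0, mcar_frac = 0, seed = 21)
  x <- log2(sim$table$mat)
  oe <- d$sample_id[d$group == "TG-OE"]
  ctrl <- d$sample_id[d$group == "TG-CTRL"]
  diff <- mean(x["TARGET", oe]) - mean(x["TARGET", ctrl])
  sem <- 0.5 * sqrt(1 / length(oe) + 1 / length(ctrl))
  expect_lt(abs(diff - log2(22.8)), 3 * sem)
})

test_that("per-feature log2FC averaged over seeds recovers planted effects", {
  d <- balanced_design(6, "female")
  tg <- d$sample_id[d$genotype == "TG" & d$treatment == "CTRL"]
  wt <- d$sample_id[d$genotype == "WT" & d$treatment == "CTRL"]
  err <- NULL
  for (s in 1:50) {
    sim <- simulate_proteome(d, n_features = 150, de_frac = 0.3,
                             reversal_frac = 0, effect_mean = 1,
                             effect_sd = 0.2, noise_sd = 0.5,
                             mnar_steepness = 0, mcar_frac = 0,
                             decoy_frac = 0, seed = 100 + s)
    x <- log2(sim$table$mat)
    fc <- rowMeans(x[, tg]) - rowMeans(x[, wt])
    e <- fc - sim$truth$genotype_effect
    err <- if (is.null(err)) e else err + e
  }
  mean_err <- err / 50
  expect_lt(mean(abs(mean_err)), 0.05)
  expect_lt(sqrt(mean(mean_err^2)), 0.05)
})

test_that("phosphosite spawning follows the site-count model and id format", {
  d <- balanced_design(2, "female")
  prot <- simulate_proteome(d, n_features = 2222, de_frac = 0.1,
                            decoy_frac = 0, seed = 2)
  ph <- simulate_phospho(d, prot$truth, sites_per_protein_mean = 3.2, seed = 3)
  n_sites <- nrow(ph$table$mat)
  expect_lt(abs(n_sites - 2222 * 3.2), 3 * sqrt(2222 * 3.2))
  expect_true(all(grepl("^.+;[STY][0-9]+$", ph$truth$feature_id)))
  parsed <- parse_site_id(ph$truth$feature_id)
  expect_true(all(parsed$position >= 1 & parsed$position <= 2000))
  expect_true(all(sign(ph$truth$genotype_effect) ==
                    sign(prot$truth$genotype_effect[
                      match(ph$truth$gene, toupper(prot$truth$feature_id))])))

  ph1 <- simulate_phospho(d, prot$truth[1:50, ], sites_per_protein_mean = 1,
                          seed = 4)
  expect_equal(nrow(ph1$table$mat), 50)
  expect_error(simulate_phospho(d, data.frame(x = 1)), "truth table")
})

test_that("cohort panels plant signed correlates with the requested support", {
  pan <- simulate_cohort_panel(k_datasets = 4, n_genes = 100,
                               n_samples_per = 20, pos_correlates = 5,
                               neg_correlates = 3, support = 2, rho = 0.7,
                               seed = 6)
  expect_length(pan$datasets, 4)
  expect_true(all(vapply(pan$datasets,
                         function(m) "TARGET" %in% rownames(m), logical(1))))
  expect_equal(sum(pan$planted_sign == 1), 5 * 2)
  expect_equal(sum(pan$planted_sign == -1), 3 * 2)
  # planted correlations materialize near rho in their supported datasets
  for (dnm in colnames(pan$planted_sign)) {
    act <- which(pan$planted_sign[, dnm] != 0)
    for (g in act) {
      r <- cor(pan$datasets[[dnm]][rownames(pan$planted_sign)[g], ],
               pan$datasets[[dnm]]["TARGET", ])
      expect_equal(sign(r), as.numeric(pan$planted_sign[g, dnm]))
    }
  }
  expect_error(simulate_cohort_panel(n_genes = 10, pos_correlates = 6,
                                     neg_correlates = 6), "n_genes")
})
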