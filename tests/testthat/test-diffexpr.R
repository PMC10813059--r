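# Empirical-Bayes moderated t: closed-form correctness, calibration,
# shrinkage limits, signature calling.

random_fixture <- function(n_feat = 200, n_per = 6, seed = 1) {
  set.seed(seed)
  d <- balanced_design(n_per, "female")
  # heterogeneous variances so the prior df estimate is finite
  sds <- sqrt(1 / stats::rgamma(n_feat, shape = 4, rate = 2))
  m <- matrix(stats::rnorm(n_feat * nrow(d), 0, rep(sds, nrow(d))),
              n_feat, nrow(d),
              dimnames = list(sprintf("f%04d", seq_len(n_feat)), d$sample_id))
  list(design = d, mat = m)
}

test_that("moderated t matches the independent closed-form oracle", {
  fx <- random_fixture(200, 6, seed = 2)
  d <- fx$design
  idA <- d$sample_id[d$group == "TG-CTRL"]
  idB <- d$sample_id[d$group == "WT-CTRL"]
  dt <- fit_moderated_t(fx$mat, d, "TG-CTRL", "WT-CTRL")
  orc <- oracle_moderated_t(fx$mat, idA, idB)
  fit <- attr(dt, "fit")
  expect_lt(abs(fit$d0 - orc$d0) / orc$d0, 1e-8)
  expect_lt(abs(fit$s2_prior - orc$s2_prior) / orc$s2_prior, 1e-8)
  expect_lt(max(abs(dt$t - orc$t) / pmax(abs(orc$t), 1e-10)), 1e-8)
  expect_lt(max(abs(dt$p - orc$p) / orc$p), 1e-8)
})

test_that("moderated t agrees with the reference eBayes implementation", {
  fx <- random_fixture(150, 5, seed = 3)
  d <- fx$design
  idA <- d$sample_id[d$group == "TG-OE"]
  idB <- d$sample_id[d$group == "TG-CTRL"]
  dt <- fit_moderated_t(fx$mat, d, "TG-OE", "TG-CTRL")

  sub <- fx$mat[, c(idA, idB)]
  grp <- factor(rep(c("A", "B"), c(length(idA), length(idB))), c("B", "A"))
  fit <- limma::eBayes(limma::lmFit(sub, stats::model.matrix(~grp)))
  expect_equal(attr(dt, "fit")$d0, fit$df.prior, tolerance = 1e-10)
  expect_equal(attr(dt, "fit")$s2_prior, fit$s2.prior, tolerance = 1e-10)
  expect_equal(dt$log2FC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(dt$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(dt$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("identical group means give zero statistics", {
  fx <- random_fixture(50, 4, seed = 4)
  d <- fx$design
  m <- fx$mat
  idA <- d$sample_id[d$group == "TG-CTRL"]
  idB <- d$sample_id[d$group == "WT-CTRL"]
  m["f0001", idA] <- c(1, 2, 3, 4)
  m["f0001", idB] <- c(4, 3, 2, 1)
  dt <- fit_moderated_t(m, d, "TG-CTRL", "WT-CTRL")
  i <- which(dt$feature_id == "f0001")
  expect_equal(dt$log2FC[i], 0)
  expect_equal(dt$t[i], 0)
  expect_equal(dt$p[i], 1)
})

test_that("equal sample variances collapse shrinkage to the pooled t", {
  d <- balanced_design(4, "male")
  idA <- d$sample_id[d$group == "TG-CTRL"]
  idB <- d$sample_id[d$group == "WT-CTRL"]
  set.seed(5)
  # 20 features, every one with the same within-group sample variance:
  # reuse one centred residual pattern, shift means per feature
  base <- stats::rnorm(8)
  resid <- c(scale(base[1:4], scale = FALSE), scale(base[5:8], scale = FALSE))
  m <- t(sapply(1:20, function(i) resid + rep(stats::rnorm(2), each = 4)))
  colnames(m) <- c(idA, idB)
  rownames(m) <- paste0("f", 1:20)
  full <- matrix(stats::rnorm(20 * nrow(d)), 20, nrow(d),
                 dimnames = list(rownames(m), d$sample_id))
  full[, colnames(m)] <- m
  dt <- fit_moderated_t(full, d, "TG-CTRL", "WT-CTRL")
  fit <- attr(dt, "fit")
  s2 <- sum(resid[1:4]^2 + resid[5:8]^2) / 6
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s2_prior, s2, tolerance = 1e-12)
  # moderated t equals the ordinary pooled t feature by feature
  ord_t <- apply(full[, c(idA, idB)], 1, function(v) {
    stats::t.test(v[1:4], v[5:8], var.equal = TRUE)$statistic
  })
  expect_equal(dt$t, unname(ord_t), tolerance = 1e-10)
})

test_that("statistics are invariant to a global additive shift", {
  fx <- random_fixture(80, 4, seed = 6)
  dt1 <- fit_moderated_t(fx$mat, fx$design, "TG-CTRL", "WT-CTRL")
  dt2 <- fit_moderated_t(fx$mat + 5, fx$design, "TG-CTRL", "WT-CTRL")
  expect_equal(dt1$t, dt2$t, tolerance = 1e-12)
  expect_equal(dt1$p, dt2$p, tolerance = 1e-12)
})

test_that("BH q-values dominate p-values and are monotone in p-rank", {
  fx <- random_fixture(120, 4, seed = 7)
  dt <- fit_moderated_t(fx$mat, fx$design, "TG-OE", "WT-OE")
  expect_true(all(dt$q >= dt$p - 1e-15))
  expect_true(max(dt$q) <= 1)
  ord <- order(dt$p)
  expect_true(all(diff(dt$q[ord]) >= -1e-15))
  expect_equal(dt$q, stats::p.adjust(dt$p, "BH"))
})

test_that("signature calling uses strict thresholds and sign", {
  dt <- structure(data.frame(
    feature_id = c("a", "b", "c", "d"),
    log2FC = c(1, -1, 2, 0.5),
    t = c(3, -3, 4, 1), df_total = 10,
    p = c(0.049, 0.01, 0.05, 0.2),
    q = c(0.09, 0.04, 0.09, 0.3)), class = c("diff_table", "data.frame"))
  sig <- call_signature(dt, alpha = 0.05)
  expect_setequal(sig$up, "a")   # p = 0.05 exactly is not called
  expect_setequal(sig$down, "b")
  sig_adj <- call_signature(dt, alpha = 0.05, use_adjusted = TRUE)
  expect_setequal(sig_adj$down, "b")
  expect_length(sig_adj$up, 0)
})

test_that("sex stratification subsets samples before fitting", {
  d <- balanced_design(4)
  set.seed(8)
  m <- matrix(stats::rnorm(60 * nrow(d)), 60, nrow(d),
              dimnames = list(paste0("f", 1:60), d$sample_id))
  # plant an effect only in female TG-CTRL
  f_tg <- d$sample_id[d$sex == "female" & d$group == "TG-CTRL"]
  m["f1", f_tg] <- m["f1", f_tg] + 5
  dtf <- fit_moderated_t(m, d, "TG-CTRL", "WT-CTRL", sex = "female")
  dtm <- fit_moderated_t(m, d, "TG-CTRL", "WT-CTRL", sex = "male")
  expect_lt(dtf$p[dtf$feature_id == "f1"], 0.001)
  expect_gt(dtm$p[dtm$feature_id == "f1"], 0.05)
  expect_error(fit_moderated_t(m, d, "TG-CTRL", "WT-CTRL", sex = "other"))
})

test_that("sign of t always matches sign of the fold change", {
  fx <- random_fixture(100, 3, seed = 9)
  dt <- fit_moderated_t(fx$mat, fx$design, "TG-CTRL", "WT-CTRL")
  expect_true(all(sign(dt$t) == sign(dt$log2FC)))
})
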