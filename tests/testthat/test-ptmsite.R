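# Site-id parsing, DPP collapse, and the kernel-ECDF enrichment walk.

test_that("site ids parse in the canonical GENE;residue+position form", {
  p <- parse_site_id(c("APP;S441", "MAPT;T231", "GRIN2B;Y1472", "bad", "X;B9"))
  expect_equal(p$gene[1:3], c("APP", "MAPT", "GRIN2B"))
  expect_equal(p$residue[1:3], c("S", "T", "Y"))
  expect_equal(p$position[1:3], c(441L, 231L, 1472L))
  expect_true(all(is.na(p$gene[4:5])))
})

test_that("DPP collapse takes the union of parent proteins per direction", {
  out <- suppressMessages(collapse_to_dpp(
    deptm_up = c("APP;S441", "MAPT;S10", "MAPT;S20", "junk"),
    deptm_down = c("MAPT;T231", "STAT3;Y705")))
  expect_setequal(out$up, c("APP", "MAPT"))
  expect_setequal(out$down, c("MAPT", "STAT3"))
  expect_setequal(out$ambivalent, "MAPT")
  expect_equal(attr(out, "skipped"), 1)
})

test_that("the enrichment walk reproduces a hand-enumerated table", {
  # 6 features, set at ranks 1-3, symmetric rank weights |P/2 - rank| =
  # (2, 1, 0, 1, 2, 3), tau = 1. In-set increments r/3: 2/3, 1/3, 0;
  # out-of-set decrements 1/3. Running sum:
  # 2/3, 1, 1, 2/3, 1/3, 0 -> max + min deviation = 1 + 0 = 1
  es <- es_walk(r = c(2, 1, 0, 1, 2, 3),
                inset = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(es, 1)

  # set at the bottom three ranks: walk is -1/3, -2/3, -1, -2/3 (+2/6... )
  # steps: -1/3, -1/3, -1/3, +1/6, +2/6, +3/6; cumsum minimum -1, max 0
  es2 <- es_walk(r = c(2, 1, 0, 1, 2, 3),
                 inset = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(es2, -1)

  # interleaved set: steps +2/5, -1/3, +0, -1/3, +3/5... with weights
  # (2,1,0,1,2,3) and set at ranks {1,3,5}: denom = 2+0+2 = 4
  # steps: +1/2, -1/3, 0, -1/3, +1/2, -1/3
  # cumsum: 1/2, 1/6, 1/6, -1/6, 1/3, 0 -> ES = 1/2 + (-1/6) = 1/3
  es3 <- es_walk(r = c(2, 1, 0, 1, 2, 3),
                 inset = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(es3, 1 / 2 - 1 / 6, tolerance = 1e-12)

  expect_error(es_walk(1:3, c(TRUE, TRUE, TRUE)), "covers")
  expect_error(es_walk(1:3, c(FALSE, FALSE, FALSE)), "empty")
})

make_oriented_matrix <- function() {
  # 6 sites x 4 samples; set sites peak in sample s1 and dip in s2,
  # non-set sites the reverse, so the set tops the s1 ranking and sits at
  # the bottom of the s2 ranking
  m <- rbind(
    a1 = c(9, 1, 5, 5), a2 = c(8, 2, 5, 5), a3 = c(9.5, 0.5, 5, 5),
    b1 = c(1, 9, 5, 5), b2 = c(2, 8, 5, 5), b3 = c(0.5, 9.5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  m + matrix(seq(0, 0.23, 0.01), 6, 4)  # break exact ties deterministically
}

test_that("set scores orient positively where member sites rank high", {
  m <- make_oriented_matrix()
  es <- site_set_scores(m, list(A = c("a1", "a2", "a3")), min_overlap = 3)
  expect_gt(es["A", "s1"], 0)
  expect_lt(es["A", "s2"], 0)
  expect_true(all(es >= -1 & es <= 1))
})

test_that("scores are invariant to per-feature positive affine transforms", {
  set.seed(14)
  m <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(paste0("site", 1:20), paste0("s", 1:8)))
  sets <- list(S1 = paste0("site", 1:6), S2 = paste0("site", c(2, 9, 15, 18, 20)))
  es1 <- site_set_scores(m, sets, min_overlap = 5)
  a <- runif(20, 0.5, 3); b <- rnorm(20, 0, 10)
  m2 <- m * a + b
  es2 <- site_set_scores(m2, sets, min_overlap = 5)
  expect_equal(es1, es2, tolerance = 1e-9)
})

test_that("sample permutation permutes score columns identically", {
  set.seed(15)
  m <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("site", 1:15), paste0("s", 1:6)))
  sets <- list(S = paste0("site", 1:5))
  perm <- c(3, 1, 6, 2, 5, 4)
  es <- site_set_scores(m, sets, min_overlap = 3)
  esp <- site_set_scores(m[, perm], sets, min_overlap = 3)
  expect_equal(esp, es[, perm, drop = FALSE], ignore_attr = TRUE)
})

test_that("direction annotations reflect sites before ranking", {
  set.seed(16)
  m <- matrix(rnorm(12 * 6), 12, 6,
              dimnames = list(paste0("site", 1:12), paste0("s", 1:6)))
  ids <- paste0("site", 1:4)
  plain <- ids
  attr(plain, "direction") <- stats::setNames(rep(1, 4), ids)
  flipped <- ids
  attr(flipped, "direction") <- stats::setNames(c(1, 1, -1, -1), ids)
  es_plain <- site_set_scores(m, list(S = ids), min_overlap = 3)
  es_all_pos <- site_set_scores(m, list(S = plain), min_overlap = 3)
  es_flip <- site_set_scores(m, list(S = flipped), min_overlap = 3)
  expect_equal(es_plain, es_all_pos)          # all-(+1) equals direction-naive
  expect_false(isTRUE(all.equal(es_plain, es_flip)))
})

test_that("sets below min_overlap are dropped and constant rows excluded", {
  set.seed(17)
  m <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(paste0("site", 1:10), paste0("s", 1:5)))
  m["site10", ] <- 7  # constant
  sets <- list(big = paste0("site", 1:5), tiny = c("site1", "site2"),
               unmatched = c("zz1", "zz2", "zz3"))
  expect_warning(site_set_scores(m, sets, min_overlap = 3), "constant")
  es <- suppressWarnings(site_set_scores(m, sets, min_overlap = 3))
  expect_equal(rownames(es), "big")
})

test_that("differential scoring flags a planted set shift", {
  d <- balanced_design(6, "female")
  set.seed(18)
  es <- matrix(rnorm(50 * nrow(d), 0, 0.15), 50, nrow(d),
               dimnames = list(paste0("set", 1:50), d$sample_id))
  tg <- d$sample_id[d$genotype == "TG"]
  es["set1", tg] <- es["set1", tg] + 0.4
  dt <- differential_scores(es, d, "TG-CTRL", "WT-CTRL")
  top <- dt$feature_id[which.min(dt$p)]
  expect_equal(top, "set1")
  expect_lt(dt$q[dt$feature_id == "set1"], 0.05)
})

test_that("permuted group labels give uniform p-values", {
  d <- balanced_design(6, "female")
  ps <- c()
  for (s in 1:20) {
    set.seed(200 + s)
    es <- matrix(rnorm(40 * nrow(d), 0, 0.2), 40, nrow(d),
                 dimnames = list(paste0("set", 1:40), d$sample_id))
    dt <- differential_scores(es, d, "TG-CTRL", "WT-CTRL")
    ps <- c(ps, dt$p)
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
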