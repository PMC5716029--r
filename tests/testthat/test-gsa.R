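test_that("TMM factors behave as a composition correction", {
  same <- matrix(rep(c(10, 50, 200, 5, 80), 4), ncol = 4)
  expect_equal(tmm_factors(same), rep(1, 4))
  # pure depth difference: factors stay ~1 (library size, not composition)
  set.seed(81)
  y <- matrix(rnbinom(2000 * 2, mu = 100, size = 10), 2000)
  y2 <- cbind(y[, 1], rnbinom(2000, mu = 200, size = 10))
  f <- tmm_factors(y2)
  expect_equal(f[2] / f[1], 1, tolerance = 0.05)
  # 20% of genes 8-fold elevated in one sample: under the library-size
  # multiplier convention that sample's factor falls below 1 (its unchanged
  # genes occupy a smaller share of the library); hand value on a 50-gene
  # instance: untrimmed genes have M = log2(2500/6000), so the raw factor is
  # 2500/6000 before geometric-mean rescaling
  comp <- cbind(a = rep(50, 50), b = rep(50, 50))
  comp[1:10, "b"] <- comp[1:10, "b"] * 8
  fc <- tmm_factors(comp)
  expect_lt(fc[["b"]] / fc[["a"]], 1)
  expect_equal(fc[["b"]] / fc[["a"]], 2500 / 6000, tolerance = 1e-6)
  expect_equal(exp(mean(log(tmm_factors(comp)))), 1, tolerance = 1e-12)
})

test_that("TMM factors match the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(82)
  y <- matrix(rnbinom(4000 * 4, mu = 80, size = 5), 4000)
  y[1:800, 2] <- y[1:800, 2] * 6
  ours <- tmm_factors(y)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(y))$samples$norm.factors
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("voom weights are positive, finite and flat for flat data", {
  des <- cbind(1, rep(0:1, each = 2))
  flat <- matrix(100, 50, 4, dimnames = list(sprintf("g%02d", 1:50), NULL))
  vw <- voom_weights(flat, des, norm_factors = rep(1, 4))
  expect_true(all(vw$weights > 0), all(is.finite(vw$weights)))
  expect_equal(max(vw$weights) / min(vw$weights), 1, tolerance = 1e-6)
  set.seed(83)
  y <- matrix(rnbinom(2000 * 4, mu = 2^runif(2000, 2, 10), size = 5), 2000,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  vw2 <- voom_weights(y, des, norm_factors = rep(1, 4))
  expect_true(all(vw2$weights > 0 & is.finite(vw2$weights)))
  # mean-variance trend decreases with abundance over the well-sampled range
  mid <- rowMeans(vw2$log_cpm)
  lowq <- mid < quantile(mid, 0.2)
  topq <- mid > quantile(mid, 0.8)
  expect_gt(mean(vw2$weights[topq, ]), mean(vw2$weights[lowq, ]))
  expect_error(voom_weights(y, cbind(1, 1, 0, 0)[rep(1, 4), , drop = FALSE]),
               class = "niche_input_error")
})

test_that("voom log-cpm and weights match the established implementation", {
  skip_if_not_installed("limma")
  set.seed(84)
  y <- matrix(rnbinom(3000 * 6, mu = 2^runif(3000, 3, 10), size = 8), 3000,
              dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:6)))
  des <- cbind(1, rep(0:1, each = 3))
  f <- tmm_factors(y)
  ours <- voom_weights(y, des, norm_factors = f)
  ref <- limma::voom(y, des, lib.size = colSums(y) * f)
  expect_equal(ours$log_cpm, ref$E, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ours$weights, ref$weights, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("every rotation preserves the residual sum of squares", {
  set.seed(85)
  n <- 6
  y <- matrix(rnorm(100 * n), 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:n)))
  w <- matrix(runif(100 * n, 0.5, 2), 100, dimnames = dimnames(y))
  des <- cbind(1, rep(0:1, each = 3))
  r <- roast_set(y, w, des, c(0, 1), sprintf("g%03d", 1:30),
                 n_rotations = 200, seed = 86, keep_rotations = TRUE)
  recon <- r$rot_z1^2 + r$rot_rss
  expect_equal(recon, matrix(r$rss_total, 30, 200), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gte(r$p_up, 1 / 201)
  expect_gte(r$p_mixed, 1 / 201)
})

test_that("rotation p-values are uniform under the null", {
  des <- cbind(1, rep(0:1, each = 3))
  ps <- sapply(1:200, function(i) {
    set.seed(2000 + i)
    y <- matrix(rnorm(150 * 6), 150,
                dimnames = list(sprintf("g%03d", 1:150), paste0("s", 1:6)))
    w <- matrix(1, 150, 6, dimnames = dimnames(y))
    roast_set(y, w, des, c(0, 1), sprintf("g%03d", 1:30),
              n_rotations = 299, seed = 3000 + i)$p_up
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a coordinated shift in a gene set is detected", {
  des <- cbind(1, rep(0:1, each = 3))
  hits <- sapply(1:20, function(s) {
    set.seed(s)
    y <- matrix(rnorm(300 * 6), 300,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
    y[1:30, 4:6] <- y[1:30, 4:6] + 0.5
    w <- matrix(1, 300, 6, dimnames = dimnames(y))
    roast_set(y, w, des, c(0, 1), sprintf("g%03d", 1:30),
              n_rotations = 999, seed = s + 400)$p_up < 0.05
  })
  expect_gte(mean(hits), 0.7)
})

test_that("pathway screening adjusts per direction and reports contributors", {
  set.seed(87)
  y <- matrix(rnorm(200 * 6), 200,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  y[1:25, 4:6] <- y[1:25, 4:6] + 1.5
  w <- matrix(1, 200, 6, dimnames = dimnames(y))
  des <- cbind(1, rep(0:1, each = 3))
  sets <- c(list(signal = sprintf("g%03d", 1:25)),
            lapply(1:19, function(i) sample(rownames(y)[26:200], 25)))
  names(sets)[-1] <- paste0("null", 1:19)
  scr <- pathway_screen(sets, y, w, des, c(0, 1), n_rotations = 499,
                        seed = 88)
  expect_true(scr$significant_up[scr$set_name == "signal"])
  expect_lte(sum(scr$significant_up), 2)
  contrib <- strsplit(scr$contributing_genes[scr$set_name == "signal"], ",")[[1]]
  expect_true(all(contrib %in% sets$signal))
  expect_gte(length(contrib), 5)
  # single set: adjusted equals raw
  one <- pathway_screen(sets["signal"], y, w, des, c(0, 1),
                        n_rotations = 199, seed = 89)
  expect_equal(one$padj_up, one$p_up)
})
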