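test_that("size factors follow median-of-ratios with its equivariances", {
  m <- rbind(g1 = c(2, 4), g2 = c(8, 16))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)
  same <- rbind(g1 = c(5, 5), g2 = c(9, 9), g3 = c(2, 2))
  expect_equal(unname(size_factors(same)), c(1, 1))
  # scaling one column scales its factor
  sc <- same
  sc[, 2] <- sc[, 2] * 3
  expect_equal(unname(size_factors(sc))[2] / unname(size_factors(sc))[1], 3,
               tolerance = 1e-9)
  expect_error(size_factors(rbind(c(1, 0), c(0, 1))),
               class = "niche_value_error")
})

test_that("dispersion estimation recovers known truth", {
  # Poisson: near-zero working dispersion
  pois <- simulate_op9_counts(2000, 3, de_fraction = 0, nb_dispersion = 1e-9,
                              absent_fraction = 0, seed = 51)
  dp <- estimate_dispersions(pois$counts, pois$metadata$stage)
  expect_lt(median(dp$working), 0.05)
  # NB alpha = 0.2: trend recovers the asymptote within 25% at high mean
  nb <- simulate_op9_counts(3000, 4, de_fraction = 0, nb_dispersion = 0.2,
                            absent_fraction = 0, mean_log2_range = c(6, 10),
                            seed = 52)
  dn <- estimate_dispersions(nb$counts, nb$metadata$stage)
  expect_equal(unname(dn$trend["a0"]), 0.2, tolerance = 0.25)
  # zero within-group variance floors the raw estimate at 0
  const <- rbind(g1 = c(4, 4, 4, 4), g2 = c(10, 12, 9, 14),
                 g3 = c(3, 7, 2, 9))
  dc <- estimate_dispersions(const, c("A", "A", "B", "B"), rep(1, 4))
  expect_equal(unname(dc$raw[1]), 0)
  expect_equal(unname(dc$working[1]), unname(dc$fitted[1]))
  expect_error(estimate_dispersions(const, c("A", "B", "C", "D")),
               class = "niche_value_error")
})

test_that("exact test matches exhaustive enumeration for all totals <= 50", {
  set.seed(61)
  cfgs <- list(list(sf = c(1, 1, 1, 1, 1, 1), g = rep(c("A", "B"), each = 3)),
               list(sf = c(0.8, 1.2, 1, 1.5), g = c("A", "A", "B", "B")))
  for (alpha in c(0.05, 0.3)) {
    for (cfg in cfgs) {
      na <- sum(cfg$g == "A")
      for (total in seq(1, 50, by = 3)) {
        ka <- sample(0:total, 1)
        # spread the group sums over samples arbitrarily; only sums matter
        k <- numeric(length(cfg$g))
        k[1] <- ka
        k[na + 1] <- total - ka
        p_pkg <- nb_exact_test(k, cfg$g, cfg$sf, alpha)
        p_orc <- oracle_exact_p(ka, total - ka, cfg$sf[cfg$g == "A"],
                                cfg$sf[cfg$g == "B"], alpha)
        expect_equal(p_pkg, p_orc, tolerance = 1e-12)
      }
    }
  }
})

test_that("exact test honours its boundary conventions", {
  # modal allocation -> p = 1
  expect_equal(nb_exact_test(c(5, 5), c("A", "B"), c(1, 1), 0.1), 1)
  # zero totals -> p = 1
  expect_equal(nb_exact_test(c(0, 0, 0, 0), rep(c("A", "B"), 2), rep(1, 4), 0.1), 1)
  # p always in (0, 1]
  set.seed(62)
  for (i in 1:20) {
    k <- rnbinom(6, mu = 30, size = 5)
    p <- nb_exact_test(k, rep(c("A", "B"), each = 3), rep(1, 6), 0.15)
    expect_true(p > 0 && p <= 1)
  }
  # enumeration and normal approximation agree near the switch point
  k_big <- c(2600, 2500, 2550, 2400, 2450, 2500)
  g <- rep(c("A", "B"), each = 3)
  p_en <- nb_exact_test(k_big, g, rep(1, 6), 0.05, enum_limit = 1e6)
  p_ap <- nb_exact_test(k_big, g, rep(1, 6), 0.05, enum_limit = 1)
  expect_equal(p_en, p_ap, tolerance = 0.02)
})

test_that("p-values depend on the data only through group sums", {
  set.seed(63)
  counts <- matrix(rnbinom(50 * 6, mu = 50, size = 10), 50,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  g <- rep(c("A", "B"), each = 3)
  sf <- rep(1, 6)
  for (i in 1:50) {
    k <- counts[i, ]
    # redistribute counts within each group, preserving the group sums
    k2 <- c(sum(k[1:3]), 0, 0, 0, sum(k[4:6]), 0)
    expect_equal(nb_exact_test(k, g, sf, 0.1),
                 nb_exact_test(k2, g, sf, 0.1), tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces hand step-up computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_true(all(bh_adjust(runif(20)) >= runif(0)))
  expect_error(bh_adjust(numeric(0)), class = "niche_input_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "niche_value_error")
})

test_that("DE calls use inclusive thresholds and flag infinite fold changes", {
  de <- structure(data.frame(
    gene_id = c("exact", "small_fc", "strong", "zeroA"),
    mean_A = c(10, 10, 5, 0), mean_B = c(20, 19, 40, 8),
    log2fc = c(1, log2(1.9), 3, Inf),
    pval = c(0.001, 0.0001, 0.001, 0.002),
    padj = c(0.05, 0.001, 0.004, 0.01),
    infinite_fc = c(FALSE, FALSE, FALSE, TRUE)),
    class = c("de_table", "data.frame"))
  calls <- call_de(de, fc_threshold = 2, fdr = 0.05)
  expect_true("exact" %in% calls$up)     # fc exactly 2, padj exactly 0.05
  expect_false("small_fc" %in% calls$up) # fc 1.9 stays ns despite tiny p
  expect_true("zeroA" %in% calls$up)     # infinite fc called on padj alone
  expect_equal(calls$table$call[calls$table$gene_id == "small_fc"], "ns")
})

test_that("null simulations give calibrated raw p-values", {
  sim <- simulate_op9_counts(2000, 3, de_fraction = 0, effect_log2fc = 0,
                             nb_dispersion = 0.1, absent_fraction = 0,
                             seed = 71)
  de <- nb_diffexp(sim$counts,
                   factor(sim$metadata$stage, levels = c("flat", "reaggregate")))
  frac <- mean(de$pval < 0.05)
  expect_gte(frac, 0.025)
  expect_lte(frac, 0.075)
})
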