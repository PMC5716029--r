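make_de_table <- function(gene_ids, log2fc, padj, pval = padj / 2) {
  structure(data.frame(gene_id = gene_ids,
                       mean_A = 10, mean_B = 10 * 2^log2fc,
                       log2fc = log2fc, pval = pval, padj = padj,
                       infinite_fc = FALSE, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

test_that("secreted filter intersects with the annotation flags", {
  ann <- data.frame(gene_id = c("a", "b", "c"), secreted = c(TRUE, FALSE, TRUE))
  expect_equal(secreted_filter(c("a", "b", "d"), ann), "a")
  expect_equal(secreted_filter(c("b", "d"), ann), character(0))
  got <- secreted_filter(c("a", "c"), ann)
  expect_equal(secreted_filter(got, ann), got)  # idempotent
})

test_that("candidate ranking combines the two fold-change axes by mean rank", {
  de1 <- make_de_table(c("A", "B", "C", "D"), c(5, 4, 3, 2), rep(0.01, 4))
  de2 <- make_de_table(c("A", "B", "C", "D"), c(1, 3.5, 4, 0.5), rep(0.01, 4))
  got <- rank_candidates(c("A", "B"), de1, de2)
  # A ranks (1, 2) among candidates... ranks are computed within each table:
  # stage ranks: A=1, B=2; polarity ranks: A=2, B=1 -> tie broken by id
  expect_equal(got$gene_id[1], "A")
  # with the documented example: A = (1, 4), B = (2, 2) -> B first
  de1b <- make_de_table(c("A", "B", "X", "Y"), c(9, 8, 7, 6), rep(0.01, 4))
  de2b <- make_de_table(c("A", "B", "X", "Y"), c(1, 8, 7, 6), rep(0.01, 4))
  got2 <- rank_candidates(c("A", "B", "X", "Y"), de1b, de2b)
  expect_equal(got2$gene_id[1], "B")
  expect_lt(got2$rank_score[got2$gene_id == "B"],
            got2$rank_score[got2$gene_id == "A"])
  expect_equal(sort(got2$final_rank), 1:4)
  one <- rank_candidates("A", de1, de2)
  expect_equal(one$final_rank, 1)
  expect_error(rank_candidates(c("A", "Z"), de1, de2),
               class = "niche_input_error")
})

test_that("OP9 categories follow the RPM threshold and up-set rules", {
  rpm <- rbind(dim = c(0.4, 0.2), lit = c(3, 3), up = c(1, 9))
  colnames(rpm) <- c("flat", "reagg")
  expect_equal(op9_category("dim", rpm, "up"), "absent")
  expect_equal(op9_category("lit", rpm, "up"), "expressed")
  expect_equal(op9_category("up", rpm, "up"), "upregulated_on_reaggregation")
  expect_warning(got <- op9_category("missing", rpm, "up"),
                 class = "agmniche_warning")
  expect_equal(got, "absent")
})

test_that("hypergeometric overlap matches closed forms and brute force", {
  universe <- sprintf("u%02d", 1:20)
  ov <- overlap_test(universe[1:5], universe[1:5], universe)
  expect_equal(ov$p_value, 1 / 15504, tolerance = 1e-12)
  none <- overlap_test(universe[1:5], universe[6:10], universe)
  expect_equal(none$k, 0)
  expect_equal(none$p_value, 1)
  set.seed(93)
  for (i in 1:25) {
    N <- sample(10:40, 1)
    u <- sprintf("x%03d", seq_len(N))
    cl <- sample(u, sample(2:(N - 2), 1))
    up <- sample(u, sample(2:(N - 2), 1))
    got <- overlap_test(cl, up, u)
    expect_equal(got$p_value,
                 oracle_hyper_tail(got$k, got$K, got$n, got$N),
                 tolerance = 1e-12)
  }
  expect_error(overlap_test("a", "b", character(0)),
               class = "niche_input_error")
})

test_that("Spearman coexpression uses tie-aware mid-ranks", {
  expect_equal(coexpression(1:5, 1:5), 1)
  expect_equal(coexpression(1:5, 5:1), -1)
  expect_equal(coexpression(c(1, 2, 3, 4), c(10, 30, 20, 40)), 0.8)
  expect_warning(got <- coexpression(c(1, 1, 1), c(1, 2, 3)),
                 class = "agmniche_warning")
  expect_true(is.na(got))
  expect_error(coexpression(1:2, 1:2), class = "niche_input_error")
})

test_that("the 20-gene hand fixture reproduces its worked funnel counts", {
  genes <- sprintf("g%02d", 1:20)
  lfc_stage <- c(rep(2, 8), rep(0.2, 12))         # g01..g08 up-regulated
  padj_stage <- c(rep(0.01, 8), rep(0.6, 12))
  de_stage <- make_de_table(genes, lfc_stage, padj_stage)
  de_pol <- make_de_table(genes, seq(2, -1.8, length.out = 20), rep(0.01, 20))
  ann <- data.frame(gene_id = genes,
                    secreted = genes %in% c("g01", "g02", "g03", "g15"))
  op9_rpm <- rbind(g01 = c(0.3, 0.4), g02 = c(5, 6), g03 = c(2, 30))
  colnames(op9_rpm) <- c("flat", "reagg")
  op9_de <- make_de_table(c("g02", "g03"), c(0.1, 4), c(0.9, 0.001))
  fun <- run_funnel(de_stage, de_pol, ann, op9_rpm, op9_de)
  expect_equal(unname(fun$survivors["up"]), 8)
  expect_equal(unname(fun$survivors["secreted"]), 3)
  expect_equal(unname(fun$survivors["absent"]), 1)
  expect_equal(unname(fun$survivors["expressed"]), 1)
  expect_equal(unname(fun$survivors["upregulated_on_reaggregation"]), 1)
  # survivor counts never increase along the funnel
  expect_true(all(diff(c(fun$survivors["up"], fun$survivors["secreted"])) <= 0))
  # candidates are exactly the secreted up genes, ranked
  expect_setequal(fun$candidates$gene_id, c("g01", "g02", "g03"))
  expect_equal(sort(fun$candidates$final_rank), 1:3)
  # g01 has the highest polarity fold change among the three -> rank 1
  expect_equal(fun$candidates$gene_id[fun$candidates$final_rank == 1], "g01")
})

test_that("an empty DE-up set yields an empty but valid candidate table", {
  genes <- sprintf("g%02d", 1:5)
  de_ns <- make_de_table(genes, rep(0.1, 5), rep(0.9, 5))
  ann <- data.frame(gene_id = genes, secreted = TRUE)
  rpm <- matrix(1, 5, 2, dimnames = list(genes, c("a", "b")))
  fun <- run_funnel(de_ns, de_ns, ann, rpm, de_ns)
  expect_equal(nrow(fun$candidates), 0)
  expect_equal(unname(fun$survivors["up"]), 0)
})

test_that("the planted candidate survives the full pipeline at top rank", {
  ranks <- sapply(1:3, function(s) {
    sim <- simulate_niche_counts(n_genes = 1200, seed = s)
    tis <- paste(sim$metadata$stage, sim$metadata$domain, sep = "_")
    s1 <- tis %in% c("E9.5_AoV", "E10.5_AoV")
    de_stage <- nb_diffexp(sim$counts[, s1],
                           factor(tis[s1], levels = c("E9.5_AoV", "E10.5_AoV")))
    s2 <- tis %in% c("E10.5_AoD", "E10.5_AoV")
    de_pol <- nb_diffexp(sim$counts[, s2],
                         factor(tis[s2], levels = c("E10.5_AoD", "E10.5_AoV")))
    ann <- simulate_annotations(rownames(sim$counts), 0.1,
                                module_assignment = sim$truth$module_assignment,
                                force_secreted = sim$truth$candidate,
                                seed = s + 60)
    op9 <- simulate_op9_counts(1200, 3, candidate_id = sim$truth$candidate,
                               seed = s + 70)
    op9_de <- nb_diffexp(op9$counts,
                         factor(op9$metadata$stage,
                                levels = c("flat", "reaggregate")))
    fun <- run_funnel(de_stage, de_pol, ann$annotation,
                      rpm_normalize(op9$counts), op9_de)
    cand <- fun$candidates[fun$candidates$gene_id == sim$truth$candidate, ]
    expect_equal(cand$op9_category, "upregulated_on_reaggregation")
    cand$final_rank
  })
  expect_true(all(ranks <= 3))
})
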