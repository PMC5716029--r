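# The candidate-prioritisation funnel: stage-up-regulated genes -> secreted
# filter -> two-axis fold-change ranking -> OP9 expression category ->
# cluster/OP9 hypergeometric overlap.

#' Restrict up-regulated genes to secreted factors
#'
#' @param up_genes character vector.
#' @param annotation data.frame from \code{\link{build_annotation}} /
#'   \code{\link{load_annotation}} (gene_id, secreted).
#' @return Genes in \code{up_genes} flagged secreted.
#' @export
secreted_filter <- function(up_genes, annotation) {
  secreted <- annotation$gene_id[annotation$secreted]
  intersect(up_genes, secreted)
}

#' Rank candidates on the stage and polarity axes
#'
#' Each candidate is ranked (descending) by log2 fold change within each DE
#' table; the rank score is the mean of the two ranks and the final rank
#' orders candidates by ascending score, ties broken by gene id.
#'
#' @param candidates gene ids (the secreted up-regulated set).
#' @param de_stage,de_polarity \code{de_table}s covering all candidates
#'   (E10.5 AoV vs E9.5 AoV, and AoV vs AoD).
#' @return data.frame: gene_id, log2fc_stage, log2fc_polarity, rank_score,
#'   final_rank.
#' @export
rank_candidates <- function(candidates, de_stage, de_polarity) {
  miss <- setdiff(candidates, intersect(de_stage$gene_id, de_polarity$gene_id))
  if (length(miss)) {
    niche_stop(paste("candidates missing from a DE table:",
                     paste(utils::head(miss, 5), collapse = ", ")),
               "niche_input_error")
  }
  lfc1 <- de_stage$log2fc[match(candidates, de_stage$gene_id)]
  lfc2 <- de_polarity$log2fc[match(candidates, de_polarity$gene_id)]
  r1 <- rank(-lfc1, ties.method = "average")
  r2 <- rank(-lfc2, ties.method = "average")
  score <- (r1 + r2) / 2
  ord <- order(score, candidates)
  out <- data.frame(gene_id = candidates, log2fc_stage = lfc1,
                    log2fc_polarity = lfc2, rank_stage = r1,
                    rank_polarity = r2, rank_score = score,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' OP9 expression category of a gene
#'
#' \code{absent} when the gene never exceeds the RPM threshold in the OP9
#' samples (or is missing from the matrix, with a warning);
#' \code{upregulated_on_reaggregation} when it belongs to the OP9
#' reaggregation up-set; otherwise \code{expressed}.
#'
#' @param gene gene id.
#' @param op9_rpm genes x samples OP9 RPM matrix.
#' @param op9_up_set genes significantly up-regulated on reaggregation.
#' @param threshold RPM expression threshold (default 0.5).
#' @return Category string.
#' @export
op9_category <- function(gene, op9_rpm, op9_up_set, threshold = 0.5) {
  if (!gene %in% rownames(op9_rpm)) {
    niche_warn(paste("gene absent from the OP9 matrix:", gene))
    return("absent")
  }
  if (max(op9_rpm[gene, ]) <= threshold) return("absent")
  if (gene %in% op9_up_set) return("upregulated_on_reaggregation")
  "expressed"
}

#' Hypergeometric overlap of a gene cluster with the OP9 up-set
#'
#' One-sided upper tail P(X >= k) with population N = |universe| (genes
#' expressed in OP9), K = |OP9 up-set|, n = |cluster| draws and k the
#' intersection size.
#'
#' @param cluster_genes,op9_up_genes gene sets (subsets of universe).
#' @param universe background gene ids.
#' @return list(k, n, K, N, p_value).
#' @export
overlap_test <- function(cluster_genes, op9_up_genes, universe) {
  if (!length(universe)) niche_stop("empty universe", "niche_input_error")
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  op9_up_genes <- intersect(unique(op9_up_genes), universe)
  k <- length(intersect(cluster_genes, op9_up_genes))
  N <- length(universe)
  K <- length(op9_up_genes)
  n <- length(cluster_genes)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p_value = p)
}

#' Spearman rank correlation between two genes
#'
#' Pearson correlation of mid-ranks (tie-aware).
#'
#' @param x,y paired expression vectors (>= 3 observations).
#' @return rho in [-1, 1]; NA with a warning for a constant vector.
#' @export
coexpression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    niche_stop("need >= 3 paired observations", "niche_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    niche_warn("constant vector: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Run the full candidate funnel
#'
#' Composes the candidate screen: genes up-regulated on the stage axis
#' (|FC| and FDR thresholds from \code{config}), restricted to secreted
#' factors, ranked on both axes, assigned an OP9 expression category, plus
#' the hypergeometric overlap of each gene cluster with the OP9
#' reaggregation up-set.
#'
#' @param de_stage,de_polarity \code{de_table}s (E10.5 AoV vs E9.5 AoV;
#'   AoV vs AoD).
#' @param annotation annotation table with secreted flags.
#' @param op9_rpm OP9 RPM matrix.
#' @param op9_de \code{de_table} for reaggregate vs flat OP9.
#' @param clusters optional named cluster assignment (gene -> cluster).
#' @param config \code{\link{niche_config}} list.
#' @return Object of class \code{candidate_table}: \code{candidates}
#'   data.frame, per-stage \code{survivors} counts, and \code{overlap}
#'   data.frame (when clusters given).
#' @export
run_funnel <- function(de_stage, de_polarity, annotation, op9_rpm, op9_de,
                       clusters = NULL, config = niche_config()) {
  up <- call_de(de_stage, config$fc_threshold, config$de_fdr)$up
  secreted <- secreted_filter(up, annotation)
  op9_up <- call_de(op9_de, config$fc_threshold, config$de_fdr)$up
  if (length(secreted)) {
    ranked <- rank_candidates(secreted, de_stage, de_polarity)
    ranked$secreted <- TRUE
    ranked$op9_category <- vapply(ranked$gene_id, function(g) {
      suppressWarnings(op9_category(g, op9_rpm, op9_up,
                                    config$expression_threshold_rpm))
    }, "")
  } else {
    ranked <- data.frame(gene_id = character(0), log2fc_stage = numeric(0),
                         log2fc_polarity = numeric(0),
                         rank_score = numeric(0), final_rank = integer(0),
                         secreted = logical(0), op9_category = character(0),
                         stringsAsFactors = FALSE)
  }
  cats <- table(factor(ranked$op9_category,
                       levels = c("absent", "expressed",
                                  "upregulated_on_reaggregation")))
  overlap <- NULL
  if (!is.null(clusters)) {
    expressed_op9 <- rownames(op9_rpm)[
      apply(op9_rpm, 1, max) > config$expression_threshold_rpm]
    overlap <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
      ov <- overlap_test(names(clusters)[clusters == cl], op9_up,
                         expressed_op9)
      data.frame(cluster = cl, k = ov$k, n = ov$n, K = ov$K, N = ov$N,
                 p_value = ov$p_value,
                 significant = ov$p_value < 0.05,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    candidates = ranked,
    survivors = c(up = length(up), secreted = length(secreted),
                  absent = unname(cats["absent"]),
                  expressed = unname(cats["expressed"]),
                  upregulated_on_reaggregation =
                    unname(cats["upregulated_on_reaggregation"])),
    overlap = overlap), class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  s <- x$survivors
  cat("Candidate funnel:", s["up"], "up-regulated ->", s["secreted"],
      "secreted\n")
  cat("  OP9 categories: absent", s["absent"], "/ expressed", s["expressed"],
      "/ up on reaggregation", s["upregulated_on_reaggregation"], "\n")
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates[, c("gene_id", "log2fc_stage",
                                       "log2fc_polarity", "final_rank",
                                       "op9_category")], 10))
  }
  invisible(x)
}
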