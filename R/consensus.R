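# Gene-wise consensus clustering: subsampled average-linkage hierarchical
# clustering on Pearson distance, consensus matrices per K, CDF/AUC-based
# selection of the cluster number, and cluster-tissue association.

#' Select the most variable genes by coefficient of variation
#'
#' Genes are ranked by CV = sd / mean (sample sd) descending, ties broken
#' lexicographically by gene id, and the top \code{n} returned. Input is
#' expected to be the expression-filtered matrix (genes above the RPM floor
#' in at least one sample).
#'
#' @param expr genes x samples matrix.
#' @param n number of genes to keep (default 3000).
#' @return Character vector of gene ids.
#' @export
select_variable_genes <- function(expr, n = 3000) {
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  cv <- ifelse(m == 0, 0, s / m)
  ord <- order(-cv, rownames(expr))
  if (n > nrow(expr)) {
    niche_warn(sprintf("requested %d genes but only %d available", n, nrow(expr)))
    n <- nrow(expr)
  }
  rownames(expr)[ord[seq_len(n)]]
}

#' Median-center each gene row
#'
#' @param expr genes x samples matrix.
#' @return Matrix with per-row median 0 (idempotent).
#' @export
median_center <- function(expr) {
  sweep(expr, 1, apply(expr, 1, stats::median), `-`)
}

# 1 - Pearson correlation over samples; zero-variance rows get distance 1 to
# every other item (defined behaviour for degenerate rows).
pearson_distance <- function(mat) {
  cc <- suppressWarnings(stats::cor(t(mat)))
  cc[is.na(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' Consensus clustering over resampled hierarchical clusterings
#'
#' For each K in \code{k_range}, the item set is repeatedly subsampled
#' (fraction \code{subsample_fraction}, without replacement), each subsample
#' clustered by average-linkage agglomeration on 1 - Pearson correlation, and
#' the consensus value of an item pair taken as the number of times the two
#' items co-clustered divided by the number of times they were co-sampled.
#' The final assignment at each K comes from average-linkage clustering of
#' 1 - consensus. The same subsamples are reused across K so that consensus
#' matrices for different K are comparable. The empirical CDF of the
#' upper-triangle consensus values is evaluated at 100 evenly spaced
#' thresholds and summarised by its trapezoid-rule area (AUC).
#'
#' @param mat items x features matrix (median-centered expression).
#' @param k_range candidate cluster numbers (default 2..10).
#' @param iterations number of subsampled clusterings per K (default 50).
#' @param subsample_fraction fraction of items per iteration (1 disables
#'   subsampling; denominators then equal \code{iterations}).
#' @param seed RNG seed for the subsamples.
#' @return Object of class \code{consensus_result}: per-K consensus matrices,
#'   assignments, CDFs and AUCs, plus \code{items}.
#' @export
consensus_cluster <- function(mat, k_range = 2:10, iterations = 50,
                              subsample_fraction = 0.8, seed = NULL) {
  n <- nrow(mat)
  if (n <= max(k_range)) {
    niche_stop("need more items than the largest K", "niche_input_error")
  }
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    niche_stop("subsample_fraction must lie in (0, 1]", "niche_input_error")
  }
  items <- rownames(mat)
  if (is.null(items)) items <- as.character(seq_len(n))
  d_full <- pearson_distance(mat)
  sub_n <- max(floor(subsample_fraction * n), max(k_range) + 1L)
  subsamples <- with_seed(seed, {
    lapply(seq_len(iterations), function(i) sort(sample.int(n, sub_n)))
  })
  # co-sampling denominators are shared across K
  n_mat <- matrix(0, n, n)
  for (idx in subsamples) n_mat[idx, idx] <- n_mat[idx, idx] + 1
  trees <- lapply(subsamples, function(idx) {
    stats::hclust(stats::as.dist(d_full[idx, idx]), method = "average")
  })
  thresholds <- seq(0, 1, length.out = 100)
  per_k <- lapply(k_range, function(k) {
    i_mat <- matrix(0, n, n)
    for (r in seq_len(iterations)) {
      idx <- subsamples[[r]]
      cl <- stats::cutree(trees[[r]], k = k)
      for (g in unique(cl)) {
        mem <- idx[cl == g]
        i_mat[mem, mem] <- i_mat[mem, mem] + 1
      }
    }
    cons <- ifelse(n_mat > 0, i_mat / pmax(n_mat, 1), 0)
    diag(cons) <- ifelse(diag(n_mat) > 0, 1, 0)
    dimnames(cons) <- list(items, items)
    assign_tree <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    assignment <- stats::cutree(assign_tree, k = k)
    names(assignment) <- items
    vals <- cons[upper.tri(cons)]
    cdf <- vapply(thresholds, function(t) mean(vals <= t), 0)
    auc <- sum(diff(thresholds) * (utils::head(cdf, -1) + utils::tail(cdf, -1)) / 2)
    list(consensus = cons, assignment = assignment, cdf = cdf, auc = auc)
  })
  names(per_k) <- paste0("K", k_range)
  structure(list(k_range = k_range, runs = per_k, items = items,
                 thresholds = thresholds,
                 auc = vapply(per_k, `[[`, 0, "auc")),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering of", length(x$items), "items, K =",
      paste(range(x$k_range), collapse = ".."), "\n")
  cat("CDF areas:", paste(sprintf("K%d=%.3f", x$k_range, x$auc), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus value", ylab = "CDF",
                 main = "Consensus CDFs by K")
  cols <- grDevices::hcl.colors(length(x$k_range), "viridis")
  for (i in seq_along(x$k_range)) {
    graphics::lines(x$thresholds, x$runs[[i]]$cdf, col = cols[i])
  }
  graphics::legend("bottomright", legend = paste0("K=", x$k_range),
                   col = cols, lty = 1, cex = 0.7)
  invisible(x)
}

#' Choose K from the consensus CDF areas
#'
#' Operationalises "the lowest number of clusters for which the CDF reaches a
#' maximum" as a plateau rule: the smallest K whose relative AUC gain to K+1
#' falls below \code{tolerance}. If the area never plateaus the largest K is
#' returned with a warning.
#'
#' @param result \code{consensus_result}.
#' @param tolerance relative-gain plateau threshold (default 0.025).
#' @return Integer K.
#' @export
select_k <- function(result, tolerance = 0.025) {
  ks <- result$k_range
  if (length(ks) < 2) niche_stop("need at least two K values", "niche_input_error")
  auc <- result$auc
  gain <- diff(auc) / auc[-length(auc)]
  hit <- which(gain < tolerance)
  if (!length(hit)) {
    niche_warn("consensus CDF area never plateaus; returning the largest K")
    return(ks[length(ks)])
  }
  ks[hit[1]]
}

#' Cluster-signature ANOVA against tissue categories
#'
#' For each cluster, the per-sample mean of member-gene (median-centered)
#' expression is tested by one-way ANOVA across the tissue categories; the
#' peak tissue is the category with the largest mean signature.
#'
#' @param assignment named cluster vector (gene -> cluster).
#' @param expr genes x samples matrix used for clustering (median-centered).
#' @param metadata sample metadata; tissue = stage x domain.
#' @return data.frame with cluster, n_genes, peak_tissue, F, p.
#' @export
cluster_signature_anova <- function(assignment, expr, metadata) {
  meta <- metadata[match(colnames(expr), metadata$sample_id), ]
  tissue <- factor(paste(meta$stage, meta$domain, sep = "_"))
  if (nlevels(tissue) < 2 || any(table(tissue) < 2)) {
    niche_stop("need >= 2 tissues with replicates", "niche_input_error")
  }
  out <- lapply(sort(unique(assignment)), function(cl) {
    genes <- names(assignment)[assignment == cl]
    genes <- intersect(genes, rownames(expr))
    if (!length(genes)) {
      niche_stop(paste("empty cluster:", cl), "niche_input_error")
    }
    sig <- colMeans(expr[genes, , drop = FALSE])
    fit <- stats::anova(stats::lm(sig ~ tissue))
    means <- tapply(sig, tissue, mean)
    data.frame(cluster = cl, n_genes = length(genes),
               peak_tissue = names(means)[which.max(means)],
               F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
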