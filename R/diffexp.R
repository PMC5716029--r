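# Negative-binomial exact-test differential expression: median-of-ratios size
# factors, method-of-moments dispersions with an a0 + a1/mu parametric trend
# shared by taking the per-gene maximum, a conditional exact test on the two
# group sums, Benjamini-Hochberg adjustment, and the |FC| >= 2 / FDR <= 0.05
# call rule.

#' Median-of-ratios size factors
#'
#' factor_s = median over genes (positive in every sample) of
#' count_gs / geometric-mean_g.
#'
#' @param counts genes x samples matrix.
#' @return Positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    niche_stop("no gene has positive counts in all samples", "niche_value_error")
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(sweep(lg, 1, geo)), 2, stats::median)
}

#' Estimate NB dispersions with a parametric trend
#'
#' Per-gene method-of-moments dispersions are computed on the common
#' (size-factor-normalised) scale, pooling within-group variability across
#' replicated groups and subtracting the sampling (shot) noise. A parametric
#' trend alpha(mu) = a0 + a1/mu is fitted by iterated gamma-family regression
#' over genes with positive raw dispersion; the working dispersion of each
#' gene is the maximum of its raw value and the fitted trend (conservative
#' sharing).
#'
#' @param counts genes x samples matrix.
#' @param groups factor/vector of sample conditions.
#' @param sf size factors (default computed from \code{counts}).
#' @return list(raw, fitted, working, trend = c(a0, a1), base_mean).
#' @export
estimate_dispersions <- function(counts, groups, sf = size_factors(counts)) {
  groups <- factor(groups)
  reps <- table(groups)
  if (!any(reps >= 2)) {
    niche_stop("dispersion estimation needs at least one replicated group",
               "niche_value_error")
  }
  use <- groups %in% names(reps)[reps >= 2]
  q <- sweep(counts, 2, sf, `/`)
  base_mean <- rowMeans(q)
  g_use <- droplevels(groups[use])
  q_use <- q[, use, drop = FALSE]
  # pooled within-group variance on the common scale
  ss <- 0
  df <- 0
  for (lv in levels(g_use)) {
    cols <- g_use == lv
    if (sum(cols) < 2) next
    mu_g <- rowMeans(q_use[, cols, drop = FALSE])
    ss <- ss + rowSums((q_use[, cols, drop = FALSE] - mu_g)^2)
    df <- df + (sum(cols) - 1)
  }
  w <- ss / df
  z <- base_mean * mean(1 / sf[use])        # shot-noise contribution
  raw <- pmax(0, (w - z) / base_mean^2)
  raw[!is.finite(raw)] <- 0
  # parametric trend fit, iterated with outlier trimming
  fit_ok <- is.finite(raw) & raw > 0 & base_mean > 0
  a <- c(a0 = stats::median(raw[fit_ok]), a1 = 0)
  if (sum(fit_ok) >= 10) {
    keep <- fit_ok
    for (it in 1:3) {
      fit <- tryCatch(
        stats::glm(raw[keep] ~ I(1 / base_mean[keep]),
                   family = stats::Gamma(link = "identity"),
                   start = c(max(a[1], 1e-4), max(a[2], 1e-4))),
        error = function(e) NULL)
      if (is.null(fit)) break
      a <- pmax(stats::coef(fit), 0)
      pred <- a[1] + a[2] / base_mean
      ratio <- raw / pmax(pred, 1e-8)
      keep <- fit_ok & ratio < 15
      if (!sum(keep)) break
    }
  }
  fitted <- pmax(0, a[1] + a[2] / pmax(base_mean, 1e-8))
  working <- pmax(raw, fitted)
  list(raw = raw, fitted = fitted, working = working,
       trend = stats::setNames(as.numeric(a), c("a0", "a1")),
       base_mean = base_mean)
}

# NB size parameter for a group SUM: mean m, variance m + extra, where the
# extra term carries the overdispersion of the summed samples.
group_sum_nb <- function(mu, sf_group, alpha) {
  m <- mu * sum(sf_group)
  v <- mu * sum(sf_group) + alpha * mu^2 * sum(sf_group^2)
  size <- if (v > m) m^2 / (v - m) else Inf
  list(mean = m, size = size)
}

#' Conditional NB exact test for one gene
#'
#' Conditions on the observed total across both groups: every allocation
#' (kA, kB = total - kA) is assigned the product of NB probabilities of the
#' two group sums (means scaled by summed size factors, variances carrying
#' the gene's dispersion), and the p-value is the probability mass of
#' allocations no more likely than the observed one, divided by the total
#' mass. Totals above \code{enum_limit} switch to a normal approximation of
#' the conditional distribution.
#'
#' @param k counts for one gene (vector over samples).
#' @param groups two-level factor/vector aligned with \code{k}.
#' @param sf size factors aligned with \code{k}.
#' @param alpha NB dispersion for this gene.
#' @param enum_limit largest total enumerated exactly (default 10000).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(k, groups, sf, alpha, enum_limit = 10000) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    niche_stop("exact test needs exactly two groups", "niche_input_error")
  }
  ia <- groups == levels(groups)[1]
  ka <- sum(k[ia]); kb <- sum(k[!ia])
  total <- ka + kb
  if (total == 0) return(1)
  mu <- total / sum(sf)
  A <- group_sum_nb(mu, sf[ia], alpha)
  B <- group_sum_nb(mu, sf[!ia], alpha)
  if (total <= enum_limit) {
    ks <- 0:total
    lp <- dnb(ks, A) + dnb(total - ks, B)
    lp_obs <- dnb(ka, A) + dnb(kb, B)
    # work on the relative scale for numerical stability
    m <- max(lp)
    p_all <- exp(lp - m)
    p <- sum(p_all[lp <= lp_obs + 1e-7]) / sum(p_all)
    return(min(1, p))
  }
  # normal approximation of kA | total
  vA <- A$mean + A$mean^2 / A$size
  vB <- B$mean + B$mean^2 / B$size
  cm <- A$mean + vA / (vA + vB) * (total - A$mean - B$mean)
  cv <- vA * vB / (vA + vB)
  z <- (ka - cm) / sqrt(cv)
  min(1, 2 * stats::pnorm(-abs(z)))
}

dnb <- function(x, par) {
  if (is.infinite(par$size)) {
    stats::dpois(x, par$mean, log = TRUE)
  } else {
    stats::dnbinom(x, size = par$size, mu = par$mean, log = TRUE)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) niche_stop("empty p-value vector", "niche_input_error")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    niche_stop("p-values must lie in [0, 1]", "niche_value_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-group negative-binomial differential expression
#'
#' Runs the full DE stage for one contrast: size factors, pooled dispersion
#' estimation with the parametric trend, the conditional exact test per gene,
#' BH adjustment, and fold-change computation from size-factor-normalised
#' means (no pseudocount: a zero mean in one condition yields an infinite
#' fold change, flagged and called on the adjusted p-value alone).
#'
#' @param counts genes x samples matrix.
#' @param groups two-level condition vector; the contrast is B vs A where A
#'   is the first factor level (log2fc > 0 means higher in B).
#' @param dispersions optional \code{estimate_dispersions} result to reuse.
#' @return data.frame of class \code{de_table}: gene_id, mean_A, mean_B,
#'   log2fc, pval, padj, infinite_fc.
#' @export
nb_diffexp <- function(counts, groups, dispersions = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    niche_stop("contrast needs exactly two groups", "niche_input_error")
  }
  sf <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, groups, sf)
  }
  q <- sweep(counts, 2, sf, `/`)
  ia <- groups == levels(groups)[1]
  mean_a <- rowMeans(q[, ia, drop = FALSE])
  mean_b <- rowMeans(q[, !ia, drop = FALSE])
  pval <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, ], groups, sf, dispersions$working[i])
  }, 0)
  log2fc <- log2(mean_b) - log2(mean_a)
  out <- data.frame(gene_id = rownames(counts), mean_A = mean_a,
                    mean_B = mean_b, log2fc = log2fc, pval = pval,
                    padj = bh_adjust(pval),
                    infinite_fc = is.infinite(log2fc) | is.nan(log2fc),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, fc_threshold = 2, fdr = 0.05, ...) {
  calls <- call_de(x, fc_threshold, fdr)
  cat("NB exact-test differential expression:", nrow(x), "genes\n")
  cat(sprintf("  up (FC >= %g, FDR <= %g): %d\n", fc_threshold, fdr,
              length(calls$up)))
  cat(sprintf("  down: %d\n", length(calls$down)))
  NextMethod(object = utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Call differentially expressed genes
#'
#' up = \{padj <= fdr and fold change >= fc_threshold\} (inclusive
#' boundaries); down symmetric; everything else not significant. Genes with
#' an infinite fold change (zero mean in one condition) are called on the
#' adjusted p-value alone, in the direction of the non-zero mean.
#'
#' @param de \code{de_table}.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param fdr adjusted p-value threshold (default 0.05).
#' @return list(up, down) of gene ids, plus a \code{call} column convenience
#'   copy of the table in \code{table}.
#' @export
call_de <- function(de, fc_threshold = 2, fdr = 0.05) {
  lfc <- log2(fc_threshold)
  sig <- !is.na(de$padj) & de$padj <= fdr
  up_inf <- sig & de$infinite_fc & de$mean_B > de$mean_A
  down_inf <- sig & de$infinite_fc & de$mean_A > de$mean_B
  up <- sig & !de$infinite_fc & de$log2fc >= lfc
  down <- sig & !de$infinite_fc & de$log2fc <= -lfc
  call <- rep("ns", nrow(de))
  call[up | up_inf] <- "up"
  call[down | down_inf] <- "down"
  tab <- de
  tab$call <- call
  list(up = de$gene_id[call == "up"], down = de$gene_id[call == "down"],
       table = tab)
}
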