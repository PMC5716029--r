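# Pathway-level testing: TMM compositional normalisation, voom-style
# observation-level variance weights, and rotation gene-set tests on weighted
# linear models with BH adjustment across pathways.

#' Trimmed-mean-of-M-values scaling factors
#'
#' The reference sample is the column whose upper quartile (of counts scaled
#' by library size) is closest to the mean upper quartile. For every sample,
#' gene-wise log-ratios to the reference (M) and average log abundances (A)
#' are computed over genes positive in both; the stated fraction of extreme
#' M values is trimmed from each tail (likewise for A), and the factor is the
#' precision-weighted mean of the remaining M values (delta-method inverse
#' variances). Factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples matrix.
#' @param trim_m fraction of M values trimmed per tail (default 0.3).
#' @param trim_a fraction of A values trimmed per tail (default 0.05).
#' @return Numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib[j], 0.75)
  }, 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, 0)
  stats::setNames(f / exp(mean(log(f))), colnames(counts))
}

tmm_pair <- function(y, yr, n, nr, trim_m, trim_a) {
  pos <- y > 0 & yr > 0
  if (!any(pos)) {
    niche_stop("sample shares no positive genes with the TMM reference",
               "niche_value_error")
  }
  y <- y[pos]; yr <- yr[pos]
  m <- log2((y / n) / (yr / nr))
  a <- (log2(y / n) + log2(yr / nr)) / 2
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n_keep <- length(m)
  lo_m <- floor(n_keep * trim_m) + 1
  hi_m <- n_keep + 1 - lo_m
  lo_a <- floor(n_keep * trim_a) + 1
  hi_a <- n_keep + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Observation-level variance weights from the mean-variance trend
#'
#' log-CPM values are computed as log2((count + 0.5) / (lib x factor + 1) x
#' 1e6). Gene-wise linear models under \code{design} give residual standard
#' deviations; a lowess curve of sqrt(sd) against mean log2 count predicts a
#' standard deviation for every fitted observation, and the weight is its
#' inverse fourth power.
#'
#' @param counts genes x samples matrix.
#' @param design model matrix (full column rank).
#' @param norm_factors per-sample scaling factors (default TMM).
#' @return list(log_cpm, weights) with strictly positive finite weights.
#' @export
voom_weights <- function(counts, design, norm_factors = tmm_factors(counts)) {
  if (qr(design)$rank < ncol(design)) {
    niche_stop("design matrix is rank-deficient", "niche_input_error")
  }
  lib <- colSums(counts) * norm_factors + 1
  log_cpm <- log2(sweep(counts + 0.5, 2, lib, `/`) * 1e6)
  fit <- stats::lm.fit(design, t(log_cpm))
  res <- t(fit$residuals)
  df_res <- nrow(design) - ncol(design)
  s <- sqrt(rowSums(res^2) / df_res)
  mean_lcpm <- rowMeans(log_cpm)
  # mean log2 count scale for the trend
  sx <- mean_lcpm + mean(log2(lib)) - log2(1e6)
  sy <- sqrt(s)
  ok <- is.finite(sx) & is.finite(sy)
  if (stats::sd(sy[ok]) < 1e-10) {
    w <- matrix(1, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
    return(list(log_cpm = log_cpm, weights = w))
  }
  lo <- stats::lowess(sx[ok], sy[ok], f = 0.5)
  fitted_lcpm <- t(design %*% fit$coefficients)
  fitted_count <- 2^fitted_lcpm * matrix(lib, nrow(counts), ncol(counts),
                                         byrow = TRUE) / 1e6
  fitted_logcount <- log2(pmax(fitted_count, 1e-8))
  pred_sqrt_sd <- stats::approx(lo$x, lo$y, xout = fitted_logcount,
                                rule = 2, ties = mean)$y
  pred_sqrt_sd <- pmax(pred_sqrt_sd, 1e-4)
  w <- matrix(pred_sqrt_sd, nrow(counts), ncol(counts))^-4
  dimnames(w) <- dimnames(counts)
  dimnames(log_cpm) <- dimnames(counts)
  list(log_cpm = log_cpm, weights = w)
}

# Reparametrise a design so the requested contrast becomes the last
# coefficient: X2 = X Q where Q's last column spans the contrast direction.
contrast_design <- function(design, contrast) {
  p <- ncol(design)
  if (length(contrast) != p) {
    niche_stop("contrast length must match design columns", "niche_input_error")
  }
  qc <- qr(matrix(contrast, ncol = 1))
  Q <- qr.Q(qc, complete = TRUE)         # first column ~ contrast
  sgn <- sign(sum(Q[, 1] * contrast))    # keep orientation of the contrast
  Q[, 1] <- Q[, 1] * sgn
  design %*% Q[, c(seq_len(p)[-1], 1), drop = FALSE]
}

# Per-gene effects decomposition used by the rotation test: returns z (the
# contrast effect followed by the residual effects, length d = n - p + 1)
# for each gene after whitening by its observation weights.
gene_effects <- function(y_mat, w_mat, design2) {
  n <- ncol(y_mat)
  p <- ncol(design2)
  d <- n - p + 1
  z <- matrix(0, nrow(y_mat), d)
  for (i in seq_len(nrow(y_mat))) {
    sw <- sqrt(w_mat[i, ])
    qr_i <- qr(design2 * sw)
    u <- qr.qty(qr_i, y_mat[i, ] * sw)
    zi <- u[p:n]
    # orient the contrast effect with the contrast direction (QR may flip it)
    zi[1] <- zi[1] * sign(qr.R(qr_i)[p, p])
    z[i, ] <- zi
  }
  rownames(z) <- rownames(y_mat)
  z
}

# Empirical-Bayes variance prior: fit a scaled F / inverse-chi-square prior
# (s0^2, d0) to the per-gene residual variances s2 on df degrees of freedom
# by moment matching on the log scale. d0 = Inf when the observed spread of
# log variances does not exceed the chi-square sampling spread.
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(s02 = stats::median(s2), d0 = Inf))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    return(list(s02 = exp(mean(e)), d0 = Inf))
  }
  # invert trigamma by Newton iteration
  y <- ev
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    x <- x - delta
    if (x <= 0) x <- 1e-8
    if (abs(delta) < 1e-10 * x) break
  }
  d0 <- 2 * x
  s02 <- exp(mean(e) + digamma(x) - log(x))
  list(s02 = s02, d0 = d0)
}

# Moderated t statistics: squeeze per-gene variances toward the prior.
moderated_t <- function(z1, rss, df, prior) {
  s2 <- rss / df
  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s02, length(s2))
  } else {
    s2_post <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
  }
  z1 / sqrt(s2_post)
}

# Shared preparation for rotation testing: effects decomposition for every
# gene in the matrix plus the empirical-Bayes variance prior.
rotation_fit <- function(log_cpm, weights, design, contrast) {
  n <- ncol(log_cpm)
  p <- ncol(design)
  d <- n - p + 1
  if (d < 2) niche_stop("no residual degrees of freedom", "niche_input_error")
  design2 <- contrast_design(design, contrast)
  z <- gene_effects(log_cpm, weights, design2)
  rss_tot <- rowSums(z^2)
  prior <- fit_variance_prior(rss_tot - z[, 1]^2, d - 1)
  list(z = z, rss_tot = rss_tot, d = d, prior = prior)
}

roast_from_fit <- function(fit, gene_set, n_rotations, seed,
                           keep_rotations = FALSE) {
  genes <- intersect(gene_set, rownames(fit$z))
  if (!length(genes)) {
    niche_stop("gene set empty after matching to the matrix",
               "niche_input_error")
  }
  d <- fit$d
  z <- fit$z[genes, , drop = FALSE]
  rss_tot <- fit$rss_tot[genes]
  t_obs <- moderated_t(z[, 1], rss_tot - z[, 1]^2, d - 1, fit$prior)
  stat_up <- mean(t_obs)
  stat_mix <- mean(t_obs^2)
  R <- with_seed(seed, {
    r <- matrix(stats::rnorm(d * n_rotations), d, n_rotations)
    sweep(r, 2, sqrt(colSums(r^2)), `/`)
  })
  z1_rot <- z %*% R                               # genes x rotations
  rss_rot <- matrix(rss_tot, length(genes), n_rotations) - z1_rot^2
  t_rot <- moderated_t(z1_rot, rss_rot, d - 1, fit$prior)
  up_rot <- colMeans(t_rot)
  mix_rot <- colMeans(t_rot^2)
  p_up <- (sum(up_rot >= stat_up) + 1) / (n_rotations + 1)
  p_down <- (sum(up_rot <= stat_up) + 1) / (n_rotations + 1)
  p_mixed <- (sum(mix_rot >= stat_mix) + 1) / (n_rotations + 1)
  df_total <- if (is.infinite(fit$prior$d0)) Inf else d - 1 + fit$prior$d0
  gene_p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_obs))
  } else {
    2 * stats::pt(-abs(t_obs), df = df_total)
  }
  out <- list(genes = genes, n_genes = length(genes),
              stat_up = stat_up, stat_mixed = stat_mix,
              p_up = p_up, p_down = p_down, p_mixed = p_mixed,
              gene_t = stats::setNames(t_obs, genes),
              gene_p = stats::setNames(gene_p, genes),
              df = d - 1, prior = fit$prior)
  if (keep_rotations) {
    out$rot_z1 <- z1_rot
    out$rot_rss <- rss_rot
    out$rss_total <- rss_tot
  }
  class(out) <- "rotation_result"
  out
}

#' Rotation gene-set test (self-contained, directional and mixed)
#'
#' Gene-wise moderated t-statistics for a contrast are computed from weighted
#' least squares, with per-gene variances squeezed toward an empirical-Bayes
#' prior fitted from all genes in the matrix. The null distribution is
#' generated by random rotations of the combined contrast/residual effect
#' space: each rotation draws one random direction (shared by all genes,
#' preserving inter-gene correlation of the rotated statistics) and
#' recomputes every gene's moderated t from the rotated effects using the
#' same variance prior, which leaves each gene's residual sum of squares
#' unchanged. Set statistics are the mean of the gene t-statistics
#' (directional) and the mean of their squares (mixed);
#' p = (b + 1) / (n_rotations + 1).
#'
#' @param log_cpm genes x samples matrix (e.g. from \code{voom_weights}).
#' @param weights positive observation weights, same shape.
#' @param design model matrix.
#' @param contrast numeric contrast over design coefficients.
#' @param gene_set character vector of set member gene ids.
#' @param n_rotations Monte Carlo rotations (>= 99; default 9999).
#' @param seed RNG seed.
#' @param keep_rotations also return the rotated contrast effects and
#'   residual sums of squares (for diagnostics).
#' @return list of class \code{rotation_result}: p_up, p_down, p_mixed,
#'   set statistics, per-gene moderated t and two-sided gene p-values.
#' @export
roast_set <- function(log_cpm, weights, design, contrast, gene_set,
                      n_rotations = 9999, seed = NULL,
                      keep_rotations = FALSE) {
  if (n_rotations < 99) {
    niche_stop("need at least 99 rotations", "niche_input_error")
  }
  fit <- rotation_fit(log_cpm, weights, design, contrast)
  roast_from_fit(fit, gene_set, n_rotations, seed, keep_rotations)
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("Rotation set test: %d genes; p_up=%.4g p_down=%.4g p_mixed=%.4g\n",
              x$n_genes, x$p_up, x$p_down, x$p_mixed))
  invisible(x)
}

#' Screen a gene-set collection by rotation testing
#'
#' Applies \code{\link{roast_set}} to every set, adjusts each direction
#' across sets by Benjamini-Hochberg, flags significance at
#' \code{fdr} (default 0.2), and reports contributing genes: set members
#' whose individual contrast test has uncorrected p below
#' \code{contributing_gene_p} (default 0.2).
#'
#' @param collection named list of gene-id vectors.
#' @param log_cpm,weights,design,contrast as in \code{\link{roast_set}}.
#' @param n_rotations rotations per set.
#' @param fdr adjusted-p significance threshold.
#' @param contributing_gene_p uncorrected threshold for contributing genes.
#' @param seed RNG seed (each set gets an independent substream).
#' @return data.frame with per-set p-values, BH-adjusted values, significance
#'   flags and comma-separated contributing genes.
#' @export
pathway_screen <- function(collection, log_cpm, weights, design, contrast,
                           n_rotations = 9999, fdr = 0.2,
                           contributing_gene_p = 0.2, seed = NULL) {
  if (!length(collection)) {
    niche_stop("empty gene-set collection", "niche_input_error")
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      length(collection)))
  fit <- rotation_fit(log_cpm, weights, design, contrast)
  res <- lapply(seq_along(collection), function(i) {
    roast_from_fit(fit, collection[[i]], n_rotations, seeds[i])
  })
  contrib <- vapply(res, function(r) {
    up <- names(r$gene_p)[r$gene_p < contributing_gene_p]
    paste(up, collapse = ",")
  }, "")
  out <- data.frame(
    set_name = names(collection),
    n_genes = vapply(res, `[[`, 0, "n_genes"),
    p_up = vapply(res, `[[`, 0, "p_up"),
    p_down = vapply(res, `[[`, 0, "p_down"),
    p_mixed = vapply(res, `[[`, 0, "p_mixed"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$padj_up <- bh_adjust(out$p_up)
  out$padj_down <- bh_adjust(out$p_down)
  out$padj_mixed <- bh_adjust(out$p_mixed)
  out$significant_up <- out$padj_up < fdr
  out$significant_down <- out$padj_down < fdr
  out$contributing_genes <- contrib
  out
}
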