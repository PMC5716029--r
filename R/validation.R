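# Statistics for the wet-lab validation readouts: repopulation chimerism
# comparisons (Wilcoxon rank-sum with an exact small-sample branch), the 10%
# FDR screen across treatments, colony counts per embryo equivalent, and
# Tbp-relative qPCR expression with pooled-variance t tests.

#' Wilcoxon rank-sum comparison of donor chimerism
#'
#' Rank-sum test of treated versus control chimerism percentages. With a
#' combined sample size of at most 20 and no ties the p-value is exact (full
#' enumeration of rank allocations); otherwise a normal approximation with
#' mid-rank tie correction and continuity correction is used. One-sided
#' "greater" (treated above control) by default.
#'
#' @param treated,control numeric vectors (non-empty).
#' @param alternative \code{"greater"}, \code{"less"} or \code{"two.sided"}.
#' @return list(W, p, exact).
#' @export
chimerism_compare <- function(treated, control,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(treated) || !length(control)) {
    niche_stop("both groups must be non-empty", "niche_input_error")
  }
  n <- length(treated); m <- length(control)
  all_v <- c(treated, control)
  r <- rank(all_v)
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U for treated
  ties <- any(duplicated(all_v))
  exact <- (n + m) <= 20 && !ties
  if (exact) {
    p <- switch(alternative,
      greater = stats::pwilcox(w - 1, n, m, lower.tail = FALSE),
      less = stats::pwilcox(w, n, m),
      two.sided = {
        if (w > n * m / 2) {
          min(1, 2 * stats::pwilcox(w - 1, n, m, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(w, n, m))
        }
      })
  } else {
    mu <- n * m / 2
    tie_tab <- table(r)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
    sigma <- sqrt(sigma2)
    z <- switch(alternative,
      greater = (w - mu - 0.5) / sigma,
      less = (w - mu + 0.5) / sigma,
      two.sided = (w - mu - sign(w - mu) * 0.5) / sigma)
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = min(1, 2 * stats::pnorm(-abs(z))))
  }
  list(W = w, p = p, exact = exact)
}

#' Flag significant treatments at a false discovery rate
#'
#' Benjamini-Hochberg step-up across the per-treatment p-values at rate
#' \code{q} (default the 10% screen threshold).
#'
#' @param p_values named vector, one per treatment comparison.
#' @param q FDR threshold.
#' @return Logical vector of flags (names preserved).
#' @export
screen_fdr <- function(p_values, q = 0.10) {
  padj <- bh_adjust(p_values)
  stats::setNames(padj <= q, names(p_values))
}

#' Colonies per embryo equivalent
#'
#' @param colony_counts counts (per colony type).
#' @param plated_fraction_ee fraction of an embryo equivalent plated (> 0);
#'   the assay plates 0.005 e.e.
#' @return counts / plated_fraction_ee.
#' @export
cfu_normalize <- function(colony_counts, plated_fraction_ee = 0.005) {
  if (plated_fraction_ee <= 0) {
    niche_stop("plated fraction must be positive", "niche_input_error")
  }
  colony_counts / plated_fraction_ee
}

#' Relative qPCR expression (delta-delta Ct)
#'
#' Per sample, expression relative to the reference gene (Tbp) is
#' 2^-(Ct_target - Ct_reference); when a reference population is named, all
#' values are additionally scaled by the mean relative expression of that
#' population.
#'
#' @param records data.frame with \code{sample}, \code{population},
#'   \code{ct_target}, \code{ct_reference}.
#' @param scale_to optional population label to scale to.
#' @return data.frame with added \code{rel} and (if scaled) \code{scaled}.
#' @export
relative_expression <- function(records, scale_to = NULL) {
  need <- c("ct_target", "ct_reference")
  if (!all(need %in% names(records))) {
    niche_stop("records need ct_target and ct_reference columns",
               "niche_format_error")
  }
  if (anyNA(records$ct_reference)) {
    niche_stop("missing reference Ct values", "niche_value_error")
  }
  records$rel <- 2^-(records$ct_target - records$ct_reference)
  if (!is.null(scale_to)) {
    ref_rows <- records$population == scale_to
    if (!any(ref_rows)) {
      niche_stop(paste("reference population not present:", scale_to),
                 "niche_input_error")
    }
    records$scaled <- records$rel / mean(records$rel[ref_rows])
  }
  records
}

#' Pooled-variance two-sample t test
#'
#' Two-tailed Student t by default, as used on Tbp-normalised qPCR values.
#' Degenerate inputs (zero pooled variance) return p = 1 for equal means and
#' p = 0 (flagged) for unequal means.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param two_sided two-tailed (default) or one-tailed (b > a).
#' @return list(t, df, p, degenerate).
#' @export
group_ttest <- function(a, b, two_sided = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    niche_stop("each group needs at least 2 values", "niche_input_error")
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = Inf * sign(mean(b) - mean(a)), df = df, p = 0,
                degenerate = TRUE))
  }
  t_stat <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- if (two_sided) 2 * stats::pt(-abs(t_stat), df) else
    stats::pt(t_stat, df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p, degenerate = FALSE)
}
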