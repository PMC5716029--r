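# Exploratory stage: PCA of normalised expression and one-way ANOVA linking
# principal components to the categorical sample traits (embryonic stage and
# dorso-ventral polarity).

#' Principal components of an expression matrix
#'
#' Samples are projected onto components computed from zero-centered,
#' unit-variance gene variables (sample n-1 denominators). Zero-variance genes
#' are excluded before scaling. Orientation is made reproducible by flipping
#' each component so its largest-magnitude gene loading is positive.
#'
#' @param expr genes x samples matrix (typically filtered RPM).
#' @return Object of class \code{niche_pca}: \code{scores} (samples x
#'   components), \code{variance_fraction}, \code{genes_used}.
#' @export
niche_pca <- function(expr) {
  if (ncol(expr) < 2) niche_stop("need at least 2 samples", "niche_input_error")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (!nrow(expr)) niche_stop("no genes with positive variance", "niche_input_error")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| positive per component
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    col <- pc$rotation[, j]
    sign(col[which.max(abs(col))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  # at most min(samples - 1, genes) informative components
  ncomp <- min(ncol(expr) - 1, nrow(expr), ncol(scores))
  structure(list(scores = scores[, seq_len(ncomp), drop = FALSE],
                 variance_fraction = vf[seq_len(ncomp)],
                 genes_used = rownames(expr)),
            class = "niche_pca")
}

#' @export
print.niche_pca <- function(x, ...) {
  cat("PCA of", length(x$genes_used), "genes x", nrow(x$scores), "samples\n")
  vf <- round(100 * x$variance_fraction[seq_len(min(5, length(x$variance_fraction)))], 1)
  cat("variance explained (%):", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}

#' One-way ANOVA of a principal component against a sample trait
#'
#' Tests whether a component's scores separate the levels of a categorical
#' trait. \code{"stage"} groups all samples by embryonic stage (the UGR is an
#' E10.5 tissue and is included); \code{"polarity"} compares AoV versus AoD
#' and excludes UGR samples, which carry no dorso-ventral label.
#'
#' @param pca \code{niche_pca} object.
#' @param metadata sample metadata (sample_id, stage, domain).
#' @param trait \code{"stage"} or \code{"polarity"}.
#' @param component component index (1 = PC1).
#' @return list(F, p, df) from the exact F distribution.
#' @export
pc_trait_anova <- function(pca, metadata, trait = c("stage", "polarity"),
                           component = 1) {
  trait <- match.arg(trait)
  scores <- pca$scores[, component]
  meta <- metadata[match(rownames(pca$scores), metadata$sample_id), ]
  if (trait == "stage") {
    grp <- meta$stage
  } else {
    keep <- meta$domain %in% c("AoV", "AoD")
    scores <- scores[keep]
    grp <- meta$domain[keep]
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2) {
    niche_stop("trait must have at least two groups", "niche_input_error")
  }
  if (any(table(grp) < 2)) {
    niche_stop("every trait group needs at least 2 samples", "niche_input_error")
  }
  n <- length(scores)
  k <- nlevels(grp)
  gm <- mean(scores)
  means <- tapply(scores, grp, mean)
  ssb <- sum(tapply(scores, grp, length) * (means - gm)^2)
  ssw <- sum((scores - means[grp])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, p = 1, df = c(df1, df2)))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE), df = c(df1, df2))
}
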