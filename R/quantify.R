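# Gene-level quantification: fractional assignment of multi-mapping reads,
# reads-per-million scaling, and the 0.5 RPM expression filter.

#' Fractional gene counts from read alignments
#'
#' Uniquely mapped reads contribute 1 to their gene. A read hitting genes
#' g1..gk is divided into fractions weighted proportionally to the unique-read
#' evidence of each candidate: gene gi receives U(gi) / sum_j U(gj), where
#' U(g) is the number of uniquely mapped reads of g. When no candidate has any
#' unique evidence the read is split equally among its hits (the count of such
#' reads is reported as an attribute), so total assigned mass always equals
#' the number of reads. The weighting is a single pass from unique counts, not
#' an iterative re-estimation.
#'
#' @param alignments data.frame with a \code{genes} column of comma-separated
#'   gene hits per read (as produced by \code{\link{simulate_alignments}}).
#' @param gene_ids optional universe of genes to report (zeros included).
#' @return Named numeric vector of (possibly fractional) counts, with
#'   attribute \code{n_equal_split}.
#' @export
fractional_counts <- function(alignments, gene_ids = NULL) {
  if (is.null(alignments) || !nrow(alignments)) {
    niche_stop("empty alignment set", "niche_input_error")
  }
  hits <- strsplit(as.character(alignments$genes), ",", fixed = TRUE)
  nhit <- lengths(hits)
  if (any(nhit == 0)) {
    niche_stop("alignment record with no gene hits", "niche_value_error")
  }
  unique_hits <- unlist(hits[nhit == 1], use.names = FALSE)
  u_tab <- table(unique_hits)
  all_genes <- if (is.null(gene_ids)) {
    sort(unique(unlist(hits, use.names = FALSE)))
  } else gene_ids
  counts <- stats::setNames(numeric(length(all_genes)), all_genes)
  counts[names(u_tab)] <- as.numeric(u_tab)
  uniq_of <- function(g) {
    v <- u_tab[g]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  n_equal <- 0L
  for (h in hits[nhit > 1]) {
    u <- uniq_of(h)
    tot <- sum(u)
    if (tot == 0) {
      w <- rep(1 / length(h), length(h))
      n_equal <- n_equal + 1L
    } else {
      w <- u / tot
    }
    counts[h] <- counts[h] + w
  }
  attr(counts, "n_equal_split") <- n_equal
  counts
}

#' Reads-per-million normalisation
#'
#' Scales each sample so its assigned counts sum to one million:
#' RPM = count / library size x 1e6, with the library size taken as the total
#' assigned (possibly fractional) count of the sample.
#'
#' @param counts genes x samples numeric matrix.
#' @return Matrix of the same shape; all-zero columns are emitted as zeros
#'   with a warning.
#' @export
rpm_normalize <- function(counts) {
  lib <- colSums(counts)
  if (all(lib == 0)) {
    niche_stop("no sample has a positive column sum", "niche_value_error")
  }
  if (any(lib == 0)) {
    niche_warn(paste("all-zero sample columns left as zeros:",
                     paste(colnames(counts)[lib == 0], collapse = ", ")))
    lib[lib == 0] <- 1
  }
  sweep(counts, 2, lib, `/`) * 1e6
}

#' Remove genes below the expression floor
#'
#' A gene is retained iff its RPM reaches \code{threshold} in at least one
#' sample; genes below the floor in all samples are removed (strict-less-than
#' removal, so a gene exactly at the threshold stays). Gene order preserved.
#'
#' @param rpm genes x samples RPM matrix.
#' @param threshold expression floor (RPM, > 0); default 0.5.
#' @return Filtered matrix.
#' @export
filter_expressed <- function(rpm, threshold = 0.5) {
  if (threshold <= 0) {
    niche_stop("threshold must be positive", "niche_input_error")
  }
  keep <- apply(rpm, 1, max) >= threshold
  if (!any(keep)) niche_warn("no gene passes the expression filter")
  rpm[keep, , drop = FALSE]
}
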