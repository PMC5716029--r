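#' @keywords internal
"_PACKAGE"

# Typed condition helper: every validation failure carries a stable class so
# callers (and tests) can dispatch on the kind of problem, not the message.
niche_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "agmniche_error")))
}

niche_warn <- function(msg, class = "agmniche_warning") {
  warning(warningCondition(msg, class = c(class, "agmniche_warning")))
}

# Run an expression under a fixed RNG state without clobbering the caller's.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    niche_stop("label vectors must have equal length", "niche_input_error")
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Default analysis configuration
#'
#' The constants used across the pipeline: the 0.5 RPM expression floor, the
#' 3000-gene variable set, the K = 2..10 consensus range with 50 iterations at
#' 80% subsampling, the 2-fold / 5% FDR differential-expression call rule, the
#' 20% pathway FDR with contributing genes at uncorrected p < 0.2, and the 10%
#' FDR used for the validation screens.
#'
#' @param ... named overrides for any field.
#' @return A named list of settings.
#' @export
niche_config <- function(...) {
  cfg <- list(
    expression_threshold_rpm = 0.5,
    top_variable_genes = 3000,
    k_range = 2:10,
    n_consensus_iterations = 50,
    subsample_fraction = 0.8,
    k_selection_tolerance = 0.025,
    fc_threshold = 2,
    de_fdr = 0.05,
    pathway_fdr = 0.2,
    contributing_gene_p = 0.2,
    repopulation_fdr = 0.10,
    n_rotations = 9999,
    random_seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    niche_stop(paste("unknown config fields:", paste(unknown, collapse = ", ")),
               "niche_config_error")
  }
  cfg[names(dots)] <- dots
  numeric_fields <- setdiff(names(cfg), c("k_range", "random_seed"))
  bad <- numeric_fields[vapply(cfg[numeric_fields],
                               function(x) !is.numeric(x) || any(x <= 0), TRUE)]
  if (length(bad)) {
    niche_stop(paste("config thresholds must be positive:",
                     paste(bad, collapse = ", ")), "niche_config_error")
  }
  cfg
}
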