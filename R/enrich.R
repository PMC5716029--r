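# DAG-aware Gene Ontology enrichment: classic one-sided Fisher/hypergeometric
# per term, and the elim decorrelation in which genes explained by a
# significant child term are removed from its ancestors before they are
# tested.

#' GO term enrichment of a study set against a universe
#'
#' Annotations are propagated to ancestor terms when a DAG is supplied
#' (true-path rule). In \code{classic} mode every term gets a one-sided
#' hypergeometric upper-tail p-value for the overlap of its annotated genes
#' with the study set. In \code{elim} mode terms are processed
#' most-specific-first (by DAG depth); when a term scores p below
#' \code{elim_cutoff} its genes are eliminated from all ancestor terms before
#' those are tested, decorrelating parent p-values from child-specific
#' signal.
#'
#' @param study_set character vector, a subset of \code{universe}.
#' @param universe background gene ids (e.g. all expressed genes).
#' @param term2gene data.frame (term_id, gene_id).
#' @param dag optional edge data.frame (child, parent, relation).
#' @param mode \code{"classic"} or \code{"elim"}.
#' @param elim_cutoff child significance level triggering elimination
#'   (default 0.01).
#' @return data.frame: term_id, annotated, significant, expected, p_value
#'   (terms annotating zero universe genes are skipped).
#' @export
fisher_enrichment <- function(study_set, universe, term2gene, dag = NULL,
                              mode = c("classic", "elim"),
                              elim_cutoff = 0.01) {
  mode <- match.arg(mode)
  extra <- setdiff(study_set, universe)
  if (length(extra)) {
    niche_stop(paste("study genes outside the universe:",
                     paste(utils::head(extra, 5), collapse = ", ")),
               "niche_input_error")
  }
  anc <- dag_ancestors(dag)
  term_genes <- split(as.character(term2gene$gene_id),
                      as.character(term2gene$term_id))
  term_genes <- lapply(term_genes, function(g) intersect(unique(g), universe))
  # propagate: every ancestor inherits the genes of its descendants
  if (length(anc)) {
    inherited <- term_genes
    for (t in names(term_genes)) {
      for (a in anc[[t]]) {
        inherited[[a]] <- union(inherited[[a]], term_genes[[t]])
      }
    }
    term_genes <- inherited
  }
  term_genes <- term_genes[lengths(term_genes) > 0]
  n_univ <- length(unique(universe))
  n_study <- length(unique(study_set))
  # process order: most specific first (largest ancestor count = deepest)
  depth <- vapply(names(term_genes),
                  function(t) length(anc[[t]]), 0L)
  ord <- names(term_genes)[order(-depth, names(term_genes))]
  eliminated <- stats::setNames(vector("list", length(term_genes)),
                                names(term_genes))
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    t <- ord[i]
    genes <- setdiff(term_genes[[t]], eliminated[[t]])
    k_ann <- length(genes)
    k_sig <- length(intersect(genes, study_set))
    p <- if (k_ann == 0) 1 else {
      stats::phyper(k_sig - 1, n_study, n_univ - n_study, k_ann,
                    lower.tail = FALSE)
    }
    if (mode == "elim" && p < elim_cutoff && length(anc[[t]])) {
      for (a in intersect(anc[[t]], names(term_genes))) {
        eliminated[[a]] <- union(eliminated[[a]], genes)
      }
    }
    rows[[i]] <- data.frame(
      term_id = t, annotated = length(term_genes[[t]]),
      tested = k_ann, significant = k_sig,
      expected = n_study * length(term_genes[[t]]) / n_univ,
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
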