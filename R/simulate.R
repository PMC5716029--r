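# Negative-binomial simulators with planted ground truth. Counts are drawn as
# NB(mu, size = 1/alpha) so that Var = mu + alpha * mu^2, the same
# parameterisation the differential-expression module estimates; recovery
# tests are therefore coherent end to end. All generators take an explicit
# seed and restore the caller's RNG state.

niche_design <- function() {
  tissues <- c("E9.5_AoV", "E9.5_AoD", "E10.5_AoV", "E10.5_AoD", "E10.5_UGR")
  meta <- do.call(rbind, lapply(tissues, function(t) {
    parts <- strsplit(t, "_", fixed = TRUE)[[1]]
    data.frame(sample_id = paste0(t, "_r", 1:3), stage = parts[1],
               domain = parts[2], replicate = 1:3, tissue = t,
               stringsAsFactors = FALSE)
  }))
  meta
}

#' Simulate read-to-gene alignment summaries
#'
#' Fixture generator for the fractional quantifier: each read either maps
#' uniquely to one gene or ambiguously to 2-4 distinct genes chosen uniformly.
#'
#' @param n_reads number of reads (> 0).
#' @param gene_ids at least two gene identifiers.
#' @param multimap_rate probability a read is ambiguous, in [0, 1].
#' @param seed RNG seed.
#' @return data.frame with \code{read_id}, \code{genes} (comma-separated
#'   hits) and \code{is_unique}.
#' @export
simulate_alignments <- function(n_reads, gene_ids, multimap_rate = 0.15,
                                seed = NULL) {
  if (n_reads <= 0) niche_stop("n_reads must be positive", "niche_input_error")
  if (length(gene_ids) < 2) {
    niche_stop("need at least two genes", "niche_input_error")
  }
  if (multimap_rate < 0 || multimap_rate > 1) {
    niche_stop("multimap_rate must lie in [0, 1]", "niche_input_error")
  }
  with_seed(seed, {
    multi <- stats::runif(n_reads) < multimap_rate
    genes <- character(n_reads)
    genes[!multi] <- sample(gene_ids, sum(!multi), replace = TRUE)
    if (any(multi)) {
      k <- sample(2:min(4, length(gene_ids)), sum(multi), replace = TRUE)
      genes[multi] <- vapply(k, function(kk) {
        paste(sample(gene_ids, kk), collapse = ",")
      }, "")
    }
    data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
               genes = genes, is_unique = !multi, stringsAsFactors = FALSE)
  })
}

#' Simulate AGM niche RNA-seq counts with planted gene modules
#'
#' Emulates the profiling design of the embryonic aorta-gonad-mesonephros:
#' five tissues (E9.5 AoV/AoD, E10.5 AoV/AoD/UGR) in triplicate, 15 samples.
#' Five gene modules are planted, one peaking in each tissue (baseline mean
#' multiplied by \code{2^effect_log2fc} in the peak tissue), giving five
#' sharply distinct high-variance expression programs. Background genes
#' additionally carry bounded random log2 coefficients on the stage and
#' polarity axes (developmental drift), reproducing the broad covariation
#' that makes stage and polarity the dominant principal components of real
#' niche transcriptomes; the drift is capped below the 2-fold call
#' threshold, so these genes remain differential-expression background. A
#' designated secreted-candidate gene is planted ventrally polarised and
#' rising from E9.5 to E10.5, mimicking the expression behaviour that makes
#' a gene a niche-factor candidate.
#'
#' @param n_genes total genes.
#' @param module_sizes five module sizes, one per peak tissue (order:
#'   E9.5 AoV, E9.5 AoD, E10.5 AoV, E10.5 AoD, E10.5 UGR).
#' @param effect_log2fc log2 fold elevation of module genes in their peak
#'   tissue.
#' @param nb_dispersion NB dispersion alpha.
#' @param mean_log2_range log2 range of baseline gene means (log-uniform).
#' @param libsize_range relative per-sample depth multipliers (log-uniform).
#' @param drift_sd_stage,drift_sd_polarity SD (log2) of the background drift
#'   coefficients on each axis.
#' @param drift_bound absolute cap (log2) on the drift coefficients; the
#'   default keeps every background gene below the 2-fold call threshold.
#' @param candidate plant the candidate gene (id \code{"gene_candidate"})?
#' @param candidate_stage_lfc,candidate_polarity_lfc planted log2 fold changes
#'   of the candidate on the stage (E10.5 AoV vs E9.5 AoV) and polarity
#'   (AoV vs AoD) axes.
#' @param seed RNG seed.
#' @return list(counts, metadata, truth); \code{truth} records per-gene module
#'   assignment, planted up/down sets for the stage and polarity contrasts,
#'   and the candidate id.
#' @export
simulate_niche_counts <- function(n_genes = 3000,
                                  module_sizes = c(110, 105, 100, 95, 90),
                                  effect_log2fc = 3,
                                  nb_dispersion = 0.05,
                                  mean_log2_range = c(5, 10),
                                  libsize_range = c(0.75, 1.33),
                                  drift_sd_stage = 0.7,
                                  drift_sd_polarity = 0.55,
                                  drift_bound = 1,
                                  candidate = TRUE,
                                  candidate_stage_lfc = 4,
                                  candidate_polarity_lfc = 4,
                                  seed = NULL) {
  if (length(module_sizes) != 5) {
    niche_stop("module_sizes must have length 5 (one module per tissue)",
               "niche_input_error")
  }
  if (sum(module_sizes) >= n_genes) {
    niche_stop("module sizes must sum to less than n_genes", "niche_input_error")
  }
  if (nb_dispersion <= 0) {
    niche_stop("dispersion must be positive", "niche_input_error")
  }
  if (effect_log2fc < 0) {
    niche_stop("effect_log2fc must be non-negative", "niche_input_error")
  }
  meta <- niche_design()
  tissues <- unique(meta$tissue)
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    base_mean <- 2^stats::runif(n_genes, mean_log2_range[1], mean_log2_range[2])
    module <- rep("background", n_genes)
    idx <- 1L
    for (m in seq_along(module_sizes)) {
      take <- idx:(idx + module_sizes[m] - 1L)
      module[take] <- paste0("module", m)
      idx <- idx + module_sizes[m]
    }
    names(module) <- gene_ids

    # per-gene, per-tissue mean multipliers: one module peaking per tissue
    patterns <- list(
      module1 = "E9.5_AoV",
      module2 = "E9.5_AoD",
      module3 = "E10.5_AoV",
      module4 = "E10.5_AoD",
      module5 = "E10.5_UGR")
    mult <- matrix(1, n_genes, length(tissues), dimnames = list(gene_ids, tissues))
    if (effect_log2fc > 0) {
      for (m in seq_along(module_sizes)) {
        mult[module == paste0("module", m), patterns[[m]]] <- 2^effect_log2fc
      }
    }
    # background drift: modest per-gene responses to stage and polarity,
    # bounded below the 2-fold call threshold so background genes stay
    # differential-expression-negative by construction
    bg <- module == "background"
    if (any(bg) && (drift_sd_stage > 0 || drift_sd_polarity > 0)) {
      clip <- function(x) pmin(pmax(x, -drift_bound), drift_bound)
      b_stage <- clip(stats::rnorm(sum(bg), 0, drift_sd_stage))
      b_pol <- clip(stats::rnorm(sum(bg), 0, drift_sd_polarity))
      is_e105 <- grepl("^E10.5", tissues)
      is_aov <- grepl("AoV$", tissues)
      drift <- outer(b_stage, as.numeric(is_e105)) +
        outer(b_pol, as.numeric(is_aov))
      mult[bg, ] <- mult[bg, ] * 2^drift
    }
    candidate_id <- NULL
    if (candidate) {
      candidate_id <- "gene_candidate"
      gene_ids[n_genes] <- candidate_id
      rownames(mult) <- gene_ids
      names(module) <- gene_ids
      module[candidate_id] <- "candidate"
      base_mean[n_genes] <- 2^7  # solidly expressed
      mult[candidate_id, ] <- 1
      mult[candidate_id, "E9.5_AoV"] <- 2^1
      mult[candidate_id, "E10.5_AoV"] <- 2^(1 + candidate_stage_lfc)
      # polarity axis: AoV vs AoD at E10.5 is 1 + candidate_stage_lfc vs 0;
      # cap by the requested polarity lfc via the AoD level
      mult[candidate_id, "E10.5_AoD"] <-
        2^max(0, 1 + candidate_stage_lfc - candidate_polarity_lfc)
    }

    depth <- exp(stats::runif(nrow(meta), log(libsize_range[1]),
                              log(libsize_range[2])))
    mu <- mult[, meta$tissue, drop = FALSE] * base_mean
    mu <- sweep(mu, 2, depth, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                     nrow = n_genes,
                     dimnames = list(gene_ids, meta$sample_id))

    # contrasts: stage = E10.5 AoV vs E9.5 AoV; polarity = AoV vs AoD (E10.5)
    up_stage <- gene_ids[module == "module3"]
    down_stage <- gene_ids[module == "module1"]
    up_pol <- gene_ids[module == "module3"]
    down_pol <- gene_ids[module == "module4"]
    if (!is.null(candidate_id)) {
      up_stage <- c(up_stage, candidate_id)
      up_pol <- c(up_pol, candidate_id)
    }
    truth <- list(
      module_assignment = module,
      de_up = list(stage = up_stage, polarity = up_pol),
      de_down = list(stage = down_stage, polarity = down_pol),
      candidate = candidate_id,
      module_pattern = lapply(patterns, identity)
    )
    list(counts = counts, metadata = meta[, c("sample_id", "stage", "domain",
                                              "replicate")],
         truth = truth)
  })
}

#' Simulate the two-condition OP9 stromal experiment
#'
#' Flat (submersed) versus reaggregate culture with NB counts, planted
#' up/down-regulated sets of equal size, and a configurable fraction of genes
#' kept below the expression threshold in both conditions (the "absent"
#' category of the candidate funnel). A designated candidate gene can be
#' forced to be expressed and up-regulated on reaggregation.
#'
#' @param n_genes total genes.
#' @param n_reps_per_condition replicates per condition (>= 2).
#' @param de_fraction fraction of genes differentially expressed, in [0, 1);
#'   split equally up/down.
#' @param effect_log2fc planted |log2 fold change|.
#' @param nb_dispersion NB dispersion alpha.
#' @param absent_fraction fraction of genes silenced in both conditions.
#' @param mean_log2_range log2 range of baseline means.
#' @param candidate_id optional gene id forced expressed and into the up set.
#' @param force_up additional gene ids forced expressed and up-regulated
#'   (e.g. to plant an overlap between an AGM cluster and the OP9 up-set).
#' @param seed RNG seed.
#' @return list(counts, metadata, truth) with truth up/down/absent sets.
#' @export
simulate_op9_counts <- function(n_genes = 3000, n_reps_per_condition = 3,
                                de_fraction = 0.1, effect_log2fc = 2,
                                nb_dispersion = 0.05, absent_fraction = 0.1,
                                mean_log2_range = c(4, 10),
                                candidate_id = NULL, force_up = NULL,
                                seed = NULL) {
  if (n_reps_per_condition < 2) {
    niche_stop("need at least 2 replicates per condition", "niche_input_error")
  }
  if (de_fraction < 0 || de_fraction >= 1) {
    niche_stop("de_fraction must lie in [0, 1)", "niche_input_error")
  }
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    if (!is.null(candidate_id)) gene_ids[n_genes] <- candidate_id
    n_de <- floor(de_fraction * n_genes / 2)
    pool <- seq_len(n_genes - 1L)  # keep the candidate slot free
    n_absent <- floor(absent_fraction * n_genes)
    picked <- sample(pool, 2 * n_de + n_absent)
    up_idx <- picked[seq_len(n_de)]
    down_idx <- picked[n_de + seq_len(n_de)]
    absent_idx <- picked[2 * n_de + seq_len(n_absent)]
    if (!is.null(candidate_id)) up_idx <- c(up_idx, n_genes)
    if (!is.null(force_up)) {
      forced <- match(intersect(force_up, gene_ids), gene_ids)
      up_idx <- union(up_idx, forced)
      down_idx <- setdiff(down_idx, forced)
      absent_idx <- setdiff(absent_idx, forced)
    }

    base_mean <- 2^stats::runif(n_genes, mean_log2_range[1], mean_log2_range[2])
    # silenced in both conditions: exact zeros, the scaled-down analogue of
    # genes below the RPM floor
    base_mean[absent_idx] <- 0
    mu_flat <- base_mean
    mu_reag <- base_mean
    mu_reag[up_idx] <- mu_reag[up_idx] * 2^effect_log2fc
    mu_reag[down_idx] <- mu_reag[down_idx] / 2^effect_log2fc
    meta <- data.frame(
      sample_id = c(paste0("flat_r", seq_len(n_reps_per_condition)),
                    paste0("reagg_r", seq_len(n_reps_per_condition))),
      stage = rep(c("flat", "reaggregate"), each = n_reps_per_condition),
      domain = "none",
      replicate = rep(seq_len(n_reps_per_condition), 2),
      stringsAsFactors = FALSE)
    mu <- cbind(matrix(mu_flat, n_genes, n_reps_per_condition),
                matrix(mu_reag, n_genes, n_reps_per_condition))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                     nrow = n_genes,
                     dimnames = list(gene_ids, meta$sample_id))
    truth <- list(de_up = gene_ids[up_idx], de_down = gene_ids[down_idx],
                  absent = gene_ids[absent_idx], candidate = candidate_id)
    list(counts = counts, metadata = meta, truth = truth)
  })
}

#' Simulate donor-chimerism percentages
#'
#' Per-mouse donor contribution 16 weeks post-transplant, as a normal draw
#' with a planted location shift for the treated group, clipped to [0, 100].
#'
#' @param n_treated,n_control group sizes.
#' @param control_mean_pct control-group mean chimerism.
#' @param shift_pct planted additive shift for the treated group.
#' @param noise_sd per-mouse standard deviation.
#' @param seed RNG seed.
#' @return data.frame with \code{mouse_id}, \code{condition},
#'   \code{donor_chimerism}.
#' @export
simulate_repopulation <- function(n_treated = 8, n_control = 8,
                                  control_mean_pct = 20, shift_pct = 40,
                                  noise_sd = 15, seed = NULL) {
  if (n_treated < 0 || n_control < 0) {
    niche_stop("group sizes must be non-negative", "niche_input_error")
  }
  with_seed(seed, {
    vals <- c(stats::rnorm(n_treated, control_mean_pct + shift_pct, noise_sd),
              stats::rnorm(n_control, control_mean_pct, noise_sd))
    vals <- pmin(100, pmax(0, vals))
    data.frame(
      mouse_id = sprintf("m%03d", seq_len(n_treated + n_control)),
      condition = rep(c("treated", "control"), c(n_treated, n_control)),
      donor_chimerism = vals, stringsAsFactors = FALSE)
  })
}

#' Simulate GO-style annotations over a generated DAG, plus pathway sets
#'
#' Builds an acyclic term DAG (edges only child to parent by level) whose two
#' top-level terms are the extracellular region/space terms used to define
#' secreted factors. A binomial fraction of genes is made secreted by
#' annotation to one of those terms or a descendant; all genes also receive
#' random non-secreted terms. When a planted module assignment is supplied,
#' the returned collection contains one pathway per module, drawn from within
#' that module's genes.
#'
#' @param gene_ids gene identifiers.
#' @param secreted_fraction probability a gene is secreted.
#' @param n_terms number of non-secreted terms (>= 2).
#' @param dag_depth levels of the generated DAG.
#' @param module_assignment optional named vector (gene -> module/background).
#' @param force_secreted gene ids always flagged secreted (e.g. the planted
#'   candidate).
#' @param seed RNG seed.
#' @return list(annotation, term2gene, dag, sets, secreted_genes).
#' @export
simulate_annotations <- function(gene_ids, secreted_fraction = 0.1,
                                 n_terms = 40, dag_depth = 3,
                                 module_assignment = NULL,
                                 force_secreted = NULL, seed = NULL) {
  if (n_terms < 2) niche_stop("n_terms must be >= 2", "niche_input_error")
  if (secreted_fraction <= 0 || secreted_fraction >= 1) {
    niche_stop("secreted_fraction must lie in (0, 1)", "niche_input_error")
  }
  with_seed(seed, {
    # secreted sub-DAG: children of the two canonical terms, by level
    sec_roots <- GO_SECRETED_TERMS
    sec_terms <- list(sec_roots)
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
    for (lev in seq_len(dag_depth - 1)) {
      kids <- sprintf("GO:SEC%d%02d", lev, seq_len(2 * lev))
      parents <- sample(unlist(sec_terms), length(kids), replace = TRUE)
      edges <- rbind(edges, data.frame(
        child = kids, parent = parents,
        relation = sample(c("is_a", "part_of"), length(kids), replace = TRUE),
        stringsAsFactors = FALSE))
      sec_terms <- c(sec_terms, list(kids))
    }
    sec_pool <- unlist(sec_terms)
    other_terms <- sprintf("GO:X%06d", seq_len(n_terms))
    # layer the non-secreted terms into their own DAG levels
    lev_of <- sample(seq_len(dag_depth), n_terms, replace = TRUE)
    for (lev in 2:dag_depth) {
      kids <- other_terms[lev_of == lev]
      pool <- other_terms[lev_of < lev]
      if (length(kids) && length(pool)) {
        edges <- rbind(edges, data.frame(
          child = kids, parent = sample(pool, length(kids), replace = TRUE),
          relation = "is_a", stringsAsFactors = FALSE))
      }
    }
    secreted <- stats::runif(length(gene_ids)) < secreted_fraction
    names(secreted) <- gene_ids
    if (!is.null(force_secreted)) secreted[force_secreted] <- TRUE
    rows <- lapply(gene_ids, function(g) {
      terms <- sample(other_terms, sample(1:3, 1))
      if (secreted[[g]]) terms <- c(terms, sample(sec_pool, 1))
      data.frame(term_id = terms, gene_id = g, stringsAsFactors = FALSE)
    })
    term2gene <- do.call(rbind, rows)
    annotation <- build_annotation(term2gene, edges)
    sets <- NULL
    if (!is.null(module_assignment)) {
      mods <- setdiff(unique(module_assignment),
                      c("background", "candidate"))
      sets <- lapply(mods, function(m) {
        members <- names(module_assignment)[module_assignment == m]
        sample(members, min(30, length(members)))
      })
      names(sets) <- paste0("pathway_", mods)
    }
    list(annotation = annotation, term2gene = term2gene, dag = edges,
         sets = sets,
         secreted_genes = annotation$gene_id[annotation$secreted])
  })
}
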