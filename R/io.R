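# File dialect shared by every reader/writer: UTF-8, tab-separated, '#'
# comment lines ignored, first row a header. Gene and sample identifiers are
# opaque strings; no genome-build semantics are enforced.

read_tsv_file <- function(path) {
  if (!file.exists(path)) {
    niche_stop(paste0("file not found: ", path), "niche_io_error")
  }
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Load a count matrix and its sample metadata
#'
#' Reads a genes-by-samples table (first column gene identifiers, remaining
#' columns numeric counts, possibly fractional) and a sample metadata table
#' with columns \code{sample_id}, \code{stage}, \code{domain},
#' \code{replicate}. Both are validated: identifiers must be unique, counts
#' non-negative, and the metadata must cover exactly the samples present.
#'
#' @param path counts TSV path.
#' @param metadata_path metadata TSV path.
#' @return A list with \code{counts} (numeric matrix, genes x samples),
#'   \code{metadata} (data.frame) and \code{library_size} (column sums).
#' @export
load_counts <- function(path, metadata_path) {
  tab <- read_tsv_file(path)
  if (ncol(tab) < 2) {
    niche_stop("counts file needs a gene column plus at least one sample",
               "niche_format_error")
  }
  gene_ids <- as.character(tab[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    niche_stop(paste("duplicate gene identifiers:",
                     paste(unique(dup), collapse = ", ")), "niche_duplicate_error")
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- colnames(values)[!vapply(seq_len(ncol(values)),
                                    function(j) is.numeric(tab[[j + 1]]), TRUE)]
    niche_stop(paste("non-numeric count columns:", paste(bad, collapse = ", ")),
               "niche_format_error")
  }
  if (anyNA(values) || any(values < 0)) {
    offenders <- gene_ids[apply(is.na(values) | values < 0, 1, any)]
    niche_stop(paste("negative or missing counts for:",
                     paste(utils::head(offenders, 5), collapse = ", ")),
               "niche_value_error")
  }
  rownames(values) <- gene_ids
  meta <- read_tsv_file(metadata_path)
  validate_metadata(values, meta)
  list(counts = values, metadata = meta, library_size = colSums(values))
}

validate_metadata <- function(counts, meta) {
  required <- c("sample_id", "stage", "domain", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    niche_stop(paste("metadata missing columns:",
                     paste(missing_cols, collapse = ", ")), "niche_format_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    niche_stop(paste("duplicate sample_id in metadata:",
                     paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                           collapse = ", ")), "niche_duplicate_error")
  }
  orphans <- setdiff(colnames(counts), meta$sample_id)
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(orphans) || length(extra)) {
    niche_stop(paste0("metadata/sample mismatch; samples without metadata: [",
                      paste(orphans, collapse = ", "),
                      "]; metadata without samples: [",
                      paste(extra, collapse = ", "), "]"),
               "niche_mismatch_error")
  }
  # Study design: the urogenital ridges were only profiled at E10.5.
  ugr_e95 <- meta$domain == "UGR" & meta$stage == "E9.5"
  if (any(ugr_e95)) {
    niche_stop(paste("UGR samples cannot carry stage E9.5:",
                     paste(meta$sample_id[ugr_e95], collapse = ", ")),
               "niche_design_error")
  }
  invisible(TRUE)
}

#' Load a GMT gene-set collection
#'
#' One set per line: name, description, then member gene identifiers; blank
#' members are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) {
    niche_stop(paste0("file not found: ", path), "niche_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      niche_stop(paste0("malformed GMT line (need name, description, members): '",
                        substr(ln, 1, 60), "'"), "niche_format_error")
    }
    nm <- fields[1]
    members <- unique(fields[-(1:2)][nzchar(trimws(fields[-(1:2)]))])
    if (!length(members)) {
      niche_stop(paste0("gene set '", nm, "' empty after cleaning"),
                 "niche_format_error")
    }
    if (nm %in% names(sets)) {
      niche_stop(paste0("duplicate gene set name: '", nm, "'"),
                 "niche_duplicate_error")
    }
    sets[[nm]] <- members
  }
  sets
}

# --- GO annotation with true-path propagation -------------------------------

GO_SECRETED_TERMS <- c("GO:0005576", "GO:0005615")

# Ancestor closure of every term in a child->parent edge list. is_a and
# part_of are treated identically. Detects cycles.
dag_ancestors <- function(edges) {
  if (is.null(edges) || !nrow(edges)) return(list())
  rel <- unique(as.character(edges[[3]]))
  unknown <- setdiff(rel, c("is_a", "part_of"))
  if (length(unknown)) {
    niche_stop(paste("unknown DAG relation labels:",
                     paste(unknown, collapse = ", ")), "niche_format_error")
  }
  parents <- split(as.character(edges[[2]]), as.character(edges[[1]]))
  anc <- new.env(parent = emptyenv())
  visit <- function(term, path) {
    if (term %in% path) {
      niche_stop(paste0("cycle in DAG involving term '", term, "'"),
                 "niche_cycle_error")
    }
    if (!is.null(anc[[term]])) return(anc[[term]])
    ps <- parents[[term]]
    out <- character(0)
    for (p in ps) out <- union(out, c(p, visit(p, c(path, term))))
    anc[[term]] <- out
    out
  }
  terms <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
  res <- lapply(terms, visit, path = character(0))
  names(res) <- terms
  res
}

#' Load gene annotations and derive secreted flags
#'
#' Reads a two-column term-to-gene table (\code{term_id}, \code{gene_id}) and,
#' optionally, a three-column DAG edge list (\code{child}, \code{parent},
#' \code{relation} in \{is_a, part_of\}). Annotations are propagated to all
#' ancestor terms (true-path rule). A gene is flagged secreted when its
#' propagated terms intersect GO:0005576 (extracellular region) or GO:0005615
#' (extracellular space).
#'
#' @param path term-to-gene TSV.
#' @param dag_path optional DAG edge TSV.
#' @return A data.frame with \code{gene_id}, \code{go_terms} (list column of
#'   propagated term sets) and \code{secreted}.
#' @export
load_annotation <- function(path, dag_path = NULL) {
  tab <- read_tsv_file(path)
  if (ncol(tab) < 2) {
    niche_stop("annotation table needs term_id and gene_id columns",
               "niche_format_error")
  }
  edges <- if (!is.null(dag_path)) read_tsv_file(dag_path) else NULL
  build_annotation(data.frame(term_id = as.character(tab[[1]]),
                              gene_id = as.character(tab[[2]]),
                              stringsAsFactors = FALSE),
                   edges)
}

#' Build an annotation table from in-memory term/gene pairs
#'
#' @param term2gene data.frame with term_id and gene_id columns.
#' @param edges optional data.frame (child, parent, relation).
#' @return As \code{\link{load_annotation}}.
#' @export
build_annotation <- function(term2gene, edges = NULL) {
  anc <- dag_ancestors(edges)
  by_gene <- split(as.character(term2gene$term_id),
                   as.character(term2gene$gene_id))
  gene_ids <- names(by_gene)
  go_terms <- lapply(by_gene, function(terms) {
    terms <- unique(terms)
    extra <- unlist(anc[intersect(terms, names(anc))], use.names = FALSE)
    union(terms, extra)
  })
  secreted <- vapply(go_terms,
                     function(t) any(t %in% GO_SECRETED_TERMS), TRUE)
  out <- data.frame(gene_id = gene_ids, secreted = unname(secreted),
                    stringsAsFactors = FALSE)
  out$go_terms <- unname(go_terms)
  out
}

#' Write a flat result table
#'
#' Tab-separated, full double precision, so reading the file back reproduces
#' the values exactly (round-trip stable to 1e-12 relative).
#'
#' @param x data.frame (list columns are collapsed with commas) or matrix.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  listcols <- vapply(x, is.list, TRUE)
  x[listcols] <- lapply(x[listcols], vapply, paste, "", collapse = ",")
  ok <- tryCatch({
    utils::write.table(format(x, digits = 17, trim = TRUE, scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) niche_stop(paste0("cannot write: ", path), "niche_io_error")
  invisible(path)
}

#' Read back a table written by \code{write_table}
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table_file <- function(path) read_tsv_file(path)
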