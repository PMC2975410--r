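#' Read a square gene-gene similarity/kernel matrix from TSV
#'
#' The file must have a header row of gene identifiers and a first column
#' repeating the same identifiers in the same order (the layout produced by
#' [write_similarity_matrix()]). Numerical asymmetry is removed by averaging
#' the matrix with its transpose.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with identical row and column names (the gene
#'   identifiers, in file order), symmetric by construction.
#' @export
read_similarity_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("similarity matrix file must have an id column plus data columns: ",
         path)
  }
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (nrow(vals) != ncol(vals)) {
    stop("similarity matrix is not square: ", nrow(vals), " rows vs ",
         ncol(vals), " columns")
  }
  if (anyDuplicated(ids)) {
    stop("duplicated gene identifiers in similarity matrix")
  }
  if (!identical(ids, colnames(vals))) {
    bad <- which(ids != colnames(vals))[1L]
    stop("row/column identifier mismatch at position ", bad, ": '",
         ids[bad], "' vs '", colnames(vals)[bad], "'")
  }
  if (!is.numeric(vals)) {
    idx <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals), arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      stop("non-numeric cell at row '", ids[idx[1L, 1L]], "', column '",
           colnames(vals)[idx[1L, 2L]], "'")
    }
    storage.mode(vals) <- "double"
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)
    stop("missing/non-numeric cell at row '", ids[idx[1L, 1L]],
         "', column '", colnames(vals)[idx[1L, 2L]], "'")
  }
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(ids, ids)
  vals
}

#' Write a similarity/kernel matrix as TSV
#'
#' @param K Square numeric matrix with row/column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(K, path) {
  validate_kernel_matrix(K)
  df <- data.frame(gene = rownames(K), K, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a kernel matrix
#'
#' Checks that `K` is square, numeric, named, and symmetric within `tol`.
#'
#' @param K Matrix to check.
#' @param tol Symmetry tolerance.
#' @return `K`, invisibly.
#' @export
validate_kernel_matrix <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || !is.numeric(K)) stop("kernel must be a numeric matrix")
  if (nrow(K) != ncol(K)) stop("kernel must be square")
  if (is.null(rownames(K)) || is.null(colnames(K))) {
    stop("kernel must carry gene identifiers as row and column names")
  }
  if (!identical(rownames(K), colnames(K))) {
    stop("kernel row and column identifiers differ")
  }
  if (anyDuplicated(rownames(K))) stop("duplicated gene identifiers in kernel")
  if (max(abs(K - t(K))) > tol) {
    stop("kernel is not symmetric within tolerance ", tol)
  }
  invisible(K)
}

#' Read gene annotations and a term DAG
#'
#' @param assign_path Two-column TSV (gene, term), no header.
#' @param dag_path Two-column TSV (parent term, child term), no header. May
#'   be an empty file for a flat term set.
#' @param gene_universe Optional character vector fixing the gene universe;
#'   defaults to the sorted unique genes seen in `assign_path`.
#' @return An `annotation_set`: list with `assignments` (data.frame gene,
#'   term; deduplicated), `dag` (data.frame parent, child) and
#'   `gene_universe`.
#' @export
read_annotations <- function(assign_path, dag_path, gene_universe = NULL) {
  asg <- utils::read.delim(assign_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(asg) < 2L) stop("annotation file needs two columns (gene, term)")
  asg <- data.frame(gene = asg[[1L]], term = asg[[2L]],
                    stringsAsFactors = FALSE)
  dag_raw <- tryCatch(
    utils::read.delim(dag_path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) data.frame(V1 = character(), V2 = character()))
  dag <- data.frame(parent = as.character(dag_raw[[1L]] %||% character()),
                    child = if (ncol(dag_raw) >= 2L)
                      as.character(dag_raw[[2L]]) else character(),
                    stringsAsFactors = FALSE)
  annotation_set(asg, dag, gene_universe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an annotation set
#'
#' @param assignments data.frame with columns `gene` and `term`.
#' @param dag data.frame with columns `parent` and `child` (term DAG edges).
#' @param gene_universe Optional gene-id vector; defaults to sorted unique
#'   genes of `assignments`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(assignments, dag = NULL, gene_universe = NULL) {
  if (is.null(dag)) {
    dag <- data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE)
  }
  assignments <- unique(assignments[, c("gene", "term")])
  rownames(assignments) <- NULL
  dag <- unique(dag[, c("parent", "child")])
  rownames(dag) <- NULL
  cyc <- find_dag_cycle(dag)
  if (!is.null(cyc)) {
    stop("term DAG contains a cycle through edge ", cyc[1L], " -> ", cyc[2L])
  }
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(assignments$gene))
  }
  structure(list(assignments = assignments, dag = dag,
                 gene_universe = gene_universe),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set: ", nrow(x$assignments), " gene-term pairs, ",
      length(unique(x$assignments$term)), " terms, ",
      length(x$gene_universe), " genes, ", nrow(x$dag), " DAG edges\n",
      sep = "")
  invisible(x)
}

# Kahn's algorithm; returns NULL if acyclic, else one edge on a cycle.
find_dag_cycle <- function(dag) {
  if (nrow(dag) == 0L) return(NULL)
  nodes <- unique(c(dag$parent, dag$child))
  indeg <- table(factor(dag$child, levels = nodes))
  alive <- rep(TRUE, nrow(dag))
  queue <- nodes[indeg == 0L]
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- which(alive & dag$parent == v)
    for (e in out) {
      alive[e] <- FALSE
      w <- dag$child[e]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (any(alive)) {
    e <- which(alive)[1L]
    c(dag$parent[e], dag$child[e])
  } else {
    NULL
  }
}

#' Read a GAF 2.x association file into the two-column form
#'
#' Keeps only the DB Object Symbol (column 3 when available is ignored;
#' column 2, the DB Object ID, is used) and the GO ID (column 5). Comment
#' lines starting with `!` are skipped; all other GAF columns are ignored.
#'
#' @param path Path to a GAF file.
#' @return data.frame with columns `gene`, `term` (deduplicated).
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 5L)
  if (length(short) > 0L) {
    stop("GAF line ", short[1L], " has fewer than 5 columns")
  }
  unique(data.frame(gene = vapply(parts, `[[`, "", 2L),
                    term = vapply(parts, `[[`, "", 5L),
                    stringsAsFactors = FALSE))
}

#' Up-propagate annotations along the term DAG (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. The operation is idempotent and keeps all original pairs.
#'
#' @param ann An `annotation_set`.
#' @return A new `annotation_set` with the transitive closure applied.
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(ann$dag) == 0L || nrow(ann$assignments) == 0L) return(ann)
  parents_of <- split(ann$dag$parent, ann$dag$child)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    ps <- parents_of[[term]]
    res <- if (is.null(ps)) character() else
      unique(c(ps, unlist(lapply(ps, ancestors), use.names = FALSE)))
    anc_cache[[term]] <- res
    res
  }
  per_term <- split(ann$assignments$gene, ann$assignments$term)
  extra <- lapply(names(per_term), function(tm) {
    anc <- ancestors(tm)
    if (length(anc) == 0L) return(NULL)
    data.frame(gene = rep(per_term[[tm]], times = length(anc)),
               term = rep(anc, each = length(per_term[[tm]])),
               stringsAsFactors = FALSE)
  })
  all_pairs <- unique(rbind(ann$assignments,
                            do.call(rbind, extra)))
  rownames(all_pairs) <- NULL
  structure(list(assignments = all_pairs, dag = ann$dag,
                 gene_universe = ann$gene_universe),
            class = "annotation_set")
}

#' Group functional terms by annotation count
#'
#' Terms are binned by the number of annotated genes using half-open
#' intervals `[0,60)`, `[60,100)`, `[100,300)`, `[300,Inf)`, labelled
#' `"<60"`, `"60-100"`, `"100-300"`, `">300"`. Boundaries are configurable.
#'
#' @param ann A (typically up-propagated) `annotation_set`.
#' @param breaks Increasing numeric vector of interior boundaries.
#' @param labels Labels, one more than `length(breaks)`.
#' @return data.frame with columns `term`, `positive_count`, `group_label`.
#' @export
group_terms_by_size <- function(ann, breaks = c(60, 100, 300),
                                labels = c("<60", "60-100", "100-300",
                                           ">300")) {
  stopifnot(inherits(ann, "annotation_set"),
            length(labels) == length(breaks) + 1L,
            !is.unsorted(breaks, strictly = TRUE))
  counts <- table(ann$assignments$term)
  cnt <- as.integer(counts)
  grp <- labels[findInterval(cnt, breaks) + 1L]
  data.frame(term = names(counts), positive_count = cnt,
             group_label = grp, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Genes annotated to one term
#'
#' @param ann An `annotation_set`.
#' @param term A term identifier.
#' @return Character vector of gene ids annotated to `term`.
#' @export
term_positives <- function(ann, term) {
  stopifnot(inherits(ann, "annotation_set"))
  unique(ann$assignments$gene[ann$assignments$term == term])
}

#' Read an expression matrix from TSV
#'
#' Header row holds condition ids, first column gene ids; empty cells or
#' `NA` encode missing values.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x conditions) with `NA` for missing values.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  x <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(tab[[1L]])
  if (any(rowSums(!is.na(x)) == 0L)) {
    bad <- rownames(x)[rowSums(!is.na(x)) == 0L][1L]
    stop("gene '", bad, "' has no observed expression value")
  }
  x
}

#' Write an expression matrix as TSV
#' @param x Numeric matrix with gene row names; `NA` written as `NA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected interaction edge list from TSV
#'
#' Two columns (no header), one edge per line; duplicate and reversed
#' duplicates are collapsed, self-loops dropped.
#'
#' @param path TSV path.
#' @param ids Optional gene universe; defaults to sorted unique endpoint
#'   ids. Edges outside `ids` are an error.
#' @return An `interaction_graph`: list with `ids` and `edges` (2-column
#'   character matrix).
#' @export
read_edge_list <- function(path, ids = NULL) {
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) data.frame(V1 = character(), V2 = character()))
  interaction_graph(as.matrix(tab[, 1:2, drop = FALSE]), ids)
}

#' Construct an interaction graph
#'
#' @param edges 2-column matrix of endpoint ids (character) or an empty
#'   matrix.
#' @param ids Gene universe; defaults to the sorted unique endpoints.
#' @return An object of class `interaction_graph`.
#' @export
interaction_graph <- function(edges, ids = NULL) {
  edges <- matrix(as.character(edges), ncol = 2L)
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  # canonical orientation, then dedup
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L)]
  edges <- unique(edges)
  if (is.null(ids)) ids <- sort(unique(as.vector(edges)))
  missing <- setdiff(as.vector(edges), ids)
  if (length(missing) > 0L) {
    stop("edge endpoint(s) outside gene universe: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  structure(list(ids = ids, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph: ", length(x$ids), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Adjacency matrix of an interaction graph
#' @param g An `interaction_graph`.
#' @return Symmetric 0/1 matrix over `g$ids`.
#' @export
graph_adjacency <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  n <- length(g$ids)
  A <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  if (nrow(g$edges) > 0L) {
    i <- match(g$edges[, 1L], g$ids)
    j <- match(g$edges[, 2L], g$ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}
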