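# Cohort data model: node metadata, subject connectivity matrices,
# Euclidean geometry, hemisphere edge classes, and plain-text I/O.

#' Read a node metadata table
#'
#' The node table is a TSV with columns `name`, `x`, `y`, `z`, `hemisphere`
#' (values "L"/"R") and optional `system` (cognitive-system label, e.g. a
#' resting-state network name). Coordinates are region centroids in mm. Row
#' order defines the node order of every connectivity matrix in the cohort.
#'
#' @param path path to the TSV file.
#' @return a validated `data.frame` of class `gn_nodes`.
#' @export
read_node_table <- function(path) {
  if (!file.exists(path)) gn_stop("node table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_node_table(df, context = path)
}

#' Construct and validate a node table from a data frame
#'
#' @param df data frame with columns `name`, `x`, `y`, `z`, `hemisphere` and
#'   optionally `system`.
#' @param context label used in error messages (e.g. the source file).
#' @return `df` with class `gn_nodes` prepended.
#' @export
as_node_table <- function(df, context = "node table") {
  req <- c("name", "x", "y", "z", "hemisphere")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    gn_stop("%s: missing required column(s): %s", context,
            paste(missing_cols, collapse = ", "))
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name))
    gn_stop("%s: duplicated node ids: %s", context,
            paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  for (cc in c("x", "y", "z")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]])))
      gn_stop("%s: non-finite coordinate in column '%s'", context, cc)
  }
  df$hemisphere <- as.character(df$hemisphere)
  if (any(is.na(df$hemisphere)) || !all(df$hemisphere %in% c("L", "R")))
    gn_stop("%s: hemisphere labels must all be 'L' or 'R'", context)
  if (!is.null(df$system)) {
    df$system <- as.character(df$system)
    if (any(is.na(df$system) | df$system == ""))
      gn_stop("%s: system labels, when present, must cover all nodes", context)
  }
  rownames(df) <- NULL
  class(df) <- c("gn_nodes", "data.frame")
  df
}

read_matrix_file <- function(path, node_names = NULL) {
  if (!file.exists(path)) gn_stop("matrix file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  # header detection: a header row is non-numeric
  toks <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  toks <- toks[toks != ""]
  has_header <- suppressWarnings(any(is.na(as.numeric(toks))))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  # drop a leading row-name column if present (non-numeric first column)
  if (ncol(df) > 1 && is.character(df[[1]]))
    df <- df[, -1L, drop = FALSE]
  m <- as.matrix(df)
  if (!is.numeric(m))
    gn_stop("matrix file %s contains non-numeric entries", path)
  dimnames(m) <- NULL
  if (!is.null(node_names) && nrow(m) == ncol(m) &&
      nrow(m) == length(node_names))
    dimnames(m) <- list(node_names, node_names)
  m
}

validate_subject_matrix <- function(m, n, label, tol = 1e-8,
                                    zero_diagonal = FALSE) {
  if (nrow(m) != ncol(m))
    gn_stop("%s: matrix is %d x %d, not square", label, nrow(m), ncol(m))
  if (!is.null(n) && nrow(m) != n)
    gn_stop("%s: matrix is %d x %d but the node table has %d nodes",
            label, nrow(m), ncol(m), n)
  if (any(!is.finite(m)))
    gn_stop("%s: non-finite entries", label)
  if (max(abs(m - t(m))) > tol)
    gn_stop("%s: matrix is asymmetric beyond tolerance %g", label, tol)
  if (any(m < 0))
    gn_stop("%s: negative entries are not allowed", label)
  if (any(diag(m) != 0)) {
    if (zero_diagonal) diag(m) <- 0
    else gn_stop("%s: nonzero diagonal (use zero_diagonal = TRUE to zero it)",
                 label)
  }
  m <- (m + t(m)) / 2  # remove sub-tolerance asymmetry
  m
}

#' Load a subject cohort from matrix files and a node table
#'
#' Each matrix file is an N x N delimited-text table (tab or comma,
#' autodetected; optional header row of node ids) of nonnegative symmetric
#' connectivity weights with zero diagonal, in streamline-density-like units.
#' Subject order follows the order of `matrix_paths`.
#'
#' @param matrix_paths character vector of matrix file paths, one per subject.
#' @param node_table_path path to the node metadata TSV (see
#'   [read_node_table()]).
#' @param subject_ids optional subject identifiers; defaults to file base
#'   names.
#' @param zero_diagonal if TRUE, nonzero diagonals are zeroed instead of
#'   raising an error.
#' @param tol symmetry tolerance.
#' @return an object of class `gn_cohort`: list with elements `matrices`
#'   (list of N x N matrices), `nodes` (`gn_nodes`), `subject_ids`.
#' @export
load_cohort <- function(matrix_paths, node_table_path, subject_ids = NULL,
                        zero_diagonal = FALSE, tol = 1e-8) {
  if (length(matrix_paths) < 1L) gn_stop("need at least one matrix file")
  nodes <- read_node_table(node_table_path)
  mats <- lapply(matrix_paths, read_matrix_file, node_names = nodes$name)
  mats <- mapply(validate_subject_matrix, mats,
                 label = matrix_paths,
                 MoreArgs = list(n = nrow(nodes), tol = tol,
                                 zero_diagonal = zero_diagonal),
                 SIMPLIFY = FALSE)
  ids <- subject_ids %||% tools::file_path_sans_ext(basename(matrix_paths))
  new_cohort(mats, nodes, ids)
}

#' Construct a cohort from in-memory matrices
#'
#' @param matrices list of N x N symmetric nonnegative matrices with zero
#'   diagonal.
#' @param nodes a `gn_nodes` node table (or data frame coercible via
#'   [as_node_table()]).
#' @param subject_ids optional character ids, default `"s01"`, `"s02"`, ...
#' @param tol symmetry tolerance.
#' @return a `gn_cohort`.
#' @export
new_cohort <- function(matrices, nodes, subject_ids = NULL, tol = 1e-8) {
  if (!inherits(nodes, "gn_nodes")) nodes <- as_node_table(nodes)
  t_sub <- length(matrices)
  if (t_sub < 1L) gn_stop("cohort must contain at least one subject")
  ids <- subject_ids %||% sprintf("s%02d", seq_len(t_sub))
  stopifnot(length(ids) == t_sub)
  matrices <- mapply(validate_subject_matrix, matrices,
                     label = paste0("subject ", ids),
                     MoreArgs = list(n = nrow(nodes), tol = tol),
                     SIMPLIFY = FALSE)
  matrices <- lapply(matrices, function(m) {
    dimnames(m) <- list(nodes$name, nodes$name); m
  })
  structure(list(matrices = matrices, nodes = nodes,
                 subject_ids = as.character(ids)),
            class = "gn_cohort")
}

#' @export
print.gn_cohort <- function(x, ...) {
  n <- nrow(x$nodes)
  dens <- vapply(x$matrices, function(m) sum(m[upper.tri(m)] > 0), 0) /
    (n * (n - 1) / 2)
  cat(sprintf("gn_cohort: %d subjects, %d nodes; mean subject density %.4f\n",
              length(x$matrices), n, mean(dens)))
  invisible(x)
}

#' Euclidean inter-node distance matrix
#'
#' @param nodes a `gn_nodes` table with centroid columns `x`, `y`, `z` in mm.
#' @return symmetric N x N matrix of Euclidean centroid distances (mm).
#' @export
euclidean_distances <- function(nodes) {
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) gn_stop("non-finite centroid coordinates")
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(nodes$name, nodes$name)
  d
}

#' Partition node pairs into intra- and inter-hemispheric classes
#'
#' Thresholds in the density-matched and distance-dependent builders are
#' applied separately to these two classes, mirroring the anatomical
#' distinction between callosal (inter-hemispheric) and within-hemisphere
#' connections.
#'
#' @param nodes a `gn_nodes` table with a `hemisphere` column.
#' @return object of class `gn_classes`: list with `pairs` (the canonical
#'   [upper_pairs()] matrix) and `class` (character vector, "intra"/"inter",
#'   aligned with `pairs` rows).
#' @export
hemisphere_partition <- function(nodes) {
  h <- nodes$hemisphere
  if (is.null(h) || any(is.na(h))) gn_stop("missing hemisphere labels")
  pairs <- upper_pairs(nrow(nodes))
  cls <- ifelse(h[pairs[, 1L]] == h[pairs[, 2L]], "intra", "inter")
  structure(list(pairs = pairs, class = cls), class = "gn_classes")
}

#' Trivial single-class partition
#'
#' Used when class-restricted thresholding is disabled: all node pairs belong
#' to one class "all".
#'
#' @param n number of nodes.
#' @return a `gn_classes` object with a single class.
#' @export
single_class_partition <- function(n) {
  pairs <- upper_pairs(n)
  structure(list(pairs = pairs, class = rep("all", nrow(pairs))),
            class = "gn_classes")
}

#' Write / read a group network as delimited text
#'
#' The matrix is written as a TSV with node ids as header row and first
#' column; round-trips losslessly to within 1e-12.
#'
#' @param net a `gn_group` object (see [build_group_network()]) or a plain
#'   symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_network <- function(net, path) {
  w <- if (inherits(net, "gn_group")) net$weights else net
  df <- as.data.frame(w, check.names = FALSE)
  df <- cbind(node = rownames(w) %||% paste0("n", seq_len(nrow(w))), df)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) gn_stop("cannot write group network to %s", path)
  invisible(path)
}

#' @rdname write_group_network
#' @export
read_group_network <- function(path) {
  read_matrix_file(path)
}

#' Write an evaluation report (or any result list) as JSON
#'
#' Method provenance, parameters and the random seed are serialized alongside
#' the numbers so every reported statistic can be recomputed.
#'
#' @param report a named list; typically contains elements `method`, `seed`,
#'   `parameters` plus result fields.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gn_stop("cannot write report to %s", path)
  invisible(path)
}
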