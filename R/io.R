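#' Construct a functional connectome object
#'
#' A functional connectome is a weighted, undirected whole-brain graph: a
#' square matrix of functional couplings between labelled regions of interest.
#' The constructor validates shape and labelling only; numerical cleaning
#' (zeroing negative couplings, symmetrizing, emptying the diagonal) is done by
#' [sanitize_connectome()].
#'
#' @param weights Square numeric matrix of couplings.
#' @param node_ids Character vector of region labels; defaults to the matrix
#'   dimnames or `n001 ...` when unnamed.
#' @return An object of class `connectome`: a list with elements `weights`
#'   (matrix with dimnames), `node_ids`, and `sanitized` (logical).
#' @export
as_connectome <- function(weights, node_ids = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    .stopf("fnmorph_format_error", "connectome weights must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    .stopf("fnmorph_format_error", "connectome matrix must be square, got %d x %d",
           nrow(weights), ncol(weights))
  }
  n <- nrow(weights)
  if (is.null(node_ids)) {
    node_ids <- rownames(weights) %||% colnames(weights) %||% sprintf("n%03d", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    .stopf("fnmorph_format_error", "node_ids must be %d unique labels", n)
  }
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(weights = weights, node_ids = node_ids, sanitized = FALSE),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Functional connectome: %d nodes%s\n", length(x$node_ids),
              if (isTRUE(x$sanitized)) " (sanitized)" else " (raw)"))
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("  weights: min %.4g, median %.4g, max %.4g, density %.3f\n",
              min(w), stats::median(w), max(w), mean(w > 0)))
  if (!is.null(x$report)) {
    cat(sprintf("  sanitization: %d negative cells zeroed, max asymmetry %.3g\n",
                x$report$n_negative_zeroed, x$report$max_asymmetry))
  }
  invisible(x)
}

.detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a connectome matrix from disk
#'
#' Delimited text (comma, tab or whitespace separated, `.` decimal, optional
#' header row of node ids) or an RDS container holding a named square matrix.
#' The result is raw: no sanitization is applied.
#'
#' @param path File path.
#' @param dialect `"auto"` (default, by file extension), `"delim"` or `"rds"`.
#' @return A raw [as_connectome()] object.
#' @export
load_connectome <- function(path, dialect = c("auto", "delim", "rds")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("fnmorph_io_error", "cannot read connectome: %s", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "delim"
  }
  if (dialect == "rds") {
    m <- readRDS(path)
    if (is.list(m) && !is.null(m$weights)) return(as_connectome(m$weights, m$node_ids))
    return(as_connectome(m))
  }
  first <- readLines(path, n = 1L)
  sep <- .detect_sep(first)
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(tab)
  if (!is.numeric(m)) .stopf("fnmorph_format_error", "non-numeric entries in %s", path)
  if (nrow(m) != ncol(m)) {
    .stopf("fnmorph_format_error", "matrix in %s is %d x %d, expected square",
           path, nrow(m), ncol(m))
  }
  ids <- if (has_header) colnames(m) else NULL
  rownames(m) <- NULL
  as_connectome(m, ids)
}

#' Write a connectome matrix
#'
#' Inverse of [load_connectome()]: delimited text with a header row of node
#' ids, or an RDS container. Written with full double precision so that a
#' write/load round trip is bitwise exact.
#'
#' @param fc A `connectome`.
#' @param path Output path.
#' @param dialect `"delim"` (CSV, default) or `"rds"`.
#' @export
write_connectome <- function(fc, path, dialect = c("delim", "rds")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(fc, "connectome"))
  if (dialect == "rds") {
    saveRDS(list(weights = fc$weights, node_ids = fc$node_ids), path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(fc$node_ids, collapse = ","), con)
  utils::write.table(format(fc$weights, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Sanitize a functional connectome
#'
#' Applies the cleaning rules the morphospace assumes: negative couplings are
#' set to zero (they are not modelled), the diagonal is forced to zero (the
#' chain moves between distinct states; self-loops would inflate absorption
#' times arbitrarily), and small numerical asymmetry is removed by averaging
#' `(A + t(A))/2`. Larger asymmetry, or any non-finite entry, is an error:
#' the framework is defined for undirected weighted graphs.
#'
#' @param fc A raw `connectome`.
#' @param symmetry_tol Maximum tolerated `max(abs(A - t(A)))` before averaging.
#' @return A sanitized `connectome`; `$report` lists `n_negative_zeroed` (cells,
#'   counting both triangle copies) and `max_asymmetry`.
#' @export
sanitize_connectome <- function(fc, symmetry_tol = 1e-8) {
  stopifnot(inherits(fc, "connectome"))
  A <- fc$weights
  if (any(!is.finite(A))) {
    .stopf("fnmorph_validation_error", "connectome contains non-finite entries")
  }
  asym <- max(abs(A - t(A)))
  if (asym > symmetry_tol) {
    .stopf("fnmorph_validation_error",
           "asymmetry %.3g exceeds tolerance %.3g; not an undirected connectome",
           asym, symmetry_tol)
  }
  A <- (A + t(A)) / 2
  diag(A) <- 0
  neg <- A < 0
  n_neg <- sum(neg)
  A[neg] <- 0
  if (any(A > 1)) {
    warning("couplings > 1 present; the trapping-efficiency upper bound is only ",
            "characterized for weights in [0, 1]", call. = FALSE)
  }
  out <- as_connectome(A, fc$node_ids)
  out$sanitized <- TRUE
  out$report <- list(n_negative_zeroed = n_neg, max_asymmetry = asym)
  out
}

#' Read a node-to-community partition
#'
#' Two-column TSV `node_id<TAB>community`, no header required (a header line
#' `node_id  community` is tolerated).
#'
#' @param path File path.
#' @return A `partition`: named character vector mapping node id to community.
#' @export
load_partition <- function(path) {
  if (!file.exists(path)) .stopf("fnmorph_io_error", "cannot read partition: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("node_id", "community"),
                           colClasses = "character", comment.char = "")
  if (identical(tolower(tab$node_id[1]), "node_id")) tab <- tab[-1, , drop = FALSE]
  as_partition(stats::setNames(tab$community, tab$node_id))
}

#' @rdname load_partition
#' @param assignment Named character vector: `names` are node ids, values are
#'   community labels.
#' @export
as_partition <- function(assignment) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    .stopf("fnmorph_validation_error", "partition needs unique node names")
  }
  structure(as.character(assignment), names = names(assignment), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- table(unclass(x))
  cat(sprintf("Partition: %d nodes in %d communities\n", length(x), length(sizes)))
  print(sizes)
  invisible(x)
}

#' Validate that a partition covers a connectome
#'
#' Every node of the connectome must carry exactly one community label and
#' every community must be nonempty (the communities exhaust the vertex set).
#'
#' @param partition A `partition`.
#' @param fc A `connectome`.
#' @return The partition, restricted and reordered to the connectome's nodes.
#' @export
validate_partition <- function(partition, fc) {
  missing <- setdiff(fc$node_ids, names(partition))
  if (length(missing)) {
    .stopf("fnmorph_validation_error",
           "partition missing node(s): %s", paste(missing, collapse = ", "))
  }
  as_partition(partition[fc$node_ids])
}

#' Read a cohort manifest
#'
#' Delimited table (comma or tab) with columns `subject`, `condition`,
#' `session`, `path` mapping each connectome file to its cohort cell.
#'
#' @param path Manifest file path.
#' @param check_paths Verify that every referenced matrix file exists
#'   (relative paths are resolved against the manifest's directory).
#' @return A `manifest` data frame.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) .stopf("fnmorph_io_error", "cannot read manifest: %s", path)
  first <- readLines(path, n = 1L)
  sep <- .detect_sep(first)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", comment.char = "")
  as_manifest(tab, base_dir = dirname(path), check_paths = check_paths)
}

#' @rdname load_manifest
#' @param records Data frame with columns subject, condition, session, path.
#' @param base_dir Directory against which relative paths resolve.
#' @export
as_manifest <- function(records, base_dir = ".", check_paths = TRUE) {
  need <- c("subject", "condition", "session", "path")
  if (!all(need %in% names(records))) {
    .stopf("fnmorph_format_error", "manifest needs columns: %s",
           paste(need, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  key <- do.call(paste, c(records[c("subject", "condition", "session")], sep = "\r"))
  if (anyDuplicated(key)) {
    .stopf("fnmorph_validation_error",
           "duplicate (subject, condition, session) triple(s) in manifest")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", records$path) & !is.na(records$path)
  records$path[rel] <- file.path(base_dir, records$path[rel])
  if (check_paths) {
    gone <- records$path[!is.na(records$path) & !file.exists(records$path)]
    if (length(gone)) {
      .stopf("fnmorph_validation_error", "manifest references missing file(s): %s",
             paste(utils::head(gone, 3), collapse = ", "))
    }
  }
  class(records) <- c("manifest", "data.frame")
  records
}

#' Read a behavioral score table
#'
#' One row per subject; first column `subject`, remaining columns numeric
#' scores (e.g. episodic memory, fluid intelligence gF, general intelligence g
#' — g is accepted as a supplied column, never derived here).
#'
#' @param path Delimited file path.
#' @return Data frame with character `subject` and numeric score columns.
#' @export
load_behavior <- function(path) {
  if (!file.exists(path)) .stopf("fnmorph_io_error", "cannot read behavior table: %s", path)
  first <- readLines(path, n = 1L)
  tab <- utils::read.table(path, header = TRUE, sep = .detect_sep(first),
                           comment.char = "")
  if (!"subject" %in% names(tab)) {
    .stopf("fnmorph_format_error", "behavior table needs a 'subject' column")
  }
  tab$subject <- as.character(tab$subject)
  if (anyDuplicated(tab$subject)) {
    .stopf("fnmorph_validation_error", "behavior table has duplicate subjects")
  }
  num <- tab[setdiff(names(tab), "subject")]
  if (!all(vapply(num, is.numeric, logical(1))) || any(!is.finite(as.matrix(num)))) {
    .stopf("fnmorph_validation_error", "behavior scores must be finite numerics")
  }
  tab
}

#' Write / read delimited result tables
#'
#' All result tables (coordinates, breadth, ICC, model summaries) are plain
#' delimited text so that `read_table_fnm(write_table_fnm(x))` round-trips.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_table_fnm <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_fnm
#' @export
read_table_fnm <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "",
                    stringsAsFactors = FALSE)
}

#' Read a key=value configuration file
#'
#' Plain `key = value` lines; `#` comments and blank lines ignored. Values that
#' parse as numbers are returned numeric.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) .stopf("fnmorph_format_error", "bad config line: %s", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
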