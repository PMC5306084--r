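#' Read a log2 expression matrix from a tab-delimited file
#'
#' The expected layout is the one written by \code{\link{write_expression_matrix}}:
#' a header row with \code{probe_id} followed by sample identifiers, then one
#' row per probe set with the probe identifier in the first column and log2
#' intensities in the remaining columns.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (probes x samples) with unique row and column
#'   names, all values finite.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0L) {
    stop("expression matrix file is empty: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) < 1L || ncol(df) < 2L) {
    stop("expression matrix file is empty or has no sample columns: ", path)
  }
  probes <- as.character(df[[1L]])
  dup <- probes[duplicated(probes)]
  if (length(dup)) {
    stop("duplicate probe id(s) in expression matrix: ",
         paste(unique(dup), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop("non-numeric expression value at row ", bad,
           ", column '", colnames(body)[j], "'")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- probes
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV with full precision
#'
#' Values are rendered with \code{format(..., digits = 17)} so that a
#' write/read round trip reproduces every value exactly.
#'
#' @param matrix Numeric matrix with probe row names and sample column names.
#' @param path Output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  validate_expression_matrix(matrix)
  df <- data.frame(probe_id = rownames(matrix),
                   matrix, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(NULL)
}

#' Validate an expression matrix
#'
#' Enforces the container invariants: unique probe and sample identifiers,
#' at least one probe and one sample, all values finite (the source platform
#' yields complete matrices; missing values are rejected at read time).
#'
#' @param matrix Numeric matrix, probes x samples.
#' @return The matrix, invisibly.
#' @export
validate_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("expression matrix must have at least one probe and one sample")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must carry probe row names and sample column names")
  }
  if (anyDuplicated(rownames(matrix))) stop("probe ids must be unique")
  if (anyDuplicated(colnames(matrix))) stop("sample ids must be unique")
  if (!all(is.finite(matrix))) {
    stop("expression matrix contains non-finite values (NA/NaN/Inf not supported)")
  }
  invisible(matrix)
}

#' Read a sample design table
#'
#' Columns: \code{sample_id}, \code{role} (one of \code{day0_control},
#' \code{diff_control}, \code{treated}, \code{vehicle_control}),
#' \code{compound}, \code{compound_class}, \code{concentration},
#' \code{conc_unit}, \code{system}, \code{batch}, \code{replicate}.
#' Empty strings in compound/concentration columns are read as NA.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the columns above.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  validate_sample_design(df)
}

.design_roles <- c("day0_control", "diff_control", "treated", "vehicle_control")

#' Validate a sample design table, optionally against a matrix
#'
#' @param design Design data.frame.
#' @param matrix Optional expression matrix; every design sample must then be
#'   a column of the matrix.
#' @return The design, invisibly usable.
#' @export
validate_sample_design <- function(design, matrix = NULL) {
  need <- c("sample_id", "role", "batch", "replicate")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  for (opt in c("compound", "compound_class", "concentration", "conc_unit", "system")) {
    if (!opt %in% colnames(design)) design[[opt]] <- NA
  }
  if (anyDuplicated(design$sample_id)) stop("design sample_id values must be unique")
  bad <- setdiff(unique(design$role), .design_roles)
  if (length(bad)) {
    stop("unknown role(s) in design: ", paste(bad, collapse = ", "),
         " (expected ", paste(.design_roles, collapse = "/"), ")")
  }
  if (!is.null(matrix)) {
    absent <- setdiff(design$sample_id, colnames(matrix))
    if (length(absent)) {
      stop("design references sample(s) absent from the matrix: ",
           paste(absent, collapse = ", "))
    }
  }
  design
}

#' Read a probe-to-gene-symbol annotation table
#'
#' Two tab-separated columns, \code{probe_id} and \code{symbol}; probes
#' mapping to several genes appear on repeated rows. Rows with an empty
#' symbol are dropped.
#'
#' @param path Path to a TSV file (with header).
#' @return A data.frame with columns \code{probe_id}, \code{symbol}, one row
#'   per mapping, duplicates removed.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("annotation must have two columns: probe_id, symbol")
  df <- df[, 1:2]
  colnames(df) <- c("probe_id", "symbol")
  df <- df[!is.na(df$symbol) & nzchar(df$symbol), , drop = FALSE]
  unique(df)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member
#' identifiers. Duplicate members within a line are collapsed. Whether the
#' identifiers are probe sets or gene symbols is declared once for the whole
#' collection and carried on the result, so downstream set operations can
#' refuse to mix namespaces silently.
#'
#' @param path Path to a GMT file.
#' @param namespace Identifier namespace of the members, \code{"symbol"} or
#'   \code{"probe"}.
#' @return A named list of character vectors with attributes
#'   \code{descriptions} (named character) and \code{namespace}.
#' @export
read_gmt <- function(path, namespace = c("symbol", "probe")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " (", f[1L], ") has no members")
    sets[[f[1L]]] <- members
    descs[[f[1L]]] <- f[2L]
  }
  attr(sets, "descriptions") <- descs
  attr(sets, "namespace") <- namespace
  sets
}

#' Write a stage result to disk
#'
#' Data frames are written as TSV with deterministic column order and at
#' least 15 significant digits; lists are written as JSON (unboxed scalars,
#' full precision). Writing the same object twice yields identical bytes.
#'
#' @param results A data.frame (for \code{format = "tsv"}) or any
#'   JSON-serializable list.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(results)) stop("TSV output requires a data.frame")
    num <- vapply(results, is.numeric, logical(1L))
    out <- results
    out[num] <- lapply(results[num], function(x)
      format(x, digits = 15, scientific = FALSE, trim = TRUE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  }
  invisible(NULL)
}
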