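#' Read a GMT gene-set file
#'
#' GMT is the tab-separated exchange format used by MSigDB: one gene set per
#' line, fields `name`, `description`, then one or more gene identifiers.
#' Duplicate members within a line are dropped with a warning; duplicate set
#' names across lines are an error. Empty trailing fields are ignored.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()] with member order preserved.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  descs <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[!(seq_along(f) > 2 & !nzchar(f))]  # drop empty trailing member fields
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)))
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s' (line %d): %d duplicate member(s) dropped",
                      f[1L], i, sum(duplicated(members))))
      members <- members[!duplicated(members)]
    }
    sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  gene_set_collection(sets, descriptions = descs, provenance = path)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  descs <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, descs[[nm]], gsc[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Map gene sets to an expression matrix and filter by size
#'
#' Replaces each set's members by their intersection with the matrix's gene
#' identifiers (exact, case-sensitive string match) and then removes sets
#' whose mapped size falls outside `[min_size, max_size]`. Gene-set analyses
#' conventionally discard very small sets (unstable scores) and very large
#' ones (uninformative), with default bounds 10 and 500 genes, both
#' inclusive.
#'
#' @param gsc a [gene_set_collection()].
#' @param expr an [expression_matrix()] (or any matrix with gene rownames).
#' @param min_size,max_size inclusive size bounds after mapping.
#' @return The filtered [gene_set_collection()]. Idempotent.
#' @export
apply_size_filter <- function(gsc, expr, min_size = 10L, max_size = 500L) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_size > max_size) stop("min_size must be <= max_size")
  gene_ids <- rownames(expr)
  if (is.null(gene_ids)) stop("'expr' has no gene identifiers (rownames)")
  mapped <- lapply(unclass(gsc), function(m) m[m %in% gene_ids])
  sizes <- lengths(mapped)
  keep <- sizes >= min_size & sizes <= max_size
  message(sprintf("size filter [%d, %d]: kept %d of %d gene sets (%d too small, %d too large)",
                  min_size, max_size, sum(keep), length(keep),
                  sum(sizes < min_size), sum(sizes > max_size)))
  if (!any(keep)) stop("no gene sets survive filtering")
  gene_set_collection(mapped[keep],
                      descriptions = attr(gsc, "descriptions")[keep],
                      provenance = attr(gsc, "provenance"))
}

#' Drop low-variability genes by interquartile range
#'
#' Non-specific filtering: genes are ranked by their IQR across samples and
#' the `floor(p * drop_fraction)` genes with lowest IQR are removed. Ties at
#' the cut boundary keep earlier rows; survivor row order is preserved.
#'
#' @param expr an [expression_matrix()] with continuous values.
#' @param drop_fraction fraction of genes to drop, in `[0, 1)`; default 0.5
#'   (the common "drop the less variable half" rule).
#' @return The filtered [expression_matrix()].
#' @export
iqr_filter <- function(expr, drop_fraction = 0.5) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  if (value_kind(expr) != "continuous")
    stop("iqr_filter expects continuous expression values")
  p <- nrow(expr)
  k <- floor(p * drop_fraction)
  if (k == 0L) return(expr)
  iqrs <- apply(expr, 1L, IQR)
  # ascending IQR; among ties, later rows are dropped first so earlier rows survive
  drop_idx <- order(iqrs, -seq_len(p))[seq_len(k)]
  keep <- sort(setdiff(seq_len(p), drop_idx))
  expression_matrix(unclass(expr)[keep, , drop = FALSE], value_kind(expr))
}

num_or_na <- function(s) suppressWarnings(as.numeric(s))

#' Read an expression matrix from delimited text
#'
#' Expects a TSV with a header row of sample identifiers and gene
#' identifiers in the first column. Lines starting with `#` are ignored.
#'
#' @param path input path.
#' @param value_kind `"continuous"` or `"counts"`; counts must be
#'   non-negative integers.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, value_kind = c("continuous", "counts")) {
  value_kind <- match.arg(value_kind)
  m <- read_tsv_matrix(path, what = "expression")
  if (value_kind == "counts") {
    bad <- which(m != floor(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("counts requested but non-count value %g at gene '%s', sample '%s'",
                   m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  expression_matrix(m, value_kind)
}

read_tsv_matrix <- function(path, what = "matrix") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(what, " file has no data rows: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop(what, " file needs a header row with sample identifiers")
  sample_ids <- header[-1L]
  if (all(!is.na(num_or_na(sample_ids))))
    stop(what, " file appears to be missing its header row (all header fields are numeric)")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n <- length(sample_ids)
  vals <- matrix(NA_real_, length(body), n)
  ids <- character(length(body))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != n + 1L)
      stop(sprintf("%s row %d has %d fields, expected %d", what, i, length(f), n + 1L))
    ids[i] <- f[1L]
    v <- num_or_na(f[-1L])
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row %d ('%s'), column %d ('%s')",
                   f[-1L][j], i, f[1L], j, sample_ids[j]))
    }
    vals[i, ] <- v
  }
  dimnames(vals) <- list(ids, sample_ids)
  vals
}

format_sig <- function(x, digits = 12L) {
  formatC(x, digits = digits, format = "g", flag = "-")
}

write_tsv_matrix <- function(m, path, comments = character(0), digits = 12L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(row) paste(trimws(format_sig(row, digits)), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write and read score / expression matrices as TSV
#'
#' Numbers are written with 12 significant digits; `#`-prefixed comment
#' lines (e.g. a reproducibility header) are allowed and skipped on read.
#'
#' @param em matrix to write (typically an [enrichment_matrix()]).
#' @param path file path.
#' @param comments character vector of comment lines (written `# `-prefixed).
#' @return `path` invisibly (writers); a plain numeric matrix (`read_scores`).
#' @export
write_scores <- function(em, path, comments = character(0)) {
  write_tsv_matrix(as.matrix(em), path, comments = comments)
}

#' @rdname write_scores
#' @param expr an [expression_matrix()].
#' @export
write_expression <- function(expr, path, comments = character(0)) {
  write_tsv_matrix(unclass(expr), path, comments = comments)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read_tsv_matrix(path, what = "score")
}
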