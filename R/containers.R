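#' Expression matrix container
#'
#' Wraps a genes-by-samples numeric matrix together with a declared value
#' kind. Continuous matrices hold normalized (e.g. log2 microarray)
#' intensities; count matrices hold non-negative integer RNA-seq counts.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   row and column names (gene and sample identifiers).
#' @param value_kind `"continuous"` or `"counts"`.
#' @return An `expr_matrix`: the matrix with a `value_kind` attribute.
#' @examples
#' x <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- expression_matrix(x, "continuous")
#' value_kind(em)
#' @export
expression_matrix <- function(values, value_kind = c("continuous", "counts")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene identifiers (rownames) and sample identifiers (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (value_kind == "counts") {
    if (any(values < 0))
      stop("value_kind = \"counts\" but negative entries found")
    if (any(values != floor(values)))
      stop("value_kind = \"counts\" but fractional entries found")
  }
  structure(values, value_kind = value_kind, class = c("expr_matrix", class(values)))
}

#' @rdname expression_matrix
#' @param x an object.
#' @export
value_kind <- function(x) {
  vk <- attr(x, "value_kind")
  if (is.null(vk)) "continuous" else vk
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s values)\n",
              nrow(x), ncol(x), value_kind(x)))
  invisible(x)
}

as_plain_matrix <- function(x) {
  attr(x, "value_kind") <- NULL
  class(x) <- "matrix"
  x[] <- as.numeric(x)
  x
}

#' Gene-set collection container
#'
#' A named list of character vectors of gene identifiers, as parsed from a
#' GMT file or built in code. Member lists are ordered and duplicate-free;
#' set names are unique.
#'
#' @param sets named list of character vectors (members).
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled to the number of sets.
#' @param provenance character scalar recording where the collection came from.
#' @return A `gene_set_collection`.
#' @examples
#' gsc <- gene_set_collection(list(S1 = c("g1", "g2"), S2 = c("g2", "g3")))
#' set_sizes(gsc)
#' @export
gene_set_collection <- function(sets, descriptions = NULL, provenance = "in-memory") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list with non-empty names")
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    m[!duplicated(m)]
  })
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, provenance = provenance,
            class = "gene_set_collection")
}

#' @rdname gene_set_collection
#' @param x a `gene_set_collection`.
#' @export
set_sizes <- function(x) vapply(x, length, integer(1L))

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- set_sizes(x)
  cat(sprintf("gene-set collection: %d sets (sizes %s..%s) from %s\n",
              length(x), if (length(sz)) min(sz) else NA,
              if (length(sz)) max(sz) else NA,
              attr(x, "provenance")))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  y <- unclass(x)[i]
  gene_set_collection(y,
                      descriptions = attr(x, "descriptions")[names(y)],
                      provenance = attr(x, "provenance"))
}

#' Enrichment (pathway-activity) score matrix
#'
#' Gene sets by samples matrix of per-sample enrichment scores, tagged with
#' the method that produced it and its full parameter record.
#'
#' @param scores numeric matrix, sets in rows, samples in columns.
#' @param method one of `"gsva"`, `"plage"`, `"zscore"`, `"ssgsea"`.
#' @param params named list of the parameters used.
#' @return An `enrichment_matrix`.
#' @export
enrichment_matrix <- function(scores, method, params = list()) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  method <- match.arg(method, c("gsva", "plage", "zscore", "ssgsea"))
  structure(scores, method = method, params = params,
            class = c("enrichment_matrix", class(scores)))
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment matrix (%s): %d gene sets x %d samples\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}
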