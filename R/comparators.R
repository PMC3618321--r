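# Row-standardize to mean 0 / SD 1 across samples; used by PLAGE and the
# combined z-score. Constant rows come back as NaN and are handled by the
# callers.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  (x - mu) / s
}

warn_if_counts <- function(expr, method) {
  if (value_kind(expr) == "counts")
    warning(method, " assumes continuous values; count data used as-is")
}

drop_constant <- function(genes, s, set_name) {
  keep <- s[genes] > 0
  if (!all(keep))
    warning(sprintf("gene set '%s': dropped %d constant gene(s)",
                    set_name, sum(!keep)))
  genes[keep]
}

#' PLAGE pathway activity scores
#'
#' Pathway Level Analysis of Gene Expression: each gene's profile is
#' standardized across samples, and a gene set's activity profile is the
#' first right-singular vector of the SVD of its standardized submatrix —
#' the per-sample coefficients of the set's dominant expression pattern.
#' Scores have unit Euclidean norm across samples. The SVD sign is fixed so
#' that the score profile aligns (non-negative inner product) with the
#' per-sample mean of the standardized set genes, making positive activity
#' correspond to above-average expression.
#'
#' @param expr an [expression_matrix()] (continuous; counts trigger a
#'   warning and are used as-is).
#' @param gsc a [gene_set_collection()] mapped to `expr` (see
#'   [apply_size_filter()]). Constant genes are dropped per set with a
#'   warning; a set with no non-constant genes scores 0 everywhere.
#' @return An [enrichment_matrix()].
#' @export
plage <- function(expr, gsc) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (ncol(expr) < 2L) stop("plage requires n >= 2 samples")
  warn_if_counts(expr, "plage")
  x <- as_plain_matrix(expr)
  s <- apply(x, 1L, sd)
  z <- standardize_rows(x)
  scores <- matrix(0, length(gsc), ncol(x),
                   dimnames = list(names(gsc), colnames(x)))
  for (k in seq_along(gsc)) {
    genes <- gene_check(gsc[[k]], rownames(x), names(gsc)[k])
    genes <- drop_constant(genes, s, names(gsc)[k])
    if (!length(genes)) {
      warning(sprintf("gene set '%s': no usable genes; scores set to 0", names(gsc)[k]))
      next
    }
    sub <- z[genes, , drop = FALSE]
    v1 <- svd(sub, nu = 0L, nv = 1L)$v[, 1L]
    if (sum(v1 * colMeans(sub)) < 0) v1 <- -v1
    scores[k, ] <- v1
  }
  enrichment_matrix(scores, method = "plage", params = list())
}

gene_check <- function(members, gene_ids, set_name) {
  miss <- setdiff(members, gene_ids)
  if (length(miss))
    stop(sprintf("gene set '%s': %d member(s) missing from the expression matrix; run apply_size_filter() first",
                 set_name, length(miss)))
  members
}

#' Combined z-score pathway activity
#'
#' Stouffer combination of standardized expression: each gene profile is
#' standardized across samples and a set's per-sample score is
#' `sum(z_ij) / sqrt(|set|)` over the set's genes, so that under
#' independent standard-normal gene z-scores the set score is again
#' standard normal.
#'
#' @inheritParams plage
#' @return An [enrichment_matrix()].
#' @export
combined_zscore <- function(expr, gsc) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (ncol(expr) < 2L) stop("combined_zscore requires n >= 2 samples")
  warn_if_counts(expr, "combined_zscore")
  x <- as_plain_matrix(expr)
  s <- apply(x, 1L, sd)
  z <- standardize_rows(x)
  scores <- matrix(0, length(gsc), ncol(x),
                   dimnames = list(names(gsc), colnames(x)))
  for (k in seq_along(gsc)) {
    genes <- gene_check(gsc[[k]], rownames(x), names(gsc)[k])
    genes <- drop_constant(genes, s, names(gsc)[k])
    if (!length(genes)) {
      warning(sprintf("gene set '%s': no usable genes; scores set to 0", names(gsc)[k]))
      next
    }
    scores[k, ] <- colSums(z[genes, , drop = FALSE]) / sqrt(length(genes))
  }
  enrichment_matrix(scores, method = "zscore", params = list())
}

#' ssGSEA single-sample enrichment
#'
#' Per sample, genes are ranked by expression (1 = lowest; ties broken by
#' gene row order) and, for each gene set, the running difference between
#' the weighted in-set rank ECDF (ranks raised to `weight_exponent`) and
#' the unweighted out-of-set ECDF is summed over all positions of the
#' ranking — an integrated (not maximum-deviation) KS-style statistic. The
#' resulting matrix is normalized by its global range across all sets and
#' samples.
#'
#' @inheritParams plage
#' @param weight_exponent exponent applied to ranks when weighting in-set
#'   genes; default 0.25.
#' @param normalize divide by the global score range (default `TRUE`).
#' @return An [enrichment_matrix()].
#' @export
ssgsea <- function(expr, gsc, weight_exponent = 0.25, normalize = TRUE) {
  stopifnot(inherits(gsc, "gene_set_collection"), weight_exponent >= 0)
  x <- as_plain_matrix(expr)
  p <- nrow(x)
  n <- ncol(x)
  memb <- lapply(seq_along(gsc), function(k) {
    genes <- gene_check(gsc[[k]], rownames(x), names(gsc)[k])
    rownames(x) %in% genes
  })
  scores <- matrix(NA_real_, length(gsc), n,
                   dimnames = list(names(gsc), colnames(x)))
  for (j in seq_len(n)) {
    rk <- rank(x[, j], ties.method = "first")
    ord <- order(rk, decreasing = TRUE)
    w_ord <- rk[ord]^weight_exponent
    for (k in seq_along(gsc)) {
      inset <- memb[[k]][ord]
      nin <- sum(inset)
      if (nin == 0L || nin == p)
        stop(sprintf("gene set '%s': needs at least one gene inside and one outside the matrix",
                     names(gsc)[k]))
      w <- w_ord
      w[!inset] <- 0
      ecdf_in <- cumsum(w) / sum(w)
      ecdf_out <- cumsum(!inset) / (p - nin)
      scores[k, j] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  enrichment_matrix(scores, method = "ssgsea",
                    params = list(weight_exponent = weight_exponent,
                                  normalize = normalize))
}

#' Score gene sets with a chosen single-sample method
#'
#' Dispatcher over the four per-sample enrichment methods.
#'
#' @inheritParams gsva_scores
#' @param method `"gsva"`, `"plage"`, `"zscore"` or `"ssgsea"`.
#' @param ... passed to the selected method.
#' @return An [enrichment_matrix()].
#' @export
score_gene_sets <- function(expr, gsc,
                            method = c("gsva", "plage", "zscore", "ssgsea"),
                            ...) {
  method <- match.arg(method)
  switch(method,
         gsva = gsva_scores(expr, gsc, ...),
         plage = plage(expr, gsc, ...),
         zscore = combined_zscore(expr, gsc, ...),
         ssgsea = ssgsea(expr, gsc, ...))
}
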