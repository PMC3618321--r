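#' Kernel-CDF expression-level statistics
#'
#' For each gene, a non-parametric kernel estimate of the cumulative density
#' of its expression across the sample population is evaluated at each
#' sample's value, yielding a statistic `z_ij` in (0, 1) that says how high
#' sample `j`'s value is for gene `i` relative to the other samples. This
#' puts genes with very different dynamic ranges (probe effects, GC/length
#' biases) on a common scale.
#'
#' `gaussian_kcdf()` is for continuous (e.g. log2 microarray) values:
#' `z_ij = (1/n) * sum_k Phi((x_ij - x_ik) / h_i)` with per-gene bandwidth
#' `h_i = bandwidth_factor * s_i`, `s_i` the gene's sample standard
#' deviation (the kernel integral has this closed form; no numeric
#' integration is involved). `poisson_kcdf()` is for integer counts:
#' `z_ij = (1/n) * sum_k P(Y <= x_ij)` with `Y ~ Pois(x_ik + offset)`; the
#' default offset 0.5 places the mode of each kernel at the observed count.
#' `identity_stat()` passes values through unchanged, for inputs already on
#' a common scale.
#'
#' Zero-variance genes get the smallest positive bandwidth among the other
#' genes (or 1 if all genes are constant): their statistic row is constant
#' and carries no ranking information, which is the intended semantics.
#'
#' @param expr an [expression_matrix()] (continuous for the Gaussian kernel,
#'   counts for the Poisson kernel).
#' @param bandwidth_factor multiple of the per-gene SD used as bandwidth;
#'   default 1/4.
#' @param offset positive constant added to each count to form the Poisson
#'   kernel mean; default 0.5.
#' @return A p x n numeric matrix of statistics, dimnames preserved.
#' @seealso [symmetric_ranks()]
#' @export
gaussian_kcdf <- function(expr, bandwidth_factor = 0.25) {
  if (value_kind(expr) != "continuous")
    stop("gaussian_kcdf expects continuous values; use poisson_kcdf for counts")
  stopifnot(bandwidth_factor > 0)
  x <- as_plain_matrix(expr)
  n <- ncol(x)
  if (n == 1L) {
    z <- matrix(0.5, nrow(x), 1L, dimnames = dimnames(x))
    return(z)
  }
  if (n <= 10L)
    warning("kernel density estimation with n <= 10 samples is unreliable")
  h <- apply(x, 1L, sd) * bandwidth_factor
  if (any(h == 0)) {
    pos <- h[h > 0]
    h[h == 0] <- if (length(pos)) min(pos) else 1
  }
  z <- cpp_kcdf_gaussian(x, h)
  dimnames(z) <- dimnames(x)
  z
}

#' @rdname gaussian_kcdf
#' @export
poisson_kcdf <- function(expr, offset = 0.5) {
  if (value_kind(expr) != "counts")
    stop("poisson_kcdf expects counts; use gaussian_kcdf for continuous values")
  stopifnot(offset > 0)
  x <- as_plain_matrix(expr)
  if (any(x < 0) || any(x != floor(x)))
    stop("poisson_kcdf requires non-negative integer counts")
  z <- cpp_kcdf_poisson(x, offset)
  dimnames(z) <- dimnames(x)
  z
}

#' @rdname gaussian_kcdf
#' @export
identity_stat <- function(expr) {
  as_plain_matrix(expr)
}

#' Symmetric rank statistics and traversal orders
#'
#' Within each sample, the expression-level statistics are converted to
#' ranks (1 = lowest, p = highest; ties broken by first occurrence, i.e.
#' gene row order) and folded into symmetric ranks `|p/2 - rank|`, which
#' up-weight both tails of the per-sample rank distribution. The per-sample
#' gene ordering by decreasing statistic — the order in which the
#' enrichment random walk traverses the genome — is recorded alongside.
#'
#' @param z a p x n statistic matrix (from [gaussian_kcdf()],
#'   [poisson_kcdf()] or [identity_stat()]).
#' @return A `rank_matrix`: list with elements `rank` (integer p x n, each
#'   column a permutation of `1:p`), `sym` (`|p/2 - rank|`), `order`
#'   (integer p x n; column j lists gene row indices by decreasing `z`),
#'   `gene_ids`, `sample_ids`.
#' @export
symmetric_ranks <- function(z) {
  z <- as.matrix(z)
  p <- nrow(z)
  n <- ncol(z)
  rk <- matrix(0L, p, n)
  ord <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    r <- rank(z[, j], ties.method = "first")
    rk[, j] <- as.integer(r)
    ord[, j] <- order(r, decreasing = TRUE)  # ranks are unique: deterministic
  }
  sym <- abs(p / 2 - rk)
  dimnames(rk) <- dimnames(sym) <- dimnames(z)
  structure(list(rank = rk, sym = sym, order = ord,
                 gene_ids = rownames(z), sample_ids = colnames(z)),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("rank matrix: %d genes x %d samples\n",
              nrow(x$rank), ncol(x$rank)))
  invisible(x)
}
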