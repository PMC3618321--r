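#' Kolmogorov-Smirnov-like enrichment random walk
#'
#' Walks a sample's genes in decreasing order of expression-level statistic
#' and accumulates the difference between (a) the tau-weighted symmetric-rank
#' mass of in-set genes seen so far, normalized by the total in-set mass,
#' and (b) the fraction of out-of-set genes seen so far:
#' \deqn{\nu(\ell) = \frac{\sum_{i \le \ell} |r_i|^\tau I(g_i \in \gamma)}
#'                        {\sum_{i \le p} |r_i|^\tau I(g_i \in \gamma)}
#'                - \frac{\sum_{i \le \ell} I(g_i \notin \gamma)}{p - |\gamma|}}
#' Both cumulative terms reach 1 at \eqn{\ell = p}, so the walk always ends
#' at 0; set genes concentrated in either tail of the ranking push the walk
#' far from 0 in between.
#'
#' If every in-set gene has zero symmetric rank (possible only with `tau > 0`
#' on degenerate data), the in-set term falls back to the unweighted in-set
#' fraction, with a warning.
#'
#' @param rm a `rank_matrix` from [symmetric_ranks()].
#' @param sample sample index or sample identifier.
#' @param members character vector of gene identifiers (the gene set); must
#'   all be present among `rm$gene_ids`, with at least one gene left outside
#'   the set.
#' @param tau non-negative tail weight exponent; default 1. `tau = 0`
#'   reduces the in-set term to an unweighted empirical CDF.
#' @param set_name optional label stored in the trajectory.
#' @return A `walk_trajectory`: list with `nu` (length-p vector), `set_name`,
#'   `sample_id`.
#' @seealso [es_max()], [es_diff()], [gsva_scores()]
#' @export
random_walk <- function(rm, sample, members, tau = 1, set_name = NULL) {
  stopifnot(inherits(rm, "rank_matrix"), tau >= 0)
  j <- if (is.character(sample)) match(sample, rm$sample_ids) else as.integer(sample)
  if (is.na(j) || j < 1L || j > ncol(rm$rank)) stop("unknown sample: ", sample)
  memb <- gene_membership(rm$gene_ids, members)
  tr <- walk_nu(rm$order[, j], rm$sym[, j], memb, tau)
  structure(list(nu = tr, set_name = set_name,
                 sample_id = rm$sample_ids[j]),
            class = "walk_trajectory")
}

gene_membership <- function(gene_ids, members) {
  memb <- gene_ids %in% members
  k <- sum(memb)
  if (k < length(members))
    stop(sprintf("%d gene-set member(s) missing from the expression matrix; run apply_size_filter() first",
                 length(members) - k))
  if (k == 0L) stop("gene set has no members")
  if (k == length(gene_ids))
    stop("gene set covers all genes: out-of-set term undefined")
  memb
}

walk_nu <- function(ord, sym, memb, tau) {
  p <- length(ord)
  inset <- memb[ord]
  w <- if (tau == 1) sym[ord] else sym[ord]^tau
  w[!inset] <- 0
  tot <- sum(w)
  inside <- if (tot > 0) cumsum(w) / tot else {
    warning("total in-set rank weight is zero; falling back to unweighted in-set fraction")
    cumsum(inset) / sum(inset)
  }
  unname(inside - cumsum(!inset) / (p - sum(inset)))
}

# Positive deviation wins a magnitude tie; the 1e-12 slack keeps the rule
# stable when equal-magnitude excursions differ only by accumulation
# round-off.
signed_max_dev <- function(mx, mn) {
  if (mx >= -mn - 1e-12) mx else mn
}

#' Enrichment scores from a walk trajectory
#'
#' `es_max()` is the classical maximum deviation from zero: the signed walk
#' value of largest magnitude (ties between equal-magnitude positive and
#' negative deviations return the positive one). Its null distribution is
#' bimodal, as for any KS-like statistic. `es_diff()` is the two-tail
#' difference `max(0, max nu) + min(0, min nu)`: the largest positive
#' excursion minus the magnitude of the largest negative one, so opposite
#' excursions cancel and the null distribution is unimodal and
#' approximately normal. It emphasizes sets whose genes move concordantly
#' in one direction.
#'
#' @param tr a `walk_trajectory` from [random_walk()], or a numeric vector.
#' @return A single numeric score in `[-1, 1]`.
#' @export
es_max <- function(tr) {
  nu <- if (inherits(tr, "walk_trajectory")) tr$nu else as.numeric(tr)
  mx <- max(nu)
  mn <- min(nu)
  signed_max_dev(mx, mn)
}

#' @rdname es_max
#' @export
es_diff <- function(tr) {
  nu <- if (inherits(tr, "walk_trajectory")) tr$nu else as.numeric(tr)
  max(0, max(nu)) + min(0, min(nu))
}

#' Gene set variation scores
#'
#' The full single-sample scoring pipeline: kernel-CDF expression-level
#' statistics ([gaussian_kcdf()] for continuous values, [poisson_kcdf()]
#' for counts, or raw values with `kernel = "none"`), symmetric ranks
#' ([symmetric_ranks()]), then for every (sample, gene set) pair the
#' KS-like random walk ([random_walk()]) condensed to an enrichment score
#' ([es_diff()] by default, or [es_max()]).
#'
#' Samples are coupled only through the kernel CDF step (each gene's
#' statistic is estimated from the whole sample population); downstream of
#' it, every sample's scores depend on that sample alone.
#'
#' @param expr an [expression_matrix()].
#' @param gsc a [gene_set_collection()] already mapped/size-filtered against
#'   `expr` (see [apply_size_filter()]).
#' @param kernel `"auto"` (Gaussian for continuous values, Poisson for
#'   counts), `"gaussian"`, `"poisson"`, or `"none"`.
#' @param es_mode `"diff"` (two-tail difference, default) or `"max"`
#'   (maximum deviation).
#' @param tau tail weight exponent of the walk; default 1.
#' @param bandwidth_factor,offset kernel parameters, see [gaussian_kcdf()].
#' @return An [enrichment_matrix()] (gene sets x samples), scores in
#'   `[-1, 1]`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 50, 12,
#'             dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
#' expr <- expression_matrix(x, "continuous")
#' gsc <- gene_set_collection(list(up = paste0("g", 1:10),
#'                                 rnd = paste0("g", 21:35)))
#' es <- gsva_scores(expr, gsc)
#' es[, 1:3]
#' @export
gsva_scores <- function(expr, gsc,
                        kernel = c("auto", "gaussian", "poisson", "none"),
                        es_mode = c("diff", "max"),
                        tau = 1, bandwidth_factor = 0.25, offset = 0.5) {
  kernel <- match.arg(kernel)
  es_mode <- match.arg(es_mode)
  both <- gsva_es_both(expr, gsc, kernel = kernel, tau = tau,
                       bandwidth_factor = bandwidth_factor, offset = offset)
  enrichment_matrix(both[[es_mode]], method = "gsva",
                    params = list(kernel = both$kernel, es_mode = es_mode, tau = tau,
                                  bandwidth_factor = bandwidth_factor, offset = offset))
}

# Compute both ES variants in one pass over the walks.
gsva_es_both <- function(expr, gsc, kernel = "auto", tau = 1,
                         bandwidth_factor = 0.25, offset = 0.5) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (kernel == "auto")
    kernel <- if (value_kind(expr) == "counts") "poisson" else "gaussian"
  z <- switch(kernel,
              gaussian = gaussian_kcdf(expr, bandwidth_factor),
              poisson = poisson_kcdf(expr, offset),
              none = identity_stat(expr))
  rm_ <- symmetric_ranks(z)
  p <- length(rm_$gene_ids)
  n <- ncol(rm_$rank)
  m <- length(gsc)
  memb <- lapply(unclass(gsc), function(mm) gene_membership(rm_$gene_ids, mm))
  sdiff <- smax <- matrix(NA_real_, m, n,
                          dimnames = list(names(gsc), rm_$sample_ids))
  for (j in seq_len(n)) {
    ordj <- rm_$order[, j]
    wj <- if (tau == 1) rm_$sym[, j] else rm_$sym[, j]^tau
    wj_ord <- wj[ordj]
    for (k in seq_len(m)) {
      inset <- memb[[k]][ordj]
      w <- wj_ord
      w[!inset] <- 0
      tot <- sum(w)
      inside <- if (tot > 0) cumsum(w) / tot else cumsum(inset) / sum(inset)
      nu <- inside - cumsum(!inset) / (p - sum(inset))
      mx <- max(nu)
      mn <- min(nu)
      smax[k, j] <- signed_max_dev(mx, mn)
      sdiff[k, j] <- max(0, mx) + min(0, mn)
    }
  }
  list(diff = sdiff, max = smax, kernel = kernel)
}

#' Null distribution of enrichment scores
#'
#' Simulates the no-signal reference condition: i.i.d. standard normal
#' expression for `p` genes and `n` samples, with `m` gene sets sampled
#' uniformly at random with sizes drawn from `size_range`, then scores
#' every (set, sample) pair with both enrichment statistics. Used to
#' characterise the shapes of the two score distributions under the null
#' (maximum-deviation scores are bimodal; two-tail-difference scores are
#' unimodal, approximately normal, centred at zero).
#'
#' @param p,n,m number of genes, samples, and random gene sets.
#' @param size_range inclusive range gene-set sizes are drawn from.
#' @param tau tail weight exponent; default 1.
#' @param seed optional integer seed.
#' @return List with numeric vectors `max` and `diff` (length `m * n`) and
#'   the `gene_set_collection` used.
#' @export
null_score_distribution <- function(p = 20000L, n = 30L, m = 100L,
                                    size_range = c(10L, 100L), tau = 1,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- paste0("g", seq_len(p))
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(gene_ids, paste0("s", seq_len(n))))
  sizes <- sample(size_range[1L]:size_range[2L], m, replace = TRUE)
  sets <- lapply(sizes, function(sz) sample(gene_ids, sz))
  names(sets) <- paste0("set", seq_len(m))
  gsc <- gene_set_collection(sets, provenance = "null simulation")
  both <- gsva_es_both(expression_matrix(x, "continuous"), gsc,
                       kernel = "gaussian", tau = tau)
  list(max = as.numeric(both$max), diff = as.numeric(both$diff), sets = gsc)
}
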