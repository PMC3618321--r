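# Independent straight-line oracles for the scoring pipeline. Deliberately
# naive (explicit loops, no shared code with the package internals): these
# recompute every stage directly from its mathematical definition.

oracle_gauss_z <- function(x, bw = 0.25) {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(NA_real_, p, n)
  h <- numeric(p)
  for (i in seq_len(p)) h[i] <- sd(x[i, ]) * bw
  pos <- h[h > 0]
  h[h == 0] <- if (length(pos)) min(pos) else 1
  for (i in seq_len(p)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(n)) acc <- acc + pnorm((x[i, j] - x[i, k]) / h[i])
    z[i, j] <- acc / n
  }
  z
}

# Poisson CDF by explicit log-space pmf summation (independent of ppois)
oracle_pois_cdf <- function(q, lambda) {
  y <- 0:q
  min(sum(exp(y * log(lambda) - lambda - lgamma(y + 1))), 1)
}

oracle_pois_z <- function(x, r = 0.5) {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(n)) acc <- acc + oracle_pois_cdf(x[i, j], x[i, k] + r)
    z[i, j] <- acc / n
  }
  z
}

# per-column ranks, largest value -> rank p, ties by first occurrence
oracle_ranks <- function(zcol) {
  p <- length(zcol)
  ord <- order(zcol, seq_len(p))  # ascending, earlier rows first on ties
  rk <- integer(p)
  rk[ord] <- seq_len(p)
  rk
}

# step-by-step walk accumulation for one sample and one membership vector
oracle_nu <- function(zcol, memb, tau) {
  p <- length(zcol)
  rk <- oracle_ranks(zcol)
  sym <- abs(p / 2 - rk)
  trav <- order(rk, decreasing = TRUE)
  k <- sum(memb)
  tot_in <- 0
  for (i in seq_len(p)) if (memb[trav[i]]) tot_in <- tot_in + sym[trav[i]]^tau
  nu <- numeric(p)
  cin <- cout <- 0
  for (l in seq_len(p)) {
    g <- trav[l]
    if (memb[g]) cin <- cin + (if (tot_in > 0) sym[g]^tau / tot_in else 1 / k)
    else cout <- cout + 1 / (p - k)
    nu[l] <- cin - cout
  }
  nu
}

oracle_es <- function(nu, mode) {
  mx <- -Inf; mn <- Inf
  for (v in nu) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  if (mode == "max") { if (mx >= -mn - 1e-12) mx else mn }
  else max(0, mx) + min(0, mn)
}

# full pipeline: expression matrix -> m x n score matrix
oracle_scores <- function(x, sets, kernel, tau, mode, bw = 0.25, r = 0.5) {
  z <- switch(kernel,
              gaussian = oracle_gauss_z(x, bw),
              poisson = oracle_pois_z(x, r),
              none = x)
  m <- length(sets); n <- ncol(x)
  out <- matrix(NA_real_, m, n, dimnames = list(names(sets), colnames(x)))
  for (k in seq_len(m)) {
    memb <- rownames(x) %in% sets[[k]]
    for (j in seq_len(n))
      out[k, j] <- oracle_es(oracle_nu(z[, j], memb, tau), mode)
  }
  out
}

# ssGSEA running-sum oracle for one sample (pre-normalization)
oracle_ssgsea_sample <- function(xcol, memb, alpha) {
  p <- length(xcol)
  rk <- oracle_ranks(xcol)
  trav <- order(rk, decreasing = TRUE)
  k <- sum(memb)
  tot <- 0
  for (i in seq_len(p)) if (memb[trav[i]]) tot <- tot + rk[trav[i]]^alpha
  acc <- 0; cin <- cout <- 0
  for (l in seq_len(p)) {
    g <- trav[l]
    if (memb[g]) cin <- cin + rk[g]^alpha / tot else cout <- cout + 1 / (p - k)
    acc <- acc + (cin - cout)
  }
  acc
}

rand_expr <- function(p, n, kind = "continuous", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- list(paste0("g", seq_len(p)), paste0("smp", seq_len(n)))
  if (kind == "counts") {
    x <- matrix(rpois(p * n, lambda = rep(exp(rnorm(p, 3, 1.5)), n)), p, n, dimnames = ids)
  } else {
    x <- matrix(rnorm(p * n), p, n, dimnames = ids)
  }
  expression_matrix(x, kind)
}

rand_sets <- function(gene_ids, m, min_sz = 3L, max_sz = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_sz)) max_sz <- max(min_sz, length(gene_ids) %/% 3L)
  sets <- lapply(seq_len(m), function(k)
    sample(gene_ids, sample(min_sz:max_sz, 1L)))
  names(sets) <- paste0("S", seq_len(m))
  gene_set_collection(sets)
}

# Equivalence checks between two arithmetic routes are ill-posed when two
# genes' statistics coincide to within round-off but not exactly: rank ties
# then resolve arbitrarily between the routes. Only the Poisson kernel is
# affected (ppois vs direct pmf summation differ in the last ulps); the
# Gaussian oracle adds the same pnorm terms in the same order as the
# implementation, so even exact ties break identically. For count data,
# draw instances until every per-sample statistic gap clears round-off.
rand_instance <- function(p, n, kind, m, seed, min_gap = 1e-9) {
  for (try in 0:50) {
    expr <- rand_expr(p, n, kind = kind, seed = seed + 1000L * try)
    gsc <- rand_sets(rownames(expr), m = m, min_sz = 3,
                     max_sz = max(3, p %/% 3))
    if (kind != "counts") return(list(expr = expr, gsc = gsc))
    z <- poisson_kcdf(expr)
    gaps <- apply(z, 2, function(col) min(diff(sort(col))))
    if (min(gaps) > min_gap) return(list(expr = expr, gsc = gsc))
  }
  stop("could not draw a tie-free instance")
}
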