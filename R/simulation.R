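# Derive a per-replicate child seed from a master seed; keeps replicate
# results independent of execution order and inside 32-bit integer range.
child_seed <- function(master, r) {
  as.integer((as.numeric(master) * 48271 + r * 16807) %% 2147483647)
}

#' Simulate two-group expression data from a linear additive model
#'
#' Generates `y_ij = alpha_i + beta_j + eps_ij`, mimicking normalized
#' microarray data for a case-control design: `alpha_i ~ N(0, 1)` is a
#' gene effect (e.g. probe effect), `eps_ij ~ N(0, 1)` is noise, and
#' `beta_j` is a per-sample effect. Group-1 samples and non-DE rows of
#' group-2 samples draw `beta_j ~ N(0, 1)`; at differentially expressed
#' (DE) rows, each group-2 sample draws a separate effect
#' `N(mu2_de, sigma2_de)`, so the expected group-2 minus group-1 difference
#' at DE genes is `mu2_de`. Defaults `mu2_de = 1, sigma2_de = 0.5`
#' correspond to a strong signal-to-noise ratio; `mu2_de = 0.5` to a weak
#' one.
#'
#' @param p number of genes.
#' @param n1,n2 group sizes (each >= 2).
#' @param de_genes integer indices of DE genes (possibly empty).
#' @param mu2_de,sigma2_de mean and SD of the group-2 sample effect at DE
#'   genes.
#' @param seed optional integer seed.
#' @return List with `expr` (continuous [expression_matrix()], genes
#'   `g1..gp`, samples `s1..s(n1+n2)`) and `groups` (integer vector of 1/2
#'   labels).
#' @export
simulate_additive <- function(p, n1, n2, de_genes = integer(0),
                              mu2_de = 1, sigma2_de = 0.5, seed = NULL) {
  stopifnot(n1 >= 2L, n2 >= 2L, p >= 1L)
  de_genes <- as.integer(de_genes)
  if (length(de_genes) && (min(de_genes) < 1L || max(de_genes) > p))
    stop("de_genes out of range 1..p")
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  groups <- rep(1:2, c(n1, n2))
  alpha <- rnorm(p)
  beta_base <- rnorm(n)                        # shared sample effect
  y <- alpha + matrix(rnorm(p * n), p, n)      # gene effect + noise
  y <- sweep(y, 2L, beta_base, "+")
  if (length(de_genes)) {
    g2 <- which(groups == 2L)
    beta_de <- rnorm(length(g2), mean = mu2_de, sd = sigma2_de)
    # DE rows of group-2 samples get the DE sample effect instead of the baseline
    y[de_genes, g2] <- y[de_genes, g2] +
      rep(beta_de - beta_base[g2], each = length(de_genes))
  }
  dimnames(y) <- list(paste0("g", seq_len(p)), paste0("s", seq_len(n)))
  list(expr = expression_matrix(y, "continuous"), groups = groups)
}

welch_p <- function(scores, groups) {
  t.test(scores[groups == 1L], scores[groups == 2L])$p.value
}

#' Statistical power and type-I error of single-sample scoring methods
#'
#' Monte-Carlo benchmark on the linear additive model: `p` genes, the first
#' `set_size` genes forming a DE gene set (of which a fraction
#' `de_fraction` is actually DE) and the next `set_size` genes a non-DE
#' set. Each replicate simulates a two-group data set (groups of size
#' `n/2`), scores both sets with each method, and applies a two-sample
#' t-test between the groups on each set's score vector at level `alpha`.
#' Power is the rejection fraction on the DE set; the empirical type-I
#' error is the rejection fraction on the non-DE set.
#'
#' @param n total sample size, split evenly into two groups.
#' @param effect `"weak"` (DE sample-effect mean 0.5) or `"strong"` (1).
#' @param de_fraction fraction of the DE set's genes that are DE (0.5 or
#'   0.8 in the standard scenarios).
#' @param p,set_size genes overall and per set; defaults 1000 and 30.
#' @param replicates Monte-Carlo replicates (fewer than 50 triggers a
#'   warning).
#' @param methods subset of `c("gsva", "plage", "zscore", "ssgsea")`.
#' @param alpha test level.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param ... passed to the scoring methods (e.g. `es_mode` for GSVA).
#' @return Data frame with one row per method: `power`, `type1` and their
#'   binomial standard errors, plus the scenario parameters.
#' @export
power_type1_study <- function(n = 60L, effect = c("weak", "strong"),
                              de_fraction = 0.5, p = 1000L, set_size = 30L,
                              replicates = 1000L,
                              methods = c("gsva", "plage", "zscore", "ssgsea"),
                              alpha = 0.05, seed = 1L, ...) {
  effect <- match.arg(effect)
  methods <- match.arg(methods, several.ok = TRUE)
  if (replicates < 50L) warning("fewer than 50 replicates: unstable estimates")
  stopifnot(n >= 4L, n %% 2L == 0L, 2L * set_size <= p)
  mu2 <- if (effect == "weak") 0.5 else 1
  n_de <- round(set_size * de_fraction)
  de_genes <- seq_len(n_de)                 # DE members of the first set
  gsc <- gene_set_collection(list(
    de_set = paste0("g", seq_len(set_size)),
    nonde_set = paste0("g", set_size + seq_len(set_size))
  ), provenance = "power/type-I study")
  rej_de <- rej_nonde <- matrix(0L, replicates, length(methods),
                                dimnames = list(NULL, methods))
  for (r in seq_len(replicates)) {
    sim <- simulate_additive(p, n / 2L, n / 2L, de_genes = de_genes,
                             mu2_de = mu2, sigma2_de = 0.5,
                             seed = child_seed(seed, r))
    for (meth in methods) {
      es <- suppressWarnings(score_gene_sets(sim$expr, gsc, method = meth, ...))
      rej_de[r, meth] <- welch_p(es["de_set", ], sim$groups) < alpha
      rej_nonde[r, meth] <- welch_p(es["nonde_set", ], sim$groups) < alpha
    }
  }
  power <- colMeans(rej_de)
  type1 <- colMeans(rej_nonde)
  data.frame(method = methods,
             power = power,
             type1 = type1,
             se_power = sqrt(power * (1 - power) / replicates),
             se_type1 = sqrt(type1 * (1 - type1) / replicates),
             n = n, effect = effect, de_fraction = de_fraction,
             replicates = replicates, row.names = NULL)
}

binary_auc <- function(calls, labels) {
  if (length(unique(calls)) == 1L) {
    warning("degenerate AUC: all DE calls identical; recorded as 0.5")
    return(0.5)
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = as.numeric(calls),
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Differential-pathway-calling AUC benchmark
#'
#' Genome-scale Monte-Carlo study: each replicate simulates `p` genes
#' (first `n_de_genes` DE) for `n` samples in two equal groups, builds
#' `n_sets` gene sets of size `set_size` — `n_de_sets` of them DE, sampling
#' `de_fraction` of members from DE genes and the rest from non-DE genes;
#' the remaining sets sampled uniformly from all genes — then scores all
#' sets with each method, tests each set's scores between groups
#' (two-sample t-test), adjusts p-values by Benjamini-Hochberg, and calls
#' DE at FDR `fdr`. The replicate's AUC is computed from the binary call
#' vector against the true set labels.
#'
#' @inheritParams power_type1_study
#' @param p,n_de_genes,n_sets,n_de_sets,set_size,n study dimensions;
#'   full-scale defaults are `p = 10000`, `n_de_genes = 2000`,
#'   `n_sets = 1000`, `n_de_sets = 500`, `n = 60`.
#' @param fdr Benjamini-Hochberg cutoff (0.05 or 0.01).
#' @return List with `auc` (replicates x methods matrix) and `summary`
#'   (per-method mean AUC and SE).
#' @export
auc_study <- function(effect = c("weak", "strong"), de_fraction = 0.5,
                      p = 10000L, n = 60L, n_de_genes = 2000L,
                      n_sets = 1000L, n_de_sets = 500L, set_size = 30L,
                      fdr = 0.05, replicates = 100L,
                      methods = c("gsva", "plage", "zscore", "ssgsea"),
                      seed = 1L, ...) {
  effect <- match.arg(effect)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_de_genes < p, n_de_sets < n_sets, n %% 2L == 0L)
  mu2 <- if (effect == "weak") 0.5 else 1
  labels <- rep(c(TRUE, FALSE), c(n_de_sets, n_sets - n_de_sets))
  auc <- matrix(NA_real_, replicates, length(methods),
                dimnames = list(NULL, methods))
  gene_ids <- paste0("g", seq_len(p))
  de_ids <- gene_ids[seq_len(n_de_genes)]
  nonde_ids <- gene_ids[-seq_len(n_de_genes)]
  n_de_in_set <- round(set_size * de_fraction)
  for (r in seq_len(replicates)) {
    sd_ <- child_seed(seed, r)
    sim <- simulate_additive(p, n / 2L, n / 2L,
                             de_genes = seq_len(n_de_genes),
                             mu2_de = mu2, sigma2_de = 0.5, seed = sd_)
    # set construction uses the same replicate RNG stream, after the data
    sets <- vector("list", n_sets)
    for (k in seq_len(n_sets)) {
      sets[[k]] <- if (labels[k])
        c(sample(de_ids, n_de_in_set), sample(nonde_ids, set_size - n_de_in_set))
      else
        sample(gene_ids, set_size)
    }
    names(sets) <- paste0("set", seq_len(n_sets))
    gsc <- gene_set_collection(sets, provenance = "auc study")
    for (meth in methods) {
      es <- suppressWarnings(score_gene_sets(sim$expr, gsc, method = meth, ...))
      pv <- apply(unclass(es), 1L, welch_p, groups = sim$groups)
      calls <- p.adjust(pv, method = "BH") <= fdr
      auc[r, meth] <- suppressWarnings(binary_auc(calls, labels))
    }
  }
  summary <- data.frame(method = methods,
                        mean_auc = colMeans(auc),
                        se_auc = apply(auc, 2L, sd) / sqrt(replicates),
                        replicates = replicates, effect = effect,
                        de_fraction = de_fraction, fdr = fdr,
                        row.names = NULL)
  list(auc = auc, summary = summary)
}

#' Simulate survival and censoring times for two sample groups
#'
#' Survival times are drawn per group from normal distributions (defaults
#' `N(6, 2)` for group 1 and `N(10, 2)` for group 2); censoring times from
#' `N(10, 3)`. A sample is censored when its censoring time is smaller
#' than its survival time; the observed time is the minimum of the two.
#' Negative draws are truncated at a small positive epsilon so downstream
#' proportional-hazards fits see valid times.
#'
#' @param groups integer vector of 1/2 group labels (e.g. from
#'   [simulate_additive()]).
#' @param surv_means,surv_sd per-group survival-time means and common SD.
#' @param cens_mean,cens_sd censoring-time distribution.
#' @param eps positive truncation floor for times; default 0.01.
#' @param seed optional integer seed.
#' @return Data frame with `time`, `event` (1 = death observed, 0 =
#'   censored) and `group`.
#' @export
simulate_survival <- function(groups, surv_means = c(6, 10), surv_sd = 2,
                              cens_mean = 10, cens_sd = 3, eps = 0.01,
                              seed = NULL) {
  stopifnot(all(groups %in% 1:2), length(surv_means) == 2L, eps > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(groups)
  surv <- pmax(rnorm(n, mean = surv_means[groups], sd = surv_sd), eps)
  cens <- pmax(rnorm(n, mean = cens_mean, sd = cens_sd), eps)
  data.frame(time = pmin(surv, cens),
             event = as.integer(surv <= cens),
             group = as.integer(groups))
}
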