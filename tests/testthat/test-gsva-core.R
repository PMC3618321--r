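make_rank_matrix <- function(z) symmetric_ranks(z)

test_that("random walk hits +1/-1 under maximal concentration and ends at zero", {
  set.seed(31)
  z <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  rm_ <- make_rank_matrix(z)
  top3 <- rm_$gene_ids[rm_$order[1:3, 1]]
  bottom3 <- rm_$gene_ids[rm_$order[8:10, 1]]
  tr_top <- random_walk(rm_, "s1", top3)
  tr_bot <- random_walk(rm_, "s1", bottom3)
  expect_equal(tr_top$nu[3], 1)                    # all set genes first
  expect_equal(tr_bot$nu[7], -1)                   # all set genes last
  expect_equal(tr_top$nu[10], 0)
  expect_equal(tr_bot$nu[10], 0)
  expect_true(all(abs(tr_top$nu) <= 1 + 1e-12))
})

test_that("walk trajectory equals the step-by-step accumulation oracle", {
  set.seed(32)
  z <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  rm_ <- make_rank_matrix(z)
  # genes at traversal positions 2, 5, 8 of sample 1
  members <- rm_$gene_ids[rm_$order[c(2, 5, 8), 1]]
  memb <- rm_$gene_ids %in% members
  for (tau in c(0, 1, 2)) {
    tr <- random_walk(rm_, 1, members, tau = tau)
    expect_equal(tr$nu, oracle_nu(z[, 1], memb, tau), tolerance = 1e-12)
  }
})

test_that("walk rejects degenerate gene sets", {
  set.seed(33)
  z <- matrix(rnorm(8), 8, 1, dimnames = list(paste0("g", 1:8), "s1"))
  rm_ <- make_rank_matrix(z)
  expect_error(random_walk(rm_, 1, paste0("g", 1:8)), "covers all genes")
  expect_error(random_walk(rm_, 1, c("g1", "nope")), "missing from the expression matrix")
})

test_that("enrichment statistics follow their definitions and tie rules", {
  expect_equal(es_max(c(0.2, 1, 0.5)), 1)
  expect_equal(es_max(c(-0.4, 0.3, 0)), -0.4)       # larger magnitude wins, signed
  expect_equal(es_max(c(-0.5, 0.5, 0)), 0.5)        # magnitude tie -> positive
  expect_equal(es_diff(c(0.1, 0.7, 0.2)), 0.7)      # no negative excursion
  expect_equal(es_diff(c(-0.6, 0.6, 0)), 0)         # two-sided excursions cancel
  set.seed(34)
  for (r in 1:20) {
    nu <- cumsum(rnorm(15)); nu <- nu / max(1, max(abs(nu)))
    expect_equal(es_diff(nu), oracle_es(nu, "diff"))
    expect_equal(es_max(nu), oracle_es(nu, "max"))
    expect_gte(es_diff(nu), min(nu) - 1e-12)        # ES_diff within walk range
    expect_lte(es_diff(nu), max(nu) + 1e-12)
    if (min(nu) >= 0 || max(nu) <= 0)               # one-sided walks: diff == max
      expect_equal(es_diff(nu), es_max(nu))
  }
})

test_that("pipeline scores match the end-to-end oracle on both kernels and modes", {
  for (case in 1:4) {
    kind <- if (case %% 2 == 0) "counts" else "continuous"
    kernel <- if (kind == "counts") "poisson" else "gaussian"
    inst <- rand_instance(30, 6, kind, m = 4, seed = 35 + case)
    expr <- inst$expr
    gsc <- inst$gsc
    for (tau in c(0, 1)) for (mode in c("diff", "max")) {
      es <- suppressWarnings(
        gsva_scores(expr, gsc, kernel = kernel, es_mode = mode, tau = tau))
      ref <- oracle_scores(unclass(expr), unclass(gsc), kernel, tau, mode)
      expect_equal(unclass(es), ref, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("scores are invariant to gene relabeling and sample permutation", {
  set.seed(36)
  expr <- rand_expr(40, 8)
  gsc <- rand_sets(rownames(expr), m = 3, min_sz = 5, max_sz = 12)
  es <- suppressWarnings(gsva_scores(expr, gsc))
  # relabel genes consistently
  map <- setNames(paste0("X", seq_len(40)), rownames(expr))
  x2 <- unclass(expr); rownames(x2) <- map[rownames(x2)]
  gsc2 <- gene_set_collection(lapply(unclass(gsc), function(m) unname(map[m])))
  es2 <- suppressWarnings(gsva_scores(expression_matrix(x2, "continuous"), gsc2))
  expect_equal(unclass(es2), unclass(es), ignore_attr = TRUE)
  # permute sample columns
  perm <- sample(8)
  x3 <- unclass(expr)[, perm]
  es3 <- suppressWarnings(gsva_scores(expression_matrix(x3, "continuous"), gsc))
  expect_equal(unclass(es3), unclass(es)[, perm], ignore_attr = TRUE)
})

test_that("duplicating every sample leaves per-sample scores unchanged", {
  set.seed(37)
  expr <- rand_expr(20, 4)
  gsc <- rand_sets(rownames(expr), m = 3, min_sz = 4, max_sz = 8)
  es <- suppressWarnings(gsva_scores(expr, gsc))
  x2 <- cbind(unclass(expr), unclass(expr))
  colnames(x2) <- paste0("smp", seq_len(8))
  es2 <- suppressWarnings(gsva_scores(expression_matrix(x2, "continuous"), gsc))
  expect_equal(unclass(es2)[, 1:4], unclass(es), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(unclass(es2)[, 1:4], unclass(es2)[, 5:8], ignore_attr = TRUE)
})

test_that("walk-end and score-range invariants hold over random cases", {
  set.seed(38)
  for (r in 1:5) {
    expr <- rand_expr(25, 5)
    gsc <- rand_sets(rownames(expr), m = 2, min_sz = 3, max_sz = 8)
    z <- suppressWarnings(gaussian_kcdf(expr))
    rm_ <- symmetric_ranks(z)
    for (tau in c(0, 1)) for (k in seq_along(gsc)) for (j in 1:5) {
      tr <- random_walk(rm_, j, gsc[[k]], tau = tau)
      expect_equal(tr$nu[length(tr$nu)], 0, tolerance = 1e-12)
      expect_true(all(tr$nu >= -1 - 1e-12 & tr$nu <= 1 + 1e-12))
    }
    es <- suppressWarnings(gsva_scores(expr, gsc, es_mode = "max"))
    expect_true(all(es >= -1 & es <= 1))
  }
})

test_that("the reduced-size null simulation behaves like a label-free null", {
  nd <- null_score_distribution(p = 1500, n = 12, m = 30, size_range = c(10, 50),
                                seed = 39)
  expect_length(nd$max, 30 * 12)
  se <- sd(nd$diff) / sqrt(length(nd$diff))
  expect_lt(abs(mean(nd$diff)), 3 * se + 0.02)
  expect_true(all(abs(nd$max) <= 1))
  # max-mode scores avoid a neighbourhood of zero, diff-mode scores do not
  expect_gt(min(abs(nd$max)), 0.01)
  expect_lt(min(abs(nd$diff)), 0.01)
})
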