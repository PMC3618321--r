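std_rows <- function(x) t(apply(x, 1, function(v) (v - mean(v)) / sd(v)))

test_that("PLAGE recovers standardized profiles for rank-1 sets and matches SVD", {
  set.seed(41)
  expr <- rand_expr(12, 6)
  x <- unclass(expr)
  gsc <- gene_set_collection(list(single = "g3"))
  es <- plage(expr, gsc)
  zg <- (x["g3", ] - mean(x["g3", ])) / sd(x["g3", ])
  want <- zg / sqrt(sum(zg^2))
  expect_equal(abs(unclass(es)["single", ]), abs(want), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gte(sum(es["single", ] * zg), 0)   # sign aligned with expression

  # two identical genes behave like one
  x2 <- rbind(x, dup = x["g3", ] )
  rownames(x2)[13] <- "g3dup"
  es2 <- plage(expression_matrix(x2, "continuous"),
               gene_set_collection(list(pair = c("g3", "g3dup"))))
  expect_equal(unclass(es2)["pair", ], unclass(es)["single", ],
               tolerance = 1e-10, ignore_attr = TRUE)

  # independent SVD oracle on an 8-gene set
  gsc8 <- gene_set_collection(list(s = paste0("g", 1:8)))
  es8 <- plage(expr, gsc8)
  v1 <- svd(std_rows(x[paste0("g", 1:8), ]))$v[, 1]
  expect_equal(abs(unclass(es8)["s", ]), abs(v1), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(es8["s", ]^2), 1, tolerance = 1e-10)  # unit norm
})

test_that("PLAGE and combined z-score are invariant to positive per-gene affine maps", {
  set.seed(42)
  expr <- rand_expr(10, 7)
  x <- unclass(expr)
  gsc <- gene_set_collection(list(s = paste0("g", c(1, 4, 6, 9))))
  x2 <- x * rep(runif(10, 0.5, 4), 7) + rep(rnorm(10), 7)
  dimnames(x2) <- dimnames(x)
  e2 <- expression_matrix(x2, "continuous")
  expect_equal(unclass(plage(expr, gsc)), unclass(plage(e2, gsc)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(combined_zscore(expr, gsc)), unclass(combined_zscore(e2, gsc)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("combined z-score is the Stouffer sum of standardized rows", {
  set.seed(43)
  expr <- rand_expr(9, 5)
  x <- unclass(expr)
  gsc <- gene_set_collection(list(one = "g2",
                                  four = paste0("g", c(1, 3, 8, 9))))
  es <- combined_zscore(expr, gsc)
  z <- std_rows(x)
  expect_equal(unclass(es)["one", ], z["g2", ], ignore_attr = TRUE)
  expect_equal(unclass(es)["four", ],
               colSums(z[c("g1", "g3", "g8", "g9"), ]) / 2, ignore_attr = TRUE)
  # duplicated gene scales by sqrt(2)
  x2 <- rbind(x, g7dup = x["g7", ]); rownames(x2)[10] <- "g7dup"
  es2 <- combined_zscore(expression_matrix(x2, "continuous"),
                         gene_set_collection(list(s = c("g7", "g7dup"))))
  expect_equal(unclass(es2)["s", ], sqrt(2) * z["g7", ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("constant genes are dropped with a warning; empty sets score zero", {
  x <- rbind(flat = rep(2, 5), g2 = rnorm(5), g3 = rnorm(5))
  colnames(x) <- paste0("s", 1:5)
  expr <- expression_matrix(x, "continuous")
  gsc <- gene_set_collection(list(mixed = c("flat", "g2"), dead = "flat"))
  expect_warning(expect_warning(es <- plage(expr, gsc), "constant"), "no usable")
  expect_true(all(unclass(es)["dead", ] == 0))
  expect_warning(expect_warning(es2 <- combined_zscore(expr, gsc), "constant"), "no usable")
  expect_equal(unclass(es2)["mixed", ], std_rows(x)["g2", ], ignore_attr = TRUE)
})

test_that("ssGSEA matches the running-sum oracle and normalizes the global range", {
  set.seed(44)
  expr <- rand_expr(12, 3)
  x <- unclass(expr)
  gsc <- gene_set_collection(list(a = paste0("g", c(2, 5, 7, 11)),
                                  b = paste0("g", 1:6)))
  raw <- ssgsea(expr, gsc, normalize = FALSE)
  for (k in c("a", "b")) for (j in 1:3) {
    memb <- rownames(x) %in% gsc[[k]]
    expect_equal(unclass(raw)[k, j], oracle_ssgsea_sample(x[, j], memb, 0.25),
                 tolerance = 1e-10)
  }
  norm <- ssgsea(expr, gsc)
  expect_equal(max(norm) - min(norm), 1, tolerance = 1e-12)
  expect_equal(unclass(norm), unclass(raw) / (max(raw) - min(raw)),
               ignore_attr = TRUE)
})

test_that("ssGSEA rewards concentration at the top and is deterministic", {
  p <- 20
  x1 <- matrix(seq_len(p), p, 1, dimnames = list(paste0("g", 1:p), "s1"))
  expr <- expression_matrix(cbind(x1, s2 = x1[, 1]), "continuous")
  colnames(expr) <- c("s1", "s2")
  expr <- expression_matrix(unclass(expr), "continuous")
  top <- gene_set_collection(list(s = paste0("g", 16:20)))    # highest values
  bottom <- gene_set_collection(list(s = paste0("g", 1:5)))   # lowest values
  es_top <- ssgsea(expr, top, normalize = FALSE)
  es_bot <- ssgsea(expr, bottom, normalize = FALSE)
  expect_gt(es_top[1, 1], es_bot[1, 1])
  expect_equal(es_top[1, 1], es_top[1, 2])  # identical columns, identical scores
})

test_that("the method dispatcher routes to every scorer", {
  set.seed(45)
  expr <- rand_expr(15, 5)
  gsc <- rand_sets(rownames(expr), m = 2, min_sz = 4, max_sz = 6)
  for (m in c("gsva", "plage", "zscore", "ssgsea")) {
    es <- suppressWarnings(score_gene_sets(expr, gsc, method = m))
    expect_identical(attr(es, "method"), m)
    expect_identical(dim(unclass(es)), c(2L, 5L))
  }
})
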