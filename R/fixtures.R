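#' Generate small on-disk fixtures
#'
#' Writes a compact, re-readable expression TSV and GMT pair (plus a JSON
#' manifest with file MD5 checksums) for demonstrations and integration
#' tests. All fixtures are at most 100 genes x 12 samples with at most 10
#' gene sets.
#'
#' * `toy_continuous`: 60 genes x 8 samples of N(0,1) log-scale values,
#'   5 gene sets of sizes 10-20.
#' * `toy_counts`: 60 genes x 8 samples of Poisson counts with gene-specific
#'   means, 5 gene sets.
#' * `null_study`: 100 genes x 12 samples of N(0,1) values, 10 random sets —
#'   a miniature of the null score-distribution simulation.
#'
#' @param kind fixture flavour.
#' @param dir output directory (created if missing).
#' @param seed integer seed; fixed seed gives byte-identical files.
#' @return Invisibly, a list with paths `expression`, `gene_sets`,
#'   `manifest` and the checksum table.
#' @export
make_fixture <- function(kind = c("toy_continuous", "toy_counts", "null_study"),
                         dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  dims <- switch(kind,
                 toy_continuous = c(p = 60L, n = 8L, m = 5L),
                 toy_counts = c(p = 60L, n = 8L, m = 5L),
                 null_study = c(p = 100L, n = 12L, m = 10L))
  p <- dims[["p"]]; n <- dims[["n"]]; m <- dims[["m"]]
  gene_ids <- paste0("g", seq_len(p))
  sample_ids <- paste0("s", seq_len(n))
  if (kind == "toy_counts") {
    lam <- exp(rnorm(p, mean = 2, sd = 1))
    x <- matrix(stats::rpois(p * n, rep(lam, n)), p, n,
                dimnames = list(gene_ids, sample_ids))
    expr <- expression_matrix(x, "counts")
  } else {
    x <- matrix(rnorm(p * n), p, n, dimnames = list(gene_ids, sample_ids))
    expr <- expression_matrix(x, "continuous")
  }
  sizes <- sample(10:min(20L, p %/% 2L), m, replace = TRUE)
  sets <- lapply(sizes, function(sz) sample(gene_ids, sz))
  names(sets) <- paste0("set", seq_len(m))
  gsc <- gene_set_collection(sets, provenance = paste0("fixture:", kind))
  expr_path <- file.path(dir, paste0(kind, "_expr.tsv"))
  gmt_path <- file.path(dir, paste0(kind, "_sets.gmt"))
  write_expression(expr, expr_path)
  write_gmt(gsc, gmt_path)
  sums <- tools::md5sum(c(expr_path, gmt_path))
  manifest <- file.path(dir, paste0(kind, "_manifest.json"))
  jsonlite::write_json(
    list(kind = kind, seed = seed,
         value_kind = value_kind(expr),
         genes = p, samples = n, sets = m,
         files = as.list(sums)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(expression = expr_path, gene_sets = gmt_path,
                 manifest = manifest, checksums = sums))
}
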