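test_that("dense TSV/CSV parsing handles both orientations identically", {
  v <- matrix(c(1.5, 0, 2, 3.25, 4, 0), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expression_matrix(v), tsv)
  m <- read_expression(tsv, "tsv")
  expect_identical(dim(m$values), c(3L, 2L))
  expect_equal(m$values, v)

  # transposed file with samples as rows
  t_tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(v), t(v), check.names = FALSE)
  utils::write.table(df, t_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_expression(t_tsv, "tsv", orientation = "samples_by_genes")
  expect_equal(m2$values, m$values)
  expect_identical(m2$gene_ids, m$gene_ids)

  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(data.frame(gene_id = rownames(v), v, check.names = FALSE),
                     csv, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(csv, "csv")$values, v)
})

test_that("TSV round trip preserves values to 1e-9", {
  set.seed(41)
  v <- matrix(stats::runif(200, 0, 12), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expression_matrix(v), f)
  expect_lt(max(abs(read_expression(f, "tsv")$values - v)), 1e-9)
})

test_that("MTX triplets densify with zeros elsewhere", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 2", "1 1 5.0", "3 2 2.0"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  m <- read_expression(file.path(dir, "matrix.mtx"), "mtx")
  expected <- matrix(0, 3, 2, dimnames = list(c("gA", "gB", "gC"),
                                              c("bc1", "bc2")))
  expected[1, 1] <- 5; expected[3, 2] <- 2
  expect_equal(m$values, expected)
})

test_that("malformed input is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3"), f)
  expect_error(read_expression(f, "tsv"), "line 3")
  writeLines(c("gene_id\ts1", "gA\t1", "gA\t2"), f)
  expect_error(read_expression(f, "tsv"), "duplicate gene ids")
  writeLines(c("gene_id\ts1", "gA\tNaN"), f)
  expect_error(read_expression(f, "tsv"), "NaN")
  expect_error(expression_matrix(matrix(c(1, Inf), 2, 1,
                                        dimnames = list(c("a", "b"), "s")),
                                 platform_tag = "synthetic"), "finite")
})

test_that("filter_matrix drops sparse samples then sparse genes", {
  v <- matrix(1, 5, 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  v[, 3] <- 0  # sample 3 records nothing
  m <- filter_matrix(expression_matrix(v), 0.2, 0.2)
  expect_identical(m$sample_ids, paste0("s", c(1, 2, 4, 5)))
  expect_identical(m$gene_ids, paste0("g", 1:5))

  dense <- expression_matrix(matrix(1, 4, 4,
                                    dimnames = list(paste0("g", 1:4),
                                                    paste0("s", 1:4))))
  expect_equal(filter_matrix(dense)$values, dense$values)

  expect_error(filter_matrix(expression_matrix(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))),
    "all samples")
})

test_that("filter_matrix agrees with a brute-force recount and is idempotent", {
  set.seed(42)
  for (rep in 1:20) {
    v <- matrix(stats::rbinom(100, 1, 0.35) * stats::runif(100, 0.5, 3),
                10, 10, dimnames = list(sprintf("g%02d", 1:10),
                                        sprintf("s%02d", 1:10)))
    m <- expression_matrix(v)
    res <- tryCatch(filter_matrix(m, 0.2, 0.2), error = function(e) NULL)
    # brute force: recount fractions with explicit loops
    keep_s <- vapply(1:10, function(j) mean(v[, j] > 0) >= 0.2, TRUE)
    keep_g <- vapply(1:10, function(i)
      mean(v[i, keep_s] > 0) >= 0.2, TRUE)
    if (!any(keep_s) || !any(keep_g)) {
      expect_null(res)
    } else {
      expect_identical(res$gene_ids, rownames(v)[keep_g])
      expect_identical(res$sample_ids, colnames(v)[keep_s])
    }
  }
  # a single pass is idempotent whenever the gene filter leaves every
  # retained sample above the recording threshold (the generic case; with
  # adversarial sparsity a second pass can drop further samples, which is
  # inherent to one-pass sample-then-gene filtering)
  set.seed(43)
  v <- matrix(stats::rbinom(100, 1, 0.7) * stats::runif(100, 0.5, 3),
              10, 10, dimnames = list(sprintf("g%02d", 1:10),
                                      sprintf("s%02d", 1:10)))
  once <- filter_matrix(expression_matrix(v), 0.2, 0.2)
  twice <- filter_matrix(once, 0.2, 0.2)
  expect_equal(twice$values, once$values)
})

test_that("log2 TPM and CPM normalization match the hand-computed formula", {
  v <- matrix(c(10, 10), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  m <- expression_matrix(v)
  tpm <- log_normalize(m, gene_lengths = c(gA = 1000, gB = 1000), "log2_tpm")
  expect_equal(unname(tpm$values[, 1]), log2(c(5e5, 5e5) + 1))
  expect_identical(tpm$normalization_tag, "log2_tpm")

  # unequal lengths: per-kb rates (10, 5) -> TPM (2/3, 1/3) * 1e6
  tpm2 <- log_normalize(m, gene_lengths = c(gA = 1000, gB = 2000), "log2_tpm")
  expect_equal(unname(tpm2$values[, 1]),
               log2(c(2 / 3, 1 / 3) * 1e6 + 1))

  cpm <- log_normalize(m, mode = "log2_cpm")
  expect_equal(unname(cpm$values[, 1]), log2(c(5e5, 5e5) + 1))

  zero <- expression_matrix(matrix(0, 2, 1,
                                   dimnames = list(c("a", "b"), "s")))
  expect_true(all(log_normalize(zero, mode = "log2_cpm")$values == 0))

  neg <- expression_matrix(matrix(c(1, 1), 2, 1,
                                  dimnames = list(c("a", "b"), "s")))
  neg$values[1, 1] <- -1
  expect_error(log_normalize(neg, mode = "passthrough"), "negative")
  expect_error(log_normalize(m, gene_lengths = c(gA = 1000), "log2_tpm"),
               "gB")
})

test_that("intersect_genes restricts to the common set in canonical order", {
  mk <- function(genes) expression_matrix(
    matrix(seq_along(genes), length(genes), 1,
           dimnames = list(genes, "s1")))
  out <- intersect_genes(list(mk(c("A", "B", "C")), mk(c("B", "C", "D"))))
  expect_identical(out[[1]]$gene_ids, c("B", "C"))
  expect_identical(out[[1]]$gene_ids, out[[2]]$gene_ids)

  m <- mk(c("C", "A", "B"))
  out2 <- intersect_genes(list(m, m))
  expect_identical(out2[[1]]$gene_ids, c("A", "B", "C"))
  expect_equal(out2[[1]]$values, out2[[2]]$values)

  # three-way intersection vs set-algebra oracle
  g1 <- c("A", "B", "C", "E"); g2 <- c("B", "C", "D", "E"); g3 <- c("C", "E", "F")
  out3 <- intersect_genes(list(mk(g1), mk(g2), mk(g3)))
  expect_identical(out3[[1]]$gene_ids,
                   sort(intersect(intersect(g1, g2), g3), method = "radix"))

  expect_error(intersect_genes(list(mk(c("A")), mk(c("B")))), "empty")
})

test_that("split_cells partitions deterministically with floored val/test", {
  d <- toy_separable(n_genes = 5, n_samples = 10)
  sp <- split_cells(d, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(vapply(sp, function(x) length(x$labels), 1L),
                   c(train = 8L, val = 1L, test = 1L))
  sp2 <- split_cells(d, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(sp$train$matrix$sample_ids, sp2$train$matrix$sample_ids)

  d2 <- toy_separable(n_genes = 5, n_samples = 1000)
  a <- split_cells(d2, seed = 1); b <- split_cells(d2, seed = 2)
  expect_false(identical(a$train$matrix$sample_ids,
                         b$train$matrix$sample_ids))
  expect_identical(length(a$train$labels), length(b$train$labels))
})

test_that("split_cells is disjoint and exhaustive across many seeds", {
  d <- toy_separable(n_genes = 4, n_samples = 37)
  all_ids <- d$matrix$sample_ids
  for (seed in 1:1000) {
    sp <- split_cells(d, seed = seed)
    ids <- c(sp$train$matrix$sample_ids, sp$val$matrix$sample_ids,
             sp$test$matrix$sample_ids)
    expect_identical(sort(ids), sort(all_ids))
    expect_identical(anyDuplicated(ids), 0L)
  }
})

test_that("GMT parsing keeps one deduplicated set per line", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescA\tg1\tg2\tg3",
               "setB\tdescB\tg2\tg4"), f)
  gc <- read_gmt(f)
  expect_length(gc$sets, 2)
  expect_identical(gc$sets$setA, c("g1", "g2", "g3"))
  expect_identical(unname(gc$descriptions["setB"]), "descB")

  writeLines(c("setA\td\tg1", "setA\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate set name at line 2")
  writeLines("setA\tdesc", f)
  expect_error(read_gmt(f), "line 1")
  writeLines("setA\tdesc\tg1\tg1\tg2", f)
  expect_identical(length(read_gmt(f)$sets$setA), 2L)
})

test_that("labelled datasets validate label shape and coding", {
  m <- expression_matrix(matrix(1, 2, 3,
                                dimnames = list(c("a", "b"),
                                                c("x", "y", "z"))))
  expect_error(labelled_dataset(m, c(0, 1)), "length")
  expect_error(labelled_dataset(m, c(0, 1, 2)), "binary")
  d <- labelled_dataset(m, c(0, 1, 1), cell_type = c("t1", "t2", "t1"))
  expect_identical(d$cell_type, c("t1", "t2", "t1"))
})
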