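test_that("primary-capsule gene weights aggregate W_i columns", {
  rw <- array(0, c(2, 2, 2, 2))
  p0 <- capsule_params(list(matrix(0, 2, 3), matrix(0, 2, 3)), rw)
  expect_true(all(primary_capsule_gene_weights(p0)$importance == 0))

  # d_p = 1: the l2 norm of a single row is the absolute weight
  p1 <- capsule_params(list(matrix(c(-2, 3, 0.5), 1, 3),
                            matrix(c(1, -1, 0), 1, 3)),
                       array(0, c(2, 2, 2, 1)))
  imp <- primary_capsule_gene_weights(p1)
  expect_equal(unname(imp$importance[, 1]), c(2, 3, 0.5))

  set.seed(61)
  W <- replicate(2, matrix(stats::rnorm(15), 3, 5), simplify = FALSE)
  pr <- capsule_params(W, array(0, c(2, 2, 2, 3)))
  impr <- primary_capsule_gene_weights(pr)
  for (i in 1:2) for (g in 1:5)
    expect_equal(unname(impr$importance[g, i]),
                 sqrt(sum(W[[i]][, g]^2)))
  expect_equal(unname(primary_capsule_gene_weights(pr, "signed_mean")$importance[2, 1]),
               mean(W[[1]][, 2]))
  expect_equal(unname(primary_capsule_gene_weights(pr, "mean_abs")$importance[2, 1]),
               mean(abs(W[[1]][, 2])))
})

test_that("important-gene selection uses a strict absolute threshold", {
  p <- capsule_params(list(matrix(c(0.05, 0.07, -0.08), 1, 3)),
                      array(0, c(1, 2, 2, 1)))
  imp <- primary_capsule_gene_weights(p)
  sel <- important_genes(imp, 0.06)
  expect_identical(sel$sets$primary_1, c("gene_2", "gene_3"))

  expect_length(important_genes(imp, 1)$sets$primary_1, 0)

  set.seed(62)
  W <- replicate(3, matrix(stats::rnorm(20, sd = 0.05), 2, 10),
                 simplify = FALSE)
  pr <- capsule_params(W, array(0, c(3, 2, 2, 2)))
  impr <- primary_capsule_gene_weights(pr)
  sel2 <- important_genes(impr, 0.06)
  for (i in 1:3)
    expect_identical(sel2$sets[[i]],
                     impr$gene_ids[abs(impr$importance[, i]) > 0.06])
  expect_identical(sum(sel2$combo_counts),
                   sum(rowSums(sel2$membership) > 0))
})

# hand-built model: gene 1 feeds only primary capsule 1, which routes only
# to output capsule 1; gene 3 is disconnected everywhere
block_model <- function() {
  n <- 3
  pw <- list(matrix(c(1, 0, 0, 0, 0, 0), 2, 3),   # reads gene 1 only
             matrix(c(0, 0, 1, 0, 0, 0), 2, 3))   # reads gene 2 only
  rw <- array(0, c(2, 2, 2, 2))
  rw[1, 1, , ] <- diag(2)   # primary 1 -> capsule 1 only
  rw[2, 2, , ] <- diag(2)   # primary 2 -> capsule 2 only
  cfg <- train_config(n_primary = 2, n_capsules = 2, d_p = 2, d_c = 2,
                      n_heads = 1, hidden_units = 4, seed = 1)
  m <- capstx:::with_seed(1, capstx:::init_model(n, c("g1", "g2", "g3"), cfg))
  m$encoder <- capsule_params(pw, rw, c("g1", "g2", "g3"))
  m
}

test_that("occlusion attribution respects the wiring of the encoder", {
  m <- block_model()
  ref <- expression_matrix(matrix(c(2, 1, 5, 1, 2, 4), 3, 2,
                                  dimnames = list(c("g1", "g2", "g3"),
                                                  c("s1", "s2"))))
  sc <- capsule_activation_test(m, ref)
  # disconnected gene: exactly zero attribution everywhere
  expect_identical(unname(sc["g3", ]), c(0, 0))
  # gene 1 influences only capsule 1 (and positively: it feeds it)
  expect_identical(unname(sc["g1", "capsule_2"]), 0)
  expect_gt(sc["g1", "capsule_1"], 0)
  expect_identical(unname(sc["g2", "capsule_1"]), 0)

  # attribution over a batch is the mean of per-sample attributions
  s1 <- capsule_activation_test(m, capstx:::em_subset(ref, samples = 1))
  s2 <- capsule_activation_test(m, capstx:::em_subset(ref, samples = 2))
  expect_equal(sc, (s1 + s2) / 2, tolerance = 1e-12)

  # single-capsule extraction and bounds checking
  at <- capsule_activation_test(m, ref, capsule_index = 1)
  expect_s3_class(at, "capsule_attribution")
  expect_equal(unname(at$score), unname(sc[, 1]))
  expect_error(capsule_activation_test(m, ref, capsule_index = 9),
               "out of range")

  # activate_single mode also sees the block structure
  sa <- capsule_activation_test(m, ref, mode = "activate_single")
  expect_identical(unname(sa["g3", ]), c(0, 0))
  expect_gt(sa["g1", "capsule_1"], 0)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  coll <- gene_set_collection(list(S = paste0("g", 1:5)))
  universe <- paste0("g", 1:10)
  # overlap 3 of 3 drawn from 5 successes in 10: C(5,3)/C(10,3)
  r <- hypergeometric_enrichment(paste0("g", 1:3), coll, universe,
                                 correction = "none")
  expect_equal(r$p_value, 10 / 120, tolerance = 1e-12)

  # query = set = universe: the draw is certain, p = 1
  r2 <- hypergeometric_enrichment(universe,
                                  gene_set_collection(list(all = universe)),
                                  universe)
  expect_equal(r2$p_value, 1)

  # zero overlap: P[X >= 0] = 1
  r3 <- hypergeometric_enrichment(paste0("g", 6:7),
                                  gene_set_collection(list(S = paste0("g", 1:3))),
                                  universe, correction = "none")
  expect_equal(r3$p_value, 1)

  expect_error(hypergeometric_enrichment("gX", coll, universe), "outside")

  # BH adjustment is monotone: same order by p and adjusted p
  set.seed(63)
  sets <- lapply(1:8, function(i) sample(universe, sample(2:6, 1)))
  names(sets) <- paste0("S", 1:8)
  rr <- hypergeometric_enrichment(sample(universe, 4),
                                  gene_set_collection(sets), universe)
  expect_identical(order(rr$p_value), order(rr$adjusted_p, rr$p_value))
  expect_true(all(rr$adjusted_p >= rr$p_value))
})

test_that("the capsule-pathway network emits only significant unique edges", {
  universe <- paste0("g", 1:40)
  coll <- gene_set_collection(list(path1 = paste0("g", 1:5),
                                   path2 = paste0("g", 21:30)))
  # capsule matching path1 exactly in a sparse universe
  net <- capsule_pathway_network(list(capsule_1 = paste0("g", 1:5)),
                                 coll, universe)
  expect_true("path1" %in% net$edges$pathway)
  expect_false("path2" %in% net$edges$pathway)
  expect_identical(anyDuplicated(net$edges[c("capsule", "pathway")]), 0L)
  expect_setequal(net$nodes$type, c("capsule", "pathway"))

  # no signal: empty edge table, capsule nodes only
  net0 <- capsule_pathway_network(list(capsule_1 = sample(universe, 3)),
                                 coll, universe, alpha = 1e-12)
  expect_identical(nrow(net0$edges), 0L)
  expect_identical(net0$nodes$type, "capsule")
})
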