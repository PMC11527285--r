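test_that("squash compresses the norm and preserves direction", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))

  u <- c(1, 0) # unit norm -> output norm exactly 0.5
  expect_equal(squash(u), c(0.5, 0))

  expect_equal(squash(c(3, 4)), (25 / 26) * c(0.6, 0.8), tolerance = 1e-13)

  expect_error(squash(c(1, NA)), "finite")
})

test_that("squash norm is strictly increasing in input norm and below 1", {
  set.seed(1)
  prev <- -1
  for (r in sort(stats::runif(1e4, 0, 50))) {
    nrm <- sqrt(sum(squash(c(r, 0))^2))
    expect_lt(nrm, 1)
    expect_gt(nrm, prev)
    prev <- nrm
  }
})

test_that("primary capsules are exact linear projections", {
  W0 <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  rw <- array(0, c(2, 2, 2, 2))
  p0 <- capsule_params(W0, rw)
  expect_equal(primary_capsules(c(1, 2), p0), list(c(0, 0), c(0, 0)))

  Wi <- list(diag(2), matrix(c(1, 0, 1, 1), 2, 2))
  pi_ <- capsule_params(Wi, rw)
  expect_equal(primary_capsules(c(1, 2), pi_)[[1]], c(1, 2))

  set.seed(5)
  W <- replicate(3, matrix(stats::rnorm(8), 2, 4), simplify = FALSE)
  pr <- capsule_params(W, array(0, c(3, 2, 2, 2)))
  x <- stats::rnorm(4)
  u <- primary_capsules(x, pr)
  for (i in 1:3)
    for (k in 1:2)
      expect_equal(u[[i]][k], sum(W[[i]][k, ] * x))

  expect_error(primary_capsules(c(1, 2, 3), pi_), "length 2")
})

test_that("prediction vectors are w_ij u_i, constant across iterations", {
  rw0 <- array(0, c(2, 2, 2, 2))
  p <- capsule_params(list(diag(2), diag(2)), rw0)
  expect_true(all(prediction_vectors(list(c(1, 2), c(3, 4)), p) == 0))

  rw_id <- array(0, c(1, 1, 2, 2))
  rw_id[1, 1, , ] <- diag(2)
  p_id <- capsule_params(list(diag(2)), rw_id)
  expect_equal(drop(prediction_vectors(list(c(2, 5)), p_id)), c(2, 5))

  # hand-enumerated small-integer case
  rw <- array(0, c(2, 2, 2, 2))
  rw[1, 1, , ] <- matrix(c(1, 0, 2, 1), 2, 2)
  rw[1, 2, , ] <- matrix(c(0, 1, 1, 0), 2, 2)
  rw[2, 1, , ] <- matrix(c(1, 1, 0, 2), 2, 2)
  rw[2, 2, , ] <- matrix(c(2, 0, 0, 3), 2, 2)
  ph <- capsule_params(list(diag(2), diag(2)), rw)
  u <- list(c(1, 2), c(3, -1))
  uh <- prediction_vectors(u, ph)
  for (i in 1:2) for (j in 1:2)
    expect_equal(uh[i, j, ], drop(rw[i, j, , ] %*% u[[i]]))
})

test_that("dynamic routing matches the step-by-step oracle", {
  set.seed(12)
  uhat <- array(sample(-3:3, 8, replace = TRUE), c(2, 2, 2))
  for (axis in c("input_capsules", "output_capsules")) {
    r <- dynamic_routing(uhat, 3, axis)
    v_or <- oracle_routing(uhat, 3,
                           if (axis == "input_capsules") "input" else "output")
    expect_lt(max(abs(r$v - v_or)), 1e-10)
  }
})

test_that("routing degenerate cases follow the softmax structure", {
  # single input capsule: coupling is 1, v = squash(uhat)
  uhat1 <- array(stats::rnorm(6), c(1, 3, 2))
  r1 <- dynamic_routing(uhat1, 3, "input_capsules")
  for (st in r1$trace) expect_true(all(st$c == 1))
  for (j in 1:3) expect_equal(r1$v[j, ], squash(uhat1[1, j, ]))

  # zero logits at t = 1: uniform coupling
  uhat <- array(stats::rnorm(16), c(2, 4, 2))
  r <- dynamic_routing(uhat, 1, "input_capsules")
  expect_true(all(abs(r$trace[[1]]$c - 0.5) < 1e-12))
  r2 <- dynamic_routing(uhat, 1, "output_capsules")
  expect_true(all(abs(r2$trace[[1]]$c - 0.25) < 1e-12))

  # one iteration with uniform coupling = mean over inputs, then squash
  for (j in 1:4)
    expect_equal(r$v[j, ], squash((uhat[1, j, ] + uhat[2, j, ]) / 2))

  expect_error(dynamic_routing(uhat, 0), "n_iterations")
})

test_that("coupling coefficients stay normalized along the configured axis", {
  set.seed(13)
  for (rep in 1:25) {
    uhat <- array(stats::rnorm(3 * 4 * 2, sd = 2), c(3, 4, 2))
    ri <- dynamic_routing(uhat, 4, "input_capsules")
    for (st in ri$trace) {
      expect_true(all(st$c >= 0))
      expect_lt(max(abs(colSums(st$c) - 1)), 1e-9)
      expect_true(all(sqrt(rowSums(st$v^2)) < 1))
    }
    ro <- dynamic_routing(uhat, 4, "output_capsules")
    for (st in ro$trace)
      expect_lt(max(abs(rowSums(st$c) - 1)), 1e-9)
  }
})

test_that("routing is invariant to permuting input capsules with weights", {
  set.seed(14)
  uhat <- array(stats::rnorm(4 * 3 * 2), c(4, 3, 2))
  perm <- c(3, 1, 4, 2)
  r <- dynamic_routing(uhat, 3)
  rp <- dynamic_routing(uhat[perm, , , drop = FALSE], 3)
  expect_equal(r$v, rp$v, tolerance = 1e-12)
})

test_that("batched encoding equals the per-sample pipeline", {
  set.seed(15)
  n <- 12
  params <- init_capsule_params(n, P = 3, J = 4, d_p = 3, d_c = 3,
                                gene_ids = sprintf("g%02d", 1:n))
  X <- matrix(stats::rnorm(n * 4), n,
              dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:4)))
  V <- encode_capsules(X, params)
  for (s in 1:4) {
    u <- primary_capsules(X[, s], params)
    r <- dynamic_routing(prediction_vectors(u, params), 3)
    expect_equal(V[s, , ], r$v, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # batch of one equals the single-sample slice
  V1 <- encode_capsules(X[, 1, drop = FALSE], params)
  expect_equal(V1[1, , ], V[1, , ], tolerance = 1e-14, ignore_attr = TRUE)

  # zero expression with linear (bias-free) maps encodes to zero capsules
  expect_true(all(encode_capsules(matrix(0, n, 2), params) == 0))

  # determinism
  expect_identical(encode_capsules(X, params), encode_capsules(X, params))

  # gene-list mismatch reported with the first discrepant position
  em <- expression_matrix(X[n:1, ], rev(sprintf("g%02d", 1:n)),
                          paste0("s", 1:4))
  expect_error(encode_capsules(em, params), "position 1")
})
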