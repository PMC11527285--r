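# Vectorized forward/backward passes for the capsule encoder, attention
# decoder and dense head. Arrays are laid out capsule-dim-fastest:
#   U    (d_p, P, B)      primary capsules
#   Uhat (d_c, J, P, B)   prediction vectors
#   V    (d_c, J, B)      output capsules
# The backward pass is exact through the unrolled routing loop, including the
# softmax(b) dependence of the coupling coefficients on earlier iterations.

SQUASH_EPS <- 1e-8

# stack list of P (d_p x n) matrices into (P*d_p x n)
stack_primary <- function(params) do.call(rbind, params$primary_weights)

# per-input-capsule routing matrix M_i of shape (J*d_c x d_p),
# rows ordered capsule-dim fastest within output capsule j
routing_mats <- function(params) {
  d <- params$dims
  lapply(seq_len(d$P), function(i) {
    Wi <- array(params$routing_weights[i, , , ], dim = c(d$J, d$d_c, d$d_p))
    matrix(aperm(Wi, c(2, 1, 3)), nrow = d$J * d$d_c, ncol = d$d_p)
  })
}

# softmax over dim 1 of a (P, J, B) array (each (j,b) fiber sums to 1)
softmax_dim1 <- function(b) {
  P <- dim(b)[1]
  bm <- matrix(b, nrow = P)
  mx <- apply(bm, 2, max)
  e <- exp(sweep(bm, 2, mx, "-"))
  array(sweep(e, 2, colSums(e), "/"), dim = dim(b))
}

softmax_arr <- function(b, axis) {
  if (axis == 1L) softmax_dim1(b)
  else aperm(softmax_dim1(aperm(b, c(2, 1, 3))), c(2, 1, 3))
}

# full encoder forward on a plain (n_genes x B) matrix
encoder_forward <- function(params, X, n_iterations, softmax_axis,
                            keep_trace = TRUE) {
  d <- params$dims
  B <- ncol(X)
  axis <- if (softmax_axis == "input_capsules") 1L else 2L
  PW <- stack_primary(params)
  U <- array(PW %*% X, dim = c(d$d_p, d$P, B))
  M <- routing_mats(params)
  Uhat <- array(0, dim = c(d$d_c, d$J, d$P, B))
  for (i in seq_len(d$P))
    Uhat[, , i, ] <- M[[i]] %*% matrix(U[, i, ], nrow = d$d_p)
  uh <- function(i) array(Uhat[, , i, ], dim = c(d$d_c, d$J, B))
  b <- array(0, dim = c(d$P, d$J, B))
  trace <- if (keep_trace) vector("list", n_iterations)
  v <- NULL
  for (t in seq_len(n_iterations)) {
    cc <- softmax_arr(b, axis)
    s <- array(0, dim = c(d$d_c, d$J, B))
    for (i in seq_len(d$P))
      s <- s + uh(i) * rep(cc[i, , ], each = d$d_c)
    nr2 <- colSums(matrix(s^2, nrow = d$d_c))
    nr <- matrix(sqrt(nr2), d$J, B)
    scale <- nr^2 / (1 + nr^2) / pmax(nr, SQUASH_EPS)
    v <- s * rep(scale, each = d$d_c)
    if (any(!is.finite(v)))
      stop("NaN during dynamic routing at iteration ", t)
    for (i in seq_len(d$P)) {
      agree <- colSums(matrix(uh(i) * v, nrow = d$d_c))
      b[i, , ] <- b[i, , ] + agree
    }
    if (keep_trace) trace[[t]] <- list(c = cc, s = s, nr = nr, v = v)
  }
  list(V = v, U = U, Uhat = Uhat, M = M, trace = trace, axis = axis,
       n_iterations = n_iterations)
}

# backward of softmax over the given axis: dc -> db
softmax_backward_arr <- function(dc, cc, axis) {
  dims <- dim(cc)
  if (axis == 2L) {
    dc <- aperm(dc, c(2, 1, 3)); cc <- aperm(cc, c(2, 1, 3))
  }
  P <- dim(cc)[1]
  prod <- cc * dc
  S <- colSums(matrix(prod, nrow = P))        # sums over normalized dim
  db <- cc * (dc - rep(S, each = P))
  db <- array(db, dim = dim(cc))
  if (axis == 2L) db <- aperm(db, c(2, 1, 3))
  db
}

# backward through the encoder; dV is (d_c, J, B); X is (n_genes x B).
# returns gradients for primary and routing weights
encoder_backward <- function(params, fw, X, dV) {
  d <- params$dims
  B <- dim(dV)[3]
  Uhat <- fw$Uhat
  uh <- function(i) array(Uhat[, , i, ], dim = c(d$d_c, d$J, B))
  T_ <- fw$n_iterations
  dUhat <- array(0, dim = dim(Uhat))
  db_next <- NULL
  for (t in rev(seq_len(T_))) {
    st <- fw$trace[[t]]
    dv <- if (t == T_) dV else array(0, dim = dim(dV))
    if (!is.null(db_next)) {
      # b_{t+1} = b_t + sum_dc Uhat * v_t
      for (i in seq_len(d$P)) {
        e <- rep(db_next[i, , ], each = d$d_c)
        dv <- dv + uh(i) * e
        dUhat[, , i, ] <- array(dUhat[, , i, ], dim = c(d$d_c, d$J, B)) +
          e * st$v
      }
    }
    # squash backward: v = g(r) s, g = r/(1+r^2)
    nr <- st$nr
    g <- nr / (1 + nr^2)
    gp <- (1 - nr^2) / (1 + nr^2)^2
    sdot <- matrix(colSums(matrix(st$s * dv, nrow = d$d_c)), d$J, B)
    coef <- gp * sdot / pmax(nr, SQUASH_EPS)
    ds <- dv * rep(g, each = d$d_c) + st$s * rep(coef, each = d$d_c)
    # s = sum_i c_i * Uhat_i
    dc <- array(0, dim = c(d$P, d$J, B))
    for (i in seq_len(d$P)) {
      dUhat[, , i, ] <- array(dUhat[, , i, ], dim = c(d$d_c, d$J, B)) +
        ds * rep(st$c[i, , ], each = d$d_c)
      dc[i, , ] <- colSums(matrix(uh(i) * ds, nrow = d$d_c))
    }
    db <- softmax_backward_arr(dc, st$c, fw$axis)
    if (!is.null(db_next)) db <- db + db_next
    db_next <- db
  }
  # Uhat_i = M_i U_i ; U = PW X
  dU <- array(0, dim = c(d$d_p, d$P, B))
  dWr <- array(0, dim = dim(params$routing_weights))
  for (i in seq_len(d$P)) {
    dUi_mat <- matrix(dUhat[, , i, ], nrow = d$d_c * d$J)
    Ui <- matrix(fw$U[, i, ], nrow = d$d_p)
    dM <- dUi_mat %*% t(Ui)
    dWr[i, , , ] <- aperm(array(dM, dim = c(d$d_c, d$J, d$d_p)), c(2, 1, 3))
    dU[, i, ] <- crossprod(fw$M[[i]], dUi_mat)
  }
  dPW <- matrix(dU, nrow = d$d_p * d$P) %*% t(X)
  dimnames(dPW) <- NULL
  dprimary <- lapply(seq_len(d$P), function(i)
    dPW[(i - 1) * d$d_p + seq_len(d$d_p), , drop = FALSE])
  list(primary_weights = dprimary, routing_weights = dWr)
}

# attention forward over a batch: V (d_c, J, B) -> Z (J*d_c*H x B)
attention_forward <- function(att, V, keep_cache = TRUE) {
  d_c <- att$d_c; H <- att$n_heads
  J <- dim(V)[2]; B <- dim(V)[3]
  Z <- matrix(0, J * d_c * H, B)
  cache <- if (keep_cache) vector("list", B)
  for (s in seq_len(B)) {
    Vp <- t(matrix(V[, , s], nrow = d_c))       # J x d_c
    heads <- if (keep_cache) vector("list", H)
    zs <- numeric(0)
    for (h in seq_len(H)) {
      Q <- Vp %*% t(att$Wq[, , h])
      K <- Vp %*% t(att$Wk[, , h])
      Vv <- Vp %*% t(att$Wv[, , h])
      E <- tcrossprod(Q, K) / sqrt(att$d_k)
      A <- softmax_mat(E, axis = 2L)
      Zh <- A %*% Vv
      zs <- c(zs, as.vector(t(Zh)))
      if (keep_cache) heads[[h]] <- list(Q = Q, K = K, Vv = Vv, A = A)
    }
    Z[, s] <- zs
    if (keep_cache) cache[[s]] <- list(Vp = Vp, heads = heads)
  }
  list(Z = Z, cache = cache, J = J)
}

# attention backward: dZ (J*d_c*H x B) -> dV (d_c, J, B) + weight grads
attention_backward <- function(att, afw, dZ) {
  d_c <- att$d_c; H <- att$n_heads; J <- afw$J
  B <- ncol(dZ)
  dWq <- array(0, dim = dim(att$Wq)); dWk <- dWq; dWv <- dWq
  dV <- array(0, dim = c(d_c, J, B))
  seg <- J * d_c
  for (s in seq_len(B)) {
    cs <- afw$cache[[s]]
    dVp <- matrix(0, J, d_c)
    for (h in seq_len(H)) {
      hc <- cs$heads[[h]]
      dZh <- t(matrix(dZ[(h - 1) * seg + seq_len(seg), s], nrow = d_c))
      dA <- tcrossprod(dZh, hc$Vv)
      dVv <- crossprod(hc$A, dZh)
      dE <- hc$A * (dA - rowSums(hc$A * dA))
      dE <- dE / sqrt(att$d_k)
      dQ <- dE %*% hc$K
      dK <- crossprod(dE, hc$Q)
      dVp <- dVp + dQ %*% att$Wq[, , h] + dK %*% att$Wk[, , h] +
        dVv %*% att$Wv[, , h]
      dWq[, , h] <- dWq[, , h] + crossprod(dQ, cs$Vp)
      dWk[, , h] <- dWk[, , h] + crossprod(dK, cs$Vp)
      dWv[, , h] <- dWv[, , h] + crossprod(dVv, cs$Vp)
    }
    dV[, , s] <- t(dVp)
  }
  list(Wq = dWq, Wk = dWk, Wv = dWv, dV = dV)
}

# head forward: Z (in_dim x B) -> probabilities
head_forward <- function(head, Z, activation) {
  act <- activation_fun(activation)
  Hm <- act$f(head$W1 %*% Z + head$b1)
  logits <- drop(crossprod(matrix(head$w2, ncol = 1), Hm)) + head$b2
  # keep probabilities strictly inside (0, 1) even for saturating logits
  p <- pmin(pmax(stats::plogis(logits), 1e-12), 1 - 1e-12)
  list(H = Hm, logits = logits, p = p)
}

head_backward <- function(head, hfw, Z, dlogits, activation) {
  act <- activation_fun(activation)
  dw2 <- as.numeric(hfw$H %*% dlogits)
  db2 <- sum(dlogits)
  dH <- outer(head$w2, dlogits)
  dA1 <- dH * act$dfda(hfw$H)
  list(W1 = dA1 %*% t(Z), b1 = rowSums(dA1), w2 = dw2, b2 = db2,
       dZ = crossprod(head$W1, dA1))
}

# full model forward on a plain matrix X (n_genes x B)
model_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config
  efw <- encoder_forward(model$encoder, X, cfg$routing_iterations,
                         cfg$softmax_axis, keep_trace = keep_cache)
  afw <- attention_forward(model$attention, efw$V, keep_cache = keep_cache)
  hfw <- head_forward(model$head, afw$Z, cfg$activation)
  list(p = hfw$p, logits = hfw$logits, efw = efw, afw = afw, hfw = hfw)
}

# full backward for mean BCE over the batch; returns flat gradient list
model_backward <- function(model, fwd, X, y) {
  B <- length(y)
  dlogits <- (fwd$hfw$p - y) / B
  hb <- head_backward(model$head, fwd$hfw, fwd$afw$Z, dlogits,
                      model$config$activation)
  ab <- attention_backward(model$attention, fwd$afw, hb$dZ)
  eb <- encoder_backward(model$encoder, fwd$efw, X, ab$dV)
  flat_grads(eb, ab, hb, model$encoder$dims$P)
}

# ---- flat parameter handling (for Adam and gradient checks) ----

flat_params <- function(model) {
  out <- list()
  P <- model$encoder$dims$P
  for (i in seq_len(P)) out[[paste0("enc_W", i)]] <- model$encoder$primary_weights[[i]]
  out$enc_Wr <- model$encoder$routing_weights
  out$att_Wq <- model$attention$Wq
  out$att_Wk <- model$attention$Wk
  out$att_Wv <- model$attention$Wv
  out$head_W1 <- model$head$W1
  out$head_b1 <- model$head$b1
  out$head_w2 <- model$head$w2
  out$head_b2 <- model$head$b2
  out
}

flat_grads <- function(eb, ab, hb, P) {
  out <- list()
  for (i in seq_len(P)) out[[paste0("enc_W", i)]] <- eb$primary_weights[[i]]
  out$enc_Wr <- eb$routing_weights
  out$att_Wq <- ab$Wq
  out$att_Wk <- ab$Wk
  out$att_Wv <- ab$Wv
  out$head_W1 <- hb$W1
  out$head_b1 <- hb$b1
  out$head_w2 <- hb$w2
  out$head_b2 <- hb$b2
  out
}

set_flat_params <- function(model, flat) {
  P <- model$encoder$dims$P
  for (i in seq_len(P))
    model$encoder$primary_weights[[i]] <- flat[[paste0("enc_W", i)]]
  model$encoder$routing_weights <- flat$enc_Wr
  model$attention$Wq <- flat$att_Wq
  model$attention$Wk <- flat$att_Wk
  model$attention$Wv <- flat$att_Wv
  model$head$W1 <- flat$head_W1
  model$head$b1 <- flat$head_b1
  model$head$w2 <- flat$head_w2
  model$head$b2 <- flat$head_b2
  model
}

adam_init <- function(flat) {
  z <- lapply(flat, function(x) x * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, frozen = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}
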