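# Bidirectional transformer encoder for masked-token modelling, implemented
# directly on BLAS matrix ops: token + learned positional embeddings,
# pre-norm self-attention blocks with feed-forward sublayers, a final layer
# norm, and a softmax head over the vocabulary evaluated only at masked
# positions. The pre-norm arrangement trains stably with Adam at desk-scale
# learning rates without warmup schedules. Attention projections carry no
# bias terms (the layer-norm affine parameters absorb them). Forward,
# analytic backward and the Adam update live here; the training loop is in
# mlm.R.
#
# All sequences share the same fixed length, so a batch is processed as a
# single stacked (n_seq * max_len) x dim matrix; only the per-head attention
# products are computed per sequence.

LN_EPS <- 1e-5

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
relu <- function(x) x * (x > 0)
relu_grad <- function(x) (x > 0) * 1

act_fun <- function(config) {
  if (identical(config$activation, "gelu")) {
    list(f = gelu, grad = gelu_grad)
  } else {
    list(f = relu, grad = relu_grad)
  }
}

init_transformer_params <- function(config) {
  d <- config$model_dimension
  v <- config$vocab_size
  h <- d * config$ffn_multiplier
  sd0 <- 0.02
  with_seed(derive_seed(config$seed, 101), {
    p <- list(
      E = matrix(stats::rnorm(v * d, sd = sd0), v, d),
      P = matrix(stats::rnorm(config$max_len * d, sd = sd0),
                 config$max_len, d)
    )
    for (l in seq_len(config$num_hidden_layers)) {
      pre <- sprintf("l%d.", l)
      p[[paste0(pre, "Wq")]] <- matrix(stats::rnorm(d * d, sd = sd0), d, d)
      p[[paste0(pre, "Wk")]] <- matrix(stats::rnorm(d * d, sd = sd0), d, d)
      p[[paste0(pre, "Wv")]] <- matrix(stats::rnorm(d * d, sd = sd0), d, d)
      p[[paste0(pre, "Wo")]] <- matrix(stats::rnorm(d * d, sd = sd0), d, d)
      p[[paste0(pre, "g1")]] <- rep(1, d)
      p[[paste0(pre, "b1")]] <- numeric(d)
      p[[paste0(pre, "g2")]] <- rep(1, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- matrix(stats::rnorm(d * h, sd = sd0), d, h)
      p[[paste0(pre, "bf1")]] <- numeric(h)
      p[[paste0(pre, "W2")]] <- matrix(stats::rnorm(h * d, sd = sd0), h, d)
      p[[paste0(pre, "bf2")]] <- numeric(d)
    }
    p$gf <- rep(1, d)
    p$bf <- numeric(d)
    p$Wout <- matrix(stats::rnorm(d * v, sd = sd0), d, v)
    p$bout <- numeric(v)
    p
  })
}

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(y = add_bias(xhat * rep(g, rep.int(nrow(x), length(g))), b),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, rep.int(nrow(dy), length(g)))
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# Multi-head attention products for one stacked Q/K/V triple; returns the
# context matrix and (optionally) the per-sequence-and-head attention
# weights needed for the backward pass.
mha_forward <- function(Q, K, V, n_seq, L, H, dk, keep_attn) {
  C <- matrix(0, n_seq * L, ncol(Q))
  A_list <- if (keep_attn) vector("list", n_seq * H) else NULL
  inv_sqrt_dk <- 1 / sqrt(dk)
  for (i in seq_len(n_seq)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * inv_sqrt_dk
      S <- exp(S - S[cbind(seq_len(L), max.col(S, ties.method = "first"))])
      A <- S / rowSums(S)
      C[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      if (keep_attn) A_list[[(i - 1L) * H + h]] <- A
    }
  }
  list(C = C, A_list = A_list)
}

mha_backward <- function(dC, cache, n_seq, L, H, dk) {
  d <- ncol(dC)
  dQ <- matrix(0, n_seq * L, d)
  dK <- matrix(0, n_seq * L, d)
  dV <- matrix(0, n_seq * L, d)
  inv_sqrt_dk <- 1 / sqrt(dk)
  for (i in seq_len(n_seq)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$A_list[[(i - 1L) * H + h]]
      dCi <- dC[rows, cols, drop = FALSE]
      dA <- tcrossprod(dCi, cache$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(A, dCi)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] *
        inv_sqrt_dk
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) *
        inv_sqrt_dk
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# Forward pass over a batch of token sequences.
#
# tok_mat: n_seq x max_len matrix of 0-based token ids (mask token allowed).
# mrows:   indices into the stacked row space ((i-1)*max_len + pos) at which
#          the head/loss is evaluated.
# labels:  0-based true tokens at mrows (NULL for logits-only inference).
mlm_forward <- function(params, config, tok_mat, mrows,
                        labels = NULL, want_grad = FALSE,
                        want_logits = FALSE) {
  n_seq <- nrow(tok_mat)
  L <- config$max_len
  d <- config$model_dimension
  H <- config$num_attention_heads
  dk <- d %/% H
  n_tok <- n_seq * L
  tok_vec <- as.vector(t(tok_mat))
  pos_idx <- rep(seq_len(L), times = n_seq)
  act <- act_fun(config)

  X <- params$E[tok_vec + 1L, , drop = FALSE] +
    params$P[pos_idx, , drop = FALSE]

  caches <- vector("list", config$num_hidden_layers)
  for (l in seq_len(config$num_hidden_layers)) {
    pre <- sprintf("l%d.", l)
    Xin <- X
    n1 <- ln_forward(Xin, params[[paste0(pre, "g1")]],
                     params[[paste0(pre, "b1")]])
    Q <- n1$y %*% params[[paste0(pre, "Wq")]]
    K <- n1$y %*% params[[paste0(pre, "Wk")]]
    V <- n1$y %*% params[[paste0(pre, "Wv")]]
    mh <- mha_forward(Q, K, V, n_seq, L, H, dk, keep_attn = want_grad)
    attn <- mh$C %*% params[[paste0(pre, "Wo")]]
    R1 <- Xin + attn
    n2 <- ln_forward(R1, params[[paste0(pre, "g2")]],
                     params[[paste0(pre, "b2")]])
    Hpre <- add_bias(n2$y %*% params[[paste0(pre, "W1")]],
                     params[[paste0(pre, "bf1")]])
    Hact <- act$f(Hpre)
    Ff <- add_bias(Hact %*% params[[paste0(pre, "W2")]],
                   params[[paste0(pre, "bf2")]])
    X <- R1 + Ff
    if (want_grad) {
      caches[[l]] <- list(n1 = n1, Q = Q, K = K, V = V, C = mh$C,
                          A_list = mh$A_list, R1 = R1, n2 = n2,
                          Hpre = Hpre, Hact = Hact)
    }
  }
  nf <- ln_forward(X, params$gf, params$bf)

  Xm <- nf$y[mrows, , drop = FALSE]
  logits <- add_bias(Xm %*% params$Wout, params$bout)

  loss <- NA_real_
  probs <- NULL
  if (!is.null(labels)) {
    mx <- logits[cbind(seq_len(nrow(logits)),
                       max.col(logits, ties.method = "first"))]
    ex <- exp(logits - mx)
    Z <- rowSums(ex)
    loss <- mean(mx + log(Z) -
                   logits[cbind(seq_along(labels), labels + 1L)])
    probs <- ex / Z
  }

  out <- list(loss = loss)
  if (want_logits) out$logits <- logits
  if (!want_grad) return(out)
  stopifnot(!is.null(labels))

  n_m <- length(mrows)
  dlogits <- probs
  dlogits[cbind(seq_len(n_m), labels + 1L)] <-
    dlogits[cbind(seq_len(n_m), labels + 1L)] - 1
  dlogits <- dlogits / n_m

  g <- list()
  g$Wout <- crossprod(Xm, dlogits)
  g$bout <- colSums(dlogits)
  dNf <- matrix(0, n_tok, d)
  dNf[mrows, ] <- tcrossprod(dlogits, params$Wout)
  blf <- ln_backward(dNf, nf, params$gf)
  g$gf <- blf$dg
  g$bf <- blf$db
  dX <- blf$dx

  for (l in config$num_hidden_layers:1) {
    pre <- sprintf("l%d.", l)
    cc <- caches[[l]]
    # FFN sublayer: X_out = R1 + Ff(n2(R1))
    dFf <- dX
    g[[paste0(pre, "W2")]] <- crossprod(cc$Hact, dFf)
    g[[paste0(pre, "bf2")]] <- colSums(dFf)
    dHpre <- tcrossprod(dFf, params[[paste0(pre, "W2")]]) *
      act$grad(cc$Hpre)
    g[[paste0(pre, "W1")]] <- crossprod(cc$n2$y, dHpre)
    g[[paste0(pre, "bf1")]] <- colSums(dHpre)
    dN2y <- tcrossprod(dHpre, params[[paste0(pre, "W1")]])
    bl2 <- ln_backward(dN2y, cc$n2, params[[paste0(pre, "g2")]])
    g[[paste0(pre, "g2")]] <- bl2$dg
    g[[paste0(pre, "b2")]] <- bl2$db
    dR1 <- dX + bl2$dx
    # attention sublayer: R1 = Xin + Wo-projected context of n1(Xin)
    dattn <- dR1
    g[[paste0(pre, "Wo")]] <- crossprod(cc$C, dattn)
    dC <- tcrossprod(dattn, params[[paste0(pre, "Wo")]])
    mhb <- mha_backward(dC, cc, n_seq, L, H, dk)
    g[[paste0(pre, "Wq")]] <- crossprod(cc$n1$y, mhb$dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(cc$n1$y, mhb$dK)
    g[[paste0(pre, "Wv")]] <- crossprod(cc$n1$y, mhb$dV)
    dN1y <- tcrossprod(mhb$dQ, params[[paste0(pre, "Wq")]]) +
      tcrossprod(mhb$dK, params[[paste0(pre, "Wk")]]) +
      tcrossprod(mhb$dV, params[[paste0(pre, "Wv")]])
    bl1 <- ln_backward(dN1y, cc$n1, params[[paste0(pre, "g1")]])
    g[[paste0(pre, "g1")]] <- bl1$dg
    g[[paste0(pre, "b1")]] <- bl1$db
    dX <- dR1 + bl1$dx
  }

  # embeddings
  rs_tok <- rowsum(dX, group = tok_vec)
  ids <- sort(unique(tok_vec))
  g$E <- matrix(0, nrow(params$E), d)
  g$E[ids + 1L, ] <- rs_tok
  g$P <- rowsum(dX, group = pos_idx)

  out$grads <- g
  out
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      grad_clip = 1.0) {
  if (is.finite(grad_clip) && grad_clip > 0) {
    total <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
    if (total > grad_clip) {
      sc <- grad_clip / total
      grads <- lapply(grads, function(x) x * sc)
    }
  }
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
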