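# Dense self-attention machinery for the inquiry decoder and diagnosis
# encoder. Implemented directly in base R matrix code with hand-derived
# backward passes (verified against finite differences in the test suite).
# Sequences here are short (tens of tokens), so dense per-record passes are
# adequate; there is no minibatch tensor dimension — gradients are
# accumulated across records instead.

LN_EPS <- 1e-5

#' Sinusoidal position encoding
#'
#' Fixed (non-learned) position features: for position `t` (0-based) and
#' dimension pair `i` (0-based), column `2i+1` is
#' `sin(t / 10000^(2i/h))` and column `2i+2` is `cos(t / 10000^(2i/h))`.
#'
#' @param len Sequence length.
#' @param h Embedding width (even).
#' @return `len x h` matrix.
#' @export
sinusoidal_encoding <- function(len, h) {
  if (h %% 2L != 0L) stop("embedding width must be even")
  t <- 0:(len - 1L)
  i <- 0:(h / 2L - 1L)
  ang <- outer(t, 1 / 10000^(2 * i / h))
  P <- matrix(0, len, h)
  P[, 2L * i + 1L] <- sin(ang)
  P[, 2L * i + 2L] <- cos(ang)
  P
}

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

row_softmax <- function(S) {
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)
  E / rowSums(E)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

## ---- parameter store ------------------------------------------------------

rnorm_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd),
                                               nr, nc)

init_block_params <- function(pe, pf, h, ff) {
  pe[[paste0(pf, ".Wq")]] <- rnorm_mat(h, h)
  pe[[paste0(pf, ".bq")]] <- numeric(h)
  pe[[paste0(pf, ".Wk")]] <- rnorm_mat(h, h)
  pe[[paste0(pf, ".bk")]] <- numeric(h)
  pe[[paste0(pf, ".Wv")]] <- rnorm_mat(h, h)
  pe[[paste0(pf, ".bv")]] <- numeric(h)
  pe[[paste0(pf, ".Wo")]] <- rnorm_mat(h, h)
  pe[[paste0(pf, ".bo")]] <- numeric(h)
  pe[[paste0(pf, ".ln1g")]] <- rep(1, h)
  pe[[paste0(pf, ".ln1b")]] <- numeric(h)
  pe[[paste0(pf, ".W1")]] <- rnorm_mat(h, ff)
  pe[[paste0(pf, ".b1")]] <- numeric(ff)
  pe[[paste0(pf, ".W2")]] <- rnorm_mat(ff, h)
  pe[[paste0(pf, ".b2")]] <- numeric(h)
  pe[[paste0(pf, ".ln2g")]] <- rep(1, h)
  pe[[paste0(pf, ".ln2b")]] <- numeric(h)
}

## ---- layers ---------------------------------------------------------------

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sd
  list(Y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"),
       xhat = xhat, sd = sd)
}

ln_backward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  xhat <- cache$xhat
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

mha_forward <- function(pe, pf, X, causal, nh) {
  h <- ncol(X); L <- nrow(X); dh <- h %/% nh
  Q <- add_bias(X %*% pe[[paste0(pf, ".Wq")]], pe[[paste0(pf, ".bq")]])
  K <- add_bias(X %*% pe[[paste0(pf, ".Wk")]], pe[[paste0(pf, ".bk")]])
  V <- add_bias(X %*% pe[[paste0(pf, ".Wv")]], pe[[paste0(pf, ".bv")]])
  O <- matrix(0, L, h)
  A_list <- vector("list", nh)
  for (k in seq_len(nh)) {
    idx <- (k - 1L) * dh + seq_len(dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    if (causal && L > 1L) S[upper.tri(S)] <- -Inf
    A <- row_softmax(S)
    A_list[[k]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  Y <- add_bias(O %*% pe[[paste0(pf, ".Wo")]], pe[[paste0(pf, ".bo")]])
  list(Y = Y, X = X, Q = Q, K = K, V = V, O = O, A = A_list)
}

mha_backward <- function(pe, pf, cache, dY, nh, g) {
  h <- ncol(cache$X); L <- nrow(cache$X); dh <- h %/% nh
  acc(g, paste0(pf, ".Wo"), t(cache$O) %*% dY)
  acc(g, paste0(pf, ".bo"), colSums(dY))
  dO <- dY %*% t(pe[[paste0(pf, ".Wo")]])
  dQ <- matrix(0, L, h); dK <- matrix(0, L, h); dV <- matrix(0, L, h)
  for (k in seq_len(nh)) {
    idx <- (k - 1L) * dh + seq_len(dh)
    A <- cache$A[[k]]
    dOk <- dO[, idx, drop = FALSE]
    dA <- dOk %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dOk
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dh)
  }
  acc(g, paste0(pf, ".Wq"), t(cache$X) %*% dQ)
  acc(g, paste0(pf, ".bq"), colSums(dQ))
  acc(g, paste0(pf, ".Wk"), t(cache$X) %*% dK)
  acc(g, paste0(pf, ".bk"), colSums(dK))
  acc(g, paste0(pf, ".Wv"), t(cache$X) %*% dV)
  acc(g, paste0(pf, ".bv"), colSums(dV))
  dQ %*% t(pe[[paste0(pf, ".Wq")]]) +
    dK %*% t(pe[[paste0(pf, ".Wk")]]) +
    dV %*% t(pe[[paste0(pf, ".Wv")]])
}

drop_mask <- function(L, h, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(L * h, 1L, 1 - p) / (1 - p), L, h)
}

block_forward <- function(pe, pf, X, causal, nh, dropout) {
  mha <- mha_forward(pe, pf, X, causal, nh)
  m1 <- drop_mask(nrow(X), ncol(X), dropout)
  A_out <- if (is.null(m1)) mha$Y else mha$Y * m1
  ln1 <- ln_forward(X + A_out, pe[[paste0(pf, ".ln1g")]],
                    pe[[paste0(pf, ".ln1b")]])
  H1pre <- add_bias(ln1$Y %*% pe[[paste0(pf, ".W1")]],
                    pe[[paste0(pf, ".b1")]])
  H1 <- pmax(H1pre, 0)
  FF <- add_bias(H1 %*% pe[[paste0(pf, ".W2")]], pe[[paste0(pf, ".b2")]])
  m2 <- drop_mask(nrow(X), ncol(X), dropout)
  F_out <- if (is.null(m2)) FF else FF * m2
  ln2 <- ln_forward(ln1$Y + F_out, pe[[paste0(pf, ".ln2g")]],
                    pe[[paste0(pf, ".ln2b")]])
  list(Y = ln2$Y, mha = mha, m1 = m1, ln1 = ln1, H1 = H1, H1pre = H1pre,
       m2 = m2, ln2 = ln2, X = X)
}

block_backward <- function(pe, pf, cache, dY, causal, nh, g) {
  lb2 <- ln_backward(dY, cache$ln2, pe[[paste0(pf, ".ln2g")]])
  acc(g, paste0(pf, ".ln2g"), lb2$dg)
  acc(g, paste0(pf, ".ln2b"), lb2$db)
  dR2 <- lb2$dX
  dFF <- if (is.null(cache$m2)) dR2 else dR2 * cache$m2
  acc(g, paste0(pf, ".W2"), t(cache$H1) %*% dFF)
  acc(g, paste0(pf, ".b2"), colSums(dFF))
  dH1 <- (dFF %*% t(pe[[paste0(pf, ".W2")]])) * (cache$H1pre > 0)
  acc(g, paste0(pf, ".W1"), t(cache$ln1$Y) %*% dH1)
  acc(g, paste0(pf, ".b1"), colSums(dH1))
  dLn1Y <- dR2 + dH1 %*% t(pe[[paste0(pf, ".W1")]])
  lb1 <- ln_backward(dLn1Y, cache$ln1, pe[[paste0(pf, ".ln1g")]])
  acc(g, paste0(pf, ".ln1g"), lb1$dg)
  acc(g, paste0(pf, ".ln1b"), lb1$db)
  dR1 <- lb1$dX
  dA <- if (is.null(cache$m1)) dR1 else dR1 * cache$m1
  dXmha <- mha_backward(pe, pf, cache$mha, dA, nh, g)
  dR1 + dXmha
}

## ---- gradient accumulator -------------------------------------------------

new_grads <- function() new.env(parent = emptyenv())

acc <- function(g, name, val) {
  if (is.null(g[[name]])) g[[name]] <- val else g[[name]] <- g[[name]] + val
  invisible(NULL)
}

scale_grads <- function(g, f) {
  for (nm in ls(g)) g[[nm]] <- g[[nm]] * f
  invisible(g)
}

merge_grads <- function(g, g2) {
  for (nm in ls(g2)) acc(g, nm, g2[[nm]])
  invisible(g)
}

grad_vector <- function(g) {
  nms <- sort(ls(g))
  unlist(lapply(nms, function(nm) as.numeric(g[[nm]])))
}

## ---- Adam -----------------------------------------------------------------

adam_step <- function(model, g, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- model$opt
  st$t <- (if (is.null(st$t)) 0L else st$t) + 1L
  pe <- model$params
  for (nm in ls(g)) {
    grad <- g[[nm]]
    mkey <- paste0("m.", nm); vkey <- paste0("v.", nm)
    if (is.null(st[[mkey]])) {
      st[[mkey]] <- grad * 0
      st[[vkey]] <- grad * 0
    }
    st[[mkey]] <- beta1 * st[[mkey]] + (1 - beta1) * grad
    st[[vkey]] <- beta2 * st[[vkey]] + (1 - beta2) * grad^2
    mhat <- st[[mkey]] / (1 - beta1^st$t)
    vhat <- st[[vkey]] / (1 - beta2^st$t)
    pe[[nm]] <- pe[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(model)
}
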