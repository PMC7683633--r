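# Minimal neural-network primitives shared by the sequence tagger and the
# role classifier: LSTM forward/backward, log-softmax, Adam, gradient
# clipping.  Everything is plain matrix algebra so runs stay deterministic
# under a fixed seed.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise log-softmax of a matrix of logits
.log_softmax <- function(logits) {
  m <- apply(logits, 2L, max)
  shifted <- sweep(logits, 2L, m)
  sweep(shifted, 2L, log(colSums(exp(shifted))))
}

.softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.uniform_init <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

# ---- LSTM ------------------------------------------------------------------

# X: input matrix (D x n).  W: 4H x D, U: 4H x H, b: 4H.
# Gate order within the 4H block: input, forget, output, candidate.
.lstm_forward <- function(X, W, U, b) {
  H <- ncol(U); n <- ncol(X)
  A <- W %*% X + b
  Hs <- matrix(0, H, n); Cs <- matrix(0, H, n); G <- matrix(0, 4L * H, n)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(n)) {
    a <- A[, t] + U %*% h
    ig <- .sigmoid(a[i1]); fg <- .sigmoid(a[i2])
    og <- .sigmoid(a[i3]); gg <- tanh(a[i4])
    cc <- fg * cc + ig * gg
    h <- og * tanh(cc)
    G[i1, t] <- ig; G[i2, t] <- fg; G[i3, t] <- og; G[i4, t] <- gg
    Cs[, t] <- cc; Hs[, t] <- h
  }
  list(H = Hs, C = Cs, G = G, X = X)
}

# dH: H x n gradient w.r.t. the hidden outputs.  Returns parameter
# gradients and the gradient w.r.t. the inputs.
.lstm_backward <- function(cache, dH, W, U) {
  Hs <- cache$H; Cs <- cache$C; G <- cache$G; X <- cache$X
  H <- nrow(Hs); n <- ncol(Hs)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  dA <- matrix(0, 4L * H, n)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in seq(n, 1L)) {
    dh <- dH[, t] + dh_next
    ig <- G[i1, t]; fg <- G[i2, t]; og <- G[i3, t]; gg <- G[i4, t]
    cc <- Cs[, t]
    cprev <- if (t > 1L) Cs[, t - 1L] else numeric(H)
    tc <- tanh(cc)
    dog <- dh * tc
    dc <- dh * og * (1 - tc^2) + dc_next
    dig <- dc * gg; dgg <- dc * ig; dfg <- dc * cprev
    dc_next <- dc * fg
    da <- c(dig * ig * (1 - ig), dfg * fg * (1 - fg),
            dog * og * (1 - og), dgg * (1 - gg^2))
    dA[, t] <- da
    dh_next <- as.numeric(crossprod(U, da))
  }
  Hprev <- cbind(numeric(H), Hs[, -n, drop = FALSE])
  list(dW = dA %*% t(X), dU = dA %*% t(Hprev), db = rowSums(dA),
       dX = crossprod(W, dA))
}

# ---- optimizer -------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

.zero_like <- function(params) lapply(params, function(p) p * 0)

.add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
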