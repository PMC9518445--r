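## Internal neural-network engine --------------------------------------------
##
## Batched LSTM forward / backward passes, dense layers, softmax with
## class-weighted cross-entropy, and Adam.  Everything is plain matrix
## algebra on [batch x ...] arrays; gradients are exact backpropagation
## through time and are verified against finite differences in the test
## suite.  Gate order within the packed weight matrices is (i, f, g, o):
## input gate, forget gate, candidate (tanh) input, output gate.  The cell
## update is s_t = f*s_{t-1} + i*g and the output h_t = o * tanh(s_t).

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_lstm_weights <- function(input_dim, H) {
  b <- numeric(4 * H)
  b[H + seq_len(H)] <- 1            # forget-gate bias 1: remember by default
  list(Wx = glorot(input_dim, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

init_dense_weights <- function(input_dim, units) {
  list(W = glorot(input_dim, units), b = numeric(units))
}

## X [N,T,In] -> list(H_seq [N,T,H], cache).  The input projection X * Wx is
## computed for all time steps in one matrix product; only the recurrence
## h_{t-1} * Wh runs step by step.
lstm_forward <- function(X, W) {
  N <- dim(X)[1]; T_ <- dim(X)[2]
  H <- nrow(W$Wh)
  h <- matrix(0, N, H); s <- matrix(0, N, H)
  H_seq <- array(0, dim = c(N, T_, H))
  cache <- vector("list", T_)
  Zx <- matrix(X, N * T_) %*% W$Wx      # rows indexed (n, t) column-major
  Zx <- sweep(Zx, 2, W$b, "+")
  for (t in seq_len(T_)) {
    rows <- (t - 1L) * N + seq_len(N)
    z <- Zx[rows, , drop = FALSE] + h %*% W$Wh
    ig <- sigmoid(z[, seq_len(H), drop = FALSE])
    fg <- sigmoid(z[, H + seq_len(H), drop = FALSE])
    gg <- tanh(z[, 2 * H + seq_len(H), drop = FALSE])
    og <- sigmoid(z[, 3 * H + seq_len(H), drop = FALSE])
    s_new <- fg * s + ig * gg
    ts <- tanh(s_new)
    cache[[t]] <- list(i = ig, f = fg, g = gg, o = og,
                       s_prev = s, ts = ts, h_prev = h)
    h <- og * ts
    s <- s_new
    H_seq[, t, ] <- h
  }
  list(H_seq = H_seq, cache = cache)
}

## dH [N,T,H] gradient wrt every h_t (zero where unused)
lstm_backward <- function(X, W, cache, dH) {
  N <- dim(X)[1]; T_ <- dim(X)[2]
  H <- nrow(W$Wh)
  dZ <- array(0, dim = c(N, T_, 4 * H))
  Hprev <- array(0, dim = c(N, T_, H))
  dh_next <- matrix(0, N, H); ds_next <- matrix(0, N, H)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- matrix(dH[, t, ], nrow = N) + dh_next
    do_ <- dh * cc$ts
    ds <- dh * cc$o * (1 - cc$ts^2) + ds_next
    di <- ds * cc$g
    dg <- ds * cc$i
    df <- ds * cc$s_prev
    ds_next <- ds * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dZ[, t, ] <- dz
    Hprev[, t, ] <- cc$h_prev
    dh_next <- dz %*% t(W$Wh)
  }
  dZm <- matrix(dZ, N * T_)
  dX <- array(dZm %*% t(W$Wx), dim = dim(X))
  list(dWx = crossprod(matrix(X, N * T_), dZm),
       dWh = crossprod(matrix(Hprev, N * T_), dZm),
       db = colSums(dZm), dX = dX)
}

rev_time <- function(X) {
  X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
}

## One (bi)directional recurrent layer.
## Returns $out: [N, T, width] if return_sequences else [N, width],
## width = H or 2H.  Backward-direction outputs are re-aligned to input time.
rnn_layer_forward <- function(X, Wf, Wb, return_sequences) {
  fw <- lstm_forward(X, Wf)
  if (is.null(Wb)) {
    out <- if (return_sequences) fw$H_seq
           else matrix(fw$H_seq[, dim(X)[2], ], nrow = dim(X)[1])
    return(list(out = out, fw = fw, bw = NULL))
  }
  Xr <- rev_time(X)
  bw <- lstm_forward(Xr, Wb)
  T_ <- dim(X)[2]
  if (return_sequences) {
    N <- dim(X)[1]; H <- nrow(Wf$Wh)
    out <- array(0, dim = c(N, T_, 2 * H))
    out[, , seq_len(H)] <- fw$H_seq
    out[, , H + seq_len(H)] <- rev_time(bw$H_seq)
  } else {
    out <- cbind(matrix(fw$H_seq[, T_, ], nrow = dim(X)[1]),
                 matrix(bw$H_seq[, T_, ], nrow = dim(X)[1]))
  }
  list(out = out, fw = fw, bw = bw)
}

## dOut matches $out's shape; returns dX plus weight grads for both directions
rnn_layer_backward <- function(X, Wf, Wb, fwbw, dOut, return_sequences) {
  N <- dim(X)[1]; T_ <- dim(X)[2]; H <- nrow(Wf$Wh)
  if (is.null(Wb)) {
    dH <- array(0, dim = c(N, T_, H))
    if (return_sequences) dH[] <- dOut else dH[, T_, ] <- dOut
    g <- lstm_backward(X, Wf, fwbw$fw$cache, dH)
    return(list(fwd = g[c("dWx", "dWh", "db")], bwd = NULL, dX = g$dX))
  }
  dHf <- array(0, dim = c(N, T_, H))
  dHb <- array(0, dim = c(N, T_, H))       # in *reversed* time
  if (return_sequences) {
    dHf[] <- dOut[, , seq_len(H), drop = FALSE]
    dHb[] <- rev_time(dOut[, , H + seq_len(H), drop = FALSE])
  } else {
    dHf[, T_, ] <- dOut[, seq_len(H), drop = FALSE]
    dHb[, T_, ] <- dOut[, H + seq_len(H), drop = FALSE]
  }
  gf <- lstm_backward(X, Wf, fwbw$fw$cache, dHf)
  gb <- lstm_backward(rev_time(X), Wb, fwbw$bw$cache, dHb)
  list(fwd = gf[c("dWx", "dWh", "db")], bwd = gb[c("dWx", "dWh", "db")],
       dX = gf$dX + rev_time(gb$dX))
}

activate <- function(z, act) {
  switch(act,
         tanh = tanh(z),
         sigmoid = sigmoid(z),
         relu = pmax(z, 0),
         selu = {
           l <- 1.0507009873554805; a <- 1.6732632423543772
           ifelse(z > 0, l * z, l * a * (exp(z) - 1))
         },
         stopf("unknown activation '%s'", act))
}

activate_grad <- function(z, a, act) {
  switch(act,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         relu = (z > 0) * 1,
         selu = {
           l <- 1.0507009873554805; al <- 1.6732632423543772
           ifelse(z > 0, l, l * al * exp(z))
         })
}

dense_forward <- function(X, W, act) {
  z <- X %*% W$W + matrix(W$b, nrow(X), length(W$b), byrow = TRUE)
  list(a = activate(z, act), z = z)
}

dense_backward <- function(X, W, cache, dA, act) {
  dz <- dA * activate_grad(cache$z, cache$a, act)
  list(dW = crossprod(X, dz), db = colSums(dz), dX = dz %*% t(W$W))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Inverted dropout mask (scales kept units by 1/(1-rate))
dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

## Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
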