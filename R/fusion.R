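## The fusion classifier ------------------------------------------------------
##
## Per-channel recurrent branches -> feature concatenation -> optional dense
## layers -> 2-unit softmax.  cap_fusion() is the fitting function; the
## returned object carries the weights, the architecture and the training
## trace and answers to the usual modelling generics.

param_prefixes <- function(config) {
  n <- sum(config$channels)
  dirs <- if (config$bidirectional) c("fwd", "bwd") else "fwd"
  out <- list()
  for (k in seq_len(n)) {
    for (l in seq_len(config$n_layers)) {
      for (d in dirs) out[[length(out) + 1L]] <-
          list(kind = "lstm", key = sprintf("br%d.l%d.%s", k, l, d),
               branch = k, layer = l, dir = d)
    }
    if (config$dense > 0) out[[length(out) + 1L]] <-
        list(kind = "dense", key = sprintf("br%d.dense", k), branch = k)
  }
  if (config$dense > 0) out[[length(out) + 1L]] <- list(kind = "dense", key = "fusion.dense")
  out[[length(out) + 1L]] <- list(kind = "dense", key = "out")
  out
}

branch_width <- function(config) {
  (if (config$bidirectional) 2L else 1L) * config$hidden
}

build_fusion_weights <- function(config, input_points = 100L, seed = NULL) {
  with_seed(seed, {
    H <- config$hidden; S <- config$dense
    n <- sum(config$channels)
    bw <- branch_width(config)
    params <- list()
    put <- function(key, w) for (nm in names(w))
      params[[paste(key, nm, sep = ".")]] <<- w[[nm]]
    for (spec in param_prefixes(config)) {
      if (spec$kind == "lstm") {
        in_dim <- if (spec$layer == 1) input_points else bw
        put(spec$key, init_lstm_weights(in_dim, H))
      } else if (spec$key == "out") {
        out_in <- if (S > 0) S else n * bw
        put("out", init_dense_weights(out_in, 2L))
      } else if (spec$key == "fusion.dense") {
        put("fusion.dense", init_dense_weights(n * S, S))
      } else {
        put(spec$key, init_dense_weights(bw, S))
      }
    }
    params
  })
}

get_lstm <- function(params, key) {
  w <- list(Wx = params[[paste0(key, ".Wx")]],
            Wh = params[[paste0(key, ".Wh")]],
            b = params[[paste0(key, ".b")]])
  if (is.null(w$Wx)) NULL else w
}

get_dense <- function(params, key) {
  list(W = params[[paste0(key, ".W")]], b = params[[paste0(key, ".b")]])
}

## xs: list of [N,T,I] arrays, one per *selected* channel.
## train = TRUE draws fresh dropout masks from the current RNG.
forward_fusion <- function(params, config, xs, train = FALSE) {
  n <- length(xs)
  S <- config$dense
  rate <- if (train) config$dropout else 0
  branches <- vector("list", n)
  feats <- vector("list", n)
  for (k in seq_len(n)) {
    X <- xs[[k]]
    st <- list()
    Wf1 <- get_lstm(params, sprintf("br%d.l1.fwd", k))
    Wb1 <- get_lstm(params, sprintf("br%d.l1.bwd", k))
    two <- config$n_layers == 2
    st$r1 <- rnn_layer_forward(X, Wf1, Wb1, return_sequences = two)
    if (two) {
      st$m_seq <- dropout_mask(dim(st$r1$out), rate)
      st$seq_in <- apply_mask(st$r1$out, st$m_seq)
      Wf2 <- get_lstm(params, sprintf("br%d.l2.fwd", k))
      Wb2 <- get_lstm(params, sprintf("br%d.l2.bwd", k))
      st$r2 <- rnn_layer_forward(st$seq_in, Wf2, Wb2, return_sequences = FALSE)
      h <- st$r2$out
    } else h <- st$r1$out
    st$m_h <- dropout_mask(dim(h), rate)
    st$h <- apply_mask(h, st$m_h)
    if (S > 0) {
      Wd <- get_dense(params, sprintf("br%d.dense", k))
      st$d <- dense_forward(st$h, Wd, config$activation)
      st$m_d <- dropout_mask(dim(st$d$a), rate)
      feats[[k]] <- apply_mask(st$d$a, st$m_d)
    } else feats[[k]] <- st$h
    branches[[k]] <- st
  }
  f <- do.call(cbind, feats)
  fus <- NULL; m_f <- NULL
  out_in <- f
  if (S > 0) {
    fus <- dense_forward(f, get_dense(params, "fusion.dense"), config$activation)
    m_f <- dropout_mask(dim(fus$a), rate)
    out_in <- apply_mask(fus$a, m_f)
  }
  Wo <- get_dense(params, "out")
  logits <- out_in %*% Wo$W + matrix(Wo$b, nrow(out_in), 2, byrow = TRUE)
  prob <- softmax_rows(logits)
  list(prob = prob, logits = logits,
       cache = list(branches = branches, feats = feats, f = f, fus = fus,
                    m_f = m_f, out_in = out_in))
}

## dlogits [N,2] -> named gradient list matching params
backward_fusion <- function(params, config, xs, fwd, dlogits) {
  grads <- lapply(params, function(p) p * 0)
  cc <- fwd$cache
  S <- config$dense
  n <- length(xs)
  Wo <- get_dense(params, "out")
  grads[["out.W"]] <- crossprod(cc$out_in, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  d_out_in <- dlogits %*% t(Wo$W)
  if (S > 0) {
    d_fus_a <- apply_mask(d_out_in, cc$m_f)
    g <- dense_backward(cc$f, get_dense(params, "fusion.dense"), cc$fus,
                        d_fus_a, config$activation)
    grads[["fusion.dense.W"]] <- g$dW
    grads[["fusion.dense.b"]] <- g$db
    dF <- g$dX
  } else dF <- d_out_in
  widths <- vapply(cc$feats, ncol, 1L)
  offs <- cumsum(c(0L, widths))
  for (k in seq_len(n)) {
    st <- cc$branches[[k]]
    dfk <- dF[, offs[k] + seq_len(widths[k]), drop = FALSE]
    if (S > 0) {
      dda <- apply_mask(dfk, st$m_d)
      g <- dense_backward(st$h, get_dense(params, sprintf("br%d.dense", k)),
                          st$d, dda, config$activation)
      grads[[sprintf("br%d.dense.W", k)]] <- g$dW
      grads[[sprintf("br%d.dense.b", k)]] <- g$db
      dh <- g$dX
    } else dh <- dfk
    dh <- apply_mask(dh, st$m_h)
    two <- config$n_layers == 2
    if (two) {
      g2 <- rnn_layer_backward(st$seq_in,
                               get_lstm(params, sprintf("br%d.l2.fwd", k)),
                               get_lstm(params, sprintf("br%d.l2.bwd", k)),
                               st$r2, dh, return_sequences = FALSE)
      grads <- store_lstm_grads(grads, sprintf("br%d.l2", k), g2)
      dseq <- apply_mask(g2$dX, st$m_seq)
      g1 <- rnn_layer_backward(xs[[k]],
                               get_lstm(params, sprintf("br%d.l1.fwd", k)),
                               get_lstm(params, sprintf("br%d.l1.bwd", k)),
                               st$r1, dseq, return_sequences = TRUE)
    } else {
      g1 <- rnn_layer_backward(xs[[k]],
                               get_lstm(params, sprintf("br%d.l1.fwd", k)),
                               get_lstm(params, sprintf("br%d.l1.bwd", k)),
                               st$r1, dh, return_sequences = FALSE)
    }
    grads <- store_lstm_grads(grads, sprintf("br%d.l1", k), g1)
  }
  grads
}

store_lstm_grads <- function(grads, key, g) {
  grads[[paste0(key, ".fwd.Wx")]] <- g$fwd$dWx
  grads[[paste0(key, ".fwd.Wh")]] <- g$fwd$dWh
  grads[[paste0(key, ".fwd.b")]] <- g$fwd$db
  if (!is.null(g$bwd)) {
    grads[[paste0(key, ".bwd.Wx")]] <- g$bwd$dWx
    grads[[paste0(key, ".bwd.Wh")]] <- g$bwd$dWh
    grads[[paste0(key, ".bwd.b")]] <- g$bwd$db
  }
  grads
}

## class-weighted cross-entropy; y in {0,1}; returns loss and dlogits
weighted_ce <- function(prob, y, w) {
  N <- length(y)
  p_true <- prob[cbind(seq_len(N), y + 1L)]
  wi <- w[y + 1L]
  loss <- -mean(wi * log(pmax(p_true, 1e-12)))
  Y <- matrix(0, N, 2)
  Y[cbind(seq_len(N), y + 1L)] <- 1
  dlogits <- (prob - Y) * wi / N
  list(loss = loss, dlogits = dlogits)
}

#' Inverse-frequency class weights for cost-sensitive training
#'
#' CAP data are heavily imbalanced (often >80% of seconds are not-A);
#' instead of resampling, training weights each class by
#' `N_total / (2 * N_class)`, so balanced data get unit weights.
#'
#' @param labels Binary vector with both classes present.
#' @return Numeric length-2 vector `c(weight_class0, weight_class1)`.
#' @export
#' @examples
#' compute_class_weights(c(rep(0, 80), rep(1, 20)))  # 0.625 2.5
compute_class_weights <- function(labels) {
  n <- c(sum(labels == 0), sum(labels == 1))
  if (any(n == 0)) stopf("both classes must be present to compute class weights")
  length(labels) / (2 * n)
}

#' Training control parameters
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 1024).
#' @param epochs Maximum training epochs (default 30; no early stopping).
#' @param class_weights Length-2 weights for classes (0, 1); `NULL` computes
#'   inverse-frequency weights from the training labels.
#' @param seed Integer seed controlling initialization, batch shuffling and
#'   dropout.
#' @param verbose Print per-epoch loss?
#' @return A `cap_control` list.
#' @export
cap_control <- function(learning_rate = 0.001, batch_size = 1024,
                        epochs = 30, class_weights = NULL, seed = 1L,
                        verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), class_weights = class_weights,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "cap_control")
}

select_xs <- function(windows, config) {
  windows$x[config$channels]
}

#' Fit the multichannel fusion classifier
#'
#' Trains the per-channel recurrent fusion network on epoch windows by
#' mini-batch Adam on the class-weighted cross-entropy of the softmax
#' output. Weights start from a cold (random) initialization drawn from
#' `control$seed`; there is no early stopping.
#'
#' @param windows A `cap_windows` object (see [make_windows()],
#'   [bind_windows()]) containing both classes.
#' @param config A [cap_config()] describing the architecture.
#' @param control A [cap_control()] with the training hyperparameters.
#' @return An object of class `cap_fusion` with elements `params` (weights),
#'   `config`, `control`, `class_weights`, `loss` (per-epoch mean training
#'   loss), `n_parameters`.
#' @seealso [predict.cap_fusion()], [select_threshold()]
#' @export
#' @examples
#' p <- cap_sim_params(duration_s = 60, seed = 3)
#' w <- make_windows(preprocess_recording(generate_recording(p, 1)), 2)
#' fit <- cap_fusion(w, cap_config(hidden = 4, time_steps = 2),
#'                   cap_control(epochs = 2))
#' fit
cap_fusion <- function(windows, config = cap_config(),
                       control = cap_control()) {
  stopifnot(inherits(windows, "cap_windows"), inherits(config, "cap_config"))
  if (length(windows$y) == 0) stopf("cannot train on an empty window set")
  if (windows$time_steps != config$time_steps)
    stopf("windows were cut with T = %d but config$time_steps = %d",
          windows$time_steps, config$time_steps)
  y <- as.integer(windows$y)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  w <- control$class_weights
  if (is.null(w)) w <- compute_class_weights(y)
  xs <- select_xs(windows, config)
  N <- length(y)
  with_seed(control$seed, {
    params <- build_fusion_weights(config, windows$input_points, seed = NULL)
    state <- adam_init(params)
    losses <- numeric(control$epochs)
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1, N, by = control$batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + control$batch_size - 1L, N)]
        xb <- lapply(xs, function(a) a[idx, , , drop = FALSE])
        fwd <- forward_fusion(params, config, xb, train = TRUE)
        lo <- weighted_ce(fwd$prob, y[idx], w)
        grads <- backward_fusion(params, config, xb, fwd, lo$dlogits)
        st <- adam_step(params, grads, state, control$learning_rate)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + lo$loss * length(idx)
      }
      losses[ep] <- ep_loss / N
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.5f", ep, losses[ep]))
    }
    structure(list(params = params, config = config, control = control,
                   class_weights = w, loss = losses,
                   n_parameters = n_parameters_weights(params),
                   input_points = windows$input_points),
              class = "cap_fusion")
  })
}

#' Build an untrained fusion model
#'
#' Wires the network from a configuration and randomly initializes the
#' weights (cold start) without training; useful for parameter counting,
#' architecture inspection and as the starting point of [cap_fusion()].
#'
#' @param config A [cap_config()].
#' @param input_points Samples per time step (100 at 100 Hz and 1-s epochs).
#' @param seed Integer seed for the random initialization.
#' @return An (untrained) `cap_fusion` object.
#' @export
#' @examples
#' m <- build_fusion(reference_config("ga"))
#' m$n_parameters  # 934202
build_fusion <- function(config, input_points = 100L, seed = 1L) {
  params <- build_fusion_weights(config, input_points, seed = seed)
  structure(list(params = params, config = config, control = NULL,
                 class_weights = c(1, 1), loss = numeric(0),
                 n_parameters = n_parameters_weights(params),
                 input_points = as.integer(input_points)),
            class = "cap_fusion")
}

n_parameters_weights <- function(params) {
  sum(vapply(params, length, 1L))
}

#' Count trainable parameters
#'
#' `n_parameters()` sums the sizes of every weight tensor of a built model;
#' `parameter_count()` evaluates the closed-form expression from the
#' architecture alone. The two must agree for every configuration (this is
#' asserted in the test suite across the whole search space by sampling).
#'
#' @param model A `cap_fusion` object.
#' @return Integer number of trainable scalars.
#' @export
#' @examples
#' parameter_count(reference_config("pso"))  # 723602
n_parameters <- function(model) {
  stopifnot(inherits(model, "cap_fusion"))
  model$n_parameters
}

#' @rdname n_parameters
#' @param config A [cap_config()].
#' @param input_points Samples per time step.
#' @export
parameter_count <- function(config, input_points = 100L) {
  H <- config$hidden; S <- config$dense
  n <- sum(config$channels)
  dir <- if (config$bidirectional) 2L else 1L
  bw <- dir * H
  lstm1 <- dir * 4 * (H * (input_points + H) + H)
  lstm2 <- if (config$n_layers == 2) dir * 4 * (H * (bw + H) + H) else 0
  dense <- if (S > 0) n * (bw + 1) * S + (n * S + 1) * S else 0
  out_in <- if (S > 0) S else n * bw
  n * (lstm1 + lstm2) + dense + (out_in + 1) * 2
}

#' The architectures selected by the two optimizers
#'
#' Convenience constructors for the two published optima of the search:
#' both use all three channels and a single BLSTM layer of 100 units per
#' direction; the GA pick uses T = 10, 15% dropout and 300-unit sigmoid
#' dense layers, the PSO pick T = 25, 5% dropout and 200-unit ReLU dense
#' layers.
#'
#' @param which `"ga"` or `"pso"`.
#' @return A [cap_config()].
#' @export
reference_config <- function(which = c("ga", "pso")) {
  which <- match.arg(which)
  if (which == "ga")
    cap_config(channels = c(TRUE, TRUE, TRUE), time_steps = 10, n_layers = 1,
               bidirectional = TRUE, hidden = 100, dropout = 0.15,
               dense = 300, activation = "sigmoid")
  else
    cap_config(channels = c(TRUE, TRUE, TRUE), time_steps = 25, n_layers = 1,
               bidirectional = TRUE, hidden = 100, dropout = 0.05,
               dense = 200, activation = "relu")
}

#' Predict A-phase scores or classes
#'
#' Runs the forward pass without dropout. Scores are the softmax probability
#' of the positive ("A") class; classes threshold the score.
#'
#' @param object A fitted `cap_fusion`.
#' @param newdata A `cap_windows` object.
#' @param type `"score"` for probabilities, `"class"` for 0/1 labels.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric vector of scores, or integer 0/1 vector.
#' @export
predict.cap_fusion <- function(object, newdata, type = c("score", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "cap_windows"))
  if (newdata$time_steps != object$config$time_steps)
    stopf("newdata windows have T = %d, model expects %d",
          newdata$time_steps, object$config$time_steps)
  xs <- select_xs(newdata, object$config)
  n <- length(newdata$y)
  if (n == 0) return(numeric(0))
  # chunk to bound memory on long recordings
  scores <- numeric(n)
  for (s0 in seq(1, n, by = 4096)) {
    idx <- s0:min(s0 + 4095, n)
    xb <- lapply(xs, function(a) a[idx, , , drop = FALSE])
    scores[idx] <- forward_fusion(object$params, object$config, xb)$prob[, 2]
  }
  if (type == "score") scores else as.integer(scores >= threshold)
}

#' ROC-optimal decision threshold (Youden's J)
#'
#' Scans the ROC operating points of the training scores and returns the
#' threshold maximizing `J = Sen + Spe - 1`, the standard reading of the
#' "optimal cut-off point" of the training ROC curve. Candidate thresholds
#' are midpoints between consecutive distinct scores (plus both extremes).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels with both classes present.
#' @return The selected threshold (classify as positive when
#'   `score >= threshold`).
#' @export
#' @examples
#' select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 0.5
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stopf("threshold selection needs both classes in the labels")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  j <- vapply(cand, function(th) {
    sen <- sum(scores >= th & labels == 1) / npos
    spe <- sum(scores < th & labels == 0) / nneg
    sen + spe - 1
  }, 0)
  cand[which.max(j)]
}

## S3 methods -----------------------------------------------------------------

#' @export
print.cap_fusion <- function(x, ...) {
  cat(sprintf("cap_fusion: %d-channel %s fusion classifier, %s parameters%s\n",
              sum(x$config$channels),
              if (x$config$bidirectional) "BLSTM" else "LSTM",
              format(x$n_parameters, big.mark = ","),
              if (length(x$loss)) sprintf(", trained %d epoch(s), final loss %.4f",
                                          length(x$loss), x$loss[length(x$loss)])
              else " (untrained)"))
  invisible(x)
}

#' @export
summary.cap_fusion <- function(object, ...) {
  print(object$config)
  cat(sprintf("  trainable parameters: %s (closed form %s)\n",
              format(object$n_parameters, big.mark = ","),
              format(parameter_count(object$config, object$input_points),
                     big.mark = ",")))
  cat(sprintf("  class weights: %.4g / %.4g\n",
              object$class_weights[1], object$class_weights[2]))
  if (length(object$loss))
    cat(sprintf("  training loss: %.4f -> %.4f over %d epochs\n",
                object$loss[1], object$loss[length(object$loss)],
                length(object$loss)))
  invisible(object)
}

#' @export
coef.cap_fusion <- function(object, ...) object$params

#' @export
plot.cap_fusion <- function(x, ...) {
  if (!length(x$loss)) stopf("model has no training trace to plot")
  plot(seq_along(x$loss), x$loss, type = "b", xlab = "epoch",
       ylab = "weighted cross-entropy", main = "cap_fusion training loss", ...)
  invisible(x)
}

#' @export
residuals.cap_fusion <- function(object, newdata, ...) {
  newdata$y - predict(object, newdata)
}

#' Simulate labels from the fitted class probabilities
#'
#' @param object A fitted `cap_fusion`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param newdata A `cap_windows` object to score.
#' @param ... Unused.
#' @return A matrix `length(newdata$y) x nsim` of Bernoulli draws.
#' @export
simulate.cap_fusion <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  p <- predict(object, newdata)
  with_seed(seed, {
    matrix(stats::rbinom(length(p) * nsim, 1, rep(p, nsim)), ncol = nsim)
  })
}
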