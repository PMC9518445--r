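test_that("backpropagation matches finite differences across architectures", {
  cfgs <- list(
    cap_config(channels = c(TRUE, FALSE, FALSE), time_steps = 2, n_layers = 1,
               bidirectional = FALSE, hidden = 3, dense = 0),
    cap_config(channels = c(TRUE, TRUE, TRUE), time_steps = 3, n_layers = 1,
               bidirectional = TRUE, hidden = 3, dense = 5,
               activation = "sigmoid"),
    cap_config(channels = c(TRUE, FALSE, TRUE), time_steps = 3, n_layers = 2,
               bidirectional = TRUE, hidden = 2, dense = 4,
               activation = "selu"),
    cap_config(channels = c(FALSE, TRUE, FALSE), time_steps = 2, n_layers = 2,
               bidirectional = FALSE, hidden = 3, dense = 3,
               activation = "relu"),
    cap_config(channels = c(TRUE, TRUE, FALSE), time_steps = 4, n_layers = 1,
               bidirectional = TRUE, hidden = 2, dense = 4,
               activation = "tanh"))
  for (cfg in cfgs) {
    set.seed(3)
    N <- 4; I <- 6
    xs <- lapply(seq_len(sum(cfg$channels)), function(k)
      array(rnorm(N * cfg$time_steps * I), dim = c(N, cfg$time_steps, I)))
    y <- c(0, 1, 1, 0); w <- c(0.8, 1.7)
    params <- capfuse:::build_fusion_weights(cfg, input_points = I, seed = 3)
    # jitter off exact-zero pre-activations so ReLU kinks cannot collide
    # with the symmetric difference quotient
    params <- lapply(params, function(p) p + rnorm(length(p), 0, 0.05))
    lossfun <- function(pp)
      capfuse:::weighted_ce(capfuse:::forward_fusion(pp, cfg, xs)$prob, y, w)$loss
    fwd <- capfuse:::forward_fusion(params, cfg, xs)
    lo <- capfuse:::weighted_ce(fwd$prob, y, w)
    gr <- capfuse:::backward_fusion(params, cfg, xs, fwd, lo$dlogits)
    for (nm in names(params)) {
      for (i in sample.int(length(params[[nm]]), min(4, length(params[[nm]])))) {
        eps <- 1e-5
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
        expect_lt(abs(num - gr[[nm]][i]) / max(1e-6, abs(num) + abs(gr[[nm]][i])),
                  1e-4)
      }
    }
  }
})

test_that("parameter counter and closed form agree across the search space", {
  # the two published optima at full input resolution
  for (which in c("ga", "pso")) {
    cfg <- reference_config(which)
    m <- build_fusion(cfg, input_points = 100)
    expect_equal(n_parameters(m), parameter_count(cfg, 100))
  }
  # wiring examples
  expect_equal(parameter_count(
    cap_config(channels = c(TRUE, FALSE, FALSE), time_steps = 5, n_layers = 1,
               bidirectional = FALSE, hidden = 100, dense = 0), 100),
    4 * (100 * 200 + 100) + 101 * 2)  # 80,602
  # 100+ random genome configurations at a smaller input width
  set.seed(11)
  for (k in 1:100) {
    cfg <- decode_genome(random_genome())
    m <- build_fusion(cfg, input_points = 7, seed = k)
    expect_equal(n_parameters(m), parameter_count(cfg, 7))
  }
})

test_that("branch widths follow the uni/bidirectional wiring contract", {
  cfg1 <- cap_config(channels = c(TRUE, FALSE, FALSE), time_steps = 2,
                     bidirectional = FALSE, hidden = 5, dense = 0)
  m1 <- build_fusion(cfg1, input_points = 8)
  expect_equal(dim(m1$params[["out.W"]]), c(5, 2))     # width H to softmax
  cfg2 <- cap_config(channels = c(TRUE, FALSE, FALSE), time_steps = 2,
                     bidirectional = TRUE, hidden = 5, dense = 0)
  m2 <- build_fusion(cfg2, input_points = 8)
  expect_equal(dim(m2$params[["out.W"]]), c(10, 2))    # width 2H
})

test_that("class weights implement N/(2*Nc) with its symmetry", {
  expect_equal(compute_class_weights(rep(0:1, 50)), c(1, 1))
  expect_equal(compute_class_weights(c(rep(0, 80), rep(1, 20))), c(0.625, 2.5))
  expect_error(compute_class_weights(rep(1, 10)), "both classes")

  # all-majority and all-minority constant predictors have equal weighted loss
  y <- c(rep(0L, 75), rep(1L, 25))
  w <- compute_class_weights(y)
  pmaj <- cbind(rep(0.99, 100), rep(0.01, 100))
  pmin <- cbind(rep(0.01, 100), rep(0.99, 100))
  expect_equal(capfuse:::weighted_ce(pmaj, y, w)$loss,
               capfuse:::weighted_ce(pmin, y, w)$loss, tolerance = 1e-12)
  # scaling the weights scales the gradient by the same constant
  g1 <- capfuse:::weighted_ce(pmaj, y, w)$dlogits
  g2 <- capfuse:::weighted_ce(pmaj, y, 3 * w)$dlogits
  expect_equal(g2, 3 * g1, tolerance = 1e-12)
})

test_that("training is deterministic and learns a separable problem", {
  w <- tiny_windows(2, seed = 5, duration_s = 240)
  cfg <- cap_config(hidden = 8, time_steps = 2)
  fit1 <- tiny_model()
  fit2 <- cap_fusion(w, cfg, cap_control(epochs = 12, seed = 2))
  expect_identical(fit1$loss, fit2$loss)               # same seed, same trace
  expect_lt(fit2$loss[12], fit2$loss[1])               # loss decreases
  expect_gt(roc_auc(predict(fit1, w), w$y), 0.95)      # training AUC

  fit3 <- cap_fusion(w, cfg, cap_control(epochs = 2, seed = 99))
  expect_false(identical(fit1$loss[1:2], fit3$loss))   # cold start differs

  expect_error(cap_fusion(capfuse:::empty_windows(2), cfg), "empty")
})

test_that("predictions are calibrated softmax scores", {
  w <- tiny_windows(2, seed = 5, duration_s = 240)
  m <- tiny_model()
  xs <- capfuse:::select_xs(w, m$config)
  prob <- capfuse:::forward_fusion(m$params, m$config, xs)$prob
  expect_true(all(abs(rowSums(prob) - 1) < 1e-6))
  s <- predict(m, w)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(as.integer(apply(prob, 1, which.max) == 2),
               predict(m, w, type = "class", threshold = 0.5))
  # untrained symmetric-ish initialization scores near 1/2 on average
  m0 <- build_fusion(cap_config(hidden = 8, time_steps = 2), seed = 7)
  expect_lt(abs(mean(predict(m0, w)) - 0.5), 0.1)
})

test_that("Youden threshold selection matches an exhaustive scan", {
  thr <- select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  expect_error(select_threshold(runif(5), rep(1, 5)), "both classes")

  set.seed(21)
  for (k in 1:20) {
    n <- 40
    scores <- round(runif(n), 2)             # ties included
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    thr <- select_threshold(scores, labels)
    sen <- sum(scores >= thr & labels == 1) / sum(labels == 1)
    spe <- sum(scores < thr & labels == 0) / sum(labels == 0)
    expect_equal(sen + spe - 1, youden_oracle(scores, labels), tolerance = 1e-12)
  }

  # independent labels: optimal J stays near zero
  set.seed(22)
  scores <- runif(3000); labels <- rbinom(3000, 1, 0.3)
  thr <- select_threshold(scores, labels)
  sen <- sum(scores >= thr & labels == 1) / sum(labels == 1)
  spe <- sum(scores < thr & labels == 0) / sum(labels == 0)
  expect_lt(sen + spe - 1, 0.12)
})

test_that("model generics print, summarise, simulate and residualise", {
  m <- tiny_model()
  w <- tiny_windows(2, seed = 5, duration_s = 240)
  expect_output(print(m), "fusion classifier")
  expect_output(summary(m), "trainable parameters")
  expect_named(coef(m)["out.W"], "out.W")
  r <- residuals(m, w)
  expect_equal(r, w$y - predict(m, w))
  sim <- simulate(m, nsim = 2, seed = 1, newdata = w)
  expect_equal(dim(sim), c(length(w$y), 2))
  expect_identical(sim, simulate(m, nsim = 2, seed = 1, newdata = w))
})
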