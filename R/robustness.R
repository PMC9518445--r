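## Robustness protocols: channel loss and additive white Gaussian noise ------
##
## Both protocols perturb the *test* inputs only: models are trained with
## all channels and clean signals, then evaluated on substituted or noisy
## channels.

#' Build a channel-loss scenario
#'
#' @param lost Integer channel indices (1-3) that failed; must leave at
#'   least one working channel.
#' @param replacement Named assignment: for each lost channel, the working
#'   channel whose signal substitutes it. With one working channel all lost
#'   channels map to it.
#' @return A `cap_scenario` list.
#' @export
channel_loss_scenario <- function(lost = integer(0), replacement = NULL) {
  lost <- as.integer(lost)
  working <- setdiff(1:3, lost)
  if (!length(working)) stopf("at least one channel must remain working")
  if (length(lost)) {
    if (is.null(replacement)) {
      if (length(working) > 1)
        stopf("replacement assignment required when several channels work")
      replacement <- stats::setNames(rep(working, length(lost)), lost)
    }
    replacement <- stats::setNames(as.integer(replacement),
                                   names(replacement))
    if (!all(as.integer(names(replacement)) %in% lost) ||
        !all(replacement %in% working))
      stopf("replacement must map each lost channel to a working channel")
  } else replacement <- stats::setNames(integer(0), character(0))
  structure(list(kind = "channel_loss", lost = lost, working = working,
                 replacement = replacement),
            class = "cap_scenario")
}

#' @export
print.cap_scenario <- function(x, ...) {
  if (x$kind == "channel_loss") {
    if (!length(x$lost)) cat("scenario: all channels working\n")
    else cat(sprintf("scenario: lost {%s}, substitutions %s\n",
                     paste(CAP_CHANNELS[x$lost], collapse = ", "),
                     paste(sprintf("%s<-%s", CAP_CHANNELS[as.integer(names(x$replacement))],
                                   CAP_CHANNELS[x$replacement]), collapse = ", ")))
  } else cat(sprintf("scenario: AWGN at %g dB SNR\n", x$snr_db))
  invisible(x)
}

#' Substitute lost channels by working ones
#'
#' Each lost channel's signal is replaced verbatim by the assigned working
#' channel's signal; working channels and labels are untouched. With two
#' lost channels all three model inputs end up carrying the surviving
#' channel's signal.
#'
#' @param rec A `cap_recording`.
#' @param scenario A [channel_loss_scenario()].
#' @return The perturbed recording.
#' @export
apply_channel_loss <- function(rec, scenario) {
  stopifnot(inherits(scenario, "cap_scenario"), scenario$kind == "channel_loss")
  if (!length(scenario$lost)) return(rec)
  src <- rec$signals
  for (ch in names(scenario$replacement))
    rec$signals[, as.integer(ch)] <- src[, scenario$replacement[[ch]]]
  rec
}

#' Enumerate all channel-loss scenarios
#'
#' For three channels: the clean case (1), one lost channel with either of
#' the two working substitutes (3 x 2 = 6), and two lost channels, both
#' mapped to the single survivor (3). Ten scenarios in total, grouped as
#' all / two / one working channels.
#'
#' @return List of `cap_scenario` objects with a `n_working` attribute each.
#' @export
#' @examples
#' length(enumerate_scenarios())  # 10
enumerate_scenarios <- function() {
  out <- list(channel_loss_scenario())
  for (lost in 1:3) {
    for (rep_ch in setdiff(1:3, lost)) {
      out[[length(out) + 1L]] <-
        channel_loss_scenario(lost, stats::setNames(rep_ch, lost))
    }
  }
  for (surv in 1:3) {
    lost <- setdiff(1:3, surv)
    out[[length(out) + 1L]] <-
      channel_loss_scenario(lost, stats::setNames(c(surv, surv), lost))
  }
  out
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Noise variance is `signal_power / 10^(snr_db / 10)` with the signal power
#' computed per channel over the given signal (which, after
#' [preprocess_recording()], is ~1).
#'
#' @param x Numeric signal vector with non-zero power.
#' @param snr_db Signal-to-noise ratio in dB.
#' @return The noisy signal.
#' @export
#' @examples
#' set.seed(1)
#' x <- sin(seq(0, 10, by = 0.01))
#' y <- add_awgn(x, snr_db = 0)
#' mean((y - x)^2) / mean(x^2)  # ~1
add_awgn <- function(x, snr_db) {
  p_sig <- mean(x^2)
  if (!is.finite(p_sig) || p_sig == 0)
    stopf("cannot set an SNR on a zero-power signal")
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  x + rnorm(length(x), 0, sd_n)
}

#' AWGN scenario constructor
#'
#' @param snr_db SNR in dB, within `[-20, 20]`.
#' @return A `cap_scenario`.
#' @export
awgn_scenario <- function(snr_db) {
  if (snr_db < -20 || snr_db > 20)
    stopf("snr_db must lie in [-20, 20] dB")
  structure(list(kind = "awgn", snr_db = snr_db), class = "cap_scenario")
}

apply_scenario <- function(rec, scenario, seed = NULL) {
  if (scenario$kind == "channel_loss") return(apply_channel_loss(rec, scenario))
  with_seed(seed, {
    rec$signals <- apply(rec$signals, 2, add_awgn, snr_db = scenario$snr_db)
    rec
  })
}

#' Robustness sweep of a trained model
#'
#' Applies each scenario to every (already preprocessed) test recording the
#' model was *not* trained on, scores it, and reports the per-recording AUC
#' together with quartile summaries per scenario. The clean channel-loss
#' scenario reproduces baseline predictions exactly; AWGN scenarios are
#' seeded for reproducibility.
#'
#' @param model A fitted `cap_fusion`.
#' @param test_recordings List of `cap_recording` objects (raw; they are
#'   preprocessed internally, then perturbed at the model input).
#' @param scenarios List of `cap_scenario` objects, e.g.
#'   [enumerate_scenarios()] or `lapply(snr_grid, awgn_scenario)`. The
#'   default SNR grid is `c(-20, -10, -5, 0, 5, 10, 20)` dB.
#' @param seed Seed for the noise draws.
#' @return A `data.frame` with columns `scenario`, `n_working`/`snr_db`,
#'   `subject`, `auc`, and an attached `summary` attribute with the three
#'   quartiles per scenario.
#' @export
robustness_sweep <- function(model, test_recordings,
                             scenarios = enumerate_scenarios(), seed = 1L) {
  stopifnot(inherits(model, "cap_fusion"))
  pre <- lapply(test_recordings, preprocess_recording)
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    lab <- if (sc$kind == "awgn") sprintf("awgn_%+gdB", sc$snr_db)
           else sprintf("loss_%s", if (length(sc$lost))
             paste(sc$lost, collapse = "") else "none")
    for (ri in seq_along(pre)) {
      rec <- apply_scenario(pre[[ri]], sc,
                            seed = child_seed(seed, si * 97L + ri))
      w <- make_windows(rec, model$config$time_steps)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = lab,
        detail = if (sc$kind == "awgn") sc$snr_db else 3 - length(sc$lost),
        subject = rec$subject_id,
        auc = roc_auc(predict(model, w), w$y))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2] <- if (scenarios[[1]]$kind == "awgn") "snr_db" else "n_working"
  qs <- do.call(rbind, lapply(split(out, out$scenario), function(d) {
    q <- quantile(d$auc, c(0.25, 0.5, 0.75))
    data.frame(scenario = d$scenario[1], q25 = q[[1]], median = q[[2]],
               q75 = q[[3]], row.names = NULL)
  }))
  attr(out, "summary") <- qs
  out
}
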