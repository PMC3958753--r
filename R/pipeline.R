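# End-to-end driver: preprocess -> coupling -> inference -> uncertainty.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis, with defaults matching the
#' reference workflow: 0.1-30 Hz zero-phase 3rd-order Butterworth band-pass,
#' 200 Hz analysis rate, 500 ms before/after epochs (or 200 ms sliding
#' windows at a 5 ms step), baseline intervals of epoch length, q = 0.05
#' FDR, 1000 baseline bootstraps, 100 trial bootstraps.
#'
#' @param low,high,order band-pass parameters (Hz / filter order).
#' @param fs_out analysis sampling rate (Hz).
#' @param car apply a common average reference (typical for ECoG; leave off
#'   for simulated sessions).
#' @param epochs `"before_after"` or `"sliding"`.
#' @param epoch_half_width trial half-width in seconds.
#' @param window_width,window_step sliding-window width and step (seconds).
#' @param baseline_guard separation between baseline intervals and trial
#'   epochs (seconds).
#' @param mode `"sensor"` or `"region"`.
#' @param measure coupling statistic; default `"correlation"` for sensors,
#'   `"canonical"` for regions (see [compute_stat_matrix()]).
#' @param q FDR level.
#' @param b_null baseline bootstrap draws.
#' @param b_net trial bootstrap surrogates (0 disables the uncertainty
#'   stage).
#' @param seed base RNG seed; the bootstrap stages use offsets of it.
#' @return An object of class `fc_run_config`.
#' @export
run_config <- function(low = 0.1, high = 30, order = 3, fs_out = 200,
                       car = FALSE, epochs = c("before_after", "sliding"),
                       epoch_half_width = 0.5, window_width = 0.2,
                       window_step = 0.005, baseline_guard = 0.25,
                       mode = c("sensor", "region"), measure = NULL,
                       q = 0.05, b_null = 1000, b_net = 100, seed = 1L) {
  epochs <- match.arg(epochs)
  mode <- match.arg(mode)
  structure(list(
    low = low, high = high, order = order, fs_out = fs_out, car = car,
    epochs = epochs, epoch_half_width = epoch_half_width,
    window_width = window_width, window_step = window_step,
    baseline_guard = baseline_guard, mode = mode, measure = measure,
    q = q, b_null = as.integer(b_null), b_net = as.integer(b_net),
    seed = as.integer(seed)
  ), class = "fc_run_config")
}

# epoch duration in seconds implied by the config
.epoch_duration <- function(cfg) {
  if (cfg$epochs == "before_after") cfg$epoch_half_width else cfg$window_width
}

# compare an inferred edge set to a true edge set
.truth_eval <- function(net, true_edges) {
  n <- length(net$nodes)
  pos_true <- pair_position(true_edges, n)
  pos_est <- pair_position(net$edges, n)
  list(
    true_positive = sum(pos_est %in% pos_true),
    false_positive = sum(!(pos_est %in% pos_true)),
    false_negative = sum(!(pos_true %in% pos_est)),
    exact = setequal(pos_est, pos_true)
  )
}

#' Run the full network-inference pipeline
#'
#' Executes preprocessing (band-pass filter, downsample, optional common
#' average reference, epoching, baseline extraction), coupling statistics,
#' baseline-bootstrap inference with FDR thresholding, and (when
#' `config$b_net > 0`) trial-bootstrap uncertainty, on a recording or a
#' simulated session.
#'
#' @param config an [run_config()] object.
#' @param input an [fc_recording()], or an `fc_session` from
#'   [simulate_session()] / [make_example_fixture()] (in which case the
#'   ground truth is carried along and evaluated).
#' @return An `fc_result`: list with `config`, `epochs`, `baseline`, `null`,
#'   `networks` (per-epoch [infer_networks()] output), `uncertainty` (or
#'   NULL), `densities` (named per-epoch vector), and `truth_eval`
#'   (per-epoch true/false positive counts, when ground truth is known).
#' @export
#' @examples
#' \donttest{
#' sess <- simulate_session(sim_config(n_trials = 30, baseline_duration = 60,
#'                                     snr = 0.15, seed = 2))
#' res <- run_pipeline(run_config(b_null = 400, b_net = 25), sess)
#' res$densities
#' }
run_pipeline <- function(config, input) {
  stopifnot(inherits(config, "fc_run_config"))
  truth <- NULL
  if (inherits(input, "fc_session")) {
    truth <- input$truth
    rec <- input$recording
  } else if (inherits(input, "fc_recording")) {
    rec <- input
  } else {
    stop_arg("input must be an fc_recording or an fc_session")
  }

  rec <- bandpass_filter(rec, config$low, config$high, config$order)
  rec <- downsample(rec, config$fs_out)
  if (config$car) rec <- common_average_reference(rec)
  ep <- extract_epochs(rec, scheme = config$epochs,
                       half_width = config$epoch_half_width,
                       width = config$window_width, step = config$window_step)
  base <- extract_baseline_intervals(rec, duration = .epoch_duration(config),
                                     guard = config$baseline_guard,
                                     half_width = config$epoch_half_width)
  L <- dim(ep$data)[4]
  null <- bootstrap_null(base, L = L, B_null = config$b_null,
                         mode = config$mode, measure = config$measure,
                         seed = config$seed + 1L)
  nets <- infer_networks(ep, null, q = config$q)
  unc <- NULL
  if (config$b_net > 0) {
    unc <- assess_uncertainty(ep, null, nets, q = config$q,
                              B_net = config$b_net, seed = config$seed + 2L)
  }
  densities <- vapply(nets, network_density, numeric(1))
  truth_eval <- NULL
  if (!is.null(truth) && config$epochs == "before_after") {
    true_sets <- if (config$mode == "sensor") {
      list(before = truth$before_edges, after = truth$after_edges)
    } else {
      list(before = truth$region_before_edges, after = truth$region_after_edges)
    }
    truth_eval <- lapply(c(before = "before", after = "after"), function(epn) {
      .truth_eval(nets[[epn]], true_sets[[epn]])
    })
  }
  structure(list(
    config = config, epochs = ep, baseline = base, null = null,
    networks = nets, uncertainty = unc, densities = densities,
    truth = truth, truth_eval = truth_eval
  ), class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  cat("Functional network inference result (", x$null$measure, " measure)\n",
      sep = "")
  d <- x$densities
  show <- if (length(d) > 6) c(head(d, 3), tail(d, 3)) else d
  for (nm in names(show)) cat(sprintf("  epoch %-8s density %.3f\n", nm, show[[nm]]))
  if (length(d) > 6) cat("  ... (", length(d), " epochs)\n", sep = "")
  if (!is.null(x$truth_eval)) {
    for (nm in names(x$truth_eval)) {
      te <- x$truth_eval[[nm]]
      cat(sprintf("  %-8s TP %d, FP %d, FN %d%s\n", nm, te$true_positive,
                  te$false_positive, te$false_negative,
                  if (te$exact) " (exact recovery)" else ""))
    }
  }
  invisible(x)
}
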