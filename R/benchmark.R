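#' Re-identification benchmark on a packaged carrier model
#'
#' Surrogate identification study: simulate a packaged carrier transfer
#' function under constant-velocity inputs at the eleven grid speeds
#' (1.0-2.0 A/ps, i.e. 100-200 m/s), add zero-mean Gaussian noise at a
#' fixed fraction of each record's output RMS, hold one velocity record
#' out, fit the cascade structure by prediction-error minimization on the
#' rest, and score the normalized-RMSE fit percentage on the held-out
#' record. The raw molecular-dynamics traces behind the packaged models
#' are not published, so this synthetic benchmark is the reproducible
#' stand-in for identification quality.
#'
#' @param seeds integer vector; one study replicate per seed (drives both
#'   the noise draw and the optimizer restarts).
#' @param carrier `"fullerene"` or `"cnt"`.
#' @param n samples per record.
#' @param noise_rms noise standard deviation as a fraction of each
#'   record's output RMS (default 0.05, i.e. 5%).
#' @param restarts optimizer restarts per replicate (see [pem_fit()]).
#' @param holdout_velocity pulling velocity (A/ps) of the held-out
#'   validation record.
#' @return A tibble with one row per seed: `seed`, `fit_validation`,
#'   `fit_training`, `converged`.
#' @export
identification_benchmark <- function(seeds, carrier = "fullerene",
                                     n = 200, noise_rms = 0.05,
                                     restarts = 10,
                                     holdout_velocity = 1.5) {
  truth <- carrier_tf(carrier)
  vels_md <- velocity_grid(1.0, 2.0, 0.1)
  vels <- si_velocity(vels_md)
  hold <- which(abs(vels_md - holdout_velocity) < 1e-9)
  if (!length(hold)) stop("holdout_velocity must be a grid speed", call. = FALSE)
  clean <- lapply(vels, function(v) tf_simulate(truth, rep(v, n)))

  purrr::map_dfr(seeds, function(sd) {
    noisy <- withr::with_seed(as.integer(sd), {
      lapply(clean, function(y) {
        y + stats::rnorm(n, 0, noise_rms * sqrt(mean(y^2)))
      })
    })
    train <- setdiff(seq_along(vels), hold)
    recs <- sysid_records(
      inputs = lapply(vels[train], function(v) rep(v, n)),
      outputs = noisy[train], Ts = truth$Ts)
    res <- pem_fit(recs, restarts = restarts, seed = sd)
    yv <- noisy[[hold]]
    yh <- suppressWarnings(tf_simulate(res$model, rep(vels[hold], n)))
    tibble::tibble(seed = as.integer(sd),
                   fit_validation = fit_percent(yv, yh),
                   fit_training = res$fit_percent,
                   converged = res$converged)
  })
}
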