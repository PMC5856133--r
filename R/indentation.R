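#' Cumulative work of penetration
#'
#' Integrates the pulling force over penetration depth,
#' `W(d) = integral of F dz from 0 to d`, with the cumulative trapezoidal
#' rule on the trace's own depth grid (error O(h^2) in the sample spacing).
#' The final element is the total work of crossing.
#'
#' @param trace a [force_trace()] with non-decreasing depth.
#' @return A tibble of class `work_curve` with columns `depth` (A) and
#'   `work` (kcal/mol); `work[1]` is 0.
#' @export
penetration_work <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  if (nrow(trace) > 1 && any(diff(trace$depth) < 0)) {
    stop("depth must be non-decreasing", call. = FALSE)
  }
  w <- if (nrow(trace) > 1) {
    as.numeric(pracma::cumtrapz(trace$depth, trace$force))
  } else {
    0
  }
  out <- tibble::tibble(depth = trace$depth, work = w)
  structure(out, velocity = attr(trace, "velocity"),
            class = c("work_curve", class(out)))
}

#' Mean force versus depth over a set of traces
#'
#' Bins all samples of all traces into fixed-width depth bins and reports
#' the per-bin mean force, its spread and the sample count. Bins with no
#' samples are kept and flagged empty rather than interpolated.
#'
#' @param traces a list of [force_trace()] objects or a `pulling_experiment`
#'   tibble (its `trace` list-column is used).
#' @param bin_width depth bin width (A), default 0.5.
#' @param breaks optional explicit bin breaks (A); overrides `bin_width`.
#' @return A tibble with columns `bin_center`, `mean_force`, `sd_force`,
#'   `n`, `empty`.
#' @export
mean_force_profile <- function(traces, bin_width = 0.5, breaks = NULL) {
  if (inherits(traces, "pulling_experiment")) traces <- traces$trace
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  all <- purrr::map_dfr(traces, function(tr) {
    tibble::tibble(depth = tr$depth, force = tr$force)
  })
  if (is.null(breaks)) {
    lo <- floor(min(all$depth) / bin_width) * bin_width
    hi <- ceiling(max(all$depth) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
  }
  if (length(breaks) < 2) stop("need at least one bin", call. = FALSE)
  idx <- cut(all$depth, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = idx, force = all$force), .data$bin),
    mean_force = mean(.data$force), sd_force = stats::sd(.data$force),
    n = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(bin = seq_along(centers), bin_center = centers)
  out <- dplyr::left_join(out, agg, by = "bin")
  dplyr::mutate(out,
    n = dplyr::coalesce(.data$n, 0L),
    empty = .data$n == 0L,
    bin = NULL)
}

#' Per-frame RMSD against a reference structure
#'
#' `RMSD = sqrt(mean over atoms of squared displacement)` with no
#' superposition: the metric is meant to see membrane atoms being pushed
#' away by the carrier, which a rigid-body alignment would erase.
#'
#' @param reference numeric matrix, one row per atom, columns x/y/z.
#' @param frames list of matrices with the same dimensions and atom order
#'   as `reference`.
#' @return Numeric vector, one RMSD per frame (same length units as the
#'   coordinates).
#' @export
rmsd_series <- function(reference, frames) {
  reference <- as.matrix(reference)
  vapply(frames, function(fr) {
    fr <- as.matrix(fr)
    if (!identical(dim(fr), dim(reference))) {
      stop("frame dimensions must match the reference", call. = FALSE)
    }
    sqrt(mean(rowSums((fr - reference)^2)))
  }, numeric(1))
}

#' Linear trend of RMSD versus penetration depth
#'
#' Ordinary least-squares line through (depth, RMSD) pairs. The slope is
#' the membrane-disruption rate used to compare carriers; fitting against
#' depth rather than time makes runs at different pulling velocities
#' comparable.
#'
#' @param depth penetration depths (A), not all equal, length >= 3.
#' @param rmsd RMSD values, same length as `depth`.
#' @return A list of class `slope_fit` with elements `slope`, `intercept`,
#'   `stderr` (standard error of the slope), `r2`, and the underlying `lm`
#'   fit.
#' @export
rmsd_slope <- function(depth, rmsd) {
  if (length(depth) != length(rmsd)) stop("equal lengths required", call. = FALSE)
  if (length(depth) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(depth) == 0) {
    stop("depth is constant: slope fit is singular", call. = FALSE)
  }
  fit <- stats::lm(rmsd ~ depth)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a benign lm warning
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 stderr = unname(sm$coefficients[2, 2]),
                 r2 = sm$r.squared,
                 fit = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.4g +/- %.3g per A, r2 = %.4f\n",
              x$slope, x$stderr, x$r2))
  invisible(x)
}
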