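#' Normalized-RMSE fit percentage
#'
#' `100 * (1 - ||y - yhat|| / ||y - mean(y)||)`: 100 for a perfect
#' prediction, 0 for predicting the mean, negative for worse than the mean.
#'
#' @param measured measured output series, not constant.
#' @param predicted predicted output series, same length.
#' @return Fit percentage (<= 100).
#' @export
fit_percent <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("series must have equal length", call. = FALSE)
  }
  denom <- sqrt(sum((measured - mean(measured))^2))
  if (denom == 0) {
    stop("measured series is constant: fit percentage is undefined",
         call. = FALSE)
  }
  100 * (1 - sqrt(sum((measured - predicted)^2)) / denom)
}

#' Mean squared error
#'
#' @inheritParams fit_percent
#' @return Mean of squared residuals.
#' @export
mse <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("series must have equal length", call. = FALSE)
  }
  mean((measured - predicted)^2)
}

#' Assemble identification records
#'
#' An identification dataset is a tibble with list-columns `input`
#' (velocity series, m/s) and `output` (force series, N), one row per
#' record, all sampled at a common interval.
#'
#' @param inputs list of numeric input series.
#' @param outputs list of numeric output series, pairwise equal lengths.
#' @param Ts sampling interval (s).
#' @return A tibble of class `sysid_data`.
#' @export
sysid_records <- function(inputs, outputs, Ts = 1e-15) {
  if (length(inputs) != length(outputs) || !length(inputs)) {
    stop("need the same positive number of input and output series",
         call. = FALSE)
  }
  ok <- mapply(function(u, y) length(u) == length(y), inputs, outputs)
  if (!all(ok)) stop("each input/output pair must have equal length", call. = FALSE)
  out <- tibble::tibble(input = inputs, output = outputs)
  structure(out, Ts = Ts, class = c("sysid_data", class(out)))
}

#' Convert pulling traces to SI identification records
#'
#' Each constant-velocity trace becomes one record: the input is the
#' velocity held over the record (zero-order hold, matching constant-
#' velocity pulling) converted to m/s, the output the force series in
#' newtons.
#'
#' @param traces list of [force_trace()] objects or a `pulling_experiment`.
#' @param Ts sampling interval to stamp on the records (s).
#' @return A [sysid_records()] tibble.
#' @export
traces_to_records <- function(traces, Ts = 1e-15) {
  if (inherits(traces, "pulling_experiment")) traces <- traces$trace
  sysid_records(
    inputs = purrr::map(traces, function(tr) {
      rep(si_velocity(attr(tr, "velocity")), nrow(tr))
    }),
    outputs = purrr::map(traces, function(tr) si_force(tr$force)),
    Ts = Ts)
}

# ---- internal PEM machinery --------------------------------------------

# total squared prediction error over records, Inf on overflow
oe_cost <- function(model, records) {
  tot <- 0
  for (r in seq_len(nrow(records))) {
    yh <- suppressWarnings(tf_simulate(model, records$input[[r]]))
    if (any(!is.finite(yh))) return(Inf)
    tot <- tot + sum((records$output[[r]] - yh)^2)
  }
  tot
}

# equation-error (ARX) least squares on zero-padded lags; exact for
# noise-free output-error data with zero initial conditions
arx_polynomials <- function(records) {
  lag0 <- function(x, k) c(rep(0, k), x)[seq_along(x)]
  X <- NULL; Y <- NULL
  for (r in seq_len(nrow(records))) {
    u <- records$input[[r]]; y <- records$output[[r]]
    Xy <- sapply(1:6, function(i) -lag0(y, i))
    Xu <- sapply(0:5, function(j) lag0(u, j))
    X <- rbind(X, cbind(Xy, Xu)); Y <- c(Y, y)
  }
  sc <- apply(X, 2, function(col) max(abs(col)))
  sc[sc == 0] <- 1
  Xs <- sweep(X, 2, sc, "/")
  # light ridge keeps the step-input collinearity from blowing up
  th <- qr.solve(rbind(Xs, diag(1e-8, 12)), c(Y, numeric(12))) / sc
  list(A = c(1, th[1:6]), B = th[7:12])
}

# pair roots (z plane) into real monic quadratics z^2 + p1 z + p2,
# deterministically: ascending |argument|, conjugates matched
pair_roots <- function(r, nquads) {
  quads <- vector("list", 0)
  r <- r[order(abs(Arg(r)), Mod(r))]
  while (length(quads) < nquads) {
    if (length(r) < 2) {  # degenerate: pad with zero roots
      r <- c(r, complex(real = rep(0, 2 - length(r))))
    }
    r1 <- r[1]; r <- r[-1]
    if (abs(Im(r1)) > 1e-8 * max(1, Mod(r1))) {
      jj <- which.min(Mod(r - Conj(r1)))
    } else {
      im <- abs(Im(r)) < 1e-8 * pmax(1, Mod(r))
      jj <- if (any(im)) which(im)[which.min(abs(Re(r[im]) - Re(r1)))] else 1
    }
    r2 <- r[jj]; r <- r[-jj]
    quads[[length(quads) + 1]] <- c(Re(-(r1 + r2)), Re(r1 * r2))
  }
  quads
}

# map expanded (A, B) z^-1 polynomials onto the fixed cascade structure
structure_from_polynomials <- function(A, B, Ts) {
  a <- B[1]
  if (!is.finite(a) || a == 0) {
    return(discrete_tf(a = 0, Ts = Ts))
  }
  dq <- pair_roots(polyroot(rev(A)), 3)
  rb <- polyroot(rev(B / a))  # 5 zeros
  pick <- which.min(abs(Im(rb)))  # a real degree-5 poly has a real root
  bzero <- Re(rb[pick])
  nq <- pair_roots(rb[-pick], 2)
  discrete_tf(a = a, b = bzero,
              c = nq[[1]][1], d = nq[[1]][2],
              g = -nq[[2]][1], h = nq[[2]][2],
              e = -dq[[1]][1], f = dq[[1]][2],
              i = dq[[2]][1], j = dq[[2]][2],
              k = -dq[[3]][1], l = dq[[3]][2],
              Ts = Ts)
}

coef_to_tf <- function(theta, Ts) {
  do.call(discrete_tf, c(as.list(theta), list(Ts = Ts)))
}

# Levenberg-Marquardt refinement of the 12 structured parameters.
# The gain is rescaled to O(1); poles beyond pole_bound incur smooth
# penalty residuals so near-unit-circle sections stay representable
# without hard failure.
refine_fit <- function(theta0, records, Ts, pole_bound, max_iter) {
  sc <- c(max(abs(theta0[1]), 1e-300), rep(1, 11))
  yscale <- sqrt(mean(unlist(records$output)^2))
  if (yscale == 0) yscale <- 1
  resid_fn <- function(th) {
    theta <- th * sc
    names(theta) <- names(theta0)
    model <- coef_to_tf(theta, Ts)
    r <- unlist(lapply(seq_len(nrow(records)), function(ix) {
      yh <- suppressWarnings(tf_simulate(model, records$input[[ix]]))
      records$output[[ix]] - yh
    }))
    bad <- !is.finite(r)
    if (any(bad)) r[bad] <- 1e6 * yscale
    pm <- Mod(tf_poles_zeros(model)$poles)
    pen <- pmax(0, pm - pole_bound) * 100 * yscale * sqrt(length(r))
    c(r, pen)
  }
  ans <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = theta0 / sc, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, nprint = 0))),
    error = function(e) NULL)
  if (is.null(ans)) return(NULL)
  theta <- ans$par * sc
  names(theta) <- names(theta0)
  list(theta = theta, converged = ans$info %in% 1:4)
}

#' Fit the fixed-structure transfer function by prediction-error
#' minimization
#'
#' Minimizes the summed squared prediction error
#' `V = sum over records of sum_t e(t)^2` with output-error residuals
#' `e(t) = y(t) - G(q) u(t)` (the noise model is the identity: no noise
#' polynomial is estimated) over the twelve structured parameters a..l.
#'
#' The optimization runs in three stages: (1) an equation-error (ARX)
#' linear least-squares estimate of the expanded numerator/denominator
#' polynomials on zero-padded lags, (2) factorization of those polynomials
#' onto the fixed cascade structure, (3) Levenberg-Marquardt refinement of
#' the structured parameters against the output-error cost, repeated from
#' seeded random perturbations of the initial point (`restarts` times).
#' The best restart by cost wins; equal costs keep the earliest restart.
#' Pole magnitudes are softly constrained to `pole_bound` (default 1.05,
#' wide enough to represent published near-unit-circle sections, including
#' marginally unstable ones).
#'
#' @param records a [sysid_records()] tibble (or anything
#'   [traces_to_records()] accepts).
#' @param Ts sampling interval (s); defaults to the records' own.
#' @param init optional [discrete_tf()] starting point; skips the ARX
#'   stage.
#' @param restarts number of optimization starts (>= 1); restart 1 is the
#'   unperturbed initial point.
#' @param seed integer seed driving the restart perturbations (local RNG
#'   stream; the global RNG is untouched).
#' @param pole_bound soft upper bound on pole magnitudes.
#' @param max_iter Levenberg-Marquardt iteration cap per restart.
#' @return A list of class `identification_result`: `model` (the fitted
#'   [discrete_tf()]), `fit_percent` (on the training records, pooled),
#'   `mse`, `residuals` (list of per-record residual series), `n_samples`,
#'   `converged`, `restarts_used`, `cost`.
#' @export
pem_fit <- function(records, Ts = NULL, init = NULL, restarts = 5,
                    seed = 1L, pole_bound = 1.05, max_iter = 80) {
  if (inherits(records, "pulling_experiment") ||
      (is.list(records) && !is.data.frame(records) &&
       all(vapply(records, inherits, logical(1), "force_trace")))) {
    records <- traces_to_records(records, Ts = Ts %||% 1e-15)
  }
  stopifnot(inherits(records, "sysid_data"))
  if (!nrow(records)) stop("need at least one record", call. = FALSE)
  Ts <- Ts %||% attr(records, "Ts")
  if (restarts < 1) stop("restarts must be >= 1", call. = FALSE)

  theta0 <- if (is.null(init)) {
    ab <- arx_polynomials(records)
    structure_from_polynomials(ab$A, ab$B, Ts)$coef
  } else {
    stopifnot(inherits(init, "discrete_tf"))
    init$coef
  }

  perturbs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(restarts), function(r) {
      if (r == 1) rep(0, 12) else stats::rnorm(12, 0, 0.05 * r)
    })
  })

  best <- NULL
  for (r in seq_len(restarts)) {
    th_start <- theta0 * (1 + perturbs[[r]]) +
      c(0, perturbs[[r]][-1] * 0.01)  # also shift dimensionless coefs
    names(th_start) <- names(theta0)
    ans <- refine_fit(th_start, records, Ts, pole_bound, max_iter)
    if (is.null(ans)) next
    cost <- oe_cost(coef_to_tf(ans$theta, Ts), records)
    if (is.null(best) || cost < best$cost) {
      best <- list(theta = ans$theta, cost = cost, converged = ans$converged,
                   restart = r)
    }
  }
  if (is.null(best)) {
    # optimizer failed everywhere: return the flagged initial point
    best <- list(theta = theta0, cost = oe_cost(coef_to_tf(theta0, Ts), records),
                 converged = FALSE, restart = 0L)
  }

  model <- coef_to_tf(best$theta, Ts)
  resid <- purrr::map(seq_len(nrow(records)), function(ix) {
    records$output[[ix]] -
      suppressWarnings(tf_simulate(model, records$input[[ix]]))
  })
  ymeas <- unlist(records$output)
  yhat <- ymeas - unlist(resid)
  fp <- if (stats::sd(ymeas) == 0) NA_real_ else fit_percent(ymeas, yhat)
  structure(list(model = model,
                 fit_percent = fp,
                 mse = mse(ymeas, yhat),
                 residuals = resid,
                 n_samples = length(ymeas),
                 converged = isTRUE(best$converged),
                 restarts_used = restarts,
                 cost = best$cost),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "<identification_result> fit = %.2f%%, MSE = %.4g, N = %d, converged: %s\n",
    x$fit_percent, x$mse, x$n_samples, x$converged))
  invisible(x)
}

#' Draw a random stable transfer function
#'
#' Benchmark generator for identification studies: poles and zeros are
#' drawn inside the unit disk (magnitudes up to `max_pole`), assembled
#' onto the fixed cascade structure, with a log-uniform gain. Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param Ts sampling interval (s).
#' @param max_pole largest admissible pole/zero magnitude (< 1).
#' @return A stable [discrete_tf()].
#' @export
random_stable_tf <- function(Ts = 1e-15, max_pole = 0.95) {
  quad <- function() {
    r <- stats::runif(1, 0.3, max_pole)
    th <- stats::runif(1, 0.1, pi - 0.1)
    c(-2 * r * cos(th), r^2)  # z^2 + p1 z + p2 with conjugate roots
  }
  nq1 <- quad(); nq2 <- quad()
  dq1 <- quad(); dq2 <- quad(); dq3 <- quad()
  discrete_tf(a = sign(stats::runif(1, -1, 1)) * 10^stats::runif(1, -10, -9),
              b = stats::runif(1, -max_pole, max_pole),
              c = nq1[1], d = nq1[2],
              g = -nq2[1], h = nq2[2],
              e = -dq1[1], f = dq1[2],
              i = dq2[1], j = dq2[2],
              k = -dq3[1], l = dq3[2],
              Ts = Ts)
}
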