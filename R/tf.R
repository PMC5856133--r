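#' Fixed-structure discrete transfer function from velocity to force
#'
#' The velocity-to-resistance-force map is modelled by a discrete transfer
#' function with a fixed cascade structure: an overall gain `a`, one
#' first-order numerator factor and two numerator biquads over three
#' denominator biquads,
#'
#' ```
#' F(z) = a * (1 - b z^-1) (1 + c z^-1 + d z^-2) (1 - g z^-1 + h z^-2)
#'        -----------------------------------------------------------  v(z)
#'        (1 - e z^-1 + f z^-2) (1 + i z^-1 + j z^-2) (1 - k z^-1 + l z^-2)
#' ```
#'
#' Coefficient values substitute literally into the factors as written
#' (the printed signs of a coefficient table are taken at face value, the
#' factor signs above are part of the structure). The gain `a` carries the
#' physical units (N per m/s); all other coefficients are dimensionless.
#'
#' @param a overall gain (N s/m).
#' @param b first-order numerator (zero) coefficient.
#' @param c,d,g,h numerator biquad coefficients.
#' @param e,f,i,j,k,l denominator biquad coefficients.
#' @param Ts sampling interval in seconds, > 0 (default 1 fs, the MD
#'   integration step).
#' @return A list of class `discrete_tf` with elements `coef` (named
#'   numeric of a..l) and `Ts`.
#' @export
discrete_tf <- function(a = 1, b = 0, c = 0, d = 0, e = 0, f = 0,
                        g = 0, h = 0, i = 0, j = 0, k = 0, l = 0,
                        Ts = 1e-15) {
  if (Ts <= 0) stop("Ts must be > 0", call. = FALSE)
  # base::c explicitly: several arguments shadow base function names
  coef <- base::c(a = a, b = b, c = c, d = d, e = e, f = f,
                  g = g, h = h, i = i, j = j, k = k, l = l)
  if (anyNA(coef) || any(!is.finite(coef))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(coef = coef, Ts = Ts), class = "discrete_tf")
}

#' @export
print.discrete_tf <- function(x, ...) {
  cat(sprintf("<discrete_tf> gain a = %g, Ts = %g s\n", x$coef[["a"]], x$Ts))
  print(round(x$coef[-1], 4))
  invisible(x)
}

#' Expanded numerator and denominator polynomials
#'
#' Multiplies out the cascade factors into single polynomials in `z^-1`
#' (coefficient order: `z^0, z^-1, ...`). The numerator includes the gain.
#'
#' @param model a [discrete_tf()].
#' @return A list with numeric vectors `num` (degree 5, scaled by `a`) and
#'   `den` (degree 6, monic).
#' @export
tf_polynomials <- function(model) {
  p <- model$coef
  num <- pracma::conv(pracma::conv(c(1, -p[["b"]]),
                                   c(1, p[["c"]], p[["d"]])),
                      c(1, -p[["g"]], p[["h"]]))
  den <- pracma::conv(pracma::conv(c(1, -p[["e"]], p[["f"]]),
                                   c(1, p[["i"]], p[["j"]])),
                      c(1, -p[["k"]], p[["l"]]))
  list(num = as.numeric(num) * p[["a"]], den = as.numeric(den))
}

#' Simulate the transfer function on an input series
#'
#' Applies the cascade section by section as difference equations with zero
#' initial conditions, then scales by the gain. If the response overflows
#' (non-finite samples, possible when poles lie outside the unit circle),
#' the result carries `attr(, "overflow") = TRUE` and a warning is raised
#' rather than failing silently.
#'
#' @param model a [discrete_tf()].
#' @param input numeric input series (velocity, m/s).
#' @return Numeric output series (force, N), same length as `input`.
#' @export
tf_simulate <- function(model, input) {
  stopifnot(inherits(model, "discrete_tf"))
  if (any(!is.finite(input))) stop("input must be finite", call. = FALSE)
  p <- model$coef
  y <- as.numeric(signal::filter(c(1, -p[["b"]]),
                                 c(1, -p[["e"]], p[["f"]]), input))
  y <- as.numeric(signal::filter(c(1, p[["c"]], p[["d"]]),
                                 c(1, p[["i"]], p[["j"]]), y))
  y <- as.numeric(signal::filter(c(1, -p[["g"]], p[["h"]]),
                                 c(1, -p[["k"]], p[["l"]]), y))
  y <- p[["a"]] * y
  if (any(!is.finite(y))) {
    warning("simulation overflowed (unstable model?); output flagged",
            call. = FALSE)
    attr(y, "overflow") <- TRUE
  }
  y
}

#' DC (zero-frequency) gain
#'
#' The model evaluated at `z = 1`:
#' `a (1 - b)(1 + c + d)(1 - g + h) / [(1 - e + f)(1 + i + j)(1 - k + l)]`.
#' This is the steady-state force per unit of constant velocity and the
#' quantity the quasi-static field design uses.
#'
#' @param model a [discrete_tf()].
#' @return Scalar gain (N s/m).
#' @export
tf_dc_gain <- function(model) {
  p <- model$coef
  den <- (1 - p[["e"]] + p[["f"]]) * (1 + p[["i"]] + p[["j"]]) *
    (1 - p[["k"]] + p[["l"]])
  if (abs(den) < 1e-12) {
    stop("model has a pole at z = 1: DC gain is singular", call. = FALSE)
  }
  p[["a"]] * (1 - p[["b"]]) * (1 + p[["c"]] + p[["d"]]) *
    (1 - p[["g"]] + p[["h"]]) / den
}

quad_roots <- function(p1, p2) {
  # roots (in z) of z^2 + p1 z + p2, i.e. of 1 + p1 z^-1 + p2 z^-2
  if (p1 == 0 && p2 == 0) return(complex(0))
  polyroot(c(p2, p1, 1))
}

#' Poles, zeros and stability
#'
#' Roots of each quadratic (and the first-order) factor, in the z plane.
#' Sections with all-zero coefficients contribute no roots. The model is
#' stable iff every pole has magnitude < 1.
#'
#' @param model a [discrete_tf()].
#' @return A list with complex vectors `poles` and `zeros` and a logical
#'   `stable`.
#' @export
tf_poles_zeros <- function(model) {
  p <- model$coef
  zeros <- c(if (p[["b"]] != 0) complex(real = p[["b"]]),
             quad_roots(p[["c"]], p[["d"]]),
             quad_roots(-p[["g"]], p[["h"]]))
  poles <- c(quad_roots(-p[["e"]], p[["f"]]),
             quad_roots(p[["i"]], p[["j"]]),
             quad_roots(-p[["k"]], p[["l"]]))
  list(poles = poles, zeros = zeros,
       stable = length(poles) == 0 || all(Mod(poles) < 1))
}

#' Frequency response (Bode data)
#'
#' Evaluates the model at `z = exp(1i * 2 * pi * f * Ts)`. Frequencies must
#' not exceed the Nyquist rate `1 / (2 Ts)`. Phase is unwrapped.
#'
#' @param model a [discrete_tf()].
#' @param frequencies positive frequencies in Hz, at most Nyquist.
#' @return A tibble of class `frequency_response` with columns `frequency`
#'   (Hz), `magnitude_db`, `phase_deg`.
#' @export
tf_frequency_response <- function(model, frequencies) {
  nyq <- 1 / (2 * model$Ts)
  if (any(frequencies <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (any(frequencies > nyq * (1 + 1e-12))) {
    stop(sprintf("frequencies must not exceed Nyquist (%.4g Hz)", nyq),
         call. = FALSE)
  }
  p <- model$coef
  z <- exp(1i * 2 * pi * frequencies * model$Ts)
  H <- p[["a"]] *
    (1 - p[["b"]] / z) * (1 + p[["c"]] / z + p[["d"]] / z^2) *
    (1 - p[["g"]] / z + p[["h"]] / z^2) /
    ((1 - p[["e"]] / z + p[["f"]] / z^2) * (1 + p[["i"]] / z + p[["j"]] / z^2) *
       (1 - p[["k"]] / z + p[["l"]] / z^2))
  out <- tibble::tibble(frequency = frequencies,
                        magnitude_db = 20 * log10(Mod(H)),
                        phase_deg = as.numeric(signal::unwrap(Arg(H))) * 180 / pi)
  structure(out, Ts = model$Ts,
            class = c("frequency_response", class(out)))
}

#' Read or write a discrete transfer function as JSON
#'
#' The JSON carries the twelve coefficients `a`..`l`, the sampling interval
#' `Ts` (s) and unit annotations. Two fitted carrier models (fullerene and
#' end-capped CNT) ship with the package; see [carrier_tf()].
#'
#' @param file path to a JSON model file.
#' @param model a [discrete_tf()].
#' @param label optional free-form label stored in the file.
#' @return `read_tf_json()` returns a `discrete_tf`; `write_tf_json()`
#'   returns `file` invisibly.
#' @export
read_tf_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  need <- c(letters[1:12], "Ts")
  if (!all(need %in% names(x))) {
    stop("model file is missing field(s): ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  do.call(discrete_tf, lapply(x[need], as.numeric))
}

#' @rdname read_tf_json
#' @export
write_tf_json <- function(model, file, label = NULL) {
  stopifnot(inherits(model, "discrete_tf"))
  x <- c(as.list(model$coef),
         list(Ts = model$Ts,
              input_units = "m/s", output_units = "N", Ts_units = "s"))
  if (!is.null(label)) x$label <- label
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Packaged carrier transfer-function models
#'
#' Loads one of the two fitted velocity-to-force models shipped with the
#' package: the fullerene (C720) carrier or the end-capped carbon nanotube.
#' Gains are in N per m/s; the sampling interval is 1 fs. Note that the
#' fullerene model is marginally unstable (one pole pair at magnitude
#' ~1.03), which [tf_simulate()] tolerates over finite records.
#'
#' @param kind `"fullerene"` or `"cnt"`.
#' @return A [discrete_tf()].
#' @examples
#' tf_dc_gain(carrier_tf("fullerene"))
#' @export
carrier_tf <- function(kind = c("fullerene", "cnt")) {
  kind <- match.arg(kind)
  file <- system.file("extdata", paste0(kind, "_tf.json"),
                      package = "nanofield", mustWork = TRUE)
  read_tf_json(file)
}
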