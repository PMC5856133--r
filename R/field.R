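#' Magnetic constants of the superparamagnetic bead
#'
#' Constants entering the magnetophoretic force law
#' `F = (V chi / mu0) (B . grad) B` for the bead inside the nanocarrier:
#' vacuum permeability, bead radius (2 nm), bead volume (sphere, derived
#' from the radius when not given) and magnetic susceptibility (0.17).
#'
#' @param mu0 permeability of free space (T m/A).
#' @param r_a bead radius (m).
#' @param V bead volume (m^3); defaults to `(4/3) pi r_a^3` and must be
#'   consistent with `r_a` when both are supplied.
#' @param chi_bead magnetic susceptibility (dimensionless).
#' @return A list of class `magnetic_constants`.
#' @export
magnetic_constants <- function(mu0 = 4e-7 * pi, r_a = 2e-9, V = NULL,
                               chi_bead = 0.17) {
  if (mu0 <= 0 || r_a <= 0 || chi_bead <= 0) {
    stop("all constants must be positive", call. = FALSE)
  }
  V_sphere <- (4 / 3) * pi * r_a^3
  if (is.null(V)) {
    V <- V_sphere
  } else {
    if (V <= 0) stop("V must be positive", call. = FALSE)
    if (abs(V - V_sphere) > 1e-6 * V_sphere) {
      stop("V is inconsistent with r_a (expected (4/3) pi r_a^3)",
           call. = FALSE)
    }
  }
  structure(list(mu0 = mu0, r_a = r_a, V = V, chi_bead = chi_bead),
            class = "magnetic_constants")
}

#' Read or write magnetic constants as JSON
#' @param file path to a JSON file.
#' @param constants a [magnetic_constants()].
#' @return `read_magnetic_constants()` returns a `magnetic_constants`;
#'   the writer returns `file` invisibly.
#' @export
read_magnetic_constants <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(magnetic_constants,
          x[intersect(names(x), c("mu0", "r_a", "V", "chi_bead"))])
}

#' @rdname read_magnetic_constants
#' @export
write_magnetic_constants <- function(constants, file) {
  jsonlite::write_json(unclass(constants), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Membrane-crossing scenario
#'
#' A crossing scenario ties the fixed crossing distance (the bilayer
#' thickness, default 55 A) to a desired crossing time `t_s`. Because the
#' distance is fixed, the design velocity follows by time scaling:
#' `v_s = v_sim t_sim / t_s = x_membrane / t_s`.
#'
#' @param t_s desired crossing time (s), > 0.
#' @param x_membrane crossing distance (m), default 5.5e-9 (55 A).
#' @param v_sim simulated pulling velocity (m/s); optional, defaults to
#'   100 m/s (1 A/ps).
#' @param t_sim simulated crossing time (s); derived from `x_membrane` and
#'   `v_sim` when missing, and checked for consistency
#'   (`v_sim * t_sim = x_membrane`) when given.
#' @return A list of class `crossing_scenario`.
#' @export
crossing_scenario <- function(t_s, x_membrane = 5.5e-9, v_sim = 100,
                              t_sim = NULL) {
  if (t_s <= 0 || x_membrane <= 0 || v_sim <= 0) {
    stop("all scenario quantities must be positive", call. = FALSE)
  }
  if (is.null(t_sim)) {
    t_sim <- x_membrane / v_sim
  } else if (abs(v_sim * t_sim - x_membrane) > 1e-9 * x_membrane) {
    stop("inconsistent scenario: v_sim * t_sim must equal x_membrane",
         call. = FALSE)
  }
  structure(list(x_membrane = x_membrane, v_sim = v_sim, t_sim = t_sim,
                 t_s = t_s),
            class = "crossing_scenario")
}

#' Design velocity for a crossing scenario
#'
#' `v_s = v_sim t_sim / t_s = x_membrane / t_s`: halving the desired
#' crossing time doubles the required velocity.
#'
#' @param scenario a [crossing_scenario()].
#' @return Velocity in m/s.
#' @export
scaled_velocity <- function(scenario) {
  stopifnot(inherits(scenario, "crossing_scenario"))
  scenario$v_sim * scenario$t_sim / scenario$t_s
}

#' Quasi-static membrane resistance force at a crossing velocity
#'
#' At minute-scale crossings the drive sits far below the model's
#' constant-gain frequency band, so the convolution collapses to the DC
#' gain: `F = |dc gain| * v_s`, in newtons. The magnitude is taken because
#' the driving force must oppose the (negatively signed) resistance.
#'
#' @param model a [discrete_tf()] stable at DC.
#' @param v_s crossing velocity (m/s), >= 0.
#' @return Force in N.
#' @export
crossing_force <- function(model, v_s) {
  if (v_s < 0) stop("v_s must be >= 0", call. = FALSE)
  abs(tf_dc_gain(model)) * v_s
}

#' Required field-gradient product for a given force
#'
#' Inverts the axial magnetophoretic force law: with transverse field
#' components zero, `F_z = (V chi / mu0) b_z (d b_z / d z)`, so the
#' required product is `U = F mu0 / (V chi)` in T^2/m.
#'
#' @param force axial force (N), >= 0.
#' @param constants a [magnetic_constants()].
#' @return The required value of `b_z * (d b_z / d z)` (T^2/m).
#' @export
magnetophoretic_product <- function(force, constants = magnetic_constants()) {
  stopifnot(inherits(constants, "magnetic_constants"))
  if (any(force < 0)) stop("force must be >= 0", call. = FALSE)
  force * constants$mu0 / (constants$V * constants$chi_bead)
}

#' Product bounds for a band of crossing times
#'
#' The slow scenario (larger `t_s`) fixes the lower bound `L_min`, the
#' fast scenario the upper bound `L_max`, via the quasi-static force at
#' the scaled velocities. The admissible fields satisfy
#' `L_min <= b_z (d b_z / d z) <= L_max`.
#'
#' @param model a [discrete_tf()].
#' @param constants a [magnetic_constants()].
#' @param scenario_min slow-crossing [crossing_scenario()] (sets `L_min`).
#' @param scenario_max fast-crossing scenario; its `t_s` must not exceed
#'   `scenario_min$t_s`.
#' @return Named numeric `c(L_min, L_max)` in T^2/m.
#' @export
product_bounds <- function(model, constants, scenario_min, scenario_max) {
  stopifnot(inherits(scenario_min, "crossing_scenario"),
            inherits(scenario_max, "crossing_scenario"))
  if (scenario_max$t_s > scenario_min$t_s) {
    stop("scenario_max must cross at least as fast as scenario_min ",
         "(t_s ordering inverted)", call. = FALSE)
  }
  L_min <- magnetophoretic_product(
    crossing_force(model, scaled_velocity(scenario_min)), constants)
  L_max <- magnetophoretic_product(
    crossing_force(model, scaled_velocity(scenario_max)), constants)
  c(L_min = unname(L_min), L_max = unname(L_max))
}

#' Feasible (field, gradient) region under MRI limits
#'
#' The admissible set
#' `{(b, g): L_min <= b g <= L_max, 0 <= b <= b_max, 0 <= g <= g_max}` —
#' the band between two hyperbolas clipped to the MRI hardware box
#' (defaults 2.4 T and 0.18 T/m). The region is held analytically (the
#' bounds and box); the boundary polyline is sampled at `resolution`
#' points per arc for export and plotting, so resolution affects plotting
#' only, never membership. The region is empty iff `L_min > b_max * g_max`
#' (the corner product).
#'
#' @param L_min,L_max product bounds (T^2/m), `L_min <= L_max`.
#' @param b_max field ceiling (T).
#' @param g_max gradient ceiling (T/m).
#' @param resolution boundary samples per arc, >= 2.
#' @return A list of class `field_region`: the bounds, the limits, an
#'   `empty` flag and `boundary`, a tibble of (b, g) vertices tracing the
#'   closed boundary.
#' @export
feasible_region <- function(L_min, L_max, b_max = 2.4, g_max = 0.18,
                            resolution = 200) {
  if (L_min < 0 || L_max < L_min) {
    stop("need 0 <= L_min <= L_max", call. = FALSE)
  }
  if (b_max <= 0 || g_max <= 0) stop("limits must be positive", call. = FALSE)
  if (resolution < 2) stop("resolution must be >= 2", call. = FALSE)

  empty <- L_min > b_max * g_max
  if (empty) {
    boundary <- tibble::tibble(b = numeric(0), g = numeric(0))
  } else {
    b_lo <- if (L_min > 0) L_min / g_max else 0
    bs <- seq(b_lo, b_max, length.out = resolution)
    g_low <- if (L_min > 0) pmin(L_min / bs, g_max) else rep(0, resolution)
    g_high <- pmin(ifelse(bs > 0, L_max / bs, Inf), g_max)
    # lower arc left-to-right, upper arc right-to-left, closed
    boundary <- tibble::tibble(
      b = c(bs, rev(bs), bs[1]),
      g = c(g_low, rev(g_high), g_low[1]))
    # guard against last-ulp excursions outside the box
    boundary$b <- pmin(pmax(boundary$b, 0), b_max)
    boundary$g <- pmin(pmax(boundary$g, 0), g_max)
  }
  structure(list(L_min = L_min, L_max = L_max, b_max = b_max, g_max = g_max,
                 empty = empty, boundary = boundary),
            class = "field_region")
}

#' @export
print.field_region <- function(x, ...) {
  cat(sprintf("<field_region> L in [%.4g, %.4g] T^2/m, box %.3g T x %.3g T/m%s\n",
              x$L_min, x$L_max, x$b_max, x$g_max,
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Membership test for a field region
#'
#' Exact (analytic) membership: the point must satisfy the product band
#' and both hardware limits.
#'
#' @param region a [feasible_region()].
#' @param b field values (T).
#' @param g gradient values (T/m).
#' @param tol relative slack on the product band.
#' @return Logical vector.
#' @export
region_contains <- function(region, b, g, tol = 1e-9) {
  stopifnot(inherits(region, "field_region"))
  slack <- tol * max(region$L_max, 1)
  b >= 0 & b <= region$b_max & g >= 0 & g <= region$g_max &
    b * g >= region$L_min - slack & b * g <= region$L_max + slack
}

#' Export or read a feasible region
#'
#' CSV carries the boundary polyline (columns `b_T`, `grad_T_per_m`) with
#' the bounds and limits in `#`-prefixed header lines; JSON carries the
#' full region and round-trips through `read_region()`. An empty region
#' writes metadata with the empty flag set and no boundary rows.
#'
#' @param region a [feasible_region()].
#' @param file output path.
#' @param format `"csv"` or `"json"`.
#' @return `file`, invisibly; `read_region()` returns a `field_region`.
#' @export
export_region <- function(region, file, format = c("csv", "json")) {
  stopifnot(inherits(region, "field_region"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(L_min = region$L_min, L_max = region$L_max,
           b_max = region$b_max, g_max = region$g_max,
           empty = region$empty,
           boundary = list(b = region$boundary$b, g = region$boundary$g)),
      file, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- c(sprintf("# L_min\t%.17g", region$L_min),
             sprintf("# L_max\t%.17g", region$L_max),
             sprintf("# b_max\t%.17g", region$b_max),
             sprintf("# g_max\t%.17g", region$g_max),
             sprintf("# empty\t%s", tolower(as.character(region$empty))),
             "b_T,grad_T_per_m")
    rows <- sprintf("%.17g,%.17g", region$boundary$b, region$boundary$g)
    writeLines(c(hdr, rows), file)
  }
  invisible(file)
}

#' @rdname export_region
#' @export
read_region <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  reg <- feasible_region(x$L_min, x$L_max, x$b_max, x$g_max, resolution = 2)
  reg$empty <- isTRUE(x$empty)
  reg$boundary <- tibble::tibble(b = as.numeric(x$boundary$b),
                                 g = as.numeric(x$boundary$g))
  reg
}
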