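#' Constant-velocity pulling force traces
#'
#' A `force_trace` is a tibble with columns `time` (ps), `depth` (A) and
#' `force` (kcal/mol/A) describing one constant-velocity pulling record: the
#' total guiding force applied to a nanocarrier as it is pushed through a
#' lipid bilayer at fixed speed. The pulling velocity (A/ps) and free-form
#' provenance tags travel as attributes.
#'
#' @param time sample times in ps, strictly increasing.
#' @param depth displacement along the pulling axis in A. Depth is 0 at the
#'   trace start and increases along the pulling direction; any initial
#'   carrier-membrane separation is provenance, not baked into depth.
#' @param force total pulling force in kcal/mol/A.
#' @param velocity pulling speed in A/ps.
#' @param meta named list of provenance tags.
#' @return A tibble of class `force_trace`.
#' @export
force_trace <- function(time, depth, force, velocity, meta = list()) {
  if (length(time) != length(depth) || length(time) != length(force)) {
    stop("time, depth and force must have equal length", call. = FALSE)
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(velocity) || length(velocity) != 1 || velocity <= 0) {
    stop("velocity must be a single positive number (A/ps)", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), depth = as.numeric(depth),
                        force = as.numeric(force))
  structure(out,
            velocity = velocity,
            meta = meta,
            class = c("force_trace", class(out)))
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> v = %g A/ps, %d samples\n",
              attr(x, "velocity"), nrow(x)))
  NextMethod()
}

#' Pulling velocity of a force trace
#' @param trace a [force_trace()].
#' @return Pulling speed in A/ps.
#' @export
trace_velocity <- function(trace) attr(trace, "velocity")

#' Configuration of the synthetic pulling-trace generator
#'
#' Parameters of the synthetic constant-velocity pulling model: the membrane
#' resistance is a single Gaussian-in-depth bump whose amplitude grows
#' linearly with the pulling velocity, plus zero-mean Gaussian noise standing
#' in for the fluctuating harmonic-guide force. Defaults follow the study
#' conditions: guide stiffness 7 kcal/mol/A^2, a resistance peak centred
#' mid-bilayer (27.5 A of a 55 A membrane).
#'
#' @param spring_constant harmonic guide stiffness k (kcal/mol/A^2).
#' @param peak_amplitude base resistance force scale (kcal/mol/A).
#' @param peak_center depth of maximal resistance (A).
#' @param peak_width Gaussian width of the resistance bump (A), > 0.
#' @param velocity_gain linear increase of peak force with pulling velocity
#'   (kcal/mol/A per A/ps); positive values reproduce the observation that
#'   faster penetration demands larger pulling force.
#' @param noise_sd standard deviation of the additive force noise
#'   (kcal/mol/A), >= 0.
#' @param seed integer RNG seed; every generated trace draws from a local
#'   stream seeded from this value, leaving the global RNG untouched.
#' @param timestep sample spacing (ps), > 0.
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(spring_constant = 7, peak_amplitude = 20,
                         peak_center = 27.5, peak_width = 8,
                         velocity_gain = 10, noise_sd = 1,
                         seed = 1L, timestep = 0.1) {
  if (peak_width <= 0) stop("peak_width must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (timestep <= 0) stop("timestep must be > 0", call. = FALSE)
  structure(list(spring_constant = spring_constant,
                 peak_amplitude = peak_amplitude,
                 peak_center = peak_center,
                 peak_width = peak_width,
                 velocity_gain = velocity_gain,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 timestep = timestep),
            class = "trace_config")
}

#' Read or write a trace-generator configuration as JSON
#' @param file path to a JSON file.
#' @param config a [trace_config()].
#' @return `read_trace_config()` returns a `trace_config`;
#'   `write_trace_config()` returns `file` invisibly.
#' @export
read_trace_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(trace_config, x[intersect(names(x), names(formals(trace_config)))])
}

#' @rdname read_trace_config
#' @export
write_trace_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Inclusive velocity grid
#'
#' Builds the grid of constant pulling velocities by integer index so the
#' endpoints are exactly representable (no accumulated floating addition).
#' The study grid 1.0 to 2.0 A/ps in steps of 0.1 has eleven points.
#'
#' @param start,stop grid endpoints (A/ps), `stop >= start`.
#' @param step grid spacing (A/ps), > 0.
#' @return Numeric vector of velocities, ascending, endpoints included.
#' @examples
#' velocity_grid(1.0, 2.0, 0.1) # 11 speeds
#' @export
velocity_grid <- function(start, stop, step) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (stop < start) stop("stop must be >= start", call. = FALSE)
  n <- floor((stop - start) / step + 1e-9)
  start + step * (0:n)
}

#' Generate one synthetic constant-velocity pulling trace
#'
#' The force profile is a smooth resistance bump
#' `(peak_amplitude + velocity_gain * velocity) * exp(-(d - peak_center)^2 /
#' (2 * peak_width^2))` over depth `d = velocity * time`, plus zero-mean
#' Gaussian noise of sd `noise_sd`. Identical `(config, velocity, duration)`
#' yield identical traces.
#'
#' @param config a [trace_config()].
#' @param velocity pulling speed (A/ps), > 0.
#' @param duration trace length (ps), > 0; should cover the configured peak.
#' @return A [force_trace()].
#' @export
generate_trace <- function(config, velocity, duration) {
  stopifnot(inherits(config, "trace_config"))
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (velocity <= 0) stop("velocity must be > 0", call. = FALSE)
  n <- floor(duration / config$timestep + 1e-9)
  time <- config$timestep * (0:n)
  depth <- velocity * time
  amp <- config$peak_amplitude + config$velocity_gain * velocity
  force <- amp * exp(-(depth - config$peak_center)^2 / (2 * config$peak_width^2))
  if (config$noise_sd > 0) {
    # local seeded stream: derive a per-velocity offset so traces on a grid
    # are mutually independent but the whole experiment is reproducible
    stream <- config$seed + as.integer(round(velocity * 1000)) %% 100000L
    noise <- withr::with_seed(stream, stats::rnorm(length(time), 0, config$noise_sd))
    force <- force + noise
  }
  force_trace(time, depth, force, velocity,
              meta = list(generator = "gaussian-bump", seed = config$seed,
                          spring_constant = config$spring_constant))
}

#' Generate a pulling experiment over a velocity grid
#'
#' One synthetic trace per grid velocity; grid points are unique by
#' construction of [velocity_grid()].
#'
#' @inheritParams generate_trace
#' @param start,stop,step velocity grid definition (A/ps), see
#'   [velocity_grid()].
#' @return A tibble with columns `velocity` and `trace` (list-column of
#'   [force_trace()] objects), of class `pulling_experiment`.
#' @export
simulate_pulling <- function(config, start = 1.0, stop = 2.0, step = 0.1,
                             duration = 55) {
  grid <- velocity_grid(start, stop, step)
  out <- tibble::tibble(
    velocity = grid,
    trace = purrr::map(grid, function(v) generate_trace(config, v, duration))
  )
  structure(out, grid = c(start = start, stop = stop, step = step),
            class = c("pulling_experiment", class(out)))
}

#' Parse NAMD-style SMD log lines into a force trace
#'
#' Recognizes the 8-token dialect `SMD <step> <x> <y> <z> <fx> <fy> <fz>`;
#' the first whitespace-separated token must be exactly `SMD` (so words such
#' as `SMDish` are not records). Non-SMD lines are ignored. Extracts the
#' step, z coordinate and z force; `time = step * timestep`. Depth is the z
#' displacement relative to the first record.
#'
#' @param lines character vector of log lines, or a file path of length 1
#'   pointing to an existing file.
#' @param timestep MD integration step (ps) used to convert step numbers to
#'   time.
#' @param velocity pulling speed (A/ps) to attach to the trace.
#' @return A [force_trace()] where `depth` holds the raw z coordinate of the
#'   pulled group (A) and `force` the z component of the applied force.
#' @export
read_namd_smd_log <- function(lines, timestep, velocity = 1.0) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  toks <- strsplit(trimws(lines), "\\s+")
  is_smd <- vapply(toks, function(t) length(t) >= 1 && t[[1]] == "SMD", logical(1))
  if (!any(is_smd)) stop("no SMD records found in input", call. = FALSE)
  idx <- which(is_smd)
  rec <- matrix(NA_real_, nrow = length(idx), ncol = 7)
  for (r in seq_along(idx)) {
    t <- toks[[idx[r]]]
    if (length(t) != 8) {
      stop(sprintf("malformed SMD line %d: expected 8 tokens, got %d",
                   idx[r], length(t)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(t[-1]))
    if (anyNA(v)) {
      stop(sprintf("malformed SMD line %d: non-numeric field", idx[r]),
           call. = FALSE)
    }
    rec[r, ] <- v
  }
  force_trace(time = rec[, 1] * timestep,
              depth = rec[, 4],
              force = rec[, 7],
              velocity = velocity,
              meta = list(source = "namd-smd-log", timestep = timestep))
}

#' Write or read a force trace as TSV
#'
#' Columns `time_ps`, `depth_A`, `force_kcal_mol_A` with a header row naming
#' units. Values are written with 17 significant digits so that
#' write-then-read round-trips every sample to full double precision.
#'
#' @param trace a [force_trace()].
#' @param file path to a TSV file.
#' @return `read_trace_tsv()` returns a [force_trace()];
#'   `write_trace_tsv()` returns `file` invisibly.
#' @export
write_trace_tsv <- function(trace, file) {
  stopifnot(inherits(trace, "force_trace"))
  hdr <- sprintf("# velocity_A_ps\t%.17g", attr(trace, "velocity"))
  body <- sprintf("%.17g\t%.17g\t%.17g", trace$time, trace$depth, trace$force)
  writeLines(c(hdr, "time_ps\tdepth_A\tforce_kcal_mol_A", body), file)
  invisible(file)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(file) {
  lines <- readLines(file)
  vel <- 1.0
  if (length(lines) && startsWith(lines[1], "# velocity_A_ps")) {
    vel <- as.numeric(strsplit(lines[1], "\t")[[1]][2])
    lines <- lines[-1]
  }
  if (!length(lines) || !identical(lines[1], "time_ps\tdepth_A\tforce_kcal_mol_A")) {
    stop("missing or malformed TSV header: expected columns ",
         "time_ps, depth_A, force_kcal_mol_A", call. = FALSE)
  }
  df <- utils::read.delim(text = lines, sep = "\t", header = TRUE)
  need <- c("time_ps", "depth_A", "force_kcal_mol_A")
  if (!all(need %in% names(df))) {
    stop("TSV is missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  force_trace(df$time_ps, df$depth_A, df$force_kcal_mol_A, velocity = vel,
              meta = list(source = "tsv"))
}
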