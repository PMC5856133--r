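# Independent oracles used across tests. These deliberately avoid the
# package's simulation path: polynomial expansion is done by direct
# convolution and the difference equation is run as an explicit loop.

# polynomial product, coefficient order z^0, z^-1, ...
poly_mul <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1)
  for (ii in seq_along(x)) {
    out[ii:(ii + length(y) - 1)] <- out[ii:(ii + length(y) - 1)] + x[ii] * y
  }
  out
}

# expand the cascade of a discrete_tf into one rational function
expand_tf <- function(model) {
  p <- model$coef
  num <- poly_mul(poly_mul(c(1, -p[["b"]]), c(1, p[["c"]], p[["d"]])),
                  c(1, -p[["g"]], p[["h"]]))
  den <- poly_mul(poly_mul(c(1, -p[["e"]], p[["f"]]), c(1, p[["i"]], p[["j"]])),
                  c(1, -p[["k"]], p[["l"]]))
  list(num = num * p[["a"]], den = den)
}

# simulate the expanded rational function with an explicit difference
# equation loop (zero initial conditions)
simulate_expanded <- function(model, u) {
  tp <- expand_tf(model)
  b <- tp$num; a <- tp$den
  n <- length(u)
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (ii in seq_along(b)) {
      if (t - ii + 1 >= 1) acc <- acc + b[ii] * u[t - ii + 1]
    }
    for (jj in seq_along(a)[-1]) {
      if (t - jj + 1 >= 1) acc <- acc - a[jj] * y[t - jj + 1]
    }
    y[t] <- acc
  }
  y
}

table2_fullerene <- function() carrier_tf("fullerene")
table2_cnt <- function() carrier_tf("cnt")

# noise-free identification dataset from a model under constant-velocity
# step inputs (velocities in m/s)
make_step_records <- function(model, velocities, n) {
  sysid_records(
    inputs = lapply(velocities, function(v) rep(v, n)),
    outputs = lapply(velocities, function(v) tf_simulate(model, rep(v, n))),
    Ts = model$Ts)
}
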