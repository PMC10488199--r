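#' Configuration for a synthetic ACMA quench/recovery trace
#'
#' Describes one proton-pumping assay trace: baseline fluorescence of 1 until
#' Mg2+ addition at `t_mg` starts the pump, exponential quench toward
#' `plateau`, then recovery toward `recovery` after the protonophore (CCCP)
#' is added at `t_cccp`.
#'
#' The quench obeys `F(t) = plateau + (1 - plateau) * exp(-k (t - t_mg))`
#' with `k = rate / (1 - plateau)`, so the initial slope of the normalized
#' fluorescence is exactly `-rate`.
#'
#' @param t_mg,t_cccp,t_end Event times in seconds, `0 < t_mg < t_cccp < t_end`.
#' @param dt Sampling interval in seconds (assays are typically recorded at
#'   0.1 s resolution).
#' @param rate True initial quench rate of the normalized fluorescence
#'   (fraction per second, >= 0).
#' @param plateau Quench floor as a fraction of the initial fluorescence,
#'   in `[0, 1]`.
#' @param recovery Fluorescence level the trace recovers toward after CCCP.
#' @param noise_sd Standard deviation of additive Gaussian noise (fraction).
#' @param seed Integer seed; identical configs give bitwise-identical traces.
#' @return An object of class `trace_gen_config`.
#' @export
trace_gen_config <- function(t_mg = 60, t_cccp = 460, t_end = 600, dt = 0.1,
                             rate = 0.004, plateau = 0.4, recovery = 0.95,
                             noise_sd = 0, seed = 1L) {
  if (!(t_mg > 0 && t_mg < t_cccp && t_cccp < t_end))
    stop_config("invalid event ordering: need 0 < t_mg < t_cccp < t_end (got %g, %g, %g)",
                t_mg, t_cccp, t_end)
  if (dt <= 0) stop_config("dt must be positive")
  if (plateau < 0 || plateau > 1) stop_config("plateau must lie in [0, 1]")
  if (rate < 0) stop_config("rate must be >= 0")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(t_mg = t_mg, t_cccp = t_cccp, t_end = t_end, dt = dt,
                 rate = rate, plateau = plateau, recovery = recovery,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_gen_config")
}

# time constant (s) of the post-CCCP recovery; the probe response to gradient
# collapse is fast compared with the pumping phase
.recovery_tau <- 5

#' Generate a synthetic ACMA fluorescence trace
#'
#' @param cfg A [trace_gen_config()].
#' @return An `acma_trace`: data frame with columns `time_s`, `fluorescence`
#'   and attributes `t_mg`, `t_cccp`.
#' @examples
#' tr <- gen_acma_trace(trace_gen_config(rate = 0.004, noise_sd = 0))
#' head(tr)
#' @export
gen_acma_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_gen_config"))
  tt <- seq(0, cfg$t_end, by = cfg$dt)
  f <- rep(1, length(tt))
  quench <- tt >= cfg$t_mg & tt < cfg$t_cccp
  if (cfg$rate > 0 && cfg$plateau < 1) {
    k <- cfg$rate / (1 - cfg$plateau)
    f[quench] <- cfg$plateau + (1 - cfg$plateau) * exp(-k * (tt[quench] - cfg$t_mg))
    f_cccp <- cfg$plateau + (1 - cfg$plateau) * exp(-k * (cfg$t_cccp - cfg$t_mg))
  } else {
    f_cccp <- 1
  }
  # CCCP only restores fluorescence lost to the gradient: an unquenched
  # trace stays where it is
  target <- max(cfg$recovery, f_cccp)
  rec <- tt >= cfg$t_cccp
  f[rec] <- target + (f_cccp - target) * exp(-(tt[rec] - cfg$t_cccp) / .recovery_tau)
  if (cfg$noise_sd > 0)
    f <- f + local_seed(cfg$seed, stats::rnorm(length(f), sd = cfg$noise_sd))
  new_trace(tt, f, cfg$t_mg, cfg$t_cccp)
}

#' Construct a fluorescence trace object
#'
#' @param time_s Strictly increasing sample times (s).
#' @param fluorescence Fluorescence values (arbitrary units).
#' @param t_mg,t_cccp Reagent-addition times (s), both inside the time range
#'   with `t_mg < t_cccp`.
#' @return An `acma_trace` data frame.
#' @export
new_trace <- function(time_s, fluorescence, t_mg, t_cccp) {
  if (length(time_s) != length(fluorescence))
    stop_config("time and fluorescence lengths differ")
  if (any(diff(time_s) <= 0)) stop_config("time must be strictly increasing")
  if (!(t_mg < t_cccp)) stop_config("t_mg must precede t_cccp")
  if (t_mg < time_s[1] || t_cccp > time_s[length(time_s)])
    stop_config("event times must fall inside the sampled time range")
  structure(data.frame(time_s = time_s, fluorescence = fluorescence),
            t_mg = t_mg, t_cccp = t_cccp,
            class = c("acma_trace", "data.frame"))
}

#' Write / read a trace as CSV plus a JSON event sidecar
#'
#' @param trace An `acma_trace`.
#' @param path CSV path; events go to `<path>.events.json`.
#' @return `write_trace` returns `path` invisibly; `read_trace` the trace.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("time_s", "fluorescence")], path,
                   row.names = FALSE)
  jsonlite::write_json(list(t_mg = attr(trace, "t_mg"),
                            t_cccp = attr(trace, "t_cccp")),
                       paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @param path CSV path written by [write_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  ev <- jsonlite::read_json(paste0(path, ".events.json"))
  new_trace(df$time_s, df$fluorescence, ev$t_mg, ev$t_cccp)
}

#' Generate a detergent solubilization series from the Boltzmann sigmoid
#'
#' Scattering of a liposome suspension titrated with detergent follows a
#' decreasing sigmoid `y = Bottom + (Top - Bottom) / (1 + exp((x - V50)/slope))`:
#' `Top` is the starting plateau (intact vesicles), `Bottom` the fully
#' solubilized plateau, and `V50` the detergent concentration at the
#' inflection (turning) point.
#'
#' @param top,bottom Plateau scattering values (a.u.), `top > bottom`.
#' @param v50 Inflection point (mM).
#' @param slope Width parameter (mM); must be nonzero.
#' @param x_grid Strictly increasing detergent concentrations (mM).
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param seed Integer seed.
#' @return A `solubilization_series` data frame with columns `x`, `y`.
#' @export
gen_solubilization_series <- function(top, bottom, v50, slope, x_grid,
                                      noise_sd = 0, seed = 1L) {
  if (slope == 0) stop_config("slope must be nonzero")
  if (any(diff(x_grid) <= 0)) stop_config("x_grid must be strictly increasing")
  y <- boltzmann(x_grid, top, bottom, v50, slope)
  if (noise_sd > 0)
    y <- y + local_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  new_solubilization_series(x_grid, y)
}

#' @rdname gen_solubilization_series
#' @param x Detergent concentrations (mM).
#' @param y Scattering values (a.u.).
#' @export
new_solubilization_series <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y lengths differ")
  if (length(x) < 5) stop_config("a solubilization series needs >= 5 points")
  if (any(diff(x) <= 0)) stop_config("x must be strictly increasing")
  structure(data.frame(x = x, y = y),
            class = c("solubilization_series", "data.frame"))
}

#' Boltzmann sigmoid
#'
#' @param x Detergent concentration (mM).
#' @param top,bottom,v50,slope Curve parameters (see
#'   [gen_solubilization_series()]).
#' @return Predicted scattering.
#' @export
boltzmann <- function(x, top, bottom, v50, slope) {
  bottom + (top - bottom) / (1 + exp((x - v50) / slope))
}
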