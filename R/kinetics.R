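#' Normalize an ACMA trace to the fluorescence just after Mg2+ addition
#'
#' Divides the whole trace by the value of the first sample at or after
#' `t_mg` (discrete acquisition: no interpolation). Normalizing an already
#' normalized trace is a no-op.
#'
#' @param trace An `acma_trace` (see [new_trace()]).
#' @return The normalized trace; the reference value used is stored in the
#'   `reference` attribute.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "acma_trace"))
  t_mg <- attr(trace, "t_mg")
  i <- which(trace$time_s >= t_mg)[1]
  if (is.na(i))
    stop_config("no sample at or after t_mg = %g s", t_mg)
  ref <- trace$fluorescence[i]
  if (!is.finite(ref) || ref <= 0)
    stop_config("degenerate trace: reference fluorescence %g at t = %g s",
                ref, trace$time_s[i])
  out <- new_trace(trace$time_s, trace$fluorescence / ref, t_mg,
                   attr(trace, "t_cccp"))
  attr(out, "reference") <- ref
  out
}

#' Initial proton-pumping rate from the post-Mg2+ slope
#'
#' Ordinary least-squares slope of normalized fluorescence over the first
#' `window_s` seconds after Mg2+ addition; the pumping rate is the negated
#' slope. Every sample in the window is used.
#'
#' @param nt A normalized trace ([normalize_trace()]).
#' @param window_s Fit window length in seconds (default 30).
#' @return A list of class `pump_rate`: `slope` (1/s), `rate = -slope`,
#'   `window`, `n_points`, `r_squared`.
#' @export
initial_rate <- function(nt, window_s = 30) {
  stopifnot(inherits(nt, "acma_trace"))
  t_mg <- attr(nt, "t_mg")
  sel <- nt$time_s >= t_mg & nt$time_s <= t_mg + window_s
  if (sum(sel) < 2)
    stop_config("insufficient data: %d sample(s) in the %g s fit window",
                sum(sel), window_s)
  fit <- stats::lm.fit(cbind(1, nt$time_s[sel]), nt$fluorescence[sel])
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((nt$fluorescence[sel] - mean(nt$fluorescence[sel]))^2)
  structure(list(slope = slope, rate = -slope,
                 window = c(t_mg, t_mg + window_s),
                 n_points = sum(sel),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "pump_rate")
}

#' Flag traces without a genuine fluorescence drop as inactive
#'
#' A trace is inactive when the mean signal just before CCCP addition is
#' less than 10% below the post-CCCP plateau. Exactly 10% below still counts
#' as active (strict reading of "less than 10% below"). The post-CCCP
#' plateau is the last `post_window_s` seconds of the trace, which must
#' start at least 10 s after CCCP addition to skip re-equilibration.
#'
#' @param nt A normalized trace.
#' @param pre_window_s Length (s) of the window ending at CCCP addition.
#' @param post_window_s Length (s) of the plateau window at the trace end.
#' @return `TRUE` if the trace is active.
#' @export
classify_active <- function(nt, pre_window_s = 5, post_window_s = 5) {
  stopifnot(inherits(nt, "acma_trace"))
  t_cccp <- attr(nt, "t_cccp")
  t_end <- nt$time_s[length(nt$time_s)]
  pre <- nt$time_s >= t_cccp - pre_window_s & nt$time_s < t_cccp
  post_start <- max(t_end - post_window_s, t_cccp + 10)
  post <- nt$time_s >= post_start
  if (!any(pre) || !any(post))
    stop_config("insufficient data: empty pre- or post-CCCP window")
  mean(nt$fluorescence[pre]) <= 0.90 * mean(nt$fluorescence[post])
}

#' Per-condition fold changes of pumping rates
#'
#' `fold(condition) = mean(active rates of condition) / mean(active rates of
#' reference)`; inactive traces are excluded from both.
#'
#' @param rates Named list: condition -> data frame with columns `rate` and
#'   `active` (or a list of `pump_rate` objects, all treated as active).
#' @param reference Name of the reference condition (e.g. `"PC"`).
#' @return Named numeric vector of fold changes (reference = 1).
#' @export
fold_changes <- function(rates, reference) {
  if (!reference %in% names(rates))
    stop_config("reference condition '%s' absent", reference)
  mean_active <- function(r) {
    if (is.data.frame(r)) {
      v <- r$rate[r$active]
    } else {
      v <- vapply(r, function(p) p$rate, 0)
    }
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  ref <- mean_active(rates[[reference]])
  if (!is.finite(ref) || ref == 0)
    stop_config("degenerate reference: mean active rate is %g", ref)
  vapply(rates, mean_active, 0) / ref
}

#' Analyze a batch of traces listed in a manifest
#'
#' The manifest TSV has columns `trace_path`, `condition`, `replicate`.
#' Each trace is normalized, classified, and its initial rate measured;
#' fold changes are computed over active traces against `reference`.
#'
#' @param manifest Path to the manifest TSV, or an equivalent data frame.
#'   Relative `trace_path`s are resolved against the manifest's directory.
#' @param reference Reference condition for fold changes.
#' @param window_s Initial-rate window (s).
#' @return List with `per_trace` (one row per trace: condition, replicate,
#'   rate, slope, r_squared, active) and `folds` (condition, fold).
#' @export
analyze_traces <- function(manifest, reference, window_s = 30) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- utils::read.table(manifest, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$trace_path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$trace_path[i])
    nt <- normalize_trace(read_trace(p))
    pr <- initial_rate(nt, window_s)
    data.frame(trace_path = manifest$trace_path[i],
               condition = manifest$condition[i],
               replicate = manifest$replicate[i],
               rate = pr$rate, slope = pr$slope,
               r_squared = pr$r_squared,
               n_points = pr$n_points,
               active = classify_active(nt),
               stringsAsFactors = FALSE)
  })
  per_trace <- do.call(rbind, rows)
  folds <- fold_changes(split(per_trace, per_trace$condition), reference)
  list(per_trace = per_trace,
       folds = data.frame(condition = names(folds), fold = unname(folds),
                          stringsAsFactors = FALSE))
}
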