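#' Photobleaching baseline correction of a fluorescence trace
#'
#' Fits the early, holding-period part of the trace (where the VSD is at
#' rest and all fluorescence change is photobleaching drift), extrapolates
#' the fitted trend over the whole sweep, and subtracts it. The fit window
#' defaults to the first 2 s at the holding potential.
#'
#' @param fluorescence numeric trace (arbitrary units).
#' @param time_s time of each sample (s), same length.
#' @param fit_window length of the initial window used for the fit (s).
#' @param holding_s duration of the holding period (s); the fit window must
#'   not exceed it.
#' @param model `"linear"` (default) or `"exponential"`
#'   (offset + amplitude * exp(-t/tau)).
#' @return list with `corrected` (trace minus extrapolated baseline),
#'   `baseline` (the fitted trend), `f0` (fitted baseline level at t = 0)
#'   and `model`.
#' @export
baseline_correct <- function(fluorescence, time_s, fit_window = 2,
                             holding_s = fit_window,
                             model = c("linear", "exponential")) {
  model <- match.arg(model)
  stopifnot(length(fluorescence) == length(time_s), fit_window > 0)
  if (fit_window > holding_s + 1e-9)
    stop("fit_window (", fit_window, " s) exceeds the holding period (",
         holding_s, " s)")
  idx <- time_s <= fit_window
  if (sum(idx) < 3) stop("too few samples in the baseline fit window")
  tw <- time_s[idx]; fw <- fluorescence[idx]

  if (model == "linear") {
    fit <- stats::lm(fw ~ tw)
    baseline <- unname(fit$coefficients[1] + fit$coefficients[2] * time_s)
  } else {
    # exponential decay with offset; fall back to linear if the nonlinear
    # fit cannot converge (e.g. an already-flat trace)
    amp0 <- fw[1] - fw[length(fw)]
    start <- list(c0 = fw[length(fw)],
                  a = if (abs(amp0) > 0) amp0 else 1e-3 * max(abs(fw), 1),
                  tau = max(diff(range(tw)), 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(fw ~ c0 + a * exp(-tw / tau), start = start,
                        lower = c(-Inf, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      lf <- stats::lm(fw ~ tw)
      baseline <- unname(lf$coefficients[1] + lf$coefficients[2] * time_s)
    } else {
      cf <- stats::coef(fit)
      baseline <- cf[["c0"]] + cf[["a"]] * exp(-time_s / cf[["tau"]])
    }
  }
  list(corrected = fluorescence - baseline, baseline = baseline,
       f0 = baseline[which.min(time_s)], model = model)
}

#' Fractional fluorescence change
#'
#' Elementwise dF/F: the baseline-subtracted trace divided by the baseline
#' fluorescence level.
#'
#' @param corrected baseline-subtracted fluorescence trace.
#' @param f0 baseline fluorescence level; must be > 0.
#' @return dF/F trace.
#' @export
compute_dff <- function(corrected, f0) {
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be positive")
  corrected / f0
}

.xy_curve <- function(voltage_mV, value, sem = NA_real_, n = 1L,
                      degenerate = FALSE) {
  ord <- order(voltage_mV)
  if (length(sem) == length(voltage_mV)) sem <- sem[ord]
  if (length(n) == length(voltage_mV)) n <- n[ord]
  structure(data.frame(voltage_mV = voltage_mV[ord], value = value[ord],
                       sem = sem, n = n),
            degenerate = degenerate, class = c("xy_curve", "data.frame"))
}

# noise scale of a recording channel, from detrended holding-period residuals
#' @noRd
.holding_noise <- function(x, time_s, holding_s) {
  idx <- time_s <= holding_s
  if (sum(idx) < 5) return(0)
  stats::sd(stats::residuals(stats::lm(x[idx] ~ time_s[idx])))
}

#' Extract the fluorescence-voltage (F-V) relationship
#'
#' Per sweep: baseline-correct the fluorescence, convert to dF/F, average
#' over a window at the end of the test pulse, then normalise the per-voltage
#' values to the maximum across voltages.
#'
#' @param rec a `vcf_recording` (see [simulate_vcf_recording()]).
#' @param end_window averaging window at the end of the test pulse (s).
#' @param baseline_model passed to [baseline_correct()].
#' @param fit_window baseline fit window (s).
#' @return an `xy_curve` (`voltage_mV`, `value`); `attr(, "degenerate")` is
#'   TRUE (with a warning) when the pre-normalisation maximum is below 5x the
#'   holding-period noise.
#' @export
extract_fv <- function(rec, end_window = 0.1,
                       baseline_model = c("linear", "exponential"),
                       fit_window = 2) {
  baseline_model <- match.arg(baseline_model)
  proto <- attr(rec, "protocol")
  if (is.null(proto)) stop("recording carries no protocol metadata")
  sweeps <- split(as.data.frame(rec), rec$sweep_id)
  if (length(sweeps) < 2) stop("need at least 2 sweeps to build an F-V curve")
  pulse_end <- proto$holding_s + proto$test_s
  vals <- vapply(sweeps, function(sw) {
    bc <- baseline_correct(sw$fluorescence, sw$time_s,
                           fit_window = min(fit_window, proto$holding_s),
                           holding_s = proto$holding_s, model = baseline_model)
    dff <- compute_dff(bc$corrected, bc$f0)
    win <- sw$time_s >= (pulse_end - end_window) & sw$time_s < pulse_end
    mean(dff[win])
  }, numeric(1))
  volts <- vapply(sweeps, function(sw) {
    sw$voltage_mV[which(sw$time_s >= proto$holding_s)[1]]
  }, numeric(1))
  noise <- mean(vapply(sweeps, function(sw) {
    bc <- baseline_correct(sw$fluorescence, sw$time_s,
                           fit_window = min(fit_window, proto$holding_s),
                           holding_s = proto$holding_s, model = baseline_model)
    .holding_noise(compute_dff(bc$corrected, bc$f0), sw$time_s, proto$holding_s)
  }, numeric(1)))
  .normalise_curve(volts, vals, noise, "F-V")
}

#' Extract the conductance-voltage (G-V) relationship from tail currents
#'
#' The instantaneous tail current after each test pulse is proportional to
#' the open probability reached at the pulse end, at a fixed driving force.
#' Per sweep the current is averaged over a short window after the tail step
#' (following a settle gap that skips the capacitive artifact region), then
#' normalised to the maximum across sweeps.
#'
#' @param rec a `vcf_recording`.
#' @param settle_s gap after the tail step before measuring (s).
#' @param window_s length of the averaging window (s).
#' @return an `xy_curve`; degenerate-normalisation flag as in [extract_fv()].
#' @export
extract_gv <- function(rec, settle_s = 0.001, window_s = 0.004) {
  proto <- attr(rec, "protocol")
  if (is.null(proto)) stop("recording carries no protocol metadata")
  if (proto$tail_s <= 0) stop("protocol has no tail step")
  tail_start <- proto$holding_s + proto$test_s
  if (settle_s + window_s > proto$tail_s)
    stop("tail measurement window extends past the tail step")
  sweeps <- split(as.data.frame(rec), rec$sweep_id)
  if (length(sweeps) < 2) stop("need at least 2 sweeps to build a G-V curve")
  vals <- vapply(sweeps, function(sw) {
    win <- sw$time_s >= tail_start + settle_s &
           sw$time_s < tail_start + settle_s + window_s
    if (!any(win)) stop("no samples fall inside the tail window")
    mean(sw$current[win])
  }, numeric(1))
  volts <- vapply(sweeps, function(sw) {
    sw$voltage_mV[which(sw$time_s >= proto$holding_s)[1]]
  }, numeric(1))
  noise <- mean(vapply(sweeps, function(sw) {
    .holding_noise(sw$current, sw$time_s, proto$holding_s)
  }, numeric(1)))
  .normalise_curve(volts, vals, noise, "G-V")
}

# Normalise to max, flagging degenerate (no-signal) curves rather than
# silently normalising noise.
#' @noRd
.normalise_curve <- function(volts, vals, noise, what) {
  m <- max(vals)
  degenerate <- FALSE
  if (!is.finite(m) || m <= 5 * noise || m <= 0) {
    degenerate <- TRUE
    warning(what, " normalisation is degenerate: maximum response (", signif(m, 3),
            ") is below 5x the holding-period noise (", signif(noise, 3), ")")
    scale <- if (is.finite(m) && abs(m) > 0) m else 1
  } else {
    scale <- m
  }
  .xy_curve(volts, vals / scale, degenerate = degenerate)
}

#' Write / read an XY curve (F-V or G-V) as delimited text
#' @param curve an `xy_curve`.
#' @param path file path.
#' @export
write_xy_curve <- function(curve, path) write_tsv(as.data.frame(curve), path)

#' @rdname write_xy_curve
#' @export
read_xy_curve <- function(path) {
  df <- read_tsv(path)
  .xy_curve(df$voltage_mV, df$value,
            sem = df$sem %||% NA_real_, n = df$n %||% 1L)
}
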