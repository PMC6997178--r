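#' Boltzmann voltage-dependence functions
#'
#' Single and double Boltzmann curves used to fit G-V and F-V relationships:
#' \deqn{B(V) = 1 / (1 + \exp(-z (V - V_{1/2}) / V_T))}
#' where `z` is the equivalent gating valence (e0) and `V_half` the midpoint.
#' The double form is the amplitude-weighted sum of two components,
#' \eqn{A_1 B_1(V) + (1 - A_1) B_2(V)}.
#'
#' @param v voltage (mV); vectorised.
#' @param z,z1,z2 equivalent valence (e0).
#' @param v_half,v1_half,v2_half midpoint voltage (mV).
#' @param a1 amplitude of the first component, in (0, 1).
#' @param v_t thermal voltage (mV), see [thermal_voltage()].
#' @return value(s) in (0, 1).
#' @export
#' @examples
#' boltzmann(-20, z = 2, v_half = -20)   # 0.5 at the midpoint
boltzmann <- function(v, z, v_half, v_t = thermal_voltage()) {
  stopifnot(v_t > 0)
  1 / (1 + exp(-z * (v - v_half) / v_t))
}

#' @rdname boltzmann
#' @export
double_boltzmann <- function(v, a1, z1, v1_half, z2, v2_half,
                             v_t = thermal_voltage()) {
  a1 * boltzmann(v, z1, v1_half, v_t) +
    (1 - a1) * boltzmann(v, z2, v2_half, v_t)
}

.fit_result <- function(pars, rss, se, converged, model, message = NULL) {
  structure(list(pars = pars, rss = rss, se = se, converged = converged,
                 model = model, message = message),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("%s Boltzmann fit (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  if (x$converged) {
    print(round(x$pars, 4))
    cat(sprintf("  RSS = %.4g\n", x$rss))
  } else if (!is.null(x$message)) cat("  ", x$message, "\n")
  invisible(x)
}

# 95% confidence half-widths from the nls fit, NA when unavailable
#' @noRd
.fit_se <- function(fit) {
  tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    1.96 * s
  }, error = function(e) NULL)
}

#' Fit a single Boltzmann to a normalised curve
#'
#' Least-squares fit of `(z, v_half)` (optionally with a free amplitude) to
#' an `xy_curve`. Flat or otherwise unidentifiable curves return a
#' non-converged result rather than silent estimates.
#'
#' @param curve an `xy_curve` (see [extract_gv()]) or data frame with columns
#'   `voltage_mV`, `value`.
#' @param v_t thermal voltage (mV).
#' @param free_amplitude if TRUE, fit `amp * B(V)` with `amp` free.
#' @param z_bounds,v_half_bounds box constraints on the parameters.
#' @return a `boltzmann_fit` with elements `pars`, `rss`, `se` (95%
#'   half-widths), `converged`.
#' @export
fit_boltzmann <- function(curve, v_t = thermal_voltage(),
                          free_amplitude = FALSE,
                          z_bounds = c(1e-3, 10),
                          v_half_bounds = c(-150, 100)) {
  v <- curve$voltage_mV; y <- curve$value
  if (length(v) < 4) stop("need at least 4 points to fit a Boltzmann")
  if (stats::sd(y) < 1e-12)
    return(.fit_result(NULL, NA, NULL, FALSE, "single", "flat curve"))
  # midpoint start: voltage where the curve crosses half its range
  v0 <- v[which.min(abs(y - (min(y) + max(y)) / 2))]
  starts <- expand.grid(z = c(0.5, 1, 2, 4),
                        v_half = unique(c(v0, unname(stats::quantile(v, c(0.25, 0.5, 0.75))))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (free_amplitude) {
        minpack.lm::nlsLM(
          y ~ amp / (1 + exp(-z * (v - v_half) / v_t)),
          start = list(amp = max(y), z = starts$z[i], v_half = starts$v_half[i]),
          lower = c(1e-6, z_bounds[1], v_half_bounds[1]),
          upper = c(2, z_bounds[2], v_half_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          y ~ 1 / (1 + exp(-z * (v - v_half) / v_t)),
          start = list(z = starts$z[i], v_half = starts$v_half[i]),
          lower = c(z_bounds[1], v_half_bounds[1]),
          upper = c(z_bounds[2], v_half_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(.fit_result(NULL, NA, NULL, FALSE, "single", "no start converged"))
  pars <- stats::coef(best$fit)
  # a midpoint pinned at a bound means the transition was not spanned
  at_bound <- pars[["v_half"]] <= v_half_bounds[1] + 1e-6 ||
              pars[["v_half"]] >= v_half_bounds[2] - 1e-6
  if (at_bound)
    return(.fit_result(pars, best$rss, NULL, FALSE, "single",
                       "midpoint at parameter bound"))
  .fit_result(pars, best$rss, .fit_se(best$fit), TRUE, "single")
}

#' Fit a double Boltzmann to a normalised curve
#'
#' Fits `(a1, z1, v1_half, z2, v2_half)` with `a2 = 1 - a1` implied, using a
#' multi-start grid over the two midpoints (`n_grid` x `n_grid` quantile
#' pairs); the lowest-residual start wins, ties broken by smaller `a1`.
#' Components are reported ordered so `v1_half < v2_half`. Fits where the
#' two midpoints collapse (closer than `degeneracy_mV`) or where `a1` hits
#' 0/1 carry a degeneracy warning flag.
#'
#' @inheritParams fit_boltzmann
#' @param n_grid per-axis size of the midpoint start grid.
#' @param degeneracy_mV midpoint separation below which the two components
#'   are declared degenerate.
#' @param free_scale if TRUE, fit `c0 + amp * (a1 B1 + (1-a1) B2)` with a
#'   free offset and scale. Useful for curves referenced to a holding
#'   potential at which the VSD is not fully at rest, so the normalised
#'   data do not run from 0 to 1.
#' @return a `boltzmann_fit`; `$degenerate` is TRUE when the two components
#'   are not separable.
#' @export
fit_double_boltzmann <- function(curve, v_t = thermal_voltage(),
                                 n_grid = 5, degeneracy_mV = 5,
                                 z_bounds = c(1e-3, 10),
                                 v_half_bounds = c(-150, 100),
                                 free_scale = FALSE) {
  v <- curve$voltage_mV; y <- curve$value
  if (length(v) < 7) stop("need at least 7 points to fit a double Boltzmann")
  if (stats::sd(y) < 1e-12)
    return(.fit_result(NULL, NA, NULL, FALSE, "double", "flat curve"))
  qs <- unname(stats::quantile(v, probs = seq(0.1, 0.9, length.out = n_grid)))
  grid <- expand.grid(v1 = qs, v2 = qs)
  grid <- grid[grid$v1 < grid$v2, , drop = FALSE]
  grid <- rbind(grid, data.frame(v1 = min(v), v2 = max(v)))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch({
      if (free_scale) {
        minpack.lm::nlsLM(
          y ~ c0 + amp * (a1 / (1 + exp(-z1 * (v - v1_half) / v_t)) +
            (1 - a1) / (1 + exp(-z2 * (v - v2_half) / v_t))),
          start = list(c0 = min(y), amp = diff(range(y)), a1 = 0.5,
                       z1 = 2, v1_half = grid$v1[i], z2 = 2,
                       v2_half = grid$v2[i]),
          lower = c(-0.5, 1e-3, 0, z_bounds[1], v_half_bounds[1],
                    z_bounds[1], v_half_bounds[1]),
          upper = c(0.5, 2, 1, z_bounds[2], v_half_bounds[2],
                    z_bounds[2], v_half_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          y ~ a1 / (1 + exp(-z1 * (v - v1_half) / v_t)) +
            (1 - a1) / (1 + exp(-z2 * (v - v2_half) / v_t)),
          start = list(a1 = 0.5, z1 = 2, v1_half = grid$v1[i],
                       z2 = 2, v2_half = grid$v2[i]),
          lower = c(0, z_bounds[1], v_half_bounds[1], z_bounds[1],
                    v_half_bounds[1]),
          upper = c(1, z_bounds[2], v_half_bounds[2], z_bounds[2],
                    v_half_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    a1 <- stats::coef(fit)[["a1"]]
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && a1 < best$a1)) {
      best <- list(fit = fit, rss = rss, a1 = a1)
    }
  }
  if (is.null(best))
    return(.fit_result(NULL, NA, NULL, FALSE, "double", "no start converged"))
  pars <- stats::coef(best$fit)
  se <- .fit_se(best$fit)
  # enforce component ordering V1/2(1) < V1/2(2)
  if (pars[["v1_half"]] > pars[["v2_half"]]) {
    sw <- c(z1 = "z2", z2 = "z1", v1_half = "v2_half", v2_half = "v1_half")
    old <- pars
    for (k in names(sw)) pars[[k]] <- old[[sw[[k]]]]
    pars[["a1"]] <- 1 - old[["a1"]]
    if (!is.null(se)) {
      old_se <- se
      for (k in names(sw)) se[[k]] <- old_se[[sw[[k]]]]
    }
  }
  degenerate <- abs(pars[["v2_half"]] - pars[["v1_half"]]) < degeneracy_mV ||
    pars[["a1"]] < 1e-3 || pars[["a1"]] > 1 - 1e-3
  if (degenerate)
    warning("double-Boltzmann components are degenerate (collapsed midpoints ",
            "or vanishing amplitude); consider a single-component fit")
  res <- .fit_result(pars, best$rss, se, TRUE, "double")
  res$degenerate <- degenerate
  res
}

#' Serialise a fit report as JSON
#' @param fit a `boltzmann_fit`.
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  atomic_write(function(tmp) {
    jsonlite::write_json(list(model = fit$model, converged = fit$converged,
                              pars = as.list(fit$pars), rss = fit$rss,
                              ci95_halfwidth = as.list(fit$se),
                              degenerate = fit$degenerate %||% FALSE),
                         tmp, auto_unbox = TRUE, digits = NA, null = "null")
  }, path)
}
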