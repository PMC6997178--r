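#' Two-step voltage-sensor gating scheme with two open states
#'
#' Builds the simplified kinetic scheme used throughout the package: a single
#' voltage-sensor domain (VSD) moving Resting -> Intermediate -> Activated
#' (R <-> I <-> A), with the pore conducting in both the intermediate-open
#' (IO) and activated-open (AO) states. Each transition has an Eyring-form
#' rate \eqn{k(V) = k_0 \exp(\pm z V / V_T)}. The scheme is parameterised by
#' the midpoint voltage, total gating charge and midpoint rate of each VSD
#' step, from which the four pre-exponential rates are derived with the
#' charge split evenly between the forward and backward barriers.
#'
#' Default midpoints (-50 and +40 mV) place the two fluorescence components
#' far apart, as observed for KV7.1 VCF recordings; the rates and the
#' AO/IO conductance ratio are calibration choices, not measured values.
#' The barrier asymmetry `phi` puts most of each step's charge on the
#' forward barrier, so deactivation at a moderately negative tail potential
#' is slow (KV7.1 deactivates slowly) and instantaneous tail currents
#' faithfully report the open probability at the end of the test pulse.
#'
#' @param v1_half,v2_half midpoint voltage (mV) of the R<->I and I<->A steps.
#' @param z1,z2 total gating charge (e0) moved in each step.
#' @param k1_mid,k2_mid forward ( = backward) rate (1/s) of each step at its
#'   midpoint voltage; sets the relaxation speed.
#' @param phi fraction of each step's charge on the forward barrier, in
#'   (0, 1); the backward rate carries `(1 - phi) * z`.
#' @param g_io,g_ao relative conductances of the IO and AO open states
#'   (dimensionless, >= 0). Default AO/IO ratio 4 so AO dominates.
#' @param f1_amp,f2_amp fluorescence amplitudes (dF/F units) reporting the
#'   first and second VSD transitions.
#' @param e_k reversal potential (mV).
#' @param v_t thermal voltage (mV); see [thermal_voltage()].
#' @return an object of class `gating_scheme`.
#' @export
#' @examples
#' s <- gating_scheme()
#' steady_state_occupancy(s, v = 0)
gating_scheme <- function(v1_half = -50, v2_half = 40, z1 = 2, z2 = 2,
                          k1_mid = 10, k2_mid = 2, phi = 0.75,
                          g_io = 0.25, g_ao = 1,
                          f1_amp = 0.6, f2_amp = 0.4,
                          e_k = -90, v_t = thermal_voltage()) {
  stopifnot(k1_mid > 0, k2_mid > 0, g_io >= 0, g_ao >= 0, v_t > 0,
            z1 > 0, z2 > 0, phi > 0, phi < 1)
  s <- list(
    # forward/backward pre-exponentials: k_f(V) = kf0 exp(+z_f V/V_T),
    # k_b(V) = kb0 exp(-z_b V/V_T), with z_f = phi z and z_b = (1 - phi) z
    # so the equilibrium constant is K(V) = exp(z (V - V_half)/V_T).
    a1_0 = k1_mid * exp(-(phi * z1) * v1_half / v_t), z_a1 = phi * z1,
    b1_0 = k1_mid * exp(((1 - phi) * z1) * v1_half / v_t),
    z_b1 = (1 - phi) * z1,
    a2_0 = k2_mid * exp(-(phi * z2) * v2_half / v_t), z_a2 = phi * z2,
    b2_0 = k2_mid * exp(((1 - phi) * z2) * v2_half / v_t),
    z_b2 = (1 - phi) * z2,
    v1_half = v1_half, v2_half = v2_half, z1 = z1, z2 = z2,
    g_io = g_io, g_ao = g_ao, f1_amp = f1_amp, f2_amp = f2_amp,
    e_k = e_k, v_t = v_t
  )
  class(s) <- "gating_scheme"
  s
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("Two-step VSD gating scheme (R <-> I <-> A)\n")
  cat(sprintf("  step 1: V1/2 = %g mV, z = %g e0, midpoint rate %g /s\n",
              x$v1_half, x$z1, x$a1_0 * exp(x$z_a1 * x$v1_half / x$v_t)))
  cat(sprintf("  step 2: V1/2 = %g mV, z = %g e0, midpoint rate %g /s\n",
              x$v2_half, x$z2, x$a2_0 * exp(x$z_a2 * x$v2_half / x$v_t)))
  cat(sprintf("  conductances g_IO = %g, g_AO = %g; E_K = %g mV\n",
              x$g_io, x$g_ao, x$e_k))
  invisible(x)
}

.check_scheme <- function(scheme) {
  if (!inherits(scheme, "gating_scheme"))
    stop("`scheme` must be a gating_scheme object")
  rates <- c(scheme$a1_0, scheme$b1_0, scheme$a2_0, scheme$b2_0)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("invalid scheme: all pre-exponential rates must be positive")
  if (scheme$g_io < 0 || scheme$g_ao < 0)
    stop("invalid scheme: conductances must be >= 0")
  invisible(scheme)
}

#' Construct modifier: mutation / auxiliary-subunit effects
#'
#' Describes how a construct (mutant, co-expressed subunit, or their
#' combination) perturbs the wild-type scheme: scaling of the IO and AO
#' conductances (e.g. KCNE1-like or F351A-like suppression of IO, AO-specific
#' coupling loss), VSD locking in the intermediate or activated conformation
#' (charge-swap backgrounds), an overall expression factor, and a rigid
#' voltage shift of both VSD steps (used to inject known activation-energy
#' perturbations for double-mutant-cycle benchmarks).
#'
#' @param label construct name.
#' @param g_io_scale,g_ao_scale conductance scale factors in `[0, 1]`.
#' @param lock one of `"none"`, `"locked_intermediate"`, `"locked_activated"`.
#' @param expression expression factor (>= 0) scaling both current and
#'   fluorescence signal.
#' @param dv_shift rigid shift (mV) applied to both step midpoints.
#' @return an object of class `construct_modifier`.
#' @export
construct_modifier <- function(label = "WT", g_io_scale = 1, g_ao_scale = 1,
                               lock = c("none", "locked_intermediate",
                                        "locked_activated"),
                               expression = 1, dv_shift = 0) {
  lock <- match.arg(lock)
  stopifnot(g_io_scale >= 0, g_io_scale <= 1, g_ao_scale >= 0, g_ao_scale <= 1,
            expression >= 0, is.finite(dv_shift))
  structure(list(label = label, g_io_scale = g_io_scale,
                 g_ao_scale = g_ao_scale, lock = lock,
                 expression = expression, dv_shift = dv_shift),
            class = "construct_modifier")
}

#' Combine two construct modifiers
#'
#' Conductance scales and expression factors multiply, voltage shifts add,
#' and any VSD lock overrides `"none"` (two conflicting locks are an error).
#' Used to compose a mutant with a background manoeuvre such as KCNE1
#' co-expression or a charge-swap lock.
#'
#' @param m1,m2 `construct_modifier` objects.
#' @return combined `construct_modifier`.
#' @export
combine_modifiers <- function(m1, m2) {
  locks <- setdiff(c(m1$lock, m2$lock), "none")
  if (length(unique(locks)) > 1)
    stop("cannot combine two different VSD locks")
  construct_modifier(
    label = paste(m1$label, m2$label, sep = "+"),
    g_io_scale = m1$g_io_scale * m2$g_io_scale,
    g_ao_scale = m1$g_ao_scale * m2$g_ao_scale,
    lock = if (length(locks)) locks[[1]] else "none",
    expression = m1$expression * m2$expression,
    dv_shift = m1$dv_shift + m2$dv_shift
  )
}

# Voltage-dependent rates of the modified scheme at voltage v (mV).
#' @noRd
.scheme_rates <- function(scheme, modifier, v) {
  ve <- v - (modifier$dv_shift %||% 0)
  list(
    a1 = scheme$a1_0 * exp(scheme$z_a1 * ve / scheme$v_t),
    b1 = scheme$b1_0 * exp(-scheme$z_b1 * ve / scheme$v_t),
    a2 = scheme$a2_0 * exp(scheme$z_a2 * ve / scheme$v_t),
    b2 = scheme$b2_0 * exp(-scheme$z_b2 * ve / scheme$v_t)
  )
}

.null_modifier <- function(modifier) modifier %||% construct_modifier()

#' Steady-state occupancancies of the three-state scheme
#'
#' Equilibrium occupancies of the R, I and A states at voltage `v`. For a
#' reversible linear chain these follow detailed balance,
#' \eqn{(P_R, P_I, P_A) \propto (1, K_1, K_1 K_2)} with
#' \eqn{K_1 = \alpha_1/\beta_1} and \eqn{K_2 = \alpha_2/\beta_2}.
#' VSD-locked modifiers pin the occupancy at the locked state.
#'
#' @param scheme a [gating_scheme()].
#' @param modifier optional [construct_modifier()].
#' @param v voltage(s), mV; vectorised.
#' @return matrix with columns `p_r`, `p_i`, `p_a`, one row per voltage.
#' @export
steady_state_occupancy <- function(scheme, modifier = NULL, v) {
  .check_scheme(scheme)
  modifier <- .null_modifier(modifier)
  stopifnot(all(is.finite(v)))
  n <- length(v)
  if (modifier$lock == "locked_intermediate")
    return(cbind(p_r = rep(0, n), p_i = rep(1, n), p_a = rep(0, n)))
  if (modifier$lock == "locked_activated")
    return(cbind(p_r = rep(0, n), p_i = rep(0, n), p_a = rep(1, n)))
  r <- .scheme_rates(scheme, modifier, v)
  k1 <- r$a1 / r$b1
  k2 <- r$a2 / r$b2
  z <- 1 + k1 + k1 * k2
  cbind(p_r = 1 / z, p_i = k1 / z, p_a = k1 * k2 / z)
}

# Generator matrix Q (dp/dt = Q p) of the chain at voltage v.
#' @noRd
.generator <- function(scheme, modifier, v) {
  r <- .scheme_rates(scheme, modifier, v)
  matrix(c(-r$a1,        r$b1,          0,
            r$a1, -(r$b1 + r$a2),    r$b2,
               0,        r$a2,     -r$b2),
         nrow = 3, byrow = TRUE)
}

# Occupancy time-course p(t) for t >= 0 at fixed voltage, from initial p0,
# via eigendecomposition of the generator (exact for this 3-state chain;
# eigenvalues of a reversible birth-death chain are real).
#' @noRd
.relax <- function(scheme, modifier, v, p0, t) {
  q <- .generator(scheme, modifier, v)
  eg <- eigen(q)
  vec <- Re(eg$vectors)
  val <- Re(eg$values)
  coef <- solve(vec, p0)
  out <- matrix(0, length(t), 3)
  for (k in 1:3) out <- out + outer(exp(val[k] * t), coef[k] * vec[, k])
  colnames(out) <- c("p_r", "p_i", "p_a")
  out
}

#' Relaxation of occupancies after a voltage step
#'
#' Solves the three-state master equation for a step from `v_from` (where the
#' system sits at steady state) to `v_to`, on a uniform time grid. With a
#' VSD-locked modifier the occupancy is constant at the locked state.
#'
#' @inheritParams steady_state_occupancy
#' @param v_from,v_to pre- and post-step voltages (mV).
#' @param duration total simulated time (s).
#' @param dt time step of the output grid (s); must be < `duration`.
#' @return data frame with columns `time_s`, `p_r`, `p_i`, `p_a`.
#' @export
simulate_relaxation <- function(scheme, modifier = NULL, v_from, v_to,
                                duration, dt) {
  .check_scheme(scheme)
  modifier <- .null_modifier(modifier)
  if (!(duration > 0) || !(dt > 0)) stop("duration and dt must be > 0")
  if (dt >= duration) stop("dt must be smaller than duration")
  t <- seq(0, duration, by = dt)
  p0 <- drop(steady_state_occupancy(scheme, modifier, v_from))
  if (modifier$lock != "none") {
    occ <- matrix(rep(p0, each = length(t)), ncol = 3,
                  dimnames = list(NULL, c("p_r", "p_i", "p_a")))
  } else {
    occ <- .relax(scheme, modifier, v_to, p0, t)
  }
  data.frame(time_s = t, occ)
}

#' Voltage-clamp protocol
#'
#' Standard VCF protocol: a holding period (long enough to fit the
#' photobleaching baseline), one test pulse per sweep, and a tail step at
#' fixed voltage for instantaneous-tail conductance measurement.
#'
#' @param holding_mV holding potential (mV).
#' @param holding_s holding duration (s); the baseline fit window must fit in
#'   it.
#' @param test_mV vector of test-pulse voltages (mV), one sweep each.
#' @param test_s test-pulse duration (s).
#' @param tail_mV tail-step voltage (mV).
#' @param tail_s tail-step duration (s).
#' @param dt sample interval (s).
#' @return an object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_mV = -80, holding_s = 2,
                             test_mV = seq(-100, 60, by = 20), test_s = 4,
                             tail_mV = -40, tail_s = 0.5, dt = 0.001) {
  stopifnot(holding_s >= 0, test_s > 0, tail_s >= 0, dt > 0,
            length(test_mV) >= 1)
  structure(list(holding_mV = holding_mV, holding_s = holding_s,
                 test_mV = test_mV, test_s = test_s,
                 tail_mV = tail_mV, tail_s = tail_s, dt = dt),
            class = "voltage_protocol")
}

# Per-sweep deterministic signals on the protocol time grid.
#' @noRd
.sweep_signals <- function(scheme, modifier, protocol, v_test) {
  dt <- protocol$dt
  t_hold <- seq(0, protocol$holding_s - dt, by = dt)
  t_test <- seq(0, protocol$test_s - dt, by = dt)
  t_tail <- seq(0, protocol$tail_s - dt, by = dt)

  p_hold0 <- drop(steady_state_occupancy(scheme, modifier, protocol$holding_mV))
  if (modifier$lock != "none") {
    occ_hold <- matrix(rep(p_hold0, each = length(t_hold)), ncol = 3)
    occ_test <- matrix(rep(p_hold0, each = length(t_test)), ncol = 3)
    occ_tail <- matrix(rep(p_hold0, each = length(t_tail)), ncol = 3)
  } else {
    occ_hold <- matrix(rep(p_hold0, each = length(t_hold)), ncol = 3)
    occ_test <- .relax(scheme, modifier, v_test, p_hold0, t_test)
    occ_tail <- .relax(scheme, modifier, protocol$tail_mV,
                       occ_test[nrow(occ_test), ], t_tail)
  }
  time_s <- c(t_hold,
              protocol$holding_s + t_test,
              protocol$holding_s + protocol$test_s + t_tail)
  voltage <- c(rep(protocol$holding_mV, length(t_hold)),
               rep(v_test, length(t_test)),
               rep(protocol$tail_mV, length(t_tail)))
  occ <- rbind(occ_hold, occ_test, occ_tail)
  list(time_s = time_s, voltage_mV = voltage, occ = occ)
}

#' Simulate a voltage-clamp fluorometry recording
#'
#' Generates simultaneous current and fluorescence traces for every test
#' voltage of a protocol. The fluorescence reports VSD movement through the
#' two transition amplitudes, multiplied by a mono-exponential photobleaching
#' decay; the current is ohmic through the two open states:
#' \deqn{F(t) = F_0 e^{-t/\tau}\,[1 + A_1 (P_I + P_A) + A_2 P_A] + \epsilon}
#' \deqn{I(t) = E\,(g_{IO} P_I + g_{AO} P_A)\,(V - E_K) + \epsilon}
#' with additive Gaussian noise per sample. The same seed always produces the
#' same recording.
#'
#' @inheritParams steady_state_occupancy
#' @param protocol a [voltage_protocol()]; must include a holding period
#'   (baseline correction downstream requires it).
#' @param bleach_tau photobleaching time constant (s); `Inf` disables
#'   bleaching.
#' @param f0 baseline fluorescence level (arbitrary units).
#' @param noise_sd named vector `c(current = ..., fluorescence = ...)` of
#'   additive noise standard deviations; scalars are recycled to both.
#' @param seed integer seed; mandatory when noise is non-zero.
#' @return a `vcf_recording`: data frame (`time_s`, `voltage_mV`, `current`,
#'   `fluorescence`, `sweep_id`) with the protocol and construct label
#'   attached as attributes.
#' @export
simulate_vcf_recording <- function(scheme, modifier = NULL, protocol = voltage_protocol(),
                                   bleach_tau = 30, f0 = 1,
                                   noise_sd = c(current = 0, fluorescence = 0),
                                   seed = NULL) {
  .check_scheme(scheme)
  modifier <- .null_modifier(modifier)
  if (!inherits(protocol, "voltage_protocol")) stop("need a voltage_protocol")
  if (protocol$holding_s <= 0)
    stop("protocol has no holding period; baseline correction downstream requires one")
  if (length(noise_sd) == 1) noise_sd <- c(current = unname(noise_sd),
                                           fluorescence = unname(noise_sd))
  if (any(noise_sd > 0) && is.null(seed))
    stop("`seed` is required when noise_sd > 0")

  build <- function() {
    sweeps <- lapply(seq_along(protocol$test_mV), function(i) {
      sg <- .sweep_signals(scheme, modifier, protocol, protocol$test_mV[i])
      p_i <- sg$occ[, 2]; p_a <- sg$occ[, 3]
      bleach <- if (is.finite(bleach_tau)) exp(-sg$time_s / bleach_tau) else 1
      fluor <- f0 * bleach *
        (1 + modifier$expression * (scheme$f1_amp * (p_i + p_a) +
                                    scheme$f2_amp * p_a))
      cur <- modifier$expression *
        (scheme$g_io * modifier$g_io_scale * p_i +
         scheme$g_ao * modifier$g_ao_scale * p_a) *
        (sg$voltage_mV - scheme$e_k)
      n <- length(sg$time_s)
      data.frame(time_s = sg$time_s, voltage_mV = sg$voltage_mV,
                 current = cur + stats::rnorm(n, 0, noise_sd[["current"]]),
                 fluorescence = fluor + stats::rnorm(n, 0, noise_sd[["fluorescence"]]),
                 sweep_id = i)
    })
    do.call(rbind, sweeps)
  }
  rec <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(rec, protocol = protocol, label = modifier$label,
            class = c("vcf_recording", "data.frame"))
}

#' Write / read a VCF recording as tidy delimited text
#'
#' Columns `time_s`, `voltage_mV`, `current`, `fluorescence`, `sweep_id`;
#' the protocol travels in a `# protocol:` JSON header line.
#'
#' @param rec a `vcf_recording`.
#' @param path file path.
#' @return the path ([write_vcf_recording()]) or a `vcf_recording`
#'   ([read_vcf_recording()]).
#' @export
write_vcf_recording <- function(rec, path) {
  proto <- attr(rec, "protocol")
  atomic_write(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste0("# protocol: ", jsonlite::toJSON(unclass(proto),
                                                       auto_unbox = TRUE,
                                                       digits = NA)), con)
    writeLines(paste0("# label: ", attr(rec, "label") %||% ""), con)
    utils::write.table(as.data.frame(rec), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' @rdname write_vcf_recording
#' @export
read_vcf_recording <- function(path) {
  lines <- readLines(path, n = 5)
  proto_line <- grep("^# protocol: ", lines, value = TRUE)
  label_line <- grep("^# label: ", lines, value = TRUE)
  proto <- NULL
  if (length(proto_line)) {
    proto <- jsonlite::fromJSON(sub("^# protocol: ", "", proto_line[[1]]))
    class(proto) <- "voltage_protocol"
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(df, protocol = proto,
            label = if (length(label_line)) sub("^# label: ", "", label_line[[1]]) else NULL,
            class = c("vcf_recording", "data.frame"))
}
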