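# Synthetic VCF panels with known ground truth: phenotype constructs and
# double-mutant-cycle quadruples with an injected coupling energy.

#' Effective single-Boltzmann parameters of a scheme's analytic G-V
#'
#' Computes the noiseless steady-state G-V of a (modified) scheme over a
#' voltage grid and fits a single Boltzmann, giving the effective `(z,
#' V1/2)` that the tail-current pipeline would recover. Used to translate
#' an injected coupling energy into a midpoint shift and back.
#'
#' @inheritParams steady_state_occupancy
#' @param v voltage grid (mV).
#' @return named vector `c(z = , v_half = )`.
#' @export
gv_effective_params <- function(scheme, modifier = NULL,
                                v = seq(-120, 80, by = 10)) {
  modifier <- .null_modifier(modifier)
  occ <- steady_state_occupancy(scheme, modifier, v)
  g <- scheme$g_io * modifier$g_io_scale * occ[, "p_i"] +
       scheme$g_ao * modifier$g_ao_scale * occ[, "p_a"]
  curve <- .xy_curve(v, g / max(g))
  fit <- fit_boltzmann(curve, v_t = scheme$v_t, free_amplitude = TRUE)
  if (!fit$converged) stop("effective G-V fit did not converge")
  c(z = unname(fit$pars[["z"]]), v_half = unname(fit$pars[["v_half"]]))
}

#' Standard phenotype construct modifiers
#'
#' The synthetic analogues of the benchmark constructs: wild type;
#' a classic coupling-loss mutant (VSD moves, neither open state conducts);
#' an AO-specific loss mutant (only the intermediate-open conductance
#' remains); an expression null; plus the background manoeuvres used by the
#' four-test classifier (KCNE1-like and F351A-like IO suppression, and the
#' two VSD-locking charge-swap backgrounds).
#'
#' @return named list of [construct_modifier()] objects.
#' @export
phenotype_modifiers <- function() {
  list(
    WT_like = construct_modifier("WT"),
    classic_EM_loss = construct_modifier("classicLoss", g_io_scale = 0,
                                         g_ao_scale = 0),
    AO_specific_loss = construct_modifier("aoLoss", g_ao_scale = 0),
    expression_null = construct_modifier("null", expression = 0),
    kcne1 = construct_modifier("KCNE1", g_io_scale = 0),
    f351a = construct_modifier("F351A", g_io_scale = 0),
    locked_intermediate = construct_modifier("E1R/R2E",
                                             lock = "locked_intermediate"),
    locked_activated = construct_modifier("E1R/R4E",
                                          lock = "locked_activated")
  )
}

#' Panel specification for synthetic VCF data
#'
#' @param constructs named list of [construct_modifier()] objects; default
#'   the four phenotype classes of [phenotype_modifiers()].
#' @param dmc_deltas coupling energies (kcal/mol) injected into
#'   double-mutant-cycle quadruples; one quadruple per value.
#' @param dmc_shift_mVs midpoint shifts (mV) of the two single mutants in
#'   each quadruple.
#' @param protocol a [voltage_protocol()].
#' @param scheme a [gating_scheme()].
#' @param bleach_tau photobleaching time constant (s).
#' @param noise_sd named noise SDs, see [simulate_vcf_recording()].
#' @param seed integer seed (mandatory).
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(constructs = phenotype_modifiers()[1:4],
                       dmc_deltas = numeric(0),
                       dmc_shift_mVs = c(20, 10),
                       protocol = voltage_protocol(),
                       scheme = gating_scheme(),
                       bleach_tau = 30,
                       noise_sd = c(current = 0.3, fluorescence = 0.002),
                       seed = 1) {
  structure(list(constructs = constructs, dmc_deltas = dmc_deltas,
                 dmc_shift_mVs = dmc_shift_mVs, protocol = protocol,
                 scheme = scheme, bleach_tau = bleach_tau,
                 noise_sd = noise_sd, seed = seed),
            class = "panel_spec")
}

#' Modifiers of a double-mutant-cycle quadruple with injected coupling
#'
#' Builds wild type, two single mutants and the double mutant as rigid
#' midpoint shifts of the gating scheme. Single-mutant shifts are additive
#' in voltage; the double mutant carries the extra shift
#' \eqn{\delta V = -\delta / (z_{eff} F)} that encodes the injected
#' coupling energy `delta` through the G-V-derived activation energy.
#'
#' @param scheme the wild-type [gating_scheme()].
#' @param delta injected coupling energy (kcal/mol).
#' @param shifts length-2 midpoint shifts (mV) of the two single mutants.
#' @param base background modifier shared by all four constructs. The
#'   default suppresses the IO conductance so each construct's G-V is a
#'   clean single-Boltzmann transition (the activated-open step), matching
#'   the single-Boltzmann energy analysis downstream; with the full
#'   two-component conductance the single-Boltzmann activation energy is
#'   not a well-posed quantity to recover.
#' @return list of four modifiers (`wt`, `mut1`, `mut2`, `double`) plus the
#'   effective wild-type `z` used for the energy-to-voltage conversion.
#' @export
dmc_quadruple <- function(scheme, delta, shifts = c(20, 10),
                          base = construct_modifier("dmc", g_io_scale = 0)) {
  eff <- gv_effective_params(scheme, base)
  dv_delta <- -delta * 1000 / (eff[["z"]] * FARADAY_KCAL)
  mk <- function(label, dv)
    combine_modifiers(base, construct_modifier(label, dv_shift = dv))
  list(
    wt = mk("wt", 0),
    mut1 = mk("mut1", shifts[1]),
    mut2 = mk("mut2", shifts[2]),
    double = mk("double", shifts[1] + shifts[2] + dv_delta),
    z_eff = eff[["z"]]
  )
}

#' Generate a synthetic VCF panel with ground truth
#'
#' Simulates one recording per construct (phenotype constructs plus
#' double-mutant-cycle quadruples with injected coupling energies) and
#' returns the recordings together with a ground-truth table sufficient to
#' score every downstream classifier and estimator. Identical specs and
#' seeds give identical output.
#'
#' @param spec a [panel_spec()].
#' @return list with `recordings` (named list of `vcf_recording`) and
#'   `truth` (data frame: construct, kind, true label / injected delta,
#'   modifier parameters).
#' @export
generate_vcf_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  recordings <- list()
  truth <- list()
  seed_i <- spec$seed
  sim <- function(mod) {
    seed_i <<- seed_i + 1
    simulate_vcf_recording(spec$scheme, mod, spec$protocol,
                           bleach_tau = spec$bleach_tau,
                           noise_sd = spec$noise_sd, seed = seed_i)
  }
  for (nm in names(spec$constructs)) {
    mod <- spec$constructs[[nm]]
    recordings[[nm]] <- sim(mod)
    truth[[length(truth) + 1]] <- data.frame(
      construct = nm, kind = "phenotype", true_label = nm,
      delta = NA_real_, role = NA_character_,
      g_io_scale = mod$g_io_scale, g_ao_scale = mod$g_ao_scale,
      lock = mod$lock, expression = mod$expression, dv_shift = mod$dv_shift)
  }
  for (d in spec$dmc_deltas) {
    quad <- dmc_quadruple(spec$scheme, d, spec$dmc_shift_mVs)
    for (role in c("wt", "mut1", "mut2", "double")) {
      mod <- quad[[role]]
      nm <- sprintf("dmc%+.2f_%s", d, role)
      recordings[[nm]] <- sim(mod)
      truth[[length(truth) + 1]] <- data.frame(
        construct = nm, kind = "dmc", true_label = NA_character_,
        delta = d, role = role,
        g_io_scale = mod$g_io_scale, g_ao_scale = mod$g_ao_scale,
        lock = mod$lock, expression = mod$expression, dv_shift = mod$dv_shift)
    }
  }
  list(recordings = recordings, truth = do.call(rbind, truth))
}

#' Recover an injected coupling energy from simulated recordings
#'
#' End-to-end double-mutant-cycle pipeline on a simulated quadruple:
#' extract the tail-current G-V of each construct, fit a single Boltzmann,
#' convert to activation energies and form the coupling energy.
#'
#' @param recordings named list holding the four `vcf_recording`s.
#' @param roles named character vector mapping roles (`wt`, `mut1`, `mut2`,
#'   `double`) to recording names.
#' @param threshold interaction threshold (kcal/mol).
#' @return a `dmc_result` (see [dmc_cycle()]).
#' @export
dmc_pipeline <- function(recordings, roles, threshold = 1.0) {
  fits <- do.call(rbind, lapply(names(roles), function(role) {
    rec <- recordings[[roles[[role]]]]
    if (is.null(rec)) stop("missing recording for role ", role)
    gv <- extract_gv(rec)
    fit <- fit_boltzmann(gv, free_amplitude = TRUE)
    if (!fit$converged) stop("G-V fit failed for role ", role)
    data.frame(role = role, z = fit$pars[["z"]],
               v_half_mV = fit$pars[["v_half"]])
  }))
  dmc_from_fits(fits, threshold = threshold)
}

#' Measure phenotype readouts of a construct by simulation
#'
#' Simulates the construct standalone and under the four diagnostic
#' backgrounds (KCNE1-like suppression, intermediate- and activated-locked
#' VSD, F351A-like suppression), plus the wild type for normalisation, and
#' assembles the readouts consumed by [classify_phenotype()]. Peak tail
#' current is the current readout; fluorescence modulation and a
#' double-Boltzmann F-V fit provide the VSD readouts.
#'
#' @param modifier the construct's [construct_modifier()].
#' @param scheme a [gating_scheme()].
#' @param protocol a [voltage_protocol()].
#' @param bleach_tau,noise_sd,seed simulation settings, see
#'   [simulate_vcf_recording()].
#' @param expression_detected logical surface-expression readout; defaults
#'   to the truth encoded in the modifier (`expression > 0`).
#' @return named list of readouts (see [classify_phenotype()]).
#' @export
simulate_phenotype_readouts <- function(modifier, scheme = gating_scheme(),
                                        protocol = voltage_protocol(),
                                        bleach_tau = 30,
                                        noise_sd = c(current = 0, fluorescence = 0),
                                        seed = 1,
                                        expression_detected = NULL) {
  backgrounds <- phenotype_modifiers()[c("kcne1", "locked_intermediate",
                                         "locked_activated", "f351a")]
  sim <- function(mod, s) simulate_vcf_recording(scheme, mod, protocol,
                                                 bleach_tau = bleach_tau,
                                                 noise_sd = noise_sd, seed = s)
  tail_by_sweep <- function(rec) {
    tail_start <- protocol$holding_s + protocol$test_s
    win <- rec$time_s >= tail_start + 0.001 & rec$time_s < tail_start + 0.005
    sweeps <- split(rec$current[win], rec$sweep_id[win])
    vapply(sweeps, mean, numeric(1))
  }
  peak_tail <- function(rec) max(tail_by_sweep(rec))
  fluor_amplitude <- function(rec) {
    amp <- vapply(split(as.data.frame(rec), rec$sweep_id), function(sw) {
      bc <- baseline_correct(sw$fluorescence, sw$time_s,
                             fit_window = min(2, protocol$holding_s),
                             holding_s = protocol$holding_s)
      max(abs(compute_dff(bc$corrected, bc$f0)))
    }, numeric(1))
    max(amp)
  }
  rec_wt <- sim(construct_modifier("WT"), seed)
  rec_alone <- sim(modifier, seed + 1)
  # standalone current relative to WT, compared per test voltage so that a
  # construct conducting only at intermediate voltages is not penalised for
  # the missing AO component; voltages where WT barely conducts (< 10% of
  # its peak) are excluded to keep the ratio well-conditioned
  tw <- tail_by_sweep(rec_wt)
  ta <- tail_by_sweep(rec_alone)
  use <- tw > 0.1 * max(tw)
  i_wt <- max(tw)
  i_alone <- peak_tail(rec_alone)
  rel_current <- if (any(use)) max(ta[use] / tw[use]) else 0
  f_wt <- fluor_amplitude(rec_wt)
  f_alone <- fluor_amplitude(rec_alone)

  i_cond <- vapply(seq_along(backgrounds), function(k) {
    peak_tail(sim(combine_modifiers(modifier, backgrounds[[k]]), seed + 1 + k))
  }, numeric(1))
  names(i_cond) <- names(backgrounds)

  two_fv <- FALSE
  if (f_alone > 0.2 * f_wt) {
    fv <- tryCatch(suppressWarnings(extract_fv(rec_alone)),
                   warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(fv)) {
      fit <- tryCatch(suppressWarnings(fit_double_boltzmann(fv, free_scale = TRUE)),
                      error = function(e) NULL)
      two_fv <- !is.null(fit) && fit$converged && !isTRUE(fit$degenerate) &&
        fit$pars[["a1"]] > 0.1 && fit$pars[["a1"]] < 0.9 &&
        (fit$pars[["v2_half"]] - fit$pars[["v1_half"]]) > 20
    }
  }
  safe_ratio <- function(num, den) if (den <= 0) NA_real_ else num / den
  list(
    rel_current = rel_current,
    fluorescence_detected = f_alone > 0.2 * f_wt,
    two_fv_components = two_fv,
    ratio_kcne1 = safe_ratio(i_cond[["kcne1"]], i_alone),
    ratio_locked = safe_ratio(i_cond[["locked_activated"]],
                              i_cond[["locked_intermediate"]]),
    ratio_f351a = safe_ratio(i_cond[["f351a"]], i_alone),
    expression_detected = expression_detected %||% (modifier$expression > 0)
  )
}
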