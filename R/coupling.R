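#' Activation energy from Boltzmann parameters
#'
#' Free energy of voltage-dependent activation derived from a G-V Boltzmann
#' fit, \eqn{\Delta G = -z F V_{1/2}}, with the Faraday constant
#' F = 23.06 kcal/(mol V) and the midpoint converted from mV to V.
#'
#' @param z equivalent valence (e0).
#' @param v_half_mV midpoint voltage (mV).
#' @return activation energy in kcal/mol.
#' @export
#' @examples
#' activation_energy(1, -100)   # +2.306 kcal/mol
activation_energy <- function(z, v_half_mV) {
  stopifnot(is.finite(z), is.finite(v_half_mV))
  -z * FARADAY_KCAL * (v_half_mV / 1000)
}

#' Double-mutant-cycle coupling energy
#'
#' Non-additivity of single-mutant activation energies in the double mutant:
#' with energies of the wild type (`g0`), the two single mutants (`g1`,
#' `g2`) and the double mutant (`g12`), the coupling energy is
#' \deqn{\Delta\Delta G = \Delta G_{12} - (\Delta G_1 + \Delta G_2)
#'       = G_{12} + G_0 - G_1 - G_2}
#' where each \eqn{\Delta} is taken relative to the wild type. Invariant
#' under adding any constant to all four energies.
#'
#' @param g0,g1,g2,g12 absolute activation energies (kcal/mol) on a common
#'   scale.
#' @return coupling energy (kcal/mol).
#' @export
#' @examples
#' coupling_energy(1.7, 0.1, 1.2, -2.2)   # -1.8: the pair interacts
coupling_energy <- function(g0, g1, g2, g12) {
  stopifnot(is.finite(g0), is.finite(g1), is.finite(g2), is.finite(g12))
  g12 + g0 - g1 - g2
}

#' Interaction call from a coupling energy
#'
#' Two residues are classified as interacting when the magnitude of their
#' coupling energy reaches the threshold (default 1 kcal/mol); below it they
#' are classified as not interacting.
#'
#' @param ddg coupling energy (kcal/mol).
#' @param threshold decision threshold (kcal/mol).
#' @return logical.
#' @export
classify_interaction <- function(ddg, threshold = 1.0) {
  stopifnot(threshold > 0)
  abs(ddg) >= threshold
}

#' Full double-mutant-cycle analysis from four energies
#'
#' @inheritParams coupling_energy
#' @param label pair label.
#' @param threshold interaction threshold (kcal/mol).
#' @return one-row data frame (class `dmc_result`): the four energies,
#'   `ddg`, `abs_ddg`, `interacting`, `threshold`.
#' @export
dmc_cycle <- function(g0, g1, g2, g12, label = "pair", threshold = 1.0) {
  ddg <- coupling_energy(g0, g1, g2, g12)
  structure(data.frame(pair = label, g0 = g0, g1 = g1, g2 = g2, g12 = g12,
                       ddg = ddg, abs_ddg = abs(ddg),
                       interacting = classify_interaction(ddg, threshold),
                       threshold = threshold),
            class = c("dmc_result", "data.frame"))
}

#' Double-mutant-cycle analysis from fitted Boltzmann parameters
#'
#' Takes a table of G-V Boltzmann fits for the four constructs of a cycle
#' (roles `wt`, `mut1`, `mut2`, `double`), converts each `(z, V1/2)` pair to
#' an activation energy and runs [dmc_cycle()].
#'
#' @param fits data frame with columns `role` (wt/mut1/mut2/double), `z`,
#'   `v_half_mV`, and optionally `construct`.
#' @param label pair label.
#' @param threshold interaction threshold (kcal/mol).
#' @return a `dmc_result` (see [dmc_cycle()]).
#' @export
dmc_from_fits <- function(fits, label = "pair", threshold = 1.0) {
  need <- c("wt", "mut1", "mut2", "double")
  if (!all(need %in% fits$role))
    stop("fits must contain roles: ", paste(need, collapse = ", "))
  g <- vapply(need, function(r) {
    row <- fits[fits$role == r, ][1, ]
    activation_energy(row$z, row$v_half_mV)
  }, numeric(1))
  dmc_cycle(g[["wt"]], g[["mut1"]], g[["mut2"]], g[["double"]],
            label = label, threshold = threshold)
}

#' Activator-screen hit rule
#'
#' A mutant is a screen hit (candidate coupling-disrupting mutation) when
#' its activator-induced current increase, mean plus SEM, falls strictly
#' below the wild-type mean minus twice the wild-type SEM (the "dotted
#' line" of the screen).
#'
#' @param wt_mean,wt_sem wild-type mean current increase and its SEM.
#' @param mut_mean,mut_sem mutant mean current increase and its SEM.
#' @return logical: TRUE when the mutant is a hit.
#' @export
#' @examples
#' ml277_hit_flag(2.0, 0.1, 1.5, 0.2)   # TRUE: 1.7 < 1.8
ml277_hit_flag <- function(wt_mean, wt_sem, mut_mean, mut_sem) {
  if (any(!is.finite(c(wt_mean, wt_sem))))
    stop("missing wild-type reference for the screen rule")
  stopifnot(wt_sem >= 0, mut_sem >= 0)
  (mut_mean + mut_sem) < (wt_mean - 2 * wt_sem)
}

#' Apply the screen hit rule to a screen table
#'
#' @param screen data frame with columns `construct`, `mean`, `sem` and
#'   optionally `status` (`measured`, `no_current`, `inactivating`); rows
#'   whose status is not `measured` are never flagged (their currents cannot
#'   be interpreted under the rule).
#' @param wt_label construct name of the wild-type reference row.
#' @return the table with a logical `hit` column appended.
#' @export
ml277_screen <- function(screen, wt_label = "WT") {
  if (!all(c("construct", "mean", "sem") %in% names(screen)))
    stop("screen table needs columns construct, mean, sem")
  wt <- screen[screen$construct == wt_label, ]
  if (nrow(wt) != 1) stop("missing wild-type reference row '", wt_label, "'")
  status <- screen$status %||% rep("measured", nrow(screen))
  screen$hit <- vapply(seq_len(nrow(screen)), function(i) {
    if (status[i] != "measured" || screen$construct[i] == wt_label) return(FALSE)
    ml277_hit_flag(wt$mean, wt$sem, screen$mean[i], screen$sem[i])
  }, logical(1))
  screen
}

#' Default thresholds for the phenotype classifier
#'
#' The primary experiments report only qualitative calls, so the numeric
#' cutoffs are explicit package choices: a conditional current ratio below
#' `low_ratio` counts as "suppressed", and a standalone current above
#' `robust_current` (relative to wild type = 1) counts as "robust".
#'
#' @param low_ratio ratio below which a conditional current is "low".
#' @param robust_current relative standalone current above which a construct
#'   is "robust".
#' @return named list of thresholds.
#' @export
phenotype_thresholds <- function(low_ratio = 0.2, robust_current = 0.3) {
  stopifnot(low_ratio > 0, robust_current > 0)
  list(low_ratio = low_ratio, robust_current = robust_current)
}

#' Four-test open-state phenotype classification
#'
#' Classifies a construct from a panel of functional readouts into one of:
#' \describe{
#'   \item{expression_null}{no current, no fluorescence, no membrane
#'     expression — the channel never reaches the surface.}
#'   \item{classic_EM_loss}{VSD moves (robust fluorescence) but the pore
#'     never opens: loss of electro-mechanical coupling for both open
#'     states.}
#'   \item{AO_specific_loss}{robust standalone current, but current is
#'     suppressed in every manoeuvre that isolates the activated-open state
#'     (KCNE1-like IO suppression, activated- vs intermediate-locked VSD
#'     backgrounds, F351A-like IO suppression), while both fluorescence
#'     components remain: selective disruption of the AO state. All four
#'     tests must agree.}
#'   \item{WT_like}{robust current and none of the conditional ratios low.}
#'   \item{inconclusive}{missing or contradictory readouts, or a mixed
#'     pattern across the four tests.}
#' }
#'
#' @param readouts named list with elements `rel_current` (standalone
#'   current, WT = 1), `fluorescence_detected` (logical), `two_fv_components`
#'   (logical), `ratio_kcne1`, `ratio_locked` (activated-locked /
#'   intermediate-locked), `ratio_f351a`, `expression_detected` (logical).
#'   Missing elements may be `NA`.
#' @param thresholds see [phenotype_thresholds()].
#' @return list with `label`, `reason`, and the thresholds used.
#' @export
classify_phenotype <- function(readouts, thresholds = phenotype_thresholds()) {
  g <- function(name) readouts[[name]] %||% NA
  rel_i <- g("rel_current")
  fluo <- g("fluorescence_detected")
  two_fv <- g("two_fv_components")
  ratios <- c(kcne1 = g("ratio_kcne1"), locked = g("ratio_locked"),
              f351a = g("ratio_f351a"))
  expr <- g("expression_detected")

  out <- function(label, reason) list(label = label, reason = reason,
                                      thresholds = thresholds)
  if (!is.na(rel_i) && !is.na(expr) && rel_i >= thresholds$robust_current &&
      !isTRUE(expr))
    return(out("inconclusive", "contradictory: robust current without membrane expression"))
  if (!is.na(rel_i) && !is.na(fluo) && !is.na(expr) &&
      rel_i < thresholds$robust_current && !isTRUE(fluo) && !isTRUE(expr))
    return(out("expression_null", "no current, no fluorescence, no membrane expression"))
  if (is.na(rel_i) || is.na(fluo))
    return(out("inconclusive", "missing core readouts"))
  if (rel_i < thresholds$robust_current) {
    if (isTRUE(fluo))
      return(out("classic_EM_loss",
                 "VSD fluorescence robust but standalone current lost"))
    return(out("inconclusive", "no current and no fluorescence but expression detected"))
  }
  # robust standalone current: interrogate the four AO tests
  if (any(is.na(ratios)) || is.na(two_fv))
    return(out("inconclusive", "missing conditional readouts"))
  low <- ratios < thresholds$low_ratio
  if (all(low) && isTRUE(two_fv))
    return(out("AO_specific_loss",
               "consistent suppression in all AO-isolating tests with both VSD steps intact"))
  if (!any(low))
    return(out("WT_like", "robust current, no conditional suppression"))
  out("inconclusive", "mixed pattern across the four tests")
}
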