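# Synthetic C4-symmetric pseudo-trajectories with planted state-dependent
# contact probabilities. Sidechains are reduced to the atoms each
# interaction rule needs, arranged so that the rule distance between two
# residues equals the separation of their anchor points.

# Local sidechain templates: offsets are expressed in the (u, v, w) frame of
# a pair, with u the separation axis (residue i points +u towards residue
# j), v/w perpendicular. Rule-relevant atoms sit at offsets perpendicular
# to u, so the rule distance equals the anchor separation exactly.
#' @noRd
.residue_template <- function(resid) {
  hex <- function(r) {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    cbind(0, r * cos(ang), r * sin(ang))
  }
  pent <- function(r) {
    ang <- seq(0, 2 * pi, length.out = 6)[1:5]
    cbind(0, r * cos(ang), r * sin(ang))
  }
  off <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  switch(toupper(resid),
    ALA = list(elety = "CB", xyz = off(0, 0, 0)),
    VAL = list(elety = c("CB", "CG1", "CG2"),
               xyz = off(-0.5, 0, 0, 0, 0.6, 0, 0, -0.6, 0)),
    LEU = list(elety = c("CB", "CG", "CD1", "CD2"),
               xyz = off(-0.8, 0, 0, 0, 0, 0, 0, 0.6, 0, 0, -0.6, 0)),
    ILE = list(elety = c("CB", "CG1", "CD1", "CG2"),
               xyz = off(-0.8, 0, 0, -0.4, 0, 0, 0, 0.6, 0, 0, -0.6, 0)),
    THR = list(elety = c("CB", "CG2", "OG1"),
               xyz = off(-0.5, 0, 0, 0, 0, 0, 0, 0.5, 0)),
    MET = list(elety = c("CB", "CG", "SD", "CE"),
               xyz = off(-1.0, 0, 0, -0.5, 0, 0, 0, 0, 0, 0, 0.5, 0)),
    PHE = list(elety = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               xyz = rbind(c(-1.5, 0, 0), hex(1.39))),
    TYR = list(elety = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
               xyz = rbind(c(-1.5, 0, 0), hex(1.39), c(0, 0, 0))),
    TRP = list(elety = c("CB", "NE1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
               xyz = rbind(c(-1.5, 0, 0), c(0, 0, 0), hex(1.39))),
    HIS = list(elety = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
               xyz = rbind(c(-1.2, 0, 0), pent(1.16))),
    LYS = list(elety = c("CB", "CD", "CE", "NZ"),
               xyz = off(-1.5, 0, 0, -1.0, 0, 0, -0.5, 0, 0, 0, 0, 0)),
    ARG = list(elety = c("CB", "NE", "CZ", "NH1", "NH2"),
               xyz = off(-1.5, 0, 0, -0.3, 0, 0, 0, 0, 0,
                         0, 0.55, 0, 0, -0.55, 0)),
    ASP = list(elety = c("CB", "CG", "OD1", "OD2"),
               xyz = off(-0.8, 0, 0, 0, 0, 0, 0, 0.5, 0, 0, -0.5, 0)),
    GLU = list(elety = c("CB", "CG", "CD", "OE1", "OE2"),
               xyz = off(-1.2, 0, 0, -0.7, 0, 0, 0, 0, 0,
                         0, 0.5, 0, 0, -0.5, 0)),
    ASN = list(elety = c("CB", "CG", "OD1", "ND2"),
               xyz = off(-0.8, 0, 0, 0, 0, 0, 0, 0.5, 0, 0, -0.5, 0)),
    GLN = list(elety = c("CB", "CG", "CD", "OE1", "NE2"),
               xyz = off(-1.2, 0, 0, -0.7, 0, 0, 0, 0, 0,
                         0, 0.5, 0, 0, -0.5, 0)),
    SER = list(elety = c("CB", "OG"), xyz = off(-0.5, 0, 0, 0, 0, 0)),
    stop("no synthetic template for residue ", resid)
  )
}

#' Contact-trajectory specification
#'
#' Planted ground truth for the contact pipeline: a set of residue pairs
#' with one interaction-presence probability per state model. In each frame
#' and subunit the pair is set to "in contact" (rule distance = cutoff -
#' `contact_margin`) with the planted probability, otherwise pulled apart
#' (cutoff + `far_margin`); Gaussian positional jitter is added to every
#' atom.
#'
#' @param pairs data frame with columns `resid_i`, `resid_j` and
#'   probability columns `RC`, `IO`, `AO`, `AC` in `[0, 1]`; default: eight
#'   pairs spanning all state-dependence groups and all five interaction
#'   rules.
#' @param n_frames frames per state model.
#' @param jitter_sd positional jitter SD (Angstrom).
#' @param placement_radius radius of the C4 ring on which subunits sit
#'   (Angstrom).
#' @param contact_margin,far_margin distance margins below/above the rule
#'   cutoff (Angstrom).
#' @param seed integer seed.
#' @return an object of class `contact_spec`.
#' @export
contact_spec <- function(pairs = NULL, n_frames = 200, jitter_sd = 0.05,
                         placement_radius = 30, contact_margin = 1.0,
                         far_margin = 2.0, seed = 1) {
  if (is.null(pairs)) {
    pairs <- data.frame(
      resid_i = c("LEU", "LYS", "MET", "VAL", "MET", "PHE", "HIS", "TRP"),
      resid_j = c("ILE", "GLU", "PHE", "LEU", "LEU", "TYR", "ASP", "TRP"),
      RC = c(0.95, 0.05, 0.90, 0.05, 0.90, 0.05, 0.02, 0.90),
      IO = c(0.95, 0.05, 0.90, 0.90, 0.90, 0.05, 0.02, 0.05),
      AO = c(0.95, 0.90, 0.05, 0.90, 0.90, 0.55, 0.02, 0.05),
      AC = c(0.95, 0.05, 0.90, 0.05, 0.90, 0.05, 0.02, 0.90))
  }
  stopifnot(all(c("resid_i", "resid_j", "RC", "IO", "AO", "AC") %in% names(pairs)),
            all(unlist(pairs[c("RC", "IO", "AO", "AC")]) >= 0),
            all(unlist(pairs[c("RC", "IO", "AO", "AC")]) <= 1),
            n_frames >= 1, jitter_sd >= 0, contact_margin > 0, far_margin > 0)
  pairs$resno_i <- 10L * seq_len(nrow(pairs))
  pairs$resno_j <- pairs$resno_i + 1L
  structure(list(pairs = pairs, n_frames = n_frames, jitter_sd = jitter_sd,
                 placement_radius = placement_radius,
                 contact_margin = contact_margin, far_margin = far_margin,
                 seed = seed),
            class = "contact_spec")
}

# rotation about z by angle a
#' @noRd
.rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Generate C4-symmetric contact trajectories with planted presence
#'
#' Builds one pseudo-trajectory per state model (`RC`, `IO`, `AO`, `AC`).
#' Each residue pair sits at its own height on a ring of four chains
#' (A-D, rotated 90 degrees apart); per frame and subunit the rule distance
#' toggles between contact and far according to the planted probability.
#' The ground-truth table carries the planted probabilities, the presence
#' calls they imply under the default rules, and the implied
#' state-dependence group.
#'
#' @param spec a [contact_spec()].
#' @return list with `trajectories` (named list of `kv_trajectory`),
#'   `truth` (data frame) and `pairs` (pair table for
#'   [contact_frequency_table()]).
#' @export
generate_contact_trajectory <- function(spec = contact_spec()) {
  stopifnot(inherits(spec, "contact_spec"))
  pairs <- spec$pairs
  models <- c("RC", "IO", "AO", "AC")
  chains <- c("A", "B", "C", "D")

  # static atom roster: per chain, per pair, residues i and j
  atoms <- list(); base <- list()
  for (ci in seq_along(chains)) {
    rot <- .rot_z((ci - 1) * pi / 2)
    for (k in seq_len(nrow(pairs))) {
      anchor_i <- rot %*% c(spec$placement_radius, 0, 0) + c(0, 0, 8 * k)
      u <- rot %*% c(1, 0, 0)   # radial, outward: j sits outside i
      for (side in c("i", "j")) {
        resid <- pairs[[paste0("resid_", side)]][k]
        resno <- pairs[[paste0("resno_", side)]][k]
        tpl <- .residue_template(resid)
        # orient template: +u is the direction towards the partner
        sgn <- if (side == "i") 1 else -1
        frame_m <- cbind(sgn * u, rot %*% c(0, 1, 0), c(0, 0, 1))
        local <- tpl$xyz %*% t(frame_m)
        n <- length(tpl$elety)
        atoms[[length(atoms) + 1]] <- data.frame(
          chain = chains[ci], resno = resno, resid = resid,
          elety = tpl$elety, pair = k, side = side)
        base[[length(base) + 1]] <- list(anchor = as.vector(anchor_i),
                                         local = local, u = as.vector(u),
                                         pair = k, side = side, chain_i = ci)
      }
    }
  }
  atom_df <- do.call(rbind, atoms)
  atom_df$elesy <- .infer_element(atom_df$elety)

  rules <- lapply(seq_len(nrow(pairs)), function(k)
    assign_rule(pairs$resid_i[k], pairs$resid_j[k]))
  cutoffs <- vapply(rules, `[[`, numeric(1), "cutoff")

  trajs <- with_seed(spec$seed, {
    out <- list()
    for (m in models) {
      xyz <- matrix(NA_real_, spec$n_frames, 3 * nrow(atom_df))
      for (f in seq_len(spec$n_frames)) {
        # per (pair, subunit) contact draw for this frame
        sep <- matrix(NA_real_, nrow(pairs), length(chains))
        for (k in seq_len(nrow(pairs))) {
          contact <- stats::runif(length(chains)) < pairs[[m]][k]
          sep[k, ] <- ifelse(contact, cutoffs[k] - spec$contact_margin,
                             cutoffs[k] + spec$far_margin)
        }
        coords <- matrix(NA_real_, nrow(atom_df), 3)
        row0 <- 0
        for (b in base) {
          n <- nrow(b$local)
          pos <- if (b$side == "i") b$anchor else
            b$anchor + sep[b$pair, b$chain_i] * b$u
          block <- sweep(b$local, 2, pos, "+") +
            matrix(stats::rnorm(3 * n, 0, spec$jitter_sd), n, 3)
          coords[row0 + seq_len(n), ] <- block
          row0 <- row0 + n
        }
        xyz[f, ] <- as.vector(t(coords))
      }
      out[[m]] <- trajectory(atom_df[, c("chain", "resno", "resid",
                                         "elety", "elesy")], xyz)
    }
    out
  })

  truth <- pairs
  truth$category <- vapply(rules, `[[`, character(1), "category")
  pres <- t(vapply(seq_len(nrow(pairs)), function(k) {
    presence_call(c(RC = pairs$RC[k], IO = pairs$IO[k],
                    AO = pairs$AO[k], AC = pairs$AC[k]))
  }, logical(4)))
  colnames(pres) <- paste0("present_", models)
  truth <- cbind(truth, pres)
  truth$group <- apply(pres, 1, function(p)
    state_group(stats::setNames(p, models)))

  pair_table <- data.frame(resno_i = pairs$resno_i, resid_i = pairs$resid_i,
                           resno_j = pairs$resno_j, resid_j = pairs$resid_j,
                           relation = "intra")
  list(trajectories = trajs, truth = truth, pairs = pair_table)
}
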