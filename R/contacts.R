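# Residue-class and atom-set tables for the interaction-distance taxonomy.
# All tables are plain lists so they can be overridden from a JSON config.

#' Default residue classification tables for contact rules
#'
#' Atom sets used by the interaction-distance taxonomy: terminal methyl
#' carbons of aliphatic sidechains, aromatic ring atoms (centroid
#' definition), and charged-group / polar heteroatoms for salt bridges and
#' hydrogen bonds. Tryptophan's centroid defaults to its six-membered ring.
#'
#' @return named list with elements `methyl`, `ring`, `polar`.
#' @export
contact_atom_tables <- function() {
  list(
    methyl = list(ALA = "CB", VAL = c("CG1", "CG2"), LEU = c("CD1", "CD2"),
                  ILE = c("CD1", "CG2"), THR = "CG2", MET = "CE"),
    ring = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
    polar = list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                 ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                 HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
                 ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
                 TYR = "OH", TRP = "NE1")
  )
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Default distance cutoffs per interaction category (Angstrom)
#'
#' Aliphatic van-der-Waals and aromatic pi-stacking contacts at 5.1 A,
#' electrostatic contacts (salt bridges / hydrogen bonds) at 3.5 A,
#' Met-aromatic at 7.1 A and Met-Leu at 6.1 A.
#'
#' @return named numeric vector.
#' @export
contact_cutoffs <- function() {
  c(aliphatic_vdw = 5.1, aromatic_pi = 5.1, polar_electrostatic = 3.5,
    met_aromatic = 7.1, met_leucine = 6.1)
}

#' Assign the interaction rule for a residue pair
#'
#' Deterministic category from the residue-class tables, with the
#' methionine special cases taking precedence: Met-aromatic (S to ring
#' centroid, 7.1 A) and Met-Leu (S to the branching CG carbon, 6.1 A), then
#' electrostatic when both residues carry polar/charged atoms (shortest
#' heteroatom distance, 3.5 A), pi-stacking when both are aromatic (ring
#' centroid distance, 5.1 A), and aliphatic van-der-Waals when both carry
#' terminal methyls (shortest methyl distance, 5.1 A). Any remaining pair
#' falls back to the generic shortest sidechain heavy-atom distance at the
#' van-der-Waals cutoff.
#'
#' @param resname_i,resname_j three-letter residue names.
#' @param tables atom tables, see [contact_atom_tables()].
#' @param cutoffs cutoff table, see [contact_cutoffs()].
#' @return list with `category`, `cutoff`, and the atom-set definition per
#'   residue (`atoms_i`, `atoms_j`; `"centroid:"`-prefixed sets denote ring
#'   centroids, `NULL` means all sidechain heavy atoms).
#' @export
assign_rule <- function(resname_i, resname_j, tables = contact_atom_tables(),
                        cutoffs = contact_cutoffs()) {
  ri <- toupper(resname_i); rj <- toupper(resname_j)
  if (!(ri %in% .AA3)) stop("unknown residue name: ", resname_i)
  if (!(rj %in% .AA3)) stop("unknown residue name: ", resname_j)
  is_arom <- function(r) r %in% names(tables$ring)
  is_polar <- function(r) r %in% names(tables$polar)
  is_methyl <- function(r) r %in% names(tables$methyl)

  mk <- function(category, atoms_i, atoms_j)
    list(category = category, cutoff = unname(cutoffs[[category]]),
         atoms_i = atoms_i, atoms_j = atoms_j)

  if (ri == "MET" && is_arom(rj))
    return(mk("met_aromatic", "SD", paste0("centroid:", paste(tables$ring[[rj]], collapse = ","))))
  if (rj == "MET" && is_arom(ri))
    return(mk("met_aromatic", paste0("centroid:", paste(tables$ring[[ri]], collapse = ",")), "SD"))
  if (ri == "MET" && rj == "LEU") return(mk("met_leucine", "SD", "CG"))
  if (rj == "MET" && ri == "LEU") return(mk("met_leucine", "CG", "SD"))
  # pi-stacking takes precedence over the hydrogen-bond class for pairs of
  # aromatics that also carry a polar ring atom (TRP, TYR, HIS)
  if (is_arom(ri) && is_arom(rj))
    return(mk("aromatic_pi",
              paste0("centroid:", paste(tables$ring[[ri]], collapse = ",")),
              paste0("centroid:", paste(tables$ring[[rj]], collapse = ","))))
  if (is_polar(ri) && is_polar(rj))
    return(mk("polar_electrostatic", tables$polar[[ri]], tables$polar[[rj]]))
  if (is_methyl(ri) && is_methyl(rj))
    return(mk("aliphatic_vdw", tables$methyl[[ri]], tables$methyl[[rj]]))
  # generic fallback: all sidechain heavy atoms at the vdW cutoff
  mk("aliphatic_vdw", NULL, NULL)
}

# backbone + hydrogens excluded from "sidechain heavy atoms"
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' @noRd
.sidechain_idx <- function(atoms, chain, resno) {
  which(atoms$chain == chain & atoms$resno == resno &
          !(atoms$elety %in% .BACKBONE) & atoms$elesy != "H")
}

# Resolve a rule atom-set spec against a residue's atoms; returns list
# (idx = atom indices, centroid = TRUE/FALSE)
#' @noRd
.rule_atoms <- function(traj, chain, resno, spec) {
  sc <- .sidechain_idx(traj$atoms, chain, resno)
  if (!length(sc)) stop("residue ", resno, " chain ", chain,
                        " has no sidechain heavy atoms")
  if (is.null(spec)) return(list(idx = sc, centroid = FALSE))
  centroid <- FALSE
  names_want <- spec
  if (length(spec) == 1 && startsWith(spec, "centroid:")) {
    centroid <- TRUE
    names_want <- strsplit(sub("^centroid:", "", spec), ",")[[1]]
  }
  idx <- sc[traj$atoms$elety[sc] %in% names_want]
  if (!length(idx))
    stop("residue ", resno, " chain ", chain, " is missing rule atoms: ",
         paste(names_want, collapse = ", "))
  list(idx = idx, centroid = centroid)
}

# Distance between two atom sets in one frame under a rule: centroid sets
# are collapsed to their geometric centre first; otherwise the shortest
# pairwise distance is taken.
#' @noRd
.rule_distance <- function(ci, cj, centroid_i, centroid_j) {
  if (centroid_i) ci <- matrix(colMeans(ci), ncol = 3)
  if (centroid_j) cj <- matrix(colMeans(cj), ncol = 3)
  d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
  sqrt(max(min(d2), 0))
}

#' Chain adjacency of a C4 tetramer
#'
#' In the domain-swapped tetramer each subunit contacts its neighbours;
#' inter-subunit pairs are evaluated against both the next (`i -> i+1`) and
#' previous (`i -> i-1`) chain under the cyclic A-B-C-D arrangement.
#'
#' @param chains chain identifiers in cyclic order.
#' @param direction `"next"` or `"prev"`.
#' @return named character vector mapping each chain to its neighbour.
#' @export
chain_neighbours <- function(chains = c("A", "B", "C", "D"),
                             direction = c("next", "prev")) {
  direction <- match.arg(direction)
  n <- length(chains)
  shift <- if (direction == "next") 1 else -1
  stats::setNames(chains[((seq_len(n) - 1 + shift) %% n) + 1], chains)
}

#' Per-subunit rule-distance time series for a residue pair
#'
#' For every chain and every sampled frame, evaluates the rule's distance
#' between residue `resno_i` (in that chain) and residue `resno_j` (in the
#' same chain for intra-subunit pairs, or in the neighbouring chain for
#' inter-subunit pairs).
#'
#' @param traj a `kv_trajectory` with four chains.
#' @param resno_i,resno_j residue numbers (author numbering).
#' @param rule interaction rule from [assign_rule()].
#' @param relation `"intra"`, `"inter_next"` or `"inter_prev"`.
#' @param stride keep every `stride`-th frame.
#' @return matrix of distances (Angstrom), sampled frames x chains.
#' @export
pair_distance_series <- function(traj, resno_i, resno_j, rule,
                                 relation = c("intra", "inter_next", "inter_prev"),
                                 stride = 1) {
  relation <- match.arg(relation)
  chains <- sort(unique(traj$atoms$chain))
  partner <- switch(relation,
                    intra = stats::setNames(chains, chains),
                    inter_next = chain_neighbours(chains, "next"),
                    inter_prev = chain_neighbours(chains, "prev"))
  frames <- seq(1, traj$n_frames, by = stride)
  out <- matrix(NA_real_, length(frames), length(chains),
                dimnames = list(NULL, chains))
  sets <- lapply(chains, function(ch) {
    list(i = .rule_atoms(traj, ch, resno_i, rule$atoms_i),
         j = .rule_atoms(traj, partner[[ch]], resno_j, rule$atoms_j))
  })
  names(sets) <- chains
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    for (ch in chains) {
      s <- sets[[ch]]
      out[fi, ch] <- .rule_distance(frame_coords(traj, f, s$i$idx),
                                    frame_coords(traj, f, s$j$idx),
                                    s$i$centroid, s$j$centroid)
    }
  }
  out
}

#' Interaction frequency of a distance series
#'
#' Fraction of (frame, subunit) samples in which the rule distance stays
#' below the cutoff, pooled over all four subunits.
#'
#' @param series distance matrix from [pair_distance_series()].
#' @param rule interaction rule (supplies the cutoff) or a numeric cutoff.
#' @return frequency in `[0, 1]`.
#' @export
interaction_frequency <- function(series, rule) {
  cutoff <- if (is.numeric(rule)) rule else rule$cutoff
  mean(series < cutoff)
}

#' Presence call across state models
#'
#' A pair is called present in a state model when its interaction frequency
#' reaches the primary threshold (default 0.6, i.e. present in at least
#' three of four subunits on average). When no model reaches the primary
#' threshold, the differential rule applies instead: a model is called
#' present if its frequency exceeds the lowest model's frequency by at
#' least `differential` (default 0.4).
#'
#' @param frequencies named numeric vector of per-model frequencies
#'   (typically `RC`, `IO`, `AO`, `AC`).
#' @param primary_threshold primary frequency threshold.
#' @param differential differential threshold used when no model passes the
#'   primary rule.
#' @return named logical vector of presence calls.
#' @export
#' @examples
#' presence_call(c(RC = 0.1, IO = 0.15, AO = 0.58, AC = 0.12))  # AO only
presence_call <- function(frequencies, primary_threshold = 0.6,
                          differential = 0.4) {
  if (is.null(names(frequencies)) || any(!nzchar(names(frequencies))))
    stop("frequencies must be named by state model")
  if (any(is.na(frequencies))) stop("missing state-model frequency")
  primary <- frequencies >= primary_threshold
  if (any(primary)) return(primary)
  frequencies >= min(frequencies) + differential
}

#' State-dependence group of a presence pattern
#'
#' Maps the four-model presence vector to the interaction groups used to
#' interpret state-dependent contacts: present only in the AO model
#' (`AO_specific`), present everywhere except AO (`absent_in_AO_only`),
#' present in exactly IO and AO (`IO_and_AO`), present in all four models
#' (`ubiquitous`), anything else (`other`).
#'
#' @param presence named logical vector with elements `RC`, `IO`, `AO`, `AC`.
#' @return group label (character).
#' @export
state_group <- function(presence) {
  need <- c("RC", "IO", "AO", "AC")
  if (!all(need %in% names(presence))) stop("presence needs RC, IO, AO, AC")
  p <- as.logical(presence[need])
  if (all(p)) return("ubiquitous")
  if (identical(p, c(FALSE, FALSE, TRUE, FALSE))) return("AO_specific")
  if (identical(p, c(TRUE, TRUE, FALSE, TRUE))) return("absent_in_AO_only")
  if (identical(p, c(FALSE, TRUE, TRUE, FALSE))) return("IO_and_AO")
  "other"
}

#' Candidate residue pairs by mean sidechain proximity
#'
#' Screens all residue pairs (intra-subunit, and inter-subunit against both
#' neighbouring chains) and keeps those whose minimum sidechain heavy-atom
#' distance, averaged over frames and subunits, is at or below the cutoff.
#' Glycines (no sidechain heavy atoms) are excluded, with a note attribute.
#'
#' @param traj a `kv_trajectory`.
#' @param mean_distance_cutoff cutoff on the time-averaged minimum sidechain
#'   distance (Angstrom).
#' @param stride frame stride.
#' @param relations which chain relations to screen.
#' @return data frame `resno_i`, `resid_i`, `resno_j`, `resid_j`,
#'   `relation`, `mean_min_dist`; `attr(, "excluded")` lists skipped
#'   residues.
#' @export
candidate_pairs <- function(traj, mean_distance_cutoff = 5.0, stride = 1,
                            relations = c("intra", "inter_next", "inter_prev")) {
  if (traj$n_frames < 1) stop("trajectory has no frames")
  chains <- sort(unique(traj$atoms$chain))
  res <- unique(traj$atoms[, c("chain", "resno", "resid")])
  res_a <- res[res$chain == chains[1], ]
  has_sc <- vapply(seq_len(nrow(res_a)), function(i) {
    length(.sidechain_idx(traj$atoms, chains[1], res_a$resno[i])) > 0
  }, logical(1))
  excluded <- res_a$resno[!has_sc]
  res_a <- res_a[has_sc, ]
  frames <- seq(1, traj$n_frames, by = stride)

  sc_idx <- lapply(chains, function(ch)
    lapply(res_a$resno, function(rn) .sidechain_idx(traj$atoms, ch, rn)))
  names(sc_idx) <- chains

  min_dist <- function(f, ia, ib) {
    ci <- frame_coords(traj, f, ia); cj <- frame_coords(traj, f, ib)
    d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
    sqrt(max(min(d2), 0))
  }

  rows <- list()
  nres <- nrow(res_a)
  for (relation in relations) {
    partner <- switch(relation,
                      intra = stats::setNames(chains, chains),
                      inter_next = chain_neighbours(chains, "next"),
                      inter_prev = chain_neighbours(chains, "prev"))
    for (i in seq_len(nres)) {
      j0 <- if (relation == "intra") i + 1L else 1L
      if (j0 > nres) next
      for (j in j0:nres) {
        if (relation == "intra" && j <= i) next
        dsum <- 0; nsamp <- 0
        for (ch in chains) {
          ia <- sc_idx[[ch]][[i]]
          ib <- sc_idx[[partner[[ch]]]][[j]]
          for (f in frames) {
            dsum <- dsum + min_dist(f, ia, ib)
            nsamp <- nsamp + 1
          }
        }
        md <- dsum / nsamp
        if (md <= mean_distance_cutoff) {
          rows[[length(rows) + 1]] <- data.frame(
            resno_i = res_a$resno[i], resid_i = res_a$resid[i],
            resno_j = res_a$resno[j], resid_j = res_a$resid[j],
            relation = relation, mean_min_dist = md)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resno_i = integer(), resid_i = character(),
               resno_j = integer(), resid_j = character(),
               relation = character(), mean_min_dist = numeric())
  attr(out, "excluded") <- excluded
  out
}

#' Residue-pair interaction frequencies across state models
#'
#' Full contact pipeline: for each listed pair and each state-model
#' trajectory, assigns the interaction rule, measures the per-subunit
#' distance series, pools the below-cutoff frequency, then makes presence
#' calls and assigns the state-dependence group.
#'
#' @param trajectories named list of `kv_trajectory` objects, one per state
#'   model (e.g. `RC`, `IO`, `AO`, `AC`).
#' @param pairs data frame with columns `resno_i`, `resid_i`, `resno_j`,
#'   `resid_j` and optionally `relation` (default `"intra"`).
#' @param stride frame stride.
#' @param primary_threshold,differential presence-rule thresholds, see
#'   [presence_call()].
#' @return data frame (class `pair_frequency_table`): pair identity, one
#'   frequency column per model, `present_*` columns, and `group`.
#' @export
contact_frequency_table <- function(trajectories, pairs, stride = 1,
                                    primary_threshold = 0.6,
                                    differential = 0.4) {
  models <- names(trajectories)
  if (is.null(models)) stop("trajectories must be a named list of state models")
  relation <- pairs$relation %||% rep("intra", nrow(pairs))
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    rule <- assign_rule(pairs$resid_i[k], pairs$resid_j[k])
    freqs <- vapply(models, function(m) {
      ser <- pair_distance_series(trajectories[[m]], pairs$resno_i[k],
                                  pairs$resno_j[k], rule,
                                  relation = relation[k], stride = stride)
      interaction_frequency(ser, rule)
    }, numeric(1))
    pres <- presence_call(freqs, primary_threshold, differential)
    row <- data.frame(pair = paste0(pairs$resid_i[k], pairs$resno_i[k], "-",
                                    pairs$resid_j[k], pairs$resno_j[k]),
                      resno_i = pairs$resno_i[k], resid_i = pairs$resid_i[k],
                      resno_j = pairs$resno_j[k], resid_j = pairs$resid_j[k],
                      chain_relation = relation[k], category = rule$category)
    for (m in models) row[[m]] <- unname(freqs[[m]])
    for (m in models) row[[paste0("present_", m)]] <- unname(pres[[m]])
    row$group <- if (all(c("RC", "IO", "AO", "AC") %in% models))
      state_group(pres) else NA_character_
    row
  })
  structure(do.call(rbind, out),
            class = c("pair_frequency_table", "data.frame"))
}
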