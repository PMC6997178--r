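# Shared fixtures: small schemes, toy trajectories, and independent oracles
# used across the test files. Everything is generated in code.

default_scheme <- function() gating_scheme()

# Explicit-Euler integrator of the 3-state master equation: the brute-force
# oracle for simulate_relaxation (independent of the eigen solution).
euler_relaxation <- function(scheme, v_from, v_to, duration, dt) {
  vt <- scheme$v_t
  rates <- function(v) list(
    a1 = scheme$a1_0 * exp(scheme$z_a1 * v / vt),
    b1 = scheme$b1_0 * exp(-scheme$z_b1 * v / vt),
    a2 = scheme$a2_0 * exp(scheme$z_a2 * v / vt),
    b2 = scheme$b2_0 * exp(-scheme$z_b2 * v / vt))
  r0 <- rates(v_from)
  k1 <- r0$a1 / r0$b1; k2 <- r0$a2 / r0$b2
  p <- c(1, k1, k1 * k2); p <- p / sum(p)
  r <- rates(v_to)
  n <- round(duration / dt)
  out <- matrix(NA_real_, n + 1, 3)
  out[1, ] <- p
  for (i in seq_len(n)) {
    dp <- c(-r$a1 * p[1] + r$b1 * p[2],
            r$a1 * p[1] - (r$b1 + r$a2) * p[2] + r$b2 * p[3],
            r$a2 * p[2] - r$b2 * p[3])
    p <- p + dt * dp
    out[i + 1, ] <- p
  }
  out
}

# A hand-built single-frame tetramer trajectory with one residue pair per
# chain at controlled separations; used for geometric contact tests.
toy_pair_trajectory <- function(sep_by_chain = c(A = 3, B = 3, C = 3, D = 3),
                                resid_i = "LYS", resid_j = "GLU",
                                n_frames = 1) {
  chains <- names(sep_by_chain)
  atoms <- list(); coords <- list()
  for (ci in seq_along(chains)) {
    ctr <- c(30 * ci, 0, 0)
    atoms[[2 * ci - 1]] <- data.frame(chain = chains[ci], resno = 1L,
                                      resid = resid_i, elety = "NZ")
    coords[[2 * ci - 1]] <- ctr
    atoms[[2 * ci]] <- data.frame(chain = chains[ci], resno = 2L,
                                  resid = resid_j, elety = "OE1")
    coords[[2 * ci]] <- ctr + c(sep_by_chain[ci], 0, 0)
  }
  adf <- do.call(rbind, atoms)
  xyz1 <- as.vector(t(do.call(rbind, coords)))
  trajectory(adf, matrix(rep(xyz1, n_frames), nrow = n_frames, byrow = TRUE))
}

# Brute-force per-frame contact frequency oracle: naive loops over frames,
# chains and atom pairs, independent of the package's vectorised path.
brute_force_frequency <- function(traj, resno_i, resno_j, rule,
                                  relation = "intra") {
  chains <- sort(unique(traj$atoms$chain))
  partner <- if (relation == "intra") stats::setNames(chains, chains)
             else chain_neighbours(chains,
                                   if (relation == "inter_next") "next" else "prev")
  resolve <- function(ch, rn, spec) {
    sc <- which(traj$atoms$chain == ch & traj$atoms$resno == rn &
                  !(traj$atoms$elety %in% c("N", "CA", "C", "O", "OXT")))
    if (is.null(spec)) return(list(idx = sc, centroid = FALSE))
    cen <- length(spec) == 1 && startsWith(spec, "centroid:")
    want <- if (cen) strsplit(sub("^centroid:", "", spec), ",")[[1]] else spec
    list(idx = sc[traj$atoms$elety[sc] %in% want], centroid = cen)
  }
  hits <- 0; total <- 0
  for (f in seq_len(traj$n_frames)) {
    for (ch in chains) {
      si <- resolve(ch, resno_i, rule$atoms_i)
      sj <- resolve(partner[[ch]], resno_j, rule$atoms_j)
      ci <- frame_coords(traj, f, si$idx)
      cj <- frame_coords(traj, f, sj$idx)
      if (si$centroid) ci <- matrix(colMeans(ci), ncol = 3)
      if (sj$centroid) cj <- matrix(colMeans(cj), ncol = 3)
      dmin <- Inf
      for (a in seq_len(nrow(ci))) for (b in seq_len(nrow(cj)))
        dmin <- min(dmin, sqrt(sum((ci[a, ] - cj[b, ])^2)))
      hits <- hits + (dmin < rule$cutoff)
      total <- total + 1
    }
  }
  hits / total
}

# Dense 2-D grid-search oracle for the largest clearance sphere in a slice.
grid_search_radius <- function(coords, radii, z, r_max = 5, disc = 5,
                               grid_step = 0.05) {
  g <- seq(-disc, disc, by = grid_step)
  best <- -Inf
  for (cx in g) for (cy in g) {
    if (cx^2 + cy^2 > disc^2) next
    cl <- min(sqrt((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2 +
                     (coords[, 3] - z)^2) - radii)
    if (cl > best) best <- cl
  }
  min(max(best, 0), r_max)
}
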