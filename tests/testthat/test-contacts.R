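# Interaction-rule taxonomy, distance series, frequencies, presence calls,
# state groups, candidate screening and RMSD utilities.

test_that("the rule taxonomy assigns categories and cutoffs", {
  r <- assign_rule("LEU", "ILE")
  expect_equal(r$category, "aliphatic_vdw"); expect_equal(r$cutoff, 5.1)
  r <- assign_rule("MET", "PHE")
  expect_equal(r$category, "met_aromatic"); expect_equal(r$cutoff, 7.1)
  r <- assign_rule("LYS", "GLU")
  expect_equal(r$category, "polar_electrostatic"); expect_equal(r$cutoff, 3.5)
  r <- assign_rule("MET", "LEU")
  expect_equal(r$category, "met_leucine"); expect_equal(r$cutoff, 6.1)
  expect_equal(assign_rule("PHE", "TYR")$category, "aromatic_pi")
  # Met special cases take precedence over generic classes
  expect_equal(assign_rule("LEU", "MET")$category, "met_leucine")
  expect_equal(assign_rule("TRP", "MET")$category, "met_aromatic")
  # aromatic pairs with polar ring atoms are pi-stacking, not H-bond
  expect_equal(assign_rule("TRP", "TRP")$category, "aromatic_pi")
  expect_error(assign_rule("XXX", "LEU"), "unknown residue")
})

test_that("rule distances match hand-built geometry", {
  # LYS NZ at origin, GLU OE1 3 A away: constant series of 3.0
  traj <- toy_pair_trajectory(sep_by_chain = c(A = 3, B = 3, C = 3, D = 3),
                              n_frames = 4)
  rule <- assign_rule("LYS", "GLU")
  ser <- pair_distance_series(traj, 1, 2, rule)
  expect_equal(dim(ser), c(4, 4))
  expect_true(all(abs(ser - 3) < 1e-9))

  # centroid of a regular hexagonal ring vs a point 5 A above its centre
  ring <- cbind(1.39 * cos(seq(0, 2 * pi, length.out = 7)[1:6]),
                1.39 * sin(seq(0, 2 * pi, length.out = 7)[1:6]), 0)
  atoms <- data.frame(
    chain = "A", resno = c(rep(1L, 6), 2L),
    resid = c(rep("PHE", 6), "MET"),
    elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "SD"))
  xyz <- as.vector(t(rbind(ring, c(0, 0, 5))))
  traj1 <- trajectory(atoms, xyz)
  rule <- assign_rule("MET", "PHE")
  ser <- pair_distance_series(traj1, 2, 1, rule)
  expect_equal(unname(ser[1, 1]), 5.0, tolerance = 1e-9)

  # randomised coordinates vs an independent all-pairs oracle
  set.seed(99)
  for (rep in 1:3) {
    sep <- runif(4, 2, 9)
    traj_r <- toy_pair_trajectory(sep_by_chain = c(A = sep[1], B = sep[2],
                                                   C = sep[3], D = sep[4]))
    rule <- assign_rule("LYS", "GLU")
    ser <- pair_distance_series(traj_r, 1, 2, rule)
    expect_equal(unname(ser[1, ]), unname(sep), tolerance = 1e-9)
  }
  # missing rule atoms raise an informative error
  bad <- toy_pair_trajectory()
  bad$atoms$elety[bad$atoms$elety == "NZ"] <- "CB"
  expect_error(pair_distance_series(bad, 1, 2, assign_rule("LYS", "GLU")),
               "missing rule atoms")
})

test_that("interaction frequency pools (frame, subunit) samples", {
  # below cutoff in exactly 3 of 4 subunits at all frames -> 0.75
  traj <- toy_pair_trajectory(sep_by_chain = c(A = 3, B = 3, C = 3, D = 8),
                              n_frames = 5)
  rule <- assign_rule("LYS", "GLU")
  ser <- pair_distance_series(traj, 1, 2, rule)
  expect_equal(interaction_frequency(ser, rule), 0.75)
  expect_equal(interaction_frequency(ser, 10), 1.0)
  # planted Bernoulli pattern against the binomial expectation
  set.seed(4)
  ser_b <- matrix(ifelse(runif(1000) < 0.5, 3, 8), ncol = 4)
  expect_lt(abs(interaction_frequency(ser_b, rule) - 0.5), 0.05)
})

test_that("presence calls implement the primary and differential rules", {
  expect_equal(presence_call(c(RC = 0.9, IO = 0.95, AO = 0.92, AC = 0.88)),
               c(RC = TRUE, IO = TRUE, AO = TRUE, AC = TRUE))
  expect_equal(presence_call(c(RC = 0.1, IO = 0.15, AO = 0.58, AC = 0.12)),
               c(RC = FALSE, IO = FALSE, AO = TRUE, AC = FALSE))
  expect_equal(presence_call(c(RC = 0.1, IO = 0.3, AO = 0.45, AC = 0.2)),
               c(RC = FALSE, IO = FALSE, AO = FALSE, AC = FALSE))
  expect_error(presence_call(c(0.5, 0.6, 0.7, 0.8)), "named")
})

test_that("state groups map presence patterns deterministically", {
  p <- function(rc, io, ao, ac) c(RC = rc, IO = io, AO = ao, AC = ac)
  expect_equal(state_group(p(FALSE, FALSE, TRUE, FALSE)), "AO_specific")
  expect_equal(state_group(p(TRUE, TRUE, FALSE, TRUE)), "absent_in_AO_only")
  expect_equal(state_group(p(TRUE, TRUE, TRUE, TRUE)), "ubiquitous")
  expect_equal(state_group(p(FALSE, TRUE, TRUE, FALSE)), "IO_and_AO")
  expect_equal(state_group(p(TRUE, FALSE, FALSE, TRUE)), "other")
  expect_error(state_group(c(RC = TRUE)), "RC, IO, AO, AC")
})

test_that("candidate screening uses the time-averaged minimum distance", {
  near <- toy_pair_trajectory(sep_by_chain = c(A = 3, B = 3, C = 3, D = 3))
  out <- candidate_pairs(near, relations = "intra")
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_min_dist, 3, tolerance = 1e-9)
  far <- toy_pair_trajectory(sep_by_chain = c(A = 8, B = 8, C = 8, D = 8))
  expect_equal(nrow(candidate_pairs(far, relations = "intra")), 0)
  # oscillating 4 <-> 7 A with mean 5.5: excluded, and the mean matches a
  # brute-force per-frame recomputation
  t4 <- toy_pair_trajectory(sep_by_chain = c(A = 4, B = 4, C = 4, D = 4))
  t7 <- toy_pair_trajectory(sep_by_chain = c(A = 7, B = 7, C = 7, D = 7))
  osc <- trajectory(t4$atoms, rbind(t4$xyz, t7$xyz))
  out_osc <- candidate_pairs(osc, relations = "intra")
  expect_equal(nrow(out_osc), 0)
  out_osc6 <- candidate_pairs(osc, mean_distance_cutoff = 6,
                              relations = "intra")
  expect_equal(out_osc6$mean_min_dist, 5.5, tolerance = 1e-9)
})

test_that("superposition RMSD is zero under rigid motion and exact otherwise", {
  set.seed(2)
  a <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  expect_equal(backbone_rmsd(a, a), 0, tolerance = 1e-6)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  b <- sweep(a %*% t(rot), 2, c(3, -2, 7), "+")
  expect_equal(backbone_rmsd(b, a), 0, tolerance = 1e-6)
  # displacement d along z on half the atoms: without fitting the RMSD is
  # sqrt(d^2/2); the optimal superposition removes the mean shift d/2,
  # leaving deviations of +/- d/2, i.e. RMSD d/2 (up to a small rotation
  # gain)
  n <- 30; d <- 1.2
  cc <- sweep(a, 2, colMeans(a))
  shifted <- cc
  shifted[1:(n / 2), 3] <- shifted[1:(n / 2), 3] + d
  r_fit <- backbone_rmsd(shifted, cc)
  expect_lte(r_fit, d / 2 + 1e-9)
  expect_equal(r_fit, d / 2, tolerance = 0.02)
})

test_that("frequencies are invariant under global rigid transformation", {
  gen <- generate_contact_trajectory(contact_spec(n_frames = 20, seed = 3))
  traj <- gen$trajectories$IO
  rule <- assign_rule(gen$pairs$resid_i[2], gen$pairs$resid_j[2])
  f0 <- interaction_frequency(
    pair_distance_series(traj, gen$pairs$resno_i[2], gen$pairs$resno_j[2],
                         rule), rule)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
                byrow = TRUE)
  traj_t <- transform_trajectory(traj, rot, c(11, -4, 2))
  f1 <- interaction_frequency(
    pair_distance_series(traj_t, gen$pairs$resno_i[2], gen$pairs$resno_j[2],
                         rule), rule)
  expect_identical(f0, f1)
})

test_that("pipeline frequencies equal the brute-force oracle exactly", {
  gen <- generate_contact_trajectory(contact_spec(n_frames = 40, seed = 21))
  tab <- contact_frequency_table(gen$trajectories, gen$pairs)
  for (k in c(1, 3, 6)) {
    rule <- assign_rule(gen$pairs$resid_i[k], gen$pairs$resid_j[k])
    for (m in c("RC", "AO")) {
      expect_identical(tab[[m]][k],
                       brute_force_frequency(gen$trajectories[[m]],
                                             gen$pairs$resno_i[k],
                                             gen$pairs$resno_j[k], rule))
    }
  }
})

test_that("inter-subunit relations follow the C4 adjacency convention", {
  expect_equal(chain_neighbours(direction = "next"),
               c(A = "B", B = "C", C = "D", D = "A"))
  expect_equal(chain_neighbours(direction = "prev"),
               c(A = "D", B = "A", C = "B", D = "C"))
  # place residue 2 of each chain 3 A from residue 1 of the NEXT chain
  chains <- c("A", "B", "C", "D")
  atoms <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    data.frame(chain = chains[ci], resno = c(1L, 2L),
               resid = c("LYS", "GLU"), elety = c("NZ", "OE1"))
  }))
  pos1 <- lapply(1:4, function(ci) c(40 * ci, 0, 0))
  coords <- do.call(rbind, lapply(1:4, function(ci) {
    nxt <- pos1[[(ci %% 4) + 1]]
    rbind(pos1[[ci]], nxt + c(0, 3, 0))
  }))
  traj <- trajectory(atoms, as.vector(t(coords)))
  rule <- assign_rule("GLU", "LYS")
  ser <- pair_distance_series(traj, 2, 1, rule, relation = "inter_next")
  expect_true(all(abs(ser - 3) < 1e-9))
  ser_prev <- pair_distance_series(traj, 2, 1, rule, relation = "inter_prev")
  expect_true(all(ser_prev > 30))
})
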