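# Pore-radius profiler: analytic geometries, cap behaviour, oracle
# agreement, invariances and trajectory averaging.

zaxis <- function() list(origin = c(0, 0, 0), direction = c(0, 0, 1))

test_that("a ring of atoms gives the analytic clearance radius", {
  # 12 atoms at distance 5.0 from the axis, hard-sphere radius via element
  # C (1.85): clearance at the ring plane is 5.0 - 1.85 = 3.15
  ang <- seq(0, 2 * pi, length.out = 13)[1:12]
  coords <- cbind(5 * cos(ang), 5 * sin(ang), 0)
  prof <- pore_profile(coords, elements = rep("C", 12), axis = zaxis(),
                       z_range = c(0, 0), seed = 1)
  expect_equal(prof$radius, 5 - 1.85, tolerance = 1e-6)
  # explicit per-atom radii 1.5: clearance 3.5
  prof2 <- pore_profile(coords, radii = rep(1.5, 12), axis = zaxis(),
                        z_range = c(0, 0), seed = 1)
  expect_equal(prof2$radius, 3.5, tolerance = 1e-6)
})

test_that("empty regions report exactly the 5 A cap", {
  coords <- matrix(c(8, 8, -30, -8, 8, -30, 8, -8, -30, -8, -8, -30),
                   ncol = 3, byrow = TRUE)
  expect_warning(
    prof <- pore_profile(coords, elements = rep("C", 4), axis = zaxis(),
                         z_range = c(10, 12), seed = 2),
    "capped")
  expect_true(all(prof$radius == 5.0))
  expect_error(pore_profile(matrix(numeric(0), ncol = 3), axis = zaxis()),
               "empty")
})

test_that("cylinder profiles agree with the analytic radius everywhere", {
  toy <- generate_toy_pore(pore_spec(shape = "cylinder", radius = 3.5,
                                     z_range = c(-5, 5)))
  prof <- pore_profile(toy$traj, axis = zaxis(), z_range = c(-5, 5),
                       seed = 31)
  expect_equal(nrow(prof), length(toy$analytic$z))
  expect_lt(max(abs(prof$radius - 3.5)), 0.05)
  # z grid is uniform at the configured step
  expect_equal(unique(round(diff(prof$z), 9)), 0.125)
})

test_that("the hourglass waist matches the generator and a grid oracle", {
  spec <- pore_spec(shape = "hourglass", r_waist = 0.9, r_end = 4,
                    z_waist = 0.9, z_range = c(-6, 6))
  toy <- generate_toy_pore(spec)
  prof <- pore_profile(toy$traj, axis = zaxis(), z_range = c(-6, 6),
                       seed = 32)
  mr <- min_radius(prof)
  expect_lt(abs(mr$r_min - 0.9), 0.05)
  expect_lt(abs(mr$z_at_min - spec$z_waist), 0.125 + 1e-9)
  # waist slice vs dense 2-D grid-search oracle
  coords <- frame_coords(toy$traj)
  rad <- rep(unname(atom_radii()["C"]), nrow(coords))
  z0 <- prof$z[which.min(abs(prof$z - spec$z_waist))]
  oracle <- grid_search_radius(coords, rad, z0)
  got <- prof$radius[prof$z == z0]
  expect_lt(abs(got - oracle), 0.05)
  # annealing can only do at least as well as the axis-centred clearance
  axis_clear <- vapply(prof$z, function(z) {
    min(max(min(sqrt(rowSums(sweep(coords, 2, c(0, 0, z))^2)) - rad), 0), 5)
  }, numeric(1))
  expect_true(all(prof$radius >= axis_clear - 1e-6))
})

test_that("doubling ring density leaves the profile nearly unchanged", {
  s1 <- pore_spec(shape = "cylinder", radius = 3, z_range = c(-3, 3),
                  n_ring = 12)
  s2 <- pore_spec(shape = "cylinder", radius = 3, z_range = c(-3, 3),
                  n_ring = 24)
  p1 <- pore_profile(generate_toy_pore(s1)$traj, axis = zaxis(),
                     z_range = c(-3, 3), seed = 5)
  p2 <- pore_profile(generate_toy_pore(s2)$traj, axis = zaxis(),
                     z_range = c(-3, 3), seed = 5)
  expect_lt(max(abs(p1$radius - p2$radius)), 0.05)
})

test_that("profiles are deterministic given a seed and rigid-invariant", {
  toy <- generate_toy_pore(pore_spec(shape = "hourglass", z_range = c(-4, 4)))
  p1 <- pore_profile(toy$traj, axis = zaxis(), z_range = c(-4, 4), seed = 8)
  p2 <- pore_profile(toy$traj, axis = zaxis(), z_range = c(-4, 4), seed = 8)
  expect_identical(p1, p2)
  # rotate structure and axis jointly: same profile
  th <- 0.6
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
                byrow = TRUE)
  shift <- c(5, -3, 2)
  traj_t <- transform_trajectory(toy$traj, rot, shift)
  axis_t <- list(origin = as.vector(rot %*% c(0, 0, 0)) + shift,
                 direction = as.vector(rot %*% c(0, 0, 1)))
  p3 <- pore_profile(traj_t, axis = axis_t, z_range = c(-4, 4), seed = 8)
  expect_equal(p3$radius, p1$radius, tolerance = 1e-6)
})

test_that("min_radius picks the constriction with |z| tie-breaking", {
  prof <- structure(data.frame(z = c(-2, -1, 0, 1, 2),
                               radius = c(3, 1, 2, 1, 4),
                               cx = 0, cy = 0),
                    class = c("pore_profile", "data.frame"))
  mr <- min_radius(prof)
  expect_equal(mr$r_min, 1)
  expect_equal(mr$z_at_min, -1)   # tie at +/-1 broken by smallest |z|... equal; smallest index of equal |z|
  # monotone profile: endpoint
  prof2 <- structure(data.frame(z = 0:4, radius = 5:1, cx = 0, cy = 0),
                     class = c("pore_profile", "data.frame"))
  expect_equal(min_radius(prof2)$z_at_min, 4)
  # windowed search
  expect_equal(min_radius(prof, z_window = c(0, 2))$z_at_min, 1)
  # flat capped profile is degenerate
  prof3 <- structure(data.frame(z = 0:3, radius = 5, cx = 0, cy = 0),
                     class = c("pore_profile", "data.frame"))
  expect_true(min_radius(prof3)$degenerate)
})

test_that("mean profiles average per-frame profiles", {
  toy <- generate_toy_pore(pore_spec(shape = "cylinder", radius = 3,
                                     z_range = c(-2, 2)))
  tr2 <- trajectory(toy$traj$atoms, rbind(toy$traj$xyz, toy$traj$xyz))
  mp <- mean_profile(tr2, axis = zaxis(), z_range = c(-2, 2), seed = 40)
  expect_lt(max(abs(mp$radius - 3)), 0.05)
  # two frames with waists r and r + 0.4: mean waist r + 0.2
  g1 <- generate_toy_pore(pore_spec(shape = "hourglass", r_waist = 1.0,
                                    z_range = c(-4, 4)))
  g2 <- generate_toy_pore(pore_spec(shape = "hourglass", r_waist = 1.4,
                                    z_range = c(-4, 4)))
  tr <- trajectory(g1$traj$atoms, rbind(g1$traj$xyz, g2$traj$xyz))
  mp2 <- mean_profile(tr, axis = zaxis(), z_range = c(-4, 4), seed = 41)
  expect_lt(abs(min_radius(mp2)$r_min - 1.2), 0.13)
})
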