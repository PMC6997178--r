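# Toy pore geometries with analytic radius profiles, for benchmarking the
# pore profiler against known ground truth.

#' Toy-pore specification
#'
#' Describes an axially symmetric pore built from stacked rings of carbon
#' atoms whose inner hard-sphere surface realises a known radius function
#' r(z): a straight cylinder or a smooth hourglass
#' \deqn{r(z) = r_{waist} + (r_{end} - r_{waist})
#'       (1 - e^{-(z - z_0)^2 / 2\sigma^2})}
#'
#' @param shape `"cylinder"` or `"hourglass"`.
#' @param radius cylinder radius (Angstrom).
#' @param r_end,r_waist hourglass end and waist radii (Angstrom).
#' @param z_waist axial position of the waist (Angstrom).
#' @param waist_sigma hourglass width parameter (Angstrom).
#' @param z_range axial extent `c(min, max)` (Angstrom).
#' @param ring_spacing spacing between atom rings (Angstrom).
#' @param n_ring atoms per ring.
#' @param element ring atom element (sets the hard-sphere radius via
#'   [atom_radii()]).
#' @param seed integer seed (ring phase offsets).
#' @return an object of class `pore_spec` with a callable `r_fun`.
#' @export
pore_spec <- function(shape = c("cylinder", "hourglass"), radius = 3.5,
                      r_end = 4.0, r_waist = 0.9, z_waist = 0,
                      waist_sigma = 3, z_range = c(-10, 10),
                      ring_spacing = 0.25, n_ring = 24, element = "C",
                      seed = 1) {
  shape <- match.arg(shape)
  r_fun <- if (shape == "cylinder") {
    force(radius); function(z) rep(radius, length(z))
  } else {
    function(z) r_waist + (r_end - r_waist) *
      (1 - exp(-(z - z_waist)^2 / (2 * waist_sigma^2)))
  }
  stopifnot(z_range[2] > z_range[1], ring_spacing > 0, n_ring >= 6)
  structure(list(shape = shape, r_fun = r_fun, z_range = z_range,
                 ring_spacing = ring_spacing, n_ring = n_ring,
                 element = element, seed = seed,
                 radius = radius, r_end = r_end, r_waist = r_waist,
                 z_waist = z_waist, waist_sigma = waist_sigma),
            class = "pore_spec")
}

#' Generate a toy pore structure with its analytic profile
#'
#' Stacks rings of atoms at radius `r(z) + R_atom` so the clearance radius
#' on the axis is exactly `r(z)` at each ring plane. Ring phases alternate
#' (seeded random offsets) so the wall has no straight grooves. Returns the
#' single-frame trajectory plus the analytic profile table on the same
#' axial grid the profiler would use.
#'
#' @param spec a [pore_spec()].
#' @param step grid step for the emitted analytic profile (Angstrom).
#' @return list with `traj` (a `kv_trajectory`), `analytic` (data frame
#'   `z`, `radius`), and `spec`.
#' @export
generate_toy_pore <- function(spec = pore_spec(), step = 0.125) {
  stopifnot(inherits(spec, "pore_spec"))
  r_atom <- unname(atom_radii()[spec$element])
  zs <- seq(spec$z_range[1], spec$z_range[2], by = spec$ring_spacing)
  coords <- with_seed(spec$seed, {
    do.call(rbind, lapply(zs, function(z) {
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- phase + seq(0, 2 * pi, length.out = spec$n_ring + 1)[1:spec$n_ring]
      wall <- spec$r_fun(z) + r_atom
      cbind(wall * cos(ang), wall * sin(ang), z)
    }))
  })
  n <- nrow(coords)
  atoms <- data.frame(chain = "A", resno = seq_len(n), resid = "RNG",
                      elety = spec$element, elesy = spec$element)
  grid <- seq(spec$z_range[1], spec$z_range[2], by = step)
  list(traj = trajectory(atoms, as.vector(t(coords))),
       analytic = data.frame(z = grid, radius = spec$r_fun(grid)),
       spec = spec)
}
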