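#' Default hard-sphere atomic radii (Angstrom)
#'
#' Explicit radius table used by the pore profiler so that profiles are
#' reproducible bit-for-bit from a config; values are simple hard-sphere
#' radii per element.
#'
#' @return named numeric vector.
#' @export
atom_radii <- function() {
  c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, P = 2.10, H = 1.00)
}

#' @noRd
.atom_radius_vec <- function(elesy, table = atom_radii()) {
  r <- unname(table[elesy])
  if (any(is.na(r)))
    stop("no hard-sphere radius for element(s): ",
         paste(unique(elesy[is.na(r)]), collapse = ", "))
  r
}

# Principal symmetry axis of a coordinate set: the gyration-tensor
# eigenvector whose eigenvalue is most separated from the other two (for a
# C4 channel the two perpendicular eigenvalues are nearly equal).
#' @noRd
.symmetry_axis <- function(coords) {
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  gaps <- vapply(1:3, function(i) min(abs(eg$values[i] - eg$values[-i])),
                 numeric(1))
  axis <- eg$vectors[, which.max(gaps)]
  if (axis[3] < 0) axis <- -axis
  list(origin = ctr, direction = axis / sqrt(sum(axis^2)))
}

# Orthonormal frame with w = axis direction
#' @noRd
.axis_frame <- function(direction) {
  w <- direction / sqrt(sum(direction^2))
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

# clearance of a probe centred at (cx, cy) in slice z against atoms given in
# axis coordinates; +Inf when no atom is in reach
#' @noRd
.clearance <- function(cx, cy, z, axy, az, rad) {
  if (!length(az)) return(Inf)
  min(sqrt((axy[, 1] - cx)^2 + (axy[, 2] - cy)^2 + (az - z)^2) - rad)
}

#' Pore-radius profile along the conduction axis
#'
#' HOLE-style profile: at each axial step the largest sphere that fits the
#' pore without overlapping any atom's hard sphere is found by maximising
#' the clearance \eqn{\min_i(|c - x_i| - R_i)} over sphere centres in the
#' slice plane, using Metropolis simulated annealing with geometric cooling
#' followed by a Nelder-Mead polish. Radii are capped at `r_max` (empty
#' regions report exactly the cap) and floored at 0. The centre search is
#' restricted to a disc around the axis so the probe follows the pore.
#'
#' @param traj a `kv_trajectory` (single frame used) or n x 3 coordinate
#'   matrix.
#' @param frame frame index when `traj` is a trajectory.
#' @param axis `NULL` for the automatic symmetry axis, or a list
#'   `list(origin = , direction = )`, or a 2 x 3 matrix of two points on the
#'   axis.
#' @param z_range axial range (Angstrom, axis coordinates) to profile;
#'   default covers the structure's axial extent.
#' @param step axial step (Angstrom).
#' @param r_max radius cap (Angstrom).
#' @param disc_radius search disc radius around the axis (Angstrom).
#' @param radii hard-sphere radius per atom, or a named element table; see
#'   [atom_radii()].
#' @param elements element symbols (needed when `traj` is a bare matrix and
#'   `radii` is a table).
#' @param n_anneal Metropolis iterations per slice.
#' @param t0,t_final initial and final annealing temperatures (Angstrom of
#'   clearance).
#' @param step_sd proposal standard deviation (Angstrom).
#' @param seed RNG seed (mandatory: the annealing is stochastic).
#' @return a `pore_profile` data frame: `z`, `radius`, `cx`, `cy` (centre
#'   path in axis coordinates).
#' @export
pore_profile <- function(traj, frame = 1, axis = NULL, z_range = NULL,
                         step = 0.125, r_max = 5.0, disc_radius = 5.0,
                         radii = atom_radii(), elements = NULL,
                         n_anneal = 250, t0 = 0.5, t_final = 0.01,
                         step_sd = 0.3, seed = 1) {
  coords <- if (inherits(traj, "kv_trajectory")) {
    elements <- traj$atoms$elesy
    frame_coords(traj, frame)
  } else as.matrix(traj)
  if (!nrow(coords)) stop("empty structure")
  rad <- if (length(radii) == nrow(coords) && is.null(names(radii))) radii
         else .atom_radius_vec(elements, radii)

  if (is.null(axis)) {
    ax <- .symmetry_axis(coords)
  } else if (is.matrix(axis)) {
    d <- axis[2, ] - axis[1, ]
    ax <- list(origin = axis[1, ], direction = d / sqrt(sum(d^2)))
  } else ax <- axis
  fr <- .axis_frame(ax$direction)
  local <- sweep(coords, 2, ax$origin) %*% fr   # columns: u, v, w(=z)
  axy <- local[, 1:2, drop = FALSE]
  az <- local[, 3]

  if (is.null(z_range)) z_range <- range(az)
  zs <- seq(z_range[1], z_range[2], by = step)
  out_of_extent <- z_range[1] < min(az) - 1e-9 || z_range[2] > max(az) + 1e-9
  if (out_of_extent)
    warning("z_range extends beyond the atom extent; radii there are capped")

  radius <- numeric(length(zs))
  cx <- numeric(length(zs)); cy <- numeric(length(zs))
  prev <- c(0, 0)
  n_temp <- max(n_anneal - 1, 1)
  cool <- (t_final / t0)^(1 / n_temp)

  with_seed(seed, {
    for (zi in seq_along(zs)) {
      z <- zs[zi]
      keep <- abs(az - z) < r_max + rad + disc_radius
      sxy <- axy[keep, , drop = FALSE]
      sz <- az[keep]; sr <- rad[keep]
      if (!length(sz)) {
        radius[zi] <- r_max; cx[zi] <- prev[1]; cy[zi] <- prev[2]
        next
      }
      cur <- prev
      f_cur <- .clearance(cur[1], cur[2], z, sxy, sz, sr)
      best <- cur; f_best <- f_cur
      temp <- t0
      for (it in seq_len(n_anneal)) {
        prop <- cur + stats::rnorm(2, 0, step_sd)
        if (sum(prop^2) <= disc_radius^2) {
          f_prop <- .clearance(prop[1], prop[2], z, sxy, sz, sr)
          if (f_prop >= f_cur ||
              stats::runif(1) < exp((f_prop - f_cur) / temp)) {
            cur <- prop; f_cur <- f_prop
            if (f_cur > f_best) { best <- cur; f_best <- f_cur }
          }
        }
        temp <- temp * cool
      }
      # deterministic polish from the annealing optimum
      pol <- stats::optim(best, function(p) {
        if (sum(p^2) > disc_radius^2) return(1e6 + sum(p^2))
        -.clearance(p[1], p[2], z, sxy, sz, sr)
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 400))
      if (-pol$value > f_best) { best <- pol$par; f_best <- -pol$value }
      radius[zi] <- min(max(f_best, 0), r_max)
      cx[zi] <- best[1]; cy[zi] <- best[2]
      prev <- best
    }
  })
  structure(data.frame(z = zs, radius = radius, cx = cx, cy = cy),
            class = c("pore_profile", "data.frame"))
}

#' Minimum radius (constriction) of a pore profile
#'
#' @param profile a `pore_profile`.
#' @param z_window optional `c(min, max)` axial window (Angstrom).
#' @return list with `z_at_min`, `r_min`, and `degenerate` (TRUE when the
#'   whole window sits at the radius cap so the minimum is not localised);
#'   ties are broken by smallest `|z|`.
#' @export
min_radius <- function(profile, z_window = NULL) {
  df <- profile
  if (!is.null(z_window))
    df <- df[df$z >= z_window[1] & df$z <= z_window[2], , drop = FALSE]
  if (!nrow(df)) stop("z_window contains no profile points")
  r_min <- min(df$radius)
  cand <- df$z[df$radius <= r_min + 1e-12]
  z_at <- cand[which.min(abs(cand))]
  list(z_at_min = z_at, r_min = r_min,
       degenerate = all(df$radius >= max(df$radius) - 1e-9) &&
         stats::sd(df$radius) < 1e-9)
}

#' Mean pore profile over trajectory frames
#'
#' Profiles every frame (same axis, grid and annealing parameters;
#' per-frame seeds derived from `seed`) and averages radii and centre paths
#' per axial step.
#'
#' @inheritParams pore_profile
#' @param frames frame indices (default all).
#' @return a `pore_profile` with per-z mean radius.
#' @export
mean_profile <- function(traj, frames = seq_len(traj$n_frames), seed = 1, ...) {
  profs <- lapply(seq_along(frames), function(i) {
    pore_profile(traj, frame = frames[i], seed = seed + i - 1, ...)
  })
  base <- profs[[1]]
  for (col in c("radius", "cx", "cy")) {
    base[[col]] <- Reduce(`+`, lapply(profs, `[[`, col)) / length(profs)
  }
  base
}

#' Write a pore profile as TSV
#'
#' @param profile a `pore_profile`.
#' @param path output path.
#' @param hole_layout if TRUE, write only the two columns `z` and `radius`
#'   (HOLE-compatible layout).
#' @export
write_pore_profile <- function(profile, path, hole_layout = FALSE) {
  df <- if (hole_layout) profile[, c("z", "radius")] else as.data.frame(profile)
  write_tsv(df, path)
}
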