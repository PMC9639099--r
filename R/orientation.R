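#' Build a tilt/azimuth orientation grid
#'
#' Samples the sphere of rigid-body orientations with even tilt steps and a
#' tilt-dependent number of azimuth points, so per-sample solid angles stay
#' roughly constant: the tilt runs over `theta = 0, dtheta, ..., 180` degrees
#' and at each tilt the azimuth takes `n(theta) = max(1, round(equator_count
#' * sin(theta)))` equally spaced values starting at 0 over [0, 360). With the
#' defaults (`dtheta = 10`, `equator_count = 36`) that gives 36 azimuths on
#' the equator and a single point at each pole.
#'
#' Each sample carries a solid-angle weight (steradian): the tilt band
#' `[theta - dtheta/2, theta + dtheta/2]` split evenly over its `n(theta)`
#' azimuths, with the poles treated as spherical caps of half-angle
#' `dtheta/2`; the weights sum to exactly `4*pi`. Ensemble sums weight
#' orientations evenly by default (the grid is designed so the per-sample
#' solid angles are roughly equal); the weights are attached for diagnostics.
#'
#' @param dtheta Tilt step, degrees; must divide 180.
#' @param equator_count Azimuth count at `theta = 90` degrees.
#' @param rounding How `equator_count * sin(theta)` is integerised:
#'   `"round"` (default) or `"floor"`.
#' @return A tibble with columns `theta_deg`, `phi_deg`, `weight_sr` and the
#'   attribute `M` (number of samples, also `nrow`).
#' @examples
#' g <- build_grid()
#' nrow(g)                                  # M = 412 with rounding = "round"
#' sum(g$weight_sr) - 4 * pi                # ~0
#' @export
build_grid <- function(dtheta = 10, equator_count = 36,
                       rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (!is.finite(dtheta) || dtheta <= 0 || abs(180 / dtheta - round(180 / dtheta)) > 1e-9) {
    abort("dtheta must be a positive divisor of 180 degrees")
  }
  if (equator_count < 1) abort("equator_count must be >= 1")
  # guard against sin() rounding (e.g. 36*sin(30 deg) = 17.9999...) before floor
  intify <- if (rounding == "round") round else function(x) floor(x + 1e-9)
  thetas <- seq(0, 180, by = dtheta)
  deg <- pi / 180

  rows <- purrr::map(thetas, function(th) {
    n <- max(1L, as.integer(intify(equator_count * sin(th * deg))))
    phis <- seq(0, 360, length.out = n + 1)[seq_len(n)]
    # solid angle of this tilt band (poles are caps of half-angle dtheta/2)
    lo <- max(0, th - dtheta / 2)
    hi <- min(180, th + dtheta / 2)
    band <- 2 * pi * (cos(lo * deg) - cos(hi * deg))
    tibble(theta_deg = th, phi_deg = phis, weight_sr = band / n)
  })
  grid <- dplyr::bind_rows(rows)
  attr(grid, "M") <- nrow(grid)
  grid
}

# 3x3 rotation realizing (tilt, azimuth): spin about the body z axis by phi,
# then tilt about y by theta -> R_y(theta) %*% R_z(phi), degrees. (Applying
# the azimuth last, about the lab z axis, would leave every atom height --
# and hence every observable -- unchanged, collapsing the azimuth scan.)
rotation_zy <- function(theta, phi) {
  t <- theta * pi / 180
  p <- phi * pi / 180
  Ry <- matrix(c(cos(t), 0, -sin(t),
                 0, 1, 0,
                 sin(t), 0, cos(t)), 3, 3)
  Rz <- matrix(c(cos(p), sin(p), 0,
                 -sin(p), cos(p), 0,
                 0, 0, 1), 3, 3)
  Ry %*% Rz
}

#' Rotate a structure to a grid orientation
#'
#' Centers the coordinates on the structure centroid and applies the rigid
#' rotation `R_y(theta) %*% R_z(phi)` (degrees): the azimuth phi spins the
#' body about its own z axis, then the tilt theta leans that axis over. At
#' the poles (theta = 0 or 180) all azimuths coincide up to an in-plane
#' spin, matching the single grid point placed there. The body frame at
#' `theta = phi = 0` is the structure's own input frame; since crystal
#' structures carry an arbitrary frame, absolute orientation labels are
#' convention-dependent, while ensemble summaries over a full grid are
#' frame-robust up to grid discretisation.
#'
#' @param structure A structure tibble.
#' @param theta,phi Tilt and azimuth, degrees.
#' @return The rotated, centroid-centered structure with attributes
#'   `theta`/`phi` recorded.
#' @export
orient <- function(structure, theta, phi) {
  xyz <- coords(structure)
  centered <- sweep(xyz, 2, colMeans(xyz))
  rot <- centered %*% t(rotation_zy(theta, phi))
  out <- structure
  out$x <- rot[, 1]; out$y <- rot[, 2]; out$z <- rot[, 3]
  out <- restamp(out, structure)
  attr(out, "theta") <- theta
  attr(out, "phi") <- phi
  out
}

#' Place a structure above the electrode plane
#'
#' Translates the structure rigidly along z so the gap between the electrode
#' plane (z = 0) and the van der Waals surface of the closest atom,
#' `min(z_i - radius_i)`, equals `gap`. The default 4.1 Angstrom keeps the
#' ion-exclusion (Stern) shells of protein and electrode from overlapping.
#'
#' @param structure A structure tibble (typically from [orient()]).
#' @param gap Gap between plane and closest van der Waals surface, Angstrom.
#' @return The placed structure; attribute `gap` records the setting.
#' @export
place <- function(structure, gap = 4.1) {
  if (!is.finite(gap) || gap <= 0) abort("gap must be a positive distance")
  shift <- gap - min(structure$z - structure$radius)
  out <- structure
  out$z <- structure$z + shift
  out <- restamp(out, structure)
  attr(out, "theta") <- attr(structure, "theta")
  attr(out, "phi") <- attr(structure, "phi")
  attr(out, "gap") <- gap
  out
}

#' Electron-transfer distance of a placed structure
#'
#' Perpendicular distance from the marked ET-entry atom to the electrode
#' plane, i.e. that atom's z coordinate.
#'
#' @param placed A placed structure with a marked entry atom.
#' @return Distance in Angstrom.
#' @export
et_distance <- function(placed) {
  et <- attr(placed, "et_entry_serial")
  if (is.null(et) || is.na(et)) {
    abort("no ET-entry atom marked; see mark_entry_atom()")
  }
  placed$z[match(et, placed$serial)]
}
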