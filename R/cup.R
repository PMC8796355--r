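#' Acetabular cup specification
#'
#' The simulation uses a 44-mm outer-diameter hemispherical shell.  Two
#' variants matter: the standard 4-mm shell used for the seating simulation,
#' and a 0.01-mm "eggshell" whose outer surface is the measurement surface
#' for coverage.
#'
#' @param outer_diameter_mm Outer diameter (default 44).
#' @param shell_thickness_mm Shell thickness (default 4; eggshell 0.01).
#' @param subdivision Mesh refinement level (>= 0); the hemisphere is a
#'   latitude-longitude grid with `4 * 2^subdivision` rows.
#' @return An object of class `cc_cupspec`.
#' @export
cup_spec <- function(outer_diameter_mm = 44, shell_thickness_mm = 4,
                     subdivision = 3) {
  if (outer_diameter_mm <= 0) stop("outer_diameter_mm must be > 0",
                                   call. = FALSE)
  if (shell_thickness_mm <= 0 || shell_thickness_mm >= outer_diameter_mm / 2) {
    stop("shell_thickness_mm must lie in (0, outer_diameter/2)",
         call. = FALSE)
  }
  if (subdivision < 0) stop("subdivision must be >= 0", call. = FALSE)
  structure(list(outer_diameter_mm = outer_diameter_mm,
                 shell_thickness_mm = shell_thickness_mm,
                 subdivision = as.integer(subdivision)),
            class = "cc_cupspec")
}

#' Eggshell measurement-cup specification
#' @param outer_diameter_mm Outer diameter (default 44).
#' @param subdivision Refinement level.
#' @return A [cup_spec()] with 0.01-mm shell.
#' @export
eggshell_spec <- function(outer_diameter_mm = 44, subdivision = 3) {
  cup_spec(outer_diameter_mm, 0.01, subdivision)
}

#' Cup polar axis from radiographic angles
#'
#' Radiographic conventions: inclination (abduction) is the angle between the
#' coronal-plane projection of the cup axis and the longitudinal (superior)
#' axis; anteversion is the angle between the axis and the coronal plane.
#' In frame coordinates `(lateral, anterior, superior)` the axis pointing out
#' of the cup opening is
#' `u = (cos(RA) sin(RI), sin(RA), -cos(RA) cos(RI))`
#' with `RI` = inclination and `RA` = anteversion.
#'
#' @param abduction_deg Inclination angle in degrees, in `[0, 90)`.
#' @param anteversion_deg Anteversion angle in degrees, in `[0, 90)`.
#' @param frame Optional [build_pelvic_frame()] result; when given, the axis
#'   is returned in world coordinates, otherwise in frame coordinates.
#' @return Unit length-3 vector.
#' @export
cup_axis_from_angles <- function(abduction_deg, anteversion_deg,
                                 frame = NULL) {
  if (abduction_deg < 0 || abduction_deg >= 90 ||
      anteversion_deg < 0 || anteversion_deg >= 90) {
    stop("angles must lie in [0, 90) degrees", call. = FALSE)
  }
  ri <- abduction_deg * pi / 180
  ra <- anteversion_deg * pi / 180
  u <- c(cos(ra) * sin(ri), sin(ra), -cos(ra) * cos(ri))
  u <- u / vnorm(u)
  if (is.null(frame)) {
    u
  } else {
    as.numeric(u[1] * frame$lateral_axis + u[2] * frame$anterior_axis +
               u[3] * frame$superior_axis)
  }
}

#' Recover radiographic angles from a cup axis (frame coordinates)
#' @param u Unit axis in `(lateral, anterior, superior)` coordinates.
#' @return Named vector `c(abduction_deg, anteversion_deg)`.
#' @export
angles_from_cup_axis <- function(u) {
  u <- vunit(assert_point3(u, "axis"))
  ra <- asin(u[2])
  ri <- atan2(u[1], -u[3])
  c(abduction_deg = ri * 180 / pi, anteversion_deg = ra * 180 / pi)
}

#' Cup pose: centre plus polar axis
#'
#' @param center Cup centre (mm, world coordinates).
#' @param polar_axis Unit vector out of the cup opening.
#' @param abduction_deg,anteversion_deg The angles the axis was built from
#'   (recorded for reporting; the study protocol allows 45 +- 1 and
#'   20 +- 1 degrees).
#' @param ref_dir Optional reference direction (typically the pelvic
#'   anterior axis) anchoring the cup mesh's azimuthal origin, so meshes
#'   built from this pose co-rotate with the anatomy.
#' @return An object of class `cc_cuppose`.
#' @export
cup_pose <- function(center, polar_axis, abduction_deg = NA_real_,
                     anteversion_deg = NA_real_, ref_dir = NULL) {
  polar_axis <- vunit(assert_point3(polar_axis, "polar_axis"))
  if (!is.na(abduction_deg) &&
      (abduction_deg < 44 || abduction_deg > 46)) {
    warning("abduction outside the 45 +- 1 degree protocol band")
  }
  if (!is.na(anteversion_deg) &&
      (anteversion_deg < 19 || anteversion_deg > 21)) {
    warning("anteversion outside the 20 +- 1 degree protocol band")
  }
  structure(list(center = assert_point3(center, "center"),
                 polar_axis = polar_axis,
                 abduction_deg = abduction_deg,
                 anteversion_deg = anteversion_deg,
                 ref_dir = ref_dir),
            class = "cc_cuppose")
}

# Orthonormal basis (e1, e2) completing axis p; deterministic.  When a
# reference direction is supplied (e.g. the pelvic anterior axis) the basis
# co-rotates with the anatomy, which keeps facet layouts - and therefore
# every facet-based measurement - exactly equivariant under rigid motion.
axis_basis <- function(p, ref = NULL) {
  if (is.null(ref) || vnorm(vcross(ref, p)) < 1e-6) {
    ref <- if (abs(p[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  }
  e1 <- vunit(vcross(ref, p))
  e2 <- vcross(p, e1)
  list(e1 = e1, e2 = e2)
}

# Latitude-longitude hemisphere mesh of radius r about `center`, dome pole
# along `pole` (unit).  Returns trimesh open at the equator.
hemisphere_mesh <- function(center, pole, r, n_theta, n_phi,
                            flip = FALSE, ref = NULL) {
  b <- axis_basis(pole, ref)
  theta <- seq(0, pi / 2, length.out = n_theta + 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  # vertices: pole + rings
  verts <- matrix(0, 1 + n_theta * n_phi, 3)
  verts[1, ] <- center + r * pole
  idx <- function(i, j) {           # ring i in 1..n_theta, col j in 1..n_phi
    1 + (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  }
  k <- 2
  for (i in seq_len(n_theta)) {
    st <- sin(theta[i + 1]); ct <- cos(theta[i + 1])
    for (j in seq_len(n_phi)) {
      dirv <- st * (cos(phi[j]) * b$e1 + sin(phi[j]) * b$e2) + ct * pole
      verts[k, ] <- center + r * dirv
      k <- k + 1
    }
  }
  faces <- matrix(0L, n_phi + 2 * (n_theta - 1) * n_phi, 3)
  k <- 1
  for (j in seq_len(n_phi)) {       # pole fan
    faces[k, ] <- c(1L, idx(1, j), idx(1, j + 1))
    k <- k + 1
  }
  if (n_theta > 1) {
    for (i in seq_len(n_theta - 1)) {
      for (j in seq_len(n_phi)) {
        v00 <- idx(i, j); v01 <- idx(i, j + 1)
        v10 <- idx(i + 1, j); v11 <- idx(i + 1, j + 1)
        faces[k, ] <- c(v00, v10, v11); k <- k + 1
        faces[k, ] <- c(v00, v11, v01); k <- k + 1
      }
    }
  }
  if (flip) faces <- faces[, c(1, 3, 2)]
  trimesh(verts, faces)
}

#' Build a cup mesh in a given pose
#'
#' `outer_shell_only` returns just the outer hemispherical surface (the
#' coverage measurement surface; open at the equator).  `full_shell` returns
#' the closed solid shell: outer hemisphere, inner hemisphere and the rim
#' annulus.  The outer surface area converges to `2*pi*(d/2)^2` from below
#' as the subdivision level increases (inscribed facets).
#'
#' @param spec A [cup_spec()].
#' @param pose A [cup_pose()].
#' @param variant `"outer_shell_only"` or `"full_shell"`.
#' @return A [trimesh()].
#' @export
build_cup_mesh <- function(spec, pose,
                           variant = c("outer_shell_only", "full_shell")) {
  variant <- match.arg(variant)
  r_out <- spec$outer_diameter_mm / 2
  n_theta <- 4L * 2L^spec$subdivision
  n_phi <- 4L * n_theta
  dome <- -pose$polar_axis   # dome points opposite the opening
  outer <- hemisphere_mesh(pose$center, dome, r_out, n_theta, n_phi,
                           ref = pose$ref_dir)
  if (variant == "outer_shell_only") {
    return(outer)
  }
  r_in <- r_out - spec$shell_thickness_mm
  inner <- hemisphere_mesh(pose$center, dome, r_in, n_theta, n_phi,
                           flip = TRUE, ref = pose$ref_dir)
  shell <- merge_meshes(outer, inner)
  # rim annulus joining the two equator rings
  n_out <- nrow(outer$vertices)
  last_ring_out <- (n_out - n_phi + 1):n_out
  last_ring_in <- n_out + ((nrow(inner$vertices) - n_phi + 1):
                             nrow(inner$vertices))
  ann <- matrix(0L, 2 * n_phi, 3)
  for (j in seq_len(n_phi)) {
    jo <- last_ring_out[j]; jo1 <- last_ring_out[(j %% n_phi) + 1]
    ji <- last_ring_in[j]; ji1 <- last_ring_in[(j %% n_phi) + 1]
    ann[2 * j - 1, ] <- c(jo, ji, ji1)
    ann[2 * j, ] <- c(jo, ji1, jo1)
  }
  trimesh(shell$vertices, rbind(shell$faces, ann))
}

# Deterministic quasi-uniform sample of n points on the cup outer dome
# (used for contact detection during seating).  Fibonacci spiral on the
# hemisphere about `dome`.
cup_surface_samples <- function(center, polar_axis, r, n = 200,
                                ref = NULL) {
  dome <- -polar_axis
  b <- axis_basis(dome, ref)
  i <- seq_len(n) - 0.5
  ct <- 1 - i / n            # cos(theta) in (0, 1): dome half only
  st <- sqrt(pmax(0, 1 - ct^2))
  ga <- pi * (3 - sqrt(5))
  ang <- ga * (seq_len(n) - 1)
  dirs <- outer(st * cos(ang), b$e1) + outer(st * sin(ang), b$e2) +
    outer(ct, dome)
  sweep(dirs * r, 2, center, "+")
}

# Points on the cup rim circle (radius r_out about center in the plane
# perpendicular to the polar axis).
cup_rim_points <- function(center, polar_axis, r, n = 360, ref = NULL) {
  b <- axis_basis(polar_axis, ref)
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  sweep(outer(cos(ang), b$e1) * r + outer(sin(ang), b$e2) * r, 2, center, "+")
}
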