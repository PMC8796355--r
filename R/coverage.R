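#' Classify cup facets as covered or uncovered by host bone
#'
#' A facet of the eggshell measurement surface is covered when its centroid
#' lies inside the bone solid or within `eps` mm of the bone surface
#' (see [point_in_solid()]).  The total uncoverage ratio (TUCR) is the
#' uncovered facet area divided by the total surface area of the
#' measurement shell.
#'
#' @param bone Watertight bone [trimesh()].
#' @param cup_outer_surface Cup measurement surface [trimesh()]
#'   (see [build_cup_mesh()] variant `"outer_shell_only"`).
#' @param eps Surface tolerance band in mm (default 0.1): a facet closer
#'   than this to the bone counts as supported, absorbing mesh
#'   discretization without inventing coverage.
#' @return An object of class `cc_coverage`: per-facet `covered` flags,
#'   `face_areas`, `total_area_mm2`, `uncovered_area_mm2`, `tucr`.
#' @export
classify_coverage <- function(bone, cup_outer_surface, eps = 0.1) {
  if (!bone$watertight) {
    stop(sprintf("bone mesh is not watertight: %d open/non-manifold edges",
                 bone$n_open_edges), call. = FALSE)
  }
  centroids <- face_centroids(cup_outer_surface)
  covered <- point_in_solid(bone, centroids, eps = eps)
  areas <- cup_outer_surface$face_areas
  total <- sum(areas)
  uncov <- sum(areas[!covered])
  structure(list(covered = covered,
                 face_areas = areas,
                 centroids = centroids,
                 total_area_mm2 = total,
                 uncovered_area_mm2 = uncov,
                 tucr = uncov / total),
            class = "cc_coverage")
}

#' Acetabular quadrant planes
#'
#' The quadrant system lifts the 2-D screw-zone construction to 3-D: the
#' quadrantal sagittal plane passes through both ASIS and the cup centre;
#' the quadrantal horizontal plane passes through the cup centre with its
#' normal along the ipsilateral-ASIS-to-cup-centre direction, which makes it
#' perpendicular to the quadrantal sagittal plane.  Orientation: the
#' sagittal plane's positive side is anterior; the horizontal plane's
#' positive side is inferior (its normal points from the ASIS toward the
#' cup).
#'
#' @param landmarks A [pelvic_landmarks()] object.
#' @param frame The matching [build_pelvic_frame()] result.
#' @param cup_center Cup centre (mm).
#' @return An object of class `cc_qplanes` with `sagittal_q` and
#'   `horizontal_q` [plane()]s.
#' @export
quadrant_planes <- function(landmarks, frame, cup_center) {
  cup_center <- assert_point3(cup_center, "cup_center")
  al <- landmarks$asis_left
  ar <- landmarks$asis_right
  ipsi <- if (landmarks$side == "right") ar else al
  axis_dir <- cup_center - ipsi
  # degenerate when the cup centre sits on the inter-ASIS line
  if (vnorm(vcross(ar - al, axis_dir)) / 2 <= 1e-9 * vnorm(ar - al)) {
    stop("degenerate geometry: cup centre is collinear with the two ASIS",
         call. = FALSE)
  }
  sagittal_q <- plane_from_points(al, ar, cup_center)
  if (sum(plane_normal(sagittal_q) * frame$anterior_axis) < 0) {
    sagittal_q <- plane(-sagittal_q$a, -sagittal_q$b, -sagittal_q$c,
                        -sagittal_q$d)
  }
  horizontal_q <- plane_from_point_normal(cup_center, vunit(axis_dir))
  structure(list(sagittal_q = sagittal_q, horizontal_q = horizontal_q),
            class = "cc_qplanes")
}

#' Segmental uncoverage ratios over the four acetabular quadrants
#'
#' Each facet is assigned to exactly one of the anterior-superior (A-S),
#' anterior-inferior (A-I), posterior-superior (P-S) and posterior-inferior
#' (P-I) segments by the signs of its centroid's signed distances to the two
#' quadrant planes.  Centroids within 1e-9 mm of a plane are assigned to the
#' anterior, respectively superior, side (deterministic, measure-zero
#' tie-break).  Every segmental ratio uses the TOTAL cup surface area as
#' denominator, so the four segmental ratios sum to the TUCR identically.
#'
#' @param cov A [classify_coverage()] result.
#' @param planes A [quadrant_planes()] result for the same pose.
#' @return An object of class `cc_ucrs` with fields `asucr`, `aiucr`,
#'   `psucr`, `piucr`, `tucr` plus per-segment uncovered areas.
#' @export
segmental_ucrs <- function(cov, planes) {
  s_sag <- signed_plane_distances(planes$sagittal_q, cov$centroids)
  s_hor <- signed_plane_distances(planes$horizontal_q, cov$centroids)
  tie <- 1e-9
  anterior <- s_sag > tie | abs(s_sag) <= tie       # ties -> anterior
  inferior <- s_hor > tie                            # ties -> superior
  seg <- ifelse(anterior,
                ifelse(inferior, "AI", "AS"),
                ifelse(inferior, "PI", "PS"))
  total <- cov$total_area_mm2
  unc_area <- function(lbl) {
    sum(cov$face_areas[!cov$covered & seg == lbl])
  }
  a_as <- unc_area("AS"); a_ai <- unc_area("AI")
  a_ps <- unc_area("PS"); a_pi <- unc_area("PI")
  structure(list(
    asucr = a_as / total,
    aiucr = a_ai / total,
    psucr = a_ps / total,
    piucr = a_pi / total,
    tucr = (a_as + a_ai + a_ps + a_pi) / total,
    uncovered_area_mm2 = c(AS = a_as, AI = a_ai, PS = a_ps, PI = a_pi),
    total_area_mm2 = total,
    segment = seg
  ), class = "cc_ucrs")
}

#' Export the classified cup as a colored PLY for visual QC
#'
#' Writes an ASCII PLY with per-face red/green coloring (uncovered/covered).
#'
#' @param cov A [classify_coverage()] result.
#' @param cup_outer_surface The measurement-surface mesh the coverage was
#'   computed on.
#' @param path Output path.
#' @export
write_coverage_ply <- function(cov, cup_outer_surface, path) {
  v <- cup_outer_surface$vertices
  f <- cup_outer_surface$faces
  col <- ifelse(cov$covered, "0 200 0", "220 0 0")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d %s", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L,
                     col), con)
  invisible(path)
}
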