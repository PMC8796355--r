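#' Acetabular height
#'
#' The perpendicular distance from the most superior acetabular rim point to
#' the plane parallel to the pelvic horizontal plane through the acetabular
#' lower edge.  "Most superior" is taken over the provided rim landmark set,
#' not over the whole bone mesh (on a full hemipelvis the global superior
#' extreme would be the iliac crest, which is clearly not the intended
#' point).
#'
#' @param landmarks A [pelvic_landmarks()] object.
#' @param frame The matching pelvic frame.
#' @return Height in mm (0 is reported, with a warning, when all rim points
#'   sit at the lower-edge level).
#' @export
acetabular_height <- function(landmarks, frame) {
  rim <- landmarks$acetabular_rim_points
  if (nrow(rim) < 1) stop("empty rim point list", call. = FALSE)
  sup <- signed_coordinates(frame, rim)[, "superior"]
  top <- rim[which.max(sup), ]
  lower_plane <- plane_from_point_normal(landmarks$acetabular_lower_edge,
                                         frame$superior_axis)
  h <- point_plane_distance(lower_plane, top)
  if (h <= 1e-9) {
    warning("degenerate acetabulum: all rim points at the lower-edge level")
  }
  h
}

#' Anterior-posterior diameter at half acetabular height
#'
#' A horizontal slab of thickness `slab_mm` (default 0.5 mm, the CT slice
#' thickness the morphometry emulates) is placed at half the acetabular
#' height above the lower edge.  Bone-surface vertices falling inside the
#' slab and inside the acetabular neighbourhood (a ball around the rim
#' centroid whose radius is 1.1 times the largest rim-point spread, plus
#' 0.5 mm) are collected, and the A-P diameter is their extent along the
#' frame's anterior axis.
#'
#' @param bone Bone [trimesh()].
#' @param landmarks A [pelvic_landmarks()] object.
#' @param frame The matching pelvic frame.
#' @param height_mm Acetabular height (from [acetabular_height()]).
#' @param slab_mm Slab thickness in mm.
#' @return A-P diameter in mm.
#' @export
ap_diameter <- function(bone, landmarks, frame, height_mm, slab_mm = 0.5) {
  if (height_mm <= 0) stop("height_mm must be > 0", call. = FALSE)
  le_sup <- signed_coordinates(frame, landmarks$acetabular_lower_edge)[3]
  level <- le_sup + height_mm / 2
  level_point <- frame$origin + level * frame$superior_axis
  rim <- landmarks$acetabular_rim_points
  rim_centroid <- colMeans(rim)
  rim_spread <- max(sqrt(rowSums(
    (rim - matrix(rim_centroid, nrow(rim), 3, byrow = TRUE))^2)))
  sel_radius <- 1.1 * rim_spread + 0.5
  # surface points at the half-height level: plane section of the mesh,
  # plus any vertices falling inside the slab band
  sect <- mesh_plane_section(bone, level_point, frame$superior_axis)
  co_v <- signed_coordinates(frame, bone$vertices)
  in_band <- abs(co_v[, "superior"] - level) <= slab_mm / 2
  pts <- rbind(sect, bone$vertices[in_band, , drop = FALSE])
  if (nrow(pts) > 0) {
    d_centroid <- sqrt(rowSums(
      (pts - matrix(rim_centroid, nrow(pts), 3, byrow = TRUE))^2))
    pts <- pts[d_centroid <= sel_radius, , drop = FALSE]
  }
  if (nrow(pts) == 0) {
    stop(paste0("empty slab intersection at half height ", round(level, 2),
                " mm: the slab missed the socket"), call. = FALSE)
  }
  ant <- signed_coordinates(frame, pts)[, "anterior"]
  max(ant) - min(ant)
}

#' Acetabular volume proxy V = H * R * R
#'
#' The true acetabulum in this population is roughly conic, and the study
#' protocol summarizes its size by the product of the height and the square
#' of the A-P diameter (no shape constant).
#'
#' @param height_mm Acetabular height H (mm).
#' @param ap_diameter_mm A-P diameter R (mm).
#' @return Volume proxy in mm^3, exactly `H * R * R`.
#' @export
volume_proxy <- function(height_mm, ap_diameter_mm) {
  if (height_mm <= 0 || ap_diameter_mm <= 0) {
    stop("height and A-P diameter must be > 0", call. = FALSE)
  }
  height_mm * ap_diameter_mm * ap_diameter_mm
}
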