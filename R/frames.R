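#' Pelvic landmark set
#'
#' The landmark set drives every downstream step: the anterior pelvic plane
#' (APP) frame is built from the bilateral anterior-superior iliac spines
#' (ASIS) and pubic tubercles; cup seating uses the transverse-ligament and
#' anterior-wall points; morphometrics use the acetabular rim ring and the
#' acetabular lower edge.
#'
#' @param asis_left,asis_right ASIS positions (mm).
#' @param pubic_tubercle_left,pubic_tubercle_right Pubic tubercles (mm).
#' @param transverse_ligament_point Inferior tangency landmark (mm).
#' @param anterior_wall_point Anterior tangency landmark (mm).
#' @param acetabular_lower_edge Inferior margin of the true acetabulum (mm).
#' @param acetabular_rim_points Matrix (k x 3) of rim points, k >= 1.
#' @param side `"left"` or `"right"`: the hip under study.
#' @return An object of class `cc_landmarks`.
#' @export
pelvic_landmarks <- function(asis_left, asis_right,
                             pubic_tubercle_left, pubic_tubercle_right,
                             transverse_ligament_point,
                             anterior_wall_point,
                             acetabular_lower_edge,
                             acetabular_rim_points,
                             side = c("right", "left")) {
  side <- match.arg(side)
  lm <- list(
    asis_left = assert_point3(asis_left, "asis_left"),
    asis_right = assert_point3(asis_right, "asis_right"),
    pubic_tubercle_left = assert_point3(pubic_tubercle_left,
                                        "pubic_tubercle_left"),
    pubic_tubercle_right = assert_point3(pubic_tubercle_right,
                                         "pubic_tubercle_right"),
    transverse_ligament_point = assert_point3(transverse_ligament_point,
                                              "transverse_ligament_point"),
    anterior_wall_point = assert_point3(anterior_wall_point,
                                        "anterior_wall_point"),
    acetabular_lower_edge = assert_point3(acetabular_lower_edge,
                                          "acetabular_lower_edge"),
    acetabular_rim_points = {
      m <- as.matrix(acetabular_rim_points)
      if (is.null(dim(acetabular_rim_points)) && length(acetabular_rim_points) == 3) {
        m <- matrix(acetabular_rim_points, 1, 3)
      }
      if (ncol(m) != 3 || nrow(m) < 1 || any(!is.finite(m))) {
        stop("acetabular_rim_points must be a finite k x 3 matrix, k >= 1",
             call. = FALSE)
      }
      storage.mode(m) <- "double"
      m
    },
    side = side
  )
  inter_asis <- vnorm(lm$asis_left - lm$asis_right)
  if (inter_asis < 1) {
    stop("ASIS points must be at least 1 mm apart", call. = FALSE)
  }
  if (inter_asis < 50) {
    warning("inter-ASIS distance below 50 mm: not a realistic adult pelvis")
  }
  structure(lm, class = "cc_landmarks")
}

#' @export
apply_transform.cc_landmarks <- function(transform, x) {
  out <- x
  for (k in c("asis_left", "asis_right", "pubic_tubercle_left",
              "pubic_tubercle_right", "transverse_ligament_point",
              "anterior_wall_point", "acetabular_lower_edge")) {
    out[[k]] <- apply_transform.default(transform, x[[k]])
  }
  out$acetabular_rim_points <-
    apply_transform.default(transform, x$acetabular_rim_points)
  out
}

landmark_keys <- c("asis_left", "asis_right", "pubic_tubercle_left",
                   "pubic_tubercle_right", "transverse_ligament_point",
                   "anterior_wall_point", "acetabular_lower_edge")

#' Read a landmark set from JSON
#'
#' The schema has one `[x, y, z]` mm triple per named key, an array of
#' triples under `"rim"`, and `"side": "left"|"right"`.  Missing keys raise
#' explicit errors.
#'
#' @param path JSON file path.
#' @return A [pelvic_landmarks()] object.
#' @export
read_landmarks_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(c(landmark_keys, "rim", "side"), names(j))
  if (length(missing) > 0) {
    stop(sprintf("landmark file %s is missing keys: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rim <- j$rim
  if (is.list(rim)) rim <- do.call(rbind, rim)
  pelvic_landmarks(j$asis_left, j$asis_right,
                   j$pubic_tubercle_left, j$pubic_tubercle_right,
                   j$transverse_ligament_point, j$anterior_wall_point,
                   j$acetabular_lower_edge, rim, side = j$side)
}

#' Write a landmark set to JSON
#' @param landmarks A [pelvic_landmarks()] object.
#' @param path Output path.
#' @export
write_landmarks_json <- function(landmarks, path) {
  j <- lapply(landmark_keys, function(k) landmarks[[k]])
  names(j) <- landmark_keys
  j$rim <- landmarks$acetabular_rim_points
  j$side <- landmarks$side
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the standard pelvic coordinate frame
#'
#' The coronal plane passes through both ASIS and the midpoint of the pubic
#' tubercles (the three-point reduction of the four-point APP).  The sagittal
#' plane is perpendicular to it through the tubercle midpoint with its normal
#' along the inter-ASIS direction, and the horizontal plane is perpendicular
#' to both through the same origin.  Axes: `lateral_axis` points toward the
#' study side, `anterior_axis` away from the pelvis front (positive signed
#' distance for anterior points), `superior_axis` toward the ASIS level.
#'
#' @param landmarks A [pelvic_landmarks()] object.
#' @return An object of class `cc_frame` with origin, three unit axes and
#'   the three standard planes.
#' @export
build_pelvic_frame <- function(landmarks) {
  al <- landmarks$asis_left
  ar <- landmarks$asis_right
  origin <- (landmarks$pubic_tubercle_left +
             landmarks$pubic_tubercle_right) / 2
  if (vnorm(al - ar) < 1e-9) {
    stop("zero-length inter-ASIS vector", call. = FALSE)
  }
  # right-handed anatomical triad (right, anterior, superior):
  #   right    = inter-ASIS direction (left ASIS -> right ASIS)
  #   anterior = (asis_mid - origin) x right  (coronal-plane normal)
  #   superior = right x anterior  (in-plane, toward the ASIS level)
  right_dir <- vunit(ar - al)
  s_raw <- (al + ar) / 2 - origin
  n_cor <- vcross(s_raw, right_dir)
  if (vnorm(n_cor) <= 1e-9) {
    stop("degenerate geometry: APP points are collinear", call. = FALSE)
  }
  anterior <- vunit(n_cor)
  sup <- vcross(right_dir, anterior)
  lat <- if (landmarks$side == "right") right_dir else -right_dir
  frame <- structure(list(
    origin = origin,
    lateral_axis = lat,
    anterior_axis = anterior,
    superior_axis = sup,
    coronal_plane = plane_from_point_normal(origin, anterior),
    sagittal_plane = plane_from_point_normal(origin, lat),
    horizontal_plane = plane_from_point_normal(origin, sup),
    side = landmarks$side
  ), class = "cc_frame")
  frame
}

#' Coordinates of a point in the pelvic frame
#'
#' @param frame A [build_pelvic_frame()] result.
#' @param p Point (mm) or `n x 3` matrix.
#' @return `(lateral, anterior, superior)` mm triple (or `n x 3` matrix).
#' @export
signed_coordinates <- function(frame, p) {
  basis <- cbind(frame$lateral_axis, frame$anterior_axis,
                 frame$superior_axis)
  if (is.null(dim(p))) {
    as.numeric(crossprod(basis, assert_point3(p) - frame$origin))
  } else {
    out <- (as.matrix(p) - matrix(frame$origin, nrow(p), 3, byrow = TRUE)) %*%
      basis
    colnames(out) <- c("lateral", "anterior", "superior")
    out
  }
}

#' Reconstruct a world point from frame coordinates
#' @param frame A `cc_frame`.
#' @param coords `(lateral, anterior, superior)` mm triple.
#' @return World point (mm).
#' @export
from_frame_coordinates <- function(frame, coords) {
  frame$origin + coords[1] * frame$lateral_axis +
    coords[2] * frame$anterior_axis + coords[3] * frame$superior_axis
}
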