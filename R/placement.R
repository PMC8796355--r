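#' Seat the cup in the true acetabulum
#'
#' Deterministic implementation of the implantation rules: the cup axis is
#' fixed by the configured abduction/anteversion angles; the cup is then
#' medialized along its polar axis (translated toward the dome direction,
#' starting from the centroid of the acetabular rim landmarks) until further
#' translation would drive the shell into bone; finally the pose is
#' projected onto the anterior-wall and transverse-ligament tangency
#' constraints by coordinate descent, re-checking medial contact after every
#' correction.
#'
#' Contact is detected by a strict penetration test on a deterministic
#' sample of the cup outer dome: the cup is in medial contact when moving
#' one further `step_mm` medially would place at least one sample point
#' strictly inside the bone.  The final contact depth is refined by
#' bisection to 0.01 mm so the seated centre does not depend on the
#' marching step.
#'
#' Tangency operationalization: the anterior-wall constraint matches, along
#' the anterior axis, the cup rim point nearest the anterior-wall landmark
#' with that landmark; the transverse-ligament constraint matches the
#' superior coordinate of the inferior-most cup rim point with the ligament
#' landmark's superior coordinate (the ligament is a landmark point in this
#' data model, not a surface).
#'
#' @param bone Watertight bone [trimesh()].
#' @param landmarks A [pelvic_landmarks()] object.
#' @param frame The matching pelvic frame.
#' @param spec A [cup_spec()].
#' @param abduction_deg,anteversion_deg Cup orientation (default 45 / 20).
#' @param step_mm Medialization march step (default 0.1).
#' @param tol_mm Constraint tolerance (default 0.2).
#' @param max_iter Maximum coordinate-descent sweeps (default 500).
#' @param n_samples Contact sample count on the cup dome (default 400).
#' @param search_mm Maximum medialization distance before declaring failure
#'   (default 200).
#' @return A [cup_pose()] with extra fields: `medialization_mm`,
#'   `residuals` (anterior/inferior, mm), `active_constraints`, `iterations`.
#' @export
place_cup <- function(bone, landmarks, frame, spec,
                      abduction_deg = 45, anteversion_deg = 20,
                      step_mm = 0.1, tol_mm = 0.2, max_iter = 500,
                      n_samples = 400, search_mm = 200) {
  if (!bone$watertight) {
    stop(sprintf("bone mesh is not watertight: %d open/non-manifold edges",
                 bone$n_open_edges), call. = FALSE)
  }
  u <- cup_axis_from_angles(abduction_deg, anteversion_deg, frame)
  dome <- -u
  r_out <- spec$outer_diameter_mm / 2
  start <- colMeans(landmarks$acetabular_rim_points)

  ref <- frame$anterior_axis
  penetrates <- function(center, n = n_samples) {
    s <- cup_surface_samples(center, polar_axis = u, r = r_out, n = n,
                             ref = ref)
    any(point_in_solid(bone, s, eps = 0))
  }

  # March along `dome` from `from` until the next step would penetrate,
  # then bisect the bracketing interval.  The approach march uses a coarse
  # stride and a reduced sample set; the bracket is then re-walked at
  # `step_mm` and bisected at full sampling, so the converged depth is
  # independent of the stride.  Returns the contact-depth t.
  medialize <- function(from) {
    n_coarse <- max(50L, n_samples %/% 4L)
    coarse <- 10 * step_mm
    if (penetrates(from)) {
      # already interpenetrating (can happen after a tangency correction):
      # back out laterally until free, then re-seat
      t_back <- 0
      while (penetrates(from + t_back * (-dome))) {
        t_back <- t_back + step_mm
        if (t_back > search_mm) {
          stop("placement failure: cannot back the cup out of bone",
               call. = FALSE)
        }
      }
      lo <- -t_back
      hi <- -(t_back - step_mm)
    } else {
      t <- 0
      repeat {
        if (t > search_mm) {
          stop(sprintf(paste0("placement failure: no medial contact within ",
                              "%g mm search box"), search_mm), call. = FALSE)
        }
        if (penetrates(from + (t + coarse) * dome, n_coarse)) break
        t <- t + coarse
      }
      t <- max(0, t - coarse)         # full sampling may contact earlier
      repeat {                        # refine the coarse bracket at step_mm
        if (penetrates(from + (t + step_mm) * dome)) break
        t <- t + step_mm
      }
      lo <- t
      hi <- t + step_mm
    }
    # bisect [lo, hi]: lo penetration-free, hi penetrating
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (penetrates(from + mid * dome)) hi <- mid else lo <- mid
    }
    lo
  }

  residuals <- function(center) {
    rim <- cup_rim_points(center, u, r_out, n = 720, ref = ref)
    # anterior-wall: rim point nearest the landmark, matched along anterior
    awp <- landmarks$anterior_wall_point
    d2 <- rowSums((rim - matrix(awp, nrow(rim), 3, byrow = TRUE))^2)
    near <- rim[which.min(d2), ]
    res_a <- sum((awp - near) * frame$anterior_axis)
    # transverse ligament: superior coordinate of the inferior-most rim point
    sup_co <- (rim %*% frame$superior_axis)[, 1]
    inf_pt <- rim[which.min(sup_co), ]
    lig_sup <- sum((landmarks$transverse_ligament_point - frame$origin) *
                   frame$superior_axis)
    res_i <- lig_sup - sum((inf_pt - frame$origin) * frame$superior_axis)
    c(anterior = res_a, inferior = res_i)
  }

  center <- start
  total_medial <- 0
  iter <- 0
  repeat {
    iter <- iter + 1
    t <- medialize(center)
    center <- center + t * dome
    total_medial <- total_medial + t
    res <- residuals(center)
    if (all(abs(res) <= tol_mm) || iter >= max_iter) break
    # damped corrections: never jump more than 3 mm per sweep, so a bad
    # residual cannot throw the cup onto a different contact configuration
    clamp <- function(x) max(-3, min(3, x))
    center <- center + clamp(res["anterior"]) * frame$anterior_axis +
      clamp(res["inferior"]) * frame$superior_axis
  }
  res <- residuals(center)
  medial_active <- penetrates(center + 2 * step_mm * dome)
  pose <- cup_pose(center, u, abduction_deg, anteversion_deg,
                   ref_dir = frame$anterior_axis)
  pose$medialization_mm <- total_medial
  pose$residuals <- res
  pose$active_constraints <- c(medial = medial_active,
                               anterior = abs(res["anterior"]) <= tol_mm,
                               inferior = abs(res["inferior"]) <= tol_mm)
  pose$iterations <- iter
  if (any(abs(res) > tol_mm)) {
    warning(sprintf(paste0("tangency constraints not met within tol: ",
                           "anterior %.3f mm, inferior %.3f mm"),
                    res["anterior"], res["inferior"]))
  }
  pose
}

#' Serialize a pose to JSON
#' @param pose A [cup_pose()] (typically from [place_cup()]).
#' @param path Output path.
#' @export
write_pose_json <- function(pose, path) {
  j <- list(center = pose$center, polar_axis = pose$polar_axis,
            abduction_deg = pose$abduction_deg,
            anteversion_deg = pose$anteversion_deg,
            medialization_mm = pose$medialization_mm,
            residuals = as.list(pose$residuals),
            active_constraints = as.list(pose$active_constraints))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
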