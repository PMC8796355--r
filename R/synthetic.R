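## Synthetic Crowe-IV hemipelvis phantoms.
##
## The generator builds a stylized bone model whose coverage ground truth is
## known by construction: the articular support is a spherical shell
## congruent with the cup (inner radius = cup outer radius) spanning the cup
## dome, from which per-quadrant "deficiency windows" are removed.  The two
## quadrant planes intersect in a line through the cup centre, so the four
## quadrant segments are exact dihedral sectors around that line; a window
## is the rim-adjacent part (polar angle >= theta0) of its quadrant's
## sector, with theta0 solved so the removed solid angle matches the
## requested deficiency fraction.  Ground truth is then computed from the
## realized cell set of the shell mesh by sub-cell quadrature, so the
## pipeline is compared against exactly the geometry that was built.
## Acetabular height and A-P diameter are realized by an elliptical rim
## landmark ring and a pair of small anterior/posterior wall blocks, so the
## morphometric ground truth is exact.

#' Parameters for one synthetic hip
#'
#' @param height_mm Target acetabular height H (sanity band 15-50 mm; the
#'   emulated population has H about 32 +- 4 mm).
#' @param ap_diameter_mm Target A-P diameter R (band 15-50 mm; population
#'   about 25 +- 5 mm).
#' @param deficiency Named fractions `c(AS=, AI=, PS=, PI=)`, each between 0 and 1: the
#'   fraction of each quadrant segment's cup area left unsupported by bone.
#' @param socket_depth_mm Bone stock behind the articular surface (shell
#'   thickness, default 6).
#' @param rim_offset_mm Offset of the rim ring centroid from the seated cup
#'   centre along the cup axis (default 26).
#' @param wall_block_mm Edge length of the anterior/posterior wall blocks
#'   (default 2).
#' @param mesh_resolution_mm Target facet edge length of the bone shell at
#'   the articular radius (default 1.2).
#' @param cup A [cup_spec()] (the default 44-mm cup).
#' @param abduction_deg,anteversion_deg Cup orientation the socket is built
#'   for (default 45 / 20).
#' @param side Hip side (default "right").
#' @param seed Integer echoed into the output (the construction itself is
#'   deterministic).
#' @return An object of class `cc_hipparams`.
#' @export
synthetic_hip_params <- function(height_mm = 31.99, ap_diameter_mm = 25.23,
                                 deficiency = c(AS = 0.2, AI = 0.1,
                                                PS = 0.3, PI = 0.1),
                                 socket_depth_mm = 6, rim_offset_mm = 26,
                                 wall_block_mm = 2,
                                 mesh_resolution_mm = 1.2,
                                 cup = cup_spec(),
                                 abduction_deg = 45, anteversion_deg = 20,
                                 side = "right", seed = 1L) {
  if (height_mm < 15 || height_mm > 50 ||
      ap_diameter_mm < 15 || ap_diameter_mm > 50) {
    stop("height_mm and ap_diameter_mm must lie in the [15, 50] mm band",
         call. = FALSE)
  }
  if (!all(c("AS", "AI", "PS", "PI") %in% names(deficiency))) {
    stop("deficiency must be named c(AS=, AI=, PS=, PI=)", call. = FALSE)
  }
  deficiency <- deficiency[c("AS", "AI", "PS", "PI")]
  if (any(deficiency < 0 | deficiency > 1)) {
    stop("deficiency fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(socket_depth_mm > 0, rim_offset_mm > 0, wall_block_mm > 0,
            mesh_resolution_mm > 0)
  structure(list(height_mm = height_mm, ap_diameter_mm = ap_diameter_mm,
                 deficiency = deficiency, socket_depth_mm = socket_depth_mm,
                 rim_offset_mm = rim_offset_mm, wall_block_mm = wall_block_mm,
                 mesh_resolution_mm = mesh_resolution_mm, cup = cup,
                 abduction_deg = abduction_deg,
                 anteversion_deg = anteversion_deg,
                 side = side, seed = as.integer(seed)),
            class = "cc_hipparams")
}

# Canonical pelvis landmark geometry (mm, frame = canonical basis):
# origin at the pubic-tubercle midpoint, ASIS at (+-120, 0, 80),
# tubercles at (+-15, 0, 0), right-hip socket centre near (88, -20, 5).
canonical_asis <- function(side) {
  list(asis_right = c(120, 0, 80), asis_left = c(-120, 0, 80),
       pt_right = c(15, 0, 0), pt_left = c(-15, 0, 0),
       socket_center = c(if (side == "right") 88 else -88, -20, 5))
}

# Direction on the unit sphere in (pole, b1, b2) spherical coordinates.
sph_dir <- function(theta, phi, pole, b1, b2) {
  st <- sin(theta)
  outer(st * cos(phi), b1) + outer(st * sin(phi), b2) +
    outer(cos(theta), pole)
}

# Quadrant label of direction rows `v` (n x 3) given quadrant planes whose
# zero sets pass through the cup centre.  Mirrors segmental_ucrs()'s
# tie-break (anterior / superior win ties).
quadrant_label_dirs <- function(v, planes) {
  tie <- 1e-9
  s_sag <- v %*% plane_normal(planes$sagittal_q)
  s_hor <- v %*% plane_normal(planes$horizontal_q)
  anterior <- as.vector(s_sag >= -tie)
  inferior <- as.vector(s_hor > tie)
  ifelse(anterior, ifelse(inferior, "AI", "AS"),
         ifelse(inferior, "PI", "PS"))
}

# Fraction of the cup dome's area in each quadrant (quadrature on a fine
# theta-phi grid; the dome is the hemisphere about `pole`).
quadrant_dome_weights <- function(pole, b1, b2, planes,
                                  n_theta = 256, n_phi = 512) {
  theta <- (seq_len(n_theta) - 0.5) * (pi / 2) / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  g <- expand.grid(theta = theta, phi = phi)
  v <- sph_dir(g$theta, g$phi, pole, b1, b2)
  lab <- quadrant_label_dirs(v, planes)
  wts <- sin(g$theta)
  tot <- sum(wts)
  vapply(c("AS", "AI", "PS", "PI"),
         function(q) sum(wts[lab == q]) / tot, numeric(1))
}

# Closed spherical-shell solid: radii [r_in, r_out] about `center`, spanning
# the hemisphere around `pole` minus the cells whose centre direction
# satisfies `remove_fn`.  Returns a watertight trimesh with the (theta,
# phi) grid and realized cell mask attached as attr "grid".
#
# The inner (articular) surface is circumscribed: its nodes are pushed out
# by the worst-case facet sag so no chord dips below r_in.  A congruent cup
# sphere therefore makes contact at (not before) the geometric seat -
# tangential contact amplifies any inward sag s into a seating error of
# order sqrt(2 * r * s), which would otherwise dominate the placement
# tolerance.
spherical_shell_mesh <- function(center, pole, b1, b2, r_in, r_out,
                                 remove_fn = NULL, res_deg = 3) {
  res <- res_deg * pi / 180
  half_diag <- sqrt(2) * res / 2
  r_in_node <- r_in / cos(half_diag)
  theta_lines <- seq(0, pi / 2, length.out = max(2L, ceiling(pi / 2 / res)) + 1L)
  phi_lines <- seq(0, 2 * pi, length.out = max(4L, ceiling(2 * pi / res)) + 1L)
  phi_lines <- phi_lines[-length(phi_lines)]
  nt <- length(theta_lines)           # nodes ring count (incl pole row)
  np <- length(phi_lines)

  # cells: (i in 1..nt-1) x (j in 1..np), theta in [theta_i, theta_{i+1}],
  # phi in [phi_j, phi_{j+1 (wrapped)}]; a cell is removed when remove_fn
  # is TRUE at its centre direction
  phi_next <- c(phi_lines[-1], phi_lines[1] + 2 * pi)
  solid <- matrix(TRUE, nt - 1, np)
  if (!is.null(remove_fn)) {
    tc <- (theta_lines[-nt] + theta_lines[-1]) / 2
    pc <- ((phi_lines + phi_next) / 2) %% (2 * pi)
    g <- expand.grid(theta = tc, phi = pc)
    dirs <- sph_dir(g$theta, g$phi, pole, b1, b2)
    solid <- matrix(!remove_fn(dirs), nt - 1, np)
    # never remove the pole row (the medial wall must stay closed there)
    solid[1, ] <- TRUE
    # de-pinch: diagonal corner contacts between solid cells make the wall
    # edge non-manifold; fill one removed cell of each diagonal pair
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(solid) - 1)) {
        for (j in seq_len(np)) {
          j1 <- (j %% np) + 1
          a <- solid[i, j]; b <- solid[i, j1]
          d <- solid[i + 1, j]; e <- solid[i + 1, j1]
          if (a && e && !b && !d) { solid[i, j1] <- TRUE; changed <- TRUE }
          else if (b && d && !a && !e) { solid[i, j] <- TRUE; changed <- TRUE }
        }
      }
      if (!changed) break
    }
  }

  # vertex ids: layer L (1 inner, 2 outer), ring i (1 = pole, then theta
  # rows 2..nt), col j in 1..np; pole rows collapse to a single vertex.
  nring <- nt - 1                      # non-pole theta rows
  ids_per_layer <- 1 + nring * np
  vid <- function(L, i, j) {           # i in 0 (pole) or 1..nring
    base <- (L - 1) * ids_per_layer
    if (i == 0) base + 1 else base + 1 + (i - 1) * np + ((j - 1) %% np) + 1
  }
  verts <- matrix(0, 2 * ids_per_layer, 3)
  for (L in 1:2) {
    r <- if (L == 1) r_in_node else r_out
    verts[vid(L, 0, 1), ] <- center + r * pole
    for (i in seq_len(nring)) {
      d <- sph_dir(rep(theta_lines[i + 1], np), phi_lines, pole, b1, b2)
      verts[(vid(L, i, 1)):(vid(L, i, np)), ] <-
        sweep(d * r, 2, center, "+")
    }
  }

  faces <- list()
  add <- function(a, b, c) faces[[length(faces) + 1L]] <<- c(a, b, c)

  # surface faces: inner (normal toward centre = outward from solid) and
  # outer (normal away from centre)
  for (i in seq_len(nt - 1)) {
    for (j in seq_len(np)) {
      if (!solid[i, j]) next
      j1 <- (j %% np) + 1
      if (i == 1) {                    # pole fan (theta_lines[1] == 0)
        add(vid(2, 0, 1), vid(2, 1, j), vid(2, 1, j1))       # outer
        add(vid(1, 0, 1), vid(1, 1, j1), vid(1, 1, j))       # inner
      } else {
        a <- vid(2, i - 1, j); b <- vid(2, i, j)
        cc <- vid(2, i, j1); d <- vid(2, i - 1, j1)
        add(a, b, cc); add(a, cc, d)                          # outer
        a <- vid(1, i - 1, j); b <- vid(1, i, j)
        cc <- vid(1, i, j1); d <- vid(1, i - 1, j1)
        add(a, cc, b); add(a, d, cc)                          # inner
      }
    }
  }

  # boundary walls: for each cell edge adjacent to a non-solid cell (or the
  # equator), connect the inner and outer copies of that edge
  is_solid <- function(i, j) {
    if (i < 1) return(TRUE)            # across the pole: treat as solid
    if (i > nt - 1) return(FALSE)      # beyond the equator
    solid[i, ((j - 1) %% np) + 1]
  }
  for (i in seq_len(nt - 1)) {
    for (j in seq_len(np)) {
      if (!solid[i, j]) next
      j1 <- (j %% np) + 1
      # edge at theta_{i+1} (toward equator), between cols j and j1
      if (!is_solid(i + 1, j)) {
        a1 <- vid(1, i, j); a2 <- vid(1, i, j1)
        b1_ <- vid(2, i, j); b2_ <- vid(2, i, j1)
        add(a1, a2, b2_); add(a1, b2_, b1_)
      }
      # edge at theta_i (toward pole)
      if (i > 1 && !is_solid(i - 1, j)) {
        a1 <- vid(1, i - 1, j); a2 <- vid(1, i - 1, j1)
        b1_ <- vid(2, i - 1, j); b2_ <- vid(2, i - 1, j1)
        add(a1, b2_, a2); add(a1, b1_, b2_)
      }
      # edge at phi_j (lower col side)
      if (!is_solid(i, j - 1)) {
        a1 <- if (i == 1) vid(1, 0, 1) else vid(1, i - 1, j)
        a2 <- vid(1, i, j)
        b1_ <- if (i == 1) vid(2, 0, 1) else vid(2, i - 1, j)
        b2_ <- vid(2, i, j)
        add(a1, a2, b2_)
        if (a1 != b1_) add(a1, b2_, b1_)
      }
      # edge at phi_{j+1} (upper col side)
      if (!is_solid(i, j + 1)) {
        a1 <- if (i == 1) vid(1, 0, 1) else vid(1, i - 1, j1)
        a2 <- vid(1, i, j1)
        b1_ <- if (i == 1) vid(2, 0, 1) else vid(2, i - 1, j1)
        b2_ <- vid(2, i, j1)
        add(a1, b2_, a2)
        if (a1 != b1_) add(a1, b1_, b2_)
      }
    }
  }

  f <- do.call(rbind, faces)
  # drop vertices never referenced (cells removed by windows)
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  out <- trimesh(verts[used, , drop = FALSE],
                 matrix(remap[f], ncol = 3))
  attr(out, "grid") <- list(theta_lines = theta_lines,
                            phi_lines = phi_lines, solid = solid)
  out
}

# In-plane rim basis for a cup axis u in a frame: `w` is the horizontal
# rim direction (perpendicular to both u and the superior axis), `q`
# completes it (the steepest rim direction).
rim_basis <- function(u, frame) {
  w <- vunit(vcross(u, frame$superior_axis))
  q <- vcross(u, w)
  list(w = w, q = q)
}

# Dihedral-sector decomposition of the quadrant partition.  Both quadrant
# planes contain the cup centre, so their intersection line (direction `e`)
# splits direction space into four wedges; the wedge a direction falls in
# depends only on its azimuth psi around `e`.  Returns the axis frame and
# each quadrant's psi interval.
quadrant_sectors <- function(planes) {
  n1 <- plane_normal(planes$sagittal_q)
  n2 <- plane_normal(planes$horizontal_q)
  e <- vunit(vcross(n1, n2))
  m1 <- vunit(vcross(e, n1))   # in the sagittal plane, perpendicular to e
  m2 <- vcross(e, m1)
  npsi <- 14400L
  psi <- (seq_len(npsi) - 0.5) * 2 * pi / npsi
  v <- outer(cos(psi), m1) + outer(sin(psi), m2)
  lab <- quadrant_label_dirs(v, planes)
  # boundaries where the label changes (4 of them)
  nxt <- c(lab[-1], lab[1])
  cuts <- which(lab != nxt)
  stopifnot(length(cuts) == 4)
  sectors <- list()
  for (k in seq_along(cuts)) {
    lo <- psi[cuts[k]] + pi / npsi
    hi_idx <- cuts[(k %% 4) + 1]
    hi <- psi[hi_idx] + pi / npsi
    mid <- if (hi > lo) (lo + hi) / 2 else ((lo + hi + 2 * pi) / 2) %% (2 * pi)
    vm <- cos(mid) * m1 + sin(mid) * m2
    sectors[[quadrant_label_dirs(matrix(vm, 1, 3), planes)]] <-
      c(lo = lo, hi = if (hi > lo) hi else hi + 2 * pi)
  }
  list(e = e, m1 = m1, m2 = m2, sectors = sectors)
}

# psi (azimuth around the sector axis) and theta (polar angle from the cup
# pole) of direction rows.
dir_psi <- function(v, sec) {
  atan2(v %*% sec$m2, v %*% sec$m1) %% (2 * pi)
}

in_psi_interval <- function(psi, lo, hi) {
  # interval given with hi possibly > 2*pi (wrapping)
  psi <- psi %% (2 * pi)
  (psi >= lo & psi <= hi) | (psi + 2 * pi >= lo & psi + 2 * pi <= hi)
}

# Deficiency-window search for quadrant `q_lab`: the window is the part of
# the quadrant's dihedral sector (shrunk by `margin_deg` on both sides)
# with polar angle >= theta0; theta0 is solved by bisection so the window's
# solid angle equals `needed_sr`.  Returns list(psi_lo, psi_hi, theta0).
find_window <- function(q_lab, needed_sr, pole, b1, b2, planes, sec,
                        margin_deg = 1.5, theta_cap_deg = 5) {
  if (needed_sr <= 0) return(NULL)
  margin <- margin_deg * pi / 180
  s <- sec$sectors[[q_lab]]
  lo <- s["lo"] + margin
  hi <- s["hi"] - margin
  if (hi <= lo) {
    stop(sprintf("infeasible geometry: quadrant %s sector too narrow",
                 q_lab), call. = FALSE)
  }
  # quadrature grid over the dome
  n_t <- 360L; n_p <- 720L
  theta <- (seq_len(n_t) - 0.5) * (pi / 2) / n_t
  phi <- (seq_len(n_p) - 0.5) * 2 * pi / n_p
  g <- expand.grid(theta = theta, phi = phi)
  v <- sph_dir(g$theta, g$phi, pole, b1, b2)
  in_sector <- in_psi_interval(as.vector(dir_psi(v, sec)), lo, hi)
  w_quad <- sin(g$theta) * (pi / 2 / n_t) * (2 * pi / n_p)
  area_deeper <- function(theta0) {
    sum(w_quad[in_sector & g$theta >= theta0])
  }
  theta_cap <- theta_cap_deg * pi / 180
  if (area_deeper(theta_cap) < needed_sr) {
    stop(sprintf(paste0("infeasible geometry: deficiency of quadrant %s ",
                        "needs %.3f sr but its sector only offers %.3f sr"),
                 q_lab, needed_sr, area_deeper(theta_cap)), call. = FALSE)
  }
  lo_t <- theta_cap; hi_t <- pi / 2
  for (k in 1:40) {
    mid <- (lo_t + hi_t) / 2
    if (area_deeper(mid) >= needed_sr) lo_t <- mid else hi_t <- mid
  }
  list(psi_lo = unname(lo), psi_hi = unname(hi), theta0 = lo_t)
}

# Exact-area ground truth of the realized shell: sums removed-cell areas,
# attributing boundary cells to quadrants by 6x6 sub-cell quadrature.
realized_ground_truth <- function(grid, pole, b1, b2, planes) {
  th <- grid$theta_lines; ph <- grid$phi_lines
  np <- length(ph)
  ph_next <- c(ph[-1], ph[1] + 2 * pi)
  gt <- c(AS = 0, AI = 0, PS = 0, PI = 0)
  sub <- (seq_len(6) - 0.5) / 6
  for (i in seq_len(nrow(grid$solid))) {
    removed <- which(!grid$solid[i, ])
    if (length(removed) == 0) next
    for (j in removed) {
      t_sub <- th[i] + sub * (th[i + 1] - th[i])
      p_sub <- ph[j] + sub * (ph_next[j] - ph[j])
      g <- expand.grid(theta = t_sub, phi = p_sub)
      v <- sph_dir(g$theta, g$phi, pole, b1, b2)
      lab <- quadrant_label_dirs(v, planes)
      w <- sin(g$theta)
      cell_area <- (ph_next[j] - ph[j]) * (cos(th[i]) - cos(th[i + 1]))
      for (q in names(gt)) {
        gt[[q]] <- gt[[q]] + cell_area * sum(w[lab == q]) / sum(w)
      }
    }
  }
  gt / (2 * pi)
}

# Quick feasibility probe used by the cohort sampler (mirrors the hard
# validation inside generate_hip without building meshes).
hip_feasible <- function(height_mm, ap_diameter_mm,
                         rim_offset_mm = 26, wall_block_mm = 2,
                         r_out = 22) {
  qz <- 0.74741  # |q . superior| for the 45/20 axis
  wy <- 0.88918  # |w . anterior|
  s_q <- height_mm / (2 * qz)
  s_w <- ap_diameter_mm / (2 * wy)
  sel_radius <- 1.1 * max(s_q, s_w) + 0.5
  shell_min <- sqrt(r_out^2 + rim_offset_mm^2)
  box_far <- sqrt((0.4577 * s_w)^2 + (ap_diameter_mm / 2)^2) +
    sqrt(3) * wall_block_mm / 2
  box_perp <- s_w + sqrt(3) * wall_block_mm / 2
  sel_radius < shell_min - 0.5 &&      # shell clear of the measurement ball
    box_far < sel_radius - 0.1 &&      # wall blocks inside the ball
    box_perp < r_out - 1.5             # wall blocks clear of the cup dome
}

#' Generate one synthetic Crowe-IV hip
#'
#' Builds a watertight bone model (articular support shell with deficiency
#' windows, plus two wall blocks), a consistent landmark set, and the exact
#' ground truth the pipeline should recover: segmental/total uncoverage
#' ratios, acetabular height, A-P diameter, the seated cup centre and the
#' medialization distance.
#'
#' @param params A [synthetic_hip_params()] object.
#' @return An object of class `cc_synthhip`: fields `bone`, `landmarks`,
#'   `frame`, `params`, `socket_center`, `ground_truth`.
#' @export
generate_hip <- function(params) {
  stopifnot(inherits(params, "cc_hipparams"))
  r_out <- params$cup$outer_diameter_mm / 2
  geo <- canonical_asis(params$side)
  cc <- geo$socket_center

  lm0 <- list(asis_left = geo$asis_left, asis_right = geo$asis_right,
              pt_left = geo$pt_left, pt_right = geo$pt_right)
  # frame from a provisional landmark set (rim filled in below)
  prov <- pelvic_landmarks(lm0$asis_left, lm0$asis_right, lm0$pt_left,
                           lm0$pt_right, cc, cc, cc,
                           matrix(cc, 1, 3), side = params$side)
  frame <- build_pelvic_frame(prov)
  u <- cup_axis_from_angles(params$abduction_deg, params$anteversion_deg,
                            frame)
  rb <- rim_basis(u, frame)
  w <- rb$w; q <- rb$q
  qz <- abs(sum(q * frame$superior_axis))
  wy <- abs(sum(w * frame$anterior_axis))
  s_q <- params$height_mm / (2 * qz)
  s_w <- params$ap_diameter_mm / (2 * wy)

  # rim landmark ring: ellipse about c0 = socket centre + rim offset
  a_off <- params$rim_offset_mm
  c0 <- cc + a_off * u
  n_rim <- 24L
  psi <- 2 * pi * (seq_len(n_rim) - 1L) / n_rim
  rim <- sweep(outer(cos(psi), s_w * w) + outer(sin(psi), s_q * q),
               2, c0, "+")
  q_inf <- if (sum(q * frame$superior_axis) < 0) q else -q
  lower_edge <- c0 + s_q * q_inf

  # tangency landmarks at the seated pose (cup centre = socket centre)
  ant <- frame$anterior_axis
  m_ant <- vunit(sum(w * ant) * w + sum(q * ant) * q)
  awp <- cc + r_out * m_ant
  tl <- cc + r_out * q_inf

  landmarks <- pelvic_landmarks(lm0$asis_left, lm0$asis_right,
                                lm0$pt_left, lm0$pt_right,
                                tl, awp, lower_edge, rim,
                                side = params$side)

  # wall blocks realizing the A-P diameter exactly (frame-axis aligned)
  wb <- params$wall_block_mm
  w_ant <- if (sum(w * ant) > 0) w else -w
  lat_off <- sum(s_w * w_ant * frame$lateral_axis)
  R_half <- params$ap_diameter_mm / 2
  mk_box <- function(a_lo, a_hi) {
    corners <- rbind(c(lat_off - wb / 2, a_lo, -wb / 2),
                     c(lat_off + wb / 2, a_hi, wb / 2))
    lo <- from_frame_coordinates(frame, corners[1, ]) + (c0 - frame$origin)
    hi <- from_frame_coordinates(frame, corners[2, ]) + (c0 - frame$origin)
    # canonical frame is axis-aligned so lo/hi are box corners directly
    box_mesh(pmin(lo, hi), pmax(lo, hi))
  }
  box_a <- mk_box(R_half - wb, R_half)
  box_p <- {
    corners <- rbind(c(-lat_off - wb / 2, -R_half, -wb / 2),
                     c(-lat_off + wb / 2, -R_half + wb, wb / 2))
    lo <- from_frame_coordinates(frame, corners[1, ]) + (c0 - frame$origin)
    hi <- from_frame_coordinates(frame, corners[2, ]) + (c0 - frame$origin)
    box_mesh(pmin(lo, hi), pmax(lo, hi))
  }

  # feasibility of the measurement geometry
  if (!hip_feasible(params$height_mm, params$ap_diameter_mm,
                    params$rim_offset_mm, wb, r_out)) {
    stop(paste0("infeasible geometry: height/A-P diameter targets are not ",
                "realizable with this rim offset and wall-block size"),
         call. = FALSE)
  }

  # quadrant planes at the (known) seated centre drive window placement
  planes <- quadrant_planes(landmarks, frame, cc)
  pole <- -u
  b <- axis_basis(pole)
  wts <- quadrant_dome_weights(pole, b$e1, b$e2, planes)

  f <- params$deficiency
  if (all(f >= 1)) {
    # no socket wall at all: flat plate tangent to the cup dome
    plate_n <- pole
    plate <- oriented_slab(cc + r_out * pole, plate_n, extent = 80,
                           depth = 40)
    bone <- merge_meshes(plate, box_a, box_p)
    gt <- list(asucr = unname(wts["AS"]), aiucr = unname(wts["AI"]),
               psucr = unname(wts["PS"]), piucr = unname(wts["PI"]),
               tucr = 1)
  } else {
    sec <- quadrant_sectors(planes)
    windows <- list()
    for (q_lab in c("AS", "AI", "PS", "PI")) {
      needed <- f[[q_lab]] * wts[[q_lab]] * 2 * pi
      win <- find_window(q_lab, needed, pole, b$e1, b$e2, planes, sec)
      if (!is.null(win)) windows[[length(windows) + 1L]] <- win
    }
    remove_fn <- if (length(windows) == 0) NULL else function(dirs) {
      psi <- as.vector(dir_psi(dirs, sec))
      theta <- acos(pmin(1, pmax(-1, dirs %*% pole)))
      out <- rep(FALSE, nrow(dirs))
      for (w in windows) {
        out <- out | (in_psi_interval(psi, w$psi_lo, w$psi_hi) &
                        theta >= w$theta0)
      }
      out
    }
    res_deg <- params$mesh_resolution_mm / r_out * 180 / pi
    shell <- spherical_shell_mesh(cc, pole, b$e1, b$e2, r_out,
                                  r_out + params$socket_depth_mm,
                                  remove_fn, res_deg = res_deg)
    bone <- merge_meshes(shell, box_a, box_p)
    gt_seg <- realized_ground_truth(attr(shell, "grid"), pole, b$e1, b$e2,
                                    planes)
    gt <- list(asucr = unname(gt_seg["AS"]), aiucr = unname(gt_seg["AI"]),
               psucr = unname(gt_seg["PS"]), piucr = unname(gt_seg["PI"]),
               tucr = unname(sum(gt_seg)))
  }
  gt$height_mm <- params$height_mm
  gt$ap_diameter_mm <- params$ap_diameter_mm
  gt$volume_proxy_mm3 <- params$height_mm * params$ap_diameter_mm^2
  gt$cup_center <- cc
  gt$medialization_mm <- a_off
  gt$quadrant_weights <- wts

  structure(list(bone = bone, landmarks = landmarks, frame = frame,
                 params = params, socket_center = cc, ground_truth = gt),
            class = "cc_synthhip")
}

# A thick slab: face plane through `face_point` with outward normal
# `-normal` ... the solid occupies the side the `normal` points into,
# to depth `depth`, laterally extent x extent.
oriented_slab <- function(face_point, normal, extent = 80, depth = 60) {
  n <- vunit(normal)
  b <- axis_basis(n)
  rot <- cbind(b$e1, b$e2, n)
  if (det(rot) < 0) rot <- cbind(b$e2, b$e1, n)
  local <- box_mesh(c(-extent, -extent, 0), c(extent, extent, depth))
  apply_transform(rigid_transform(rot, face_point), local)
}

#' Analytic half-space coverage fixture
#'
#' A large slab of bone bounded by a plane perpendicular to the cup polar
#' axis at signed offset `gap_mm` from the cup centre (positive offsets move
#' the face toward the dome pole, exposing a spherical zone of the cup).
#' The uncovered fraction of the 44-mm dome has the closed form
#' `clamp(gap / r, 0, 1)` (spherical-zone area over hemisphere area).
#' With `orientation = "axis_containing"` the slab face instead contains the
#' polar axis, leaving exactly half the dome uncovered.
#'
#' @param gap_mm Signed face offset along the dome direction (|gap| <= r).
#' @param cup A [cup_spec()].
#' @param orientation `"polar"` (face perpendicular to the axis) or
#'   `"axis_containing"` (face contains the axis).
#' @param side Hip side for the landmark scaffold.
#' @param rim_offset_mm Offset of the rim-ring start position (governs the
#'   analytic medialization distance, `gap_mm + rim_offset_mm - r` for the
#'   polar orientation).
#' @return A list: `bone`, `landmarks`, `frame`, `pose` (the reference pose
#'   at the fixture's cup centre), `gt` (closed-form uncovered fraction and
#'   medialization distance).
#' @export
half_space_fixture <- function(gap_mm, cup = cup_spec(),
                               orientation = c("polar", "axis_containing"),
                               side = "right", rim_offset_mm = 10) {
  orientation <- match.arg(orientation)
  r_out <- cup$outer_diameter_mm / 2
  if (abs(gap_mm) > r_out) stop("|gap_mm| must be <= the cup radius",
                                call. = FALSE)
  geo <- canonical_asis(side)
  cc <- geo$socket_center
  prov <- pelvic_landmarks(geo$asis_left, geo$asis_right, geo$pt_left,
                           geo$pt_right, cc, cc, cc, matrix(cc, 1, 3),
                           side = side)
  frame <- build_pelvic_frame(prov)
  u <- cup_axis_from_angles(45, 20, frame)
  pole <- -u
  if (orientation == "polar") {
    slab <- oriented_slab(cc + gap_mm * pole, pole, extent = 80, depth = 60)
    gt_unc <- min(max(gap_mm / r_out, 0), 1)
    seat <- cc
    medial_gt <- gap_mm + rim_offset_mm - r_out
  } else {
    n_side <- vunit(vcross(u, frame$superior_axis))
    slab <- oriented_slab(cc, n_side, extent = 80, depth = 60)
    gt_unc <- 0.5
    seat <- cc
    medial_gt <- NA_real_
  }
  rb <- rim_basis(u, frame)
  c0 <- cc + rim_offset_mm * u
  psi <- 2 * pi * (0:23) / 24
  rim <- sweep(outer(cos(psi), 20 * rb$w) + outer(sin(psi), 20 * rb$q),
               2, c0, "+")
  q_inf <- if (sum(rb$q * frame$superior_axis) < 0) rb$q else -rb$q
  # tangency landmarks at the analytic seated centre
  seat_c <- if (orientation == "polar") {
    c0 + (medial_gt) * pole
  } else {
    seat
  }
  ant <- frame$anterior_axis
  m_ant <- vunit(sum(rb$w * ant) * rb$w + sum(rb$q * ant) * rb$q)
  landmarks <- pelvic_landmarks(geo$asis_left, geo$asis_right, geo$pt_left,
                                geo$pt_right,
                                seat_c + r_out * q_inf,
                                seat_c + r_out * m_ant,
                                c0 + 20 * q_inf, rim, side = side)
  pose <- cup_pose(cc, u, 45, 20, ref_dir = frame$anterior_axis)
  list(bone = slab, landmarks = landmarks, frame = frame, pose = pose,
       gt = list(uncovered_fraction = gt_unc,
                 medialization_mm = medial_gt,
                 seated_center = seat_c))
}

#' Cohort-level generator parameters
#'
#' Defaults emulate the study population: acetabular height 31.99 +- 4.09
#' mm, A-P diameter 25.23 +- 4.82 mm, and per-quadrant deficiency-fraction
#' distributions chosen so the expected segmental uncoverage ratios match
#' the published cohort means under nominal (one-quarter) quadrant shares,
#' giving a total uncoverage ratio around 0.30 +- 0.10.  Sampling is
#' truncated-normal (+-3 SD, intersected with the generator's feasibility
#' band); the posterior-superior and posterior-inferior deficiencies share a
#' Gaussian correlation of 0.5.
#'
#' @param n_hips Number of hips (default 30).
#' @param height_mean,height_sd Height distribution (mm).
#' @param ap_mean,ap_sd A-P diameter distribution (mm).
#' @param deficiency_mean,deficiency_sd Named AS/AI/PS/PI fraction moments.
#'   The defaults are the published segmental uncoverage means (and SDs)
#'   divided by the corresponding quadrant's share of the cup dome area
#'   under the canonical geometry (AS 0.208, AI 0.125, PS 0.375, PI 0.292),
#'   so the expected segmental ratios of the synthetic cohort match the
#'   cohort being emulated.
#' @param ps_pi_correlation Gaussian correlation between the PS and PI
#'   deficiencies.
#' @param master_seed Master seed; per-hip child seeds derive from it.
#' @return An object of class `cc_cohortparams`.
#' @export
cohort_params <- function(n_hips = 30,
                          height_mean = 31.99, height_sd = 4.09,
                          ap_mean = 25.23, ap_sd = 4.82,
                          deficiency_mean = c(AS = 0.400, AI = 0.417,
                                              PS = 0.270, PI = 0.203),
                          deficiency_sd = c(AS = 0.205, AI = 0.197,
                                            PS = 0.116, PI = 0.164),
                          ps_pi_correlation = 0.5,
                          master_seed = 20200519) {
  if (n_hips < 1) stop("n_hips must be >= 1", call. = FALSE)
  if (height_sd < 0 || ap_sd < 0 || any(deficiency_sd < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(n_hips = as.integer(n_hips),
                 height_mean = height_mean, height_sd = height_sd,
                 ap_mean = ap_mean, ap_sd = ap_sd,
                 deficiency_mean = deficiency_mean[c("AS", "AI", "PS", "PI")],
                 deficiency_sd = deficiency_sd[c("AS", "AI", "PS", "PI")],
                 ps_pi_correlation = ps_pi_correlation,
                 master_seed = as.integer(master_seed)),
            class = "cc_cohortparams")
}

# Truncated-normal draw by rejection (deterministic under set.seed).
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i * 7919) %% 2147483629)
}

#' Draw the per-hip parameters of a synthetic cohort
#'
#' Separates the cohort's random draws from mesh construction so the
#' sampling distributions can be inspected (and tested) cheaply.  Heights
#' and A-P diameters are truncated-normal (+-3 SD intersected with the
#' phantom feasibility region); deficiency fractions are clamped Gaussians
#' with the configured posterior-superior/posterior-inferior correlation.
#'
#' @param cohort A [cohort_params()] object.
#' @return Data frame with columns `hip`, `seed`, `height_mm`,
#'   `ap_diameter_mm`, `f_AS`, `f_AI`, `f_PS`, `f_PI`.
#' @export
sample_cohort_params <- function(cohort) {
  stopifnot(inherits(cohort, "cc_cohortparams"))
  dm <- cohort$deficiency_mean
  ds <- cohort$deficiency_sd
  rho <- cohort$ps_pi_correlation
  f_cap <- 0.8     # feasibility ceiling for a single quadrant
  rows <- lapply(seq_len(cohort$n_hips), function(i) {
    seed_i <- child_seed(cohort$master_seed, i)
    set.seed(seed_i)
    # joint (H, R) draw restricted to the phantom's feasibility region
    for (try in 1:200) {
      h <- rtruncnorm1(cohort$height_mean, cohort$height_sd,
                       max(15, cohort$height_mean - 3 * cohort$height_sd),
                       min(44.5, cohort$height_mean + 3 * cohort$height_sd))
      r <- rtruncnorm1(cohort$ap_mean, cohort$ap_sd,
                       max(15.5, cohort$ap_mean - 3 * cohort$ap_sd),
                       min(34, cohort$ap_mean + 3 * cohort$ap_sd))
      if (hip_feasible(h, r)) break
    }
    # deficiencies: PS/PI correlated Gaussians, AS/AI independent
    z1 <- rnorm(1); z2 <- rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * z2
    clamp01 <- function(x) min(max(x, 0), f_cap)
    data.frame(hip = i, seed = seed_i, height_mm = h, ap_diameter_mm = r,
               f_AS = clamp01(rnorm(1, dm[["AS"]], ds[["AS"]])),
               f_AI = clamp01(rnorm(1, dm[["AI"]], ds[["AI"]])),
               f_PS = clamp01(dm[["PS"]] + ds[["PS"]] * z1),
               f_PI = clamp01(dm[["PI"]] + ds[["PI"]] * z2))
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' @param cohort A [cohort_params()] object.
#' @return List of [generate_hip()] results, length `n_hips`;
#'   bit-reproducible for a given master seed.
#' @export
generate_cohort <- function(cohort) {
  draws <- sample_cohort_params(cohort)
  lapply(seq_len(nrow(draws)), function(i) {
    d <- draws[i, ]
    generate_hip(synthetic_hip_params(
      height_mm = d$height_mm, ap_diameter_mm = d$ap_diameter_mm,
      deficiency = c(AS = d$f_AS, AI = d$f_AI, PS = d$f_PS, PI = d$f_PI),
      seed = d$seed))
  })
}
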