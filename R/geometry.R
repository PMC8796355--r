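#' @useDynLib cupcoverage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd cor.test lm ks.test t.test pt qt rnorm runif
#' @importFrom utils write.csv read.csv packageVersion
NULL

## ---- small vector helpers (3-vectors as length-3 numerics) ----------------

vec3 <- function(x, y, z) c(x, y, z)

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) {
    stop("cannot normalize a near-zero vector", call. = FALSE)
  }
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

assert_point3 <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3 || any(!is.finite(p))) {
    stop(sprintf("%s must be a finite numeric length-3 vector", what),
         call. = FALSE)
  }
  as.numeric(p)
}

## ---- planes ----------------------------------------------------------------

#' Oriented plane in millimetre space
#'
#' A plane is stored as coefficients `(a, b, c, d)` of the implicit equation
#' `a*x + b*y + c*z + d = 0`, with the normal `(a, b, c)` normalized to unit
#' length at construction.  The signed side of the plane is the side the
#' normal points into.
#'
#' @param a,b,c Normal components (any non-zero scale; normalized internally).
#' @param d Offset in mm (rescaled together with the normal).
#' @return An object of class `cc_plane` with fields `a`, `b`, `c`, `d`.
#' @export
plane <- function(a, b, c, d) {
  n <- sqrt(a * a + b * b + c * c)
  if (!is.finite(n) || n < 1e-12) {
    stop("degenerate plane: zero-length normal", call. = FALSE)
  }
  structure(list(a = a / n, b = b / n, c = c / n, d = d / n),
            class = "cc_plane")
}

plane_normal <- function(pl) c(pl$a, pl$b, pl$c)

#' Construct the plane through three points
#'
#' The normal is the normalized cross product of the two edge vectors.  When
#' `orient_toward` is given the normal is flipped, if needed, so that the
#' given point has positive signed distance.
#'
#' @param p,q,r Non-collinear points (mm).
#' @param orient_toward Optional point fixing the positive side.
#' @return A [plane()].
#' @export
plane_from_points <- function(p, q, r, orient_toward = NULL) {
  p <- assert_point3(p); q <- assert_point3(q); r <- assert_point3(r)
  n <- vcross(q - p, r - p)
  # |n| = 2 * triangle area
  if (vnorm(n) / 2 <= 1e-9) {
    stop("degenerate geometry: points are collinear or coincident",
         call. = FALSE)
  }
  n <- vunit(n)
  d <- -sum(n * p)
  if (!is.null(orient_toward)) {
    o <- assert_point3(orient_toward, "orient_toward")
    if (sum(n * o) + d < 0) {
      n <- -n
      d <- -d
    }
  }
  plane(n[1], n[2], n[3], d)
}

#' Plane through a point with a given normal
#' @param point Point on the plane (mm).
#' @param normal Plane normal (normalized internally).
#' @return A [plane()].
#' @export
plane_from_point_normal <- function(point, normal) {
  point <- assert_point3(point)
  n <- vunit(assert_point3(normal, "normal"))
  plane(n[1], n[2], n[3], -sum(n * point))
}

#' Perpendicular distance from a point to a plane
#'
#' Implements `|a*px + b*py + c*pz + d| / sqrt(a^2 + b^2 + c^2)` literally, so
#' the result is correct for unnormalized coefficient lists as well as for
#' [plane()] objects (whose normals are already unit length).
#'
#' @param pl A [plane()] or a list/vector with components a, b, c, d.
#' @param p Query point (mm).
#' @param signed If `TRUE` return the signed distance (positive on the side
#'   the normal points into).
#' @return Distance in mm.
#' @export
point_plane_distance <- function(pl, p, signed = FALSE) {
  p <- assert_point3(p)
  if (is.numeric(pl) && length(pl) == 4) {
    pl <- list(a = pl[1], b = pl[2], c = pl[3], d = pl[4])
  }
  num <- pl$a * p[1] + pl$b * p[2] + pl$c * p[3] + pl$d
  den <- sqrt(pl$a^2 + pl$b^2 + pl$c^2)
  if (den < 1e-12) stop("invalid plane: zero normal", call. = FALSE)
  if (signed) num / den else abs(num) / den
}

# Vectorized signed distances for an n x 3 matrix of points.
signed_plane_distances <- function(pl, pts) {
  (pts %*% plane_normal(pl) + pl$d)[, 1]
}

## ---- triangle meshes -------------------------------------------------------

#' Triangle mesh container
#'
#' Vertices are an `n x 3` numeric matrix (mm); faces an `m x 3` integer
#' matrix of 1-based vertex indices.  Per-face areas are cached at
#' construction.  The watertight flag is set only when every undirected edge
#' is shared by exactly two faces.
#'
#' @param vertices `n x 3` numeric matrix.
#' @param faces `m x 3` integer matrix (1-based).
#' @return An object of class `cc_trimesh` with fields `vertices`, `faces`,
#'   `face_areas`, `watertight`, `n_open_edges`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || any(!is.finite(vertices))) {
    stop("vertices must be a finite n x 3 matrix", call. = FALSE)
  }
  if (ncol(faces) != 3) stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("faces reference vertices outside 1..n", call. = FALSE)
  }
  areas <- face_areas(vertices, faces)
  ec <- edge_counts(faces)
  n_open <- sum(ec != 2L)
  structure(list(vertices = vertices,
                 faces = faces,
                 face_areas = areas,
                 watertight = nrow(faces) > 0 && n_open == 0L,
                 n_open_edges = n_open),
            class = "cc_trimesh")
}

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Count of faces sharing each undirected edge.
edge_counts <- function(faces) {
  if (nrow(faces) == 0) return(integer(0))
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Total surface area of a mesh
#' @param mesh A [trimesh()].
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) sum(mesh$face_areas)

#' Per-face centroids
#' @param mesh A [trimesh()].
#' @return `m x 3` matrix of face centroids (mm).
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; positive
#' when faces are wound counter-clockwise seen from outside.
#'
#' @param mesh A watertight [trimesh()].
#' @return Volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Point-in-solid membership test
#'
#' A point is "in" when it lies strictly inside the closed mesh, or within
#' `eps` mm of its surface.  The inside test is ray parity with a fixed
#' pseudo-random direction, re-cast along alternate directions whenever the
#' ray grazes an edge or vertex.
#'
#' @param mesh A watertight [trimesh()].
#' @param pts A point (length-3) or an `n x 3` matrix of query points.
#' @param eps Surface tolerance band in mm (default 0.1).
#' @return Logical vector, one flag per query point.
#' @export
point_in_solid <- function(mesh, pts, eps = 0.1) {
  if (!mesh$watertight) {
    stop(sprintf("mesh is not watertight: %d open/non-manifold edges",
                 mesh$n_open_edges), call. = FALSE)
  }
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  if (is.null(dim(pts))) pts <- matrix(assert_point3(pts), nrow = 1)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  .cpp_points_in_mesh(mesh$vertices, mesh$faces, pts, eps)
}

# Minimum distances from points to the mesh surface (mm).
min_dist_to_mesh <- function(mesh, pts) {
  if (is.null(dim(pts))) pts <- matrix(assert_point3(pts), nrow = 1)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  .cpp_min_dist_to_mesh(mesh$vertices, mesh$faces, pts)
}

## ---- rigid transforms ------------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 translation (mm).
#' @return An object of class `cc_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- assert_point3(translation, "translation")
  if (any(dim(rotation) != c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "cc_rigid")
}

#' Uniformly random rotation (for property tests)
#' @param seed Optional integer seed.
#' @return A [rigid_transform()] with random rotation and translation drawn
#'   uniformly in a +-50 mm box.
#' @export
random_rigid_transform <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # QR of a Gaussian matrix gives a Haar-ish rotation after sign fixing
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, runif(3, -50, 50))
}

#' Apply a rigid transform
#'
#' Methods exist for points (length-3 or `n x 3`), [trimesh()] objects,
#' [plane()] objects, and pelvic landmark sets.
#'
#' @param transform A [rigid_transform()].
#' @param x Object to transform.
#' @return The transformed object.
#' @export
apply_transform <- function(transform, x) UseMethod("apply_transform", x)

#' @export
apply_transform.default <- function(transform, x) {
  if (is.null(dim(x))) {
    as.numeric(transform$rotation %*% assert_point3(x) +
               transform$translation)
  } else {
    t(transform$rotation %*% t(as.matrix(x))) +
      matrix(transform$translation, nrow(x), 3, byrow = TRUE)
  }
}

#' @export
apply_transform.cc_trimesh <- function(transform, x) {
  trimesh(apply_transform.default(transform, x$vertices), x$faces)
}

#' @export
apply_transform.cc_plane <- function(transform, x) {
  n <- as.numeric(transform$rotation %*% plane_normal(x))
  # a point on the original plane, transformed
  p0 <- -x$d * plane_normal(x)
  p1 <- apply_transform.default(transform, p0)
  plane(n[1], n[2], n[3], -sum(n * p1))
}

## ---- STL input/output ------------------------------------------------------

#' Write a mesh to STL
#'
#' ASCII STL (the default) preserves coordinates to better than 1e-6 mm.
#' Binary STL stores float32 coordinates, so round-trip error grows with the
#' coordinate magnitude (about 1e-5 relative); use it only when file size
#' matters more than the last micrometre.
#'
#' @param mesh A [trimesh()].
#' @param path Output path.
#' @param binary Write binary STL instead of ASCII.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nx[i], ny[i], nz[i], a[i, ], b[i, ], c[i, ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    fmt <- function(x) sprintf("%.9e", x)
    lines <- character(7 * nrow(f) + 2)
    lines[1] <- "solid cupcoverage"
    k <- 2
    for (i in seq_len(nrow(f))) {
      lines[k] <- sprintf("  facet normal %s %s %s",
                          fmt(nx[i]), fmt(ny[i]), fmt(nz[i]))
      lines[k + 1] <- "    outer loop"
      lines[k + 2] <- sprintf("      vertex %s %s %s",
                              fmt(a[i, 1]), fmt(a[i, 2]), fmt(a[i, 3]))
      lines[k + 3] <- sprintf("      vertex %s %s %s",
                              fmt(b[i, 1]), fmt(b[i, 2]), fmt(b[i, 3]))
      lines[k + 4] <- sprintf("      vertex %s %s %s",
                              fmt(c[i, 1]), fmt(c[i, 2]), fmt(c[i, 3]))
      lines[k + 5] <- "    endloop"
      lines[k + 6] <- "  endfacet"
      k <- k + 7
    }
    lines[k] <- "endsolid cupcoverage"
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary, autodetected)
#'
#' Repeated facet vertices are merged exactly (coordinate-key dedup) so the
#' connectivity needed for watertightness checks is recovered.
#'
#' @param path STL file path.
#' @return A [trimesh()].
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    # a binary file may still start with "solid": verify by size heuristic
    txt <- tryCatch(readLines(path, n = 2L, warn = FALSE),
                    error = function(e) character(0))
    length(txt) >= 2 && grepl("facet", txt[2])
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    toks <- strsplit(trimws(vl), "\\s+")
    coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    coords <- matrix(NA_real_, 3 * nf, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (nrow(coords) %% 3 != 0) stop("malformed STL facet list", call. = FALSE)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  trimesh(verts, faces)
}

## ---- primitive meshes used by fixtures ------------------------------------

#' Axis-aligned box mesh
#' @param lo,hi Opposite corners (mm).
#' @return A watertight [trimesh()] (12 faces, outward winding).
#' @export
box_mesh <- function(lo, hi) {
  lo <- assert_point3(lo, "lo"); hi <- assert_point3(hi, "hi")
  if (any(hi <= lo)) stop("box_mesh needs hi > lo componentwise", call. = FALSE)
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  colnames(v) <- NULL
  # vertex order from expand.grid: index = 1 + (x==hi) + 2*(y==hi) + 4*(z==hi)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = hi (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = lo (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = hi (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = lo (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = hi (+x)
  trimesh(v, f)
}

# Intersection of a mesh surface with a plane: returns the endpoints of all
# face/plane crossing segments (k x 3 matrix; k = 0 when no face crosses).
mesh_plane_section <- function(mesh, point, normal) {
  n <- vunit(assert_point3(normal, "normal"))
  d <- (mesh$vertices - matrix(point, nrow(mesh$vertices), 3,
                               byrow = TRUE)) %*% n
  f <- mesh$faces
  pts <- list()
  cross_edge <- function(i1, i2) {
    d1 <- d[i1]; d2 <- d[i2]
    sel <- (d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)
    if (!any(sel)) return(NULL)
    t <- d1[sel] / (d1[sel] - d2[sel])
    mesh$vertices[i1[sel], , drop = FALSE] * (1 - t) +
      mesh$vertices[i2[sel], , drop = FALSE] * t
  }
  out <- rbind(cross_edge(f[, 1], f[, 2]),
               cross_edge(f[, 2], f[, 3]),
               cross_edge(f[, 3], f[, 1]),
               mesh$vertices[abs(d) < 1e-12, , drop = FALSE])
  if (is.null(out)) matrix(numeric(0), 0, 3) else out
}

# Merge several meshes into one (disjoint union; indices offset).
merge_meshes <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  verts <- NULL
  faces <- NULL
  off <- 0L
  for (m in parts) {
    verts <- rbind(verts, m$vertices)
    faces <- rbind(faces, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  trimesh(verts, faces)
}
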