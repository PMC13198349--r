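#' @useDynLib lpmcollide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif uniroot setNames lm coef cor t.test aggregate
#' @importFrom utils read.csv write.csv read.table write.table
NULL

# Numerical tolerance (mm) shared by all distance comparisons.
GEOM_TOL <- 1e-6

#' Structure categories recognized in a labeled scene
#'
#' `SEPTUM` (implantation surface), `RV_WALL` (free-wall shell), `PM`
#' (papillary muscles and moderator band), `TV` (tricuspid valve apparatus:
#' annulus-plane slab plus the chordae-to-annulus cone), and `CAVITY` (the
#' closed endocardial surface used for volume and ejection-fraction
#' measurement; never a collision target).
#' @export
STRUCTURE_CATEGORIES <- c("SEPTUM", "RV_WALL", "PM", "TV", "CAVITY")

# Collision-target categories, in record order.
COLLISION_CATEGORIES <- c("RV_WALL", "PM", "TV")

#' Construct a triangle mesh
#'
#' Vertices are 3D points in millimetres; faces index vertices 1-based (file
#' formats with 0-based indices are converted at the I/O boundary).
#'
#' @param vertices numeric n x 3 matrix (mm)
#' @param faces integer m x 3 matrix of 1-based vertex indices
#' @param label structure category tag (free text; scenes restrict it)
#' @param validate check index bounds and reject zero-area triangles
#' @return an object of class `triangle_mesh`
#' @export
triangle_mesh <- function(vertices, faces, label = "UNLABELED", validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(list(vertices = vertices, faces = faces, label = label),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(!is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
    a <- face_areas(mesh)
    if (any(a <= GEOM_TOL^2)) {
      stop(sprintf("mesh '%s' has %d degenerate (zero-area) triangles",
                   mesh$label, sum(a <= GEOM_TOL^2)))
    }
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces, %s>\n",
              x$label, nrow(x$vertices), nrow(x$faces),
              if (is_closed_mesh(x)) "closed" else
                sprintf("%d boundary edges", boundary_edge_count(x))))
  invisible(x)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n / pmax(sqrt(rowSums(n^2)), 1e-30) else n
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# Edge multiplicity bookkeeping: in a closed 2-manifold every undirected edge
# is shared by exactly two faces.
edge_use_counts <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(integer(0))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Number of boundary edges of a mesh
#'
#' An edge is a boundary edge when it belongs to exactly one face.
#' @param mesh a `triangle_mesh`
#' @export
boundary_edge_count <- function(mesh) {
  cnt <- edge_use_counts(mesh)
  sum(cnt == 1L)
}

#' Is the mesh a closed surface?
#' @param mesh a `triangle_mesh`
#' @export
is_closed_mesh <- function(mesh) {
  cnt <- edge_use_counts(mesh)
  length(cnt) > 0 && all(cnt == 2L)
}

#' Enclosed volume of a closed mesh, in mL
#'
#' Signed tetrahedron volumes summed over faces (divergence theorem), with
#' coordinates in mm; the absolute value is converted to mL (1 mL = 1000 mm^3).
#' Multi-component closed meshes yield the sum of component volumes.
#'
#' @param mesh a closed, consistently oriented `triangle_mesh`
#' @return volume in mL
#' @export
closed_mesh_volume <- function(mesh) {
  nb <- boundary_edge_count(mesh)
  if (nb > 0) {
    stop(sprintf("mesh '%s' is not closed: %d boundary edges", mesh$label, nb))
  }
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6) / 6) / 1000
}

#' Area-weighted vertex normals
#'
#' @param mesh a `triangle_mesh`
#' @param toward optional 3-vector; normals are flipped per vertex so they
#'   point toward this reference point (used to orient septal normals into
#'   the cavity)
#' @return n x 3 matrix of unit normals (NaN rows for isolated vertices)
#' @export
vertex_normals <- function(mesh, toward = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh, normalize = FALSE)  # area-weighted
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], f[, k])
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  isolated <- len < 1e-30
  n <- n / pmax(len, 1e-30)
  n[isolated, ] <- NaN
  if (!is.null(toward)) {
    dirs <- matrix(toward, nrow(v), 3, byrow = TRUE) - v
    flip <- rowSums(dirs * n) < 0
    flip[is.na(flip)] <- FALSE
    n[flip, ] <- -n[flip, ]
  }
  n
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh a `triangle_mesh`
#' @param rotation 3 x 3 matrix (defaults to identity)
#' @param translation length-3 vector (defaults to zero)
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, -as.numeric(translation))
  triangle_mesh(v, mesh$faces, mesh$label, validate = FALSE)
}

transform_points <- function(p, rotation = diag(3), translation = c(0, 0, 0)) {
  p <- matrix(p, ncol = 3)
  sweep(p %*% t(rotation), 2, -as.numeric(translation))
}

#' Rotation matrix about an axis
#' @param axis length-3 vector (need not be unit)
#' @param angle rotation angle in radians
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s * ux + (1 - c_) * (u %o% u)
}

# --- primitive builders (fixtures and synthetic anatomy) --------------------

#' Axis-aligned cube mesh
#' @param side edge length (mm)
#' @param center length-3 center
#' @param label structure tag
#' @export
cube_mesh <- function(side = 10, center = c(0, 0, 0), label = "UNLABELED") {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, -as.numeric(center))
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = -h
    c(5, 6, 7), c(6, 8, 7),      # z = +h
    c(1, 2, 5), c(2, 6, 5),      # y = -h
    c(3, 7, 4), c(4, 7, 8),      # y = +h
    c(1, 5, 3), c(3, 5, 7),      # x = -h
    c(2, 4, 6), c(4, 8, 6))      # x = +h
  triangle_mesh(v, f, label)
}

#' Axis-aligned box mesh
#' @param sides length-3 edge lengths (mm)
#' @param center length-3 center
#' @param label structure tag
#' @export
box_mesh <- function(sides, center = c(0, 0, 0), label = "UNLABELED") {
  m <- cube_mesh(1, c(0, 0, 0), label)
  v <- sweep(m$vertices, 2, as.numeric(sides), `*`)
  v <- sweep(v, 2, -as.numeric(center))
  triangle_mesh(v, m$faces, label)
}

#' UV-sphere mesh
#' @param radius mm
#' @param center length-3 center
#' @param n_theta latitudinal bands (>= 2)
#' @param n_phi longitudinal sectors (>= 3)
#' @param label structure tag
#' @export
uv_sphere_mesh <- function(radius = 10, center = c(0, 0, 0),
                           n_theta = 24, n_phi = 32, label = "UNLABELED") {
  th <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]  # exclude poles
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(ph = ph, th = th)
  ring <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  v <- rbind(c(0, 0, 1), ring, c(0, 0, -1)) * radius
  v <- sweep(v, 2, -as.numeric(center))
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  f <- list()
  for (j in 1:n_phi) f[[length(f) + 1]] <- c(1L, idx(1, j), idx(1, j + 1))
  nb <- n_theta - 1
  if (nb >= 2) {
    for (i in 1:(nb - 1)) for (j in 1:n_phi) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      f[[length(f) + 1]] <- c(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1))
    }
  }
  south <- nrow(v)
  for (j in 1:n_phi) f[[length(f) + 1]] <- c(south, idx(nb, j + 1), idx(nb, j))
  triangle_mesh(v, do.call(rbind, f), label)
}

#' Closed cylinder (capsule-free, flat caps) mesh
#' @param base length-3 base-center point
#' @param axis direction (normalized internally)
#' @param length mm
#' @param radius mm
#' @param n_phi circumferential resolution
#' @param label structure tag
#' @export
cylinder_solid_mesh <- function(base, axis, length, radius, n_phi = 24,
                                label = "UNLABELED") {
  a <- axis / sqrt(sum(axis^2))
  e1 <- orthonormal_to(a)
  e2 <- cross3(a, e1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  ring0 <- t(vapply(ph, function(p) base + radius * (cos(p) * e1 + sin(p) * e2),
                    numeric(3)))
  ring1 <- sweep(ring0, 2, -a * length)
  cb <- base; ct <- base + a * length
  v <- rbind(ring0, ring1, cb, ct)
  i0 <- 1:n_phi; i1 <- n_phi + (1:n_phi)
  icb <- 2L * n_phi + 1L; ict <- 2L * n_phi + 2L
  nxt <- function(j) (j %% n_phi) + 1L
  f <- list()
  for (j in 1:n_phi) {
    f[[length(f) + 1]] <- c(i0[j], i1[j], i0[nxt(j)])
    f[[length(f) + 1]] <- c(i0[nxt(j)], i1[j], i1[nxt(j)])
    f[[length(f) + 1]] <- c(icb, i0[nxt(j)], i0[j])       # base cap
    f[[length(f) + 1]] <- c(ict, i1[j], i1[nxt(j)])       # top cap
  }
  triangle_mesh(v, do.call(rbind, f), label)
}

#' Closed cone mesh from a circular base disc to an apex point
#' @param base_center center of the disc (mm)
#' @param base_normal disc normal (apex side)
#' @param base_radius mm
#' @param apex length-3 apex point
#' @param n_phi circumferential resolution
#' @param label structure tag
#' @export
cone_mesh <- function(base_center, base_normal, base_radius, apex,
                      n_phi = 16, label = "UNLABELED") {
  a <- base_normal / sqrt(sum(base_normal^2))
  e1 <- orthonormal_to(a)
  e2 <- cross3(a, e1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  ring <- t(vapply(ph, function(p)
    base_center + base_radius * (cos(p) * e1 + sin(p) * e2), numeric(3)))
  v <- rbind(ring, base_center, apex)
  ic <- n_phi + 1L; ia <- n_phi + 2L
  nxt <- function(j) (j %% n_phi) + 1L
  f <- list()
  for (j in 1:n_phi) {
    f[[length(f) + 1]] <- c(ic, nxt(j), j)          # base disc
    f[[length(f) + 1]] <- c(ia, j, nxt(j))          # lateral
  }
  triangle_mesh(v, do.call(rbind, f), label)
}

# unit vector orthogonal to a
orthonormal_to <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(a, ref)
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# concatenate several closed meshes into one multi-component mesh
merge_meshes <- function(meshes, label) {
  offs <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1]] <- m$vertices
    fs[[length(fs) + 1]] <- m$faces + offs
    offs <- offs + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), label, validate = FALSE)
}
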