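# R surface of the collision-geometry core (src/collision.cpp).
#
# "Collision" means solid-solid overlap with no minimum-penetration
# threshold: tissues and devices are rigid, and any overlap in any cardiac
# phase counts.  All comparisons use the 1e-6 mm tolerance GEOM_TOL.

#' Construct a device cylinder
#'
#' Flat-capped right circular cylinder: `base` is the implant-surface end,
#' `axis` points into the cavity.
#'
#' @param base length-3 point (mm)
#' @param axis direction (normalized internally; must be nonzero)
#' @param length mm, >= 0
#' @param radius mm, >= 0
#' @return object of class `cylinder`
#' @export
cylinder <- function(base, axis, length, radius) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("cylinder axis must be nonzero")
  if (length < 0 || radius < 0) stop("cylinder length and radius must be >= 0")
  structure(list(base = as.numeric(base), axis = as.numeric(axis) / nrm,
                 length = length, radius = radius), class = "cylinder")
}

# Build (and memoize on the mesh attribute-free copy) a BVH handle.
build_bvh <- function(mesh) {
  cpp_bvh_build(mesh$vertices, mesh$faces)
}

#' Point-in-solid test for a closed mesh
#'
#' Ray-parity rule with deterministic direction retries on degenerate hits
#' (surface grazing, edge/vertex crossings).
#'
#' @param p length-3 point or n x 3 matrix
#' @param mesh a closed `triangle_mesh`
#' @param bvh optional prebuilt handle from repeated queries
#' @return logical (vector)
#' @export
point_in_closed_mesh <- function(p, mesh = NULL, bvh = NULL) {
  if (is.null(bvh)) {
    nb <- boundary_edge_count(mesh)
    if (nb > 0) stop(sprintf("mesh is not closed: %d boundary edges", nb))
    bvh <- build_bvh(mesh)
  }
  p <- matrix(as.numeric(p), ncol = 3)
  as.logical(cpp_points_in_mesh(bvh, p))
}

#' Exact minimum distance between a segment and a triangle (mm)
#' @param a,b segment endpoints (length-3)
#' @param tri 3 x 3 matrix of triangle vertices (rows)
#' @export
segment_triangle_distance <- function(a, b, tri) {
  cpp_seg_tri_dist(as.numeric(a), as.numeric(b), matrix(as.numeric(tri), 3, 3))
}

#' Cylinder vs. closed-mesh solid overlap
#'
#' Decides whether the cylinder solid and the mesh solid intersect by the
#' union of (a) an exact triangle-vs-cylinder test on every non-excluded
#' face (the triangle is clipped to the end-cap slab and its minimum radial
#' distance to the axis compared with the radius), (b) an axis-midpoint
#' containment test against the full mesh, and (c) a vertex-in-cylinder
#' guard for excluded faces.  Face exclusion (the attachment-site
#' self-intersection rule) therefore only disables the surface-proximity
#' test, never the containment tests.
#'
#' @param cyl a [cylinder]
#' @param mesh a closed `triangle_mesh`
#' @param excluded_faces integer vector of face indices (1-based) excluded
#'   from the surface test, or an `exclusion_radius` distance via
#'   `exclusion_centre`/`exclusion_radius`
#' @param exclusion_radius exclude faces whose centroid lies within this
#'   distance (mm) of the cylinder base (0 = no exclusion); ignored when
#'   `excluded_faces` is given
#' @param bvh optional prebuilt BVH handle
#' @return list with `collides` (logical) and `witness` (length-3 point
#'   strictly inside both solids, or `NULL` when not located)
#' @export
cylinder_mesh_overlap <- function(cyl, mesh = NULL, excluded_faces = NULL,
                                  exclusion_radius = 0, bvh = NULL) {
  if (is.null(bvh)) {
    nb <- boundary_edge_count(mesh)
    if (nb > 0) stop(sprintf("mesh is not closed: %d boundary edges", nb))
    bvh <- build_bvh(mesh)
  }
  if (!is.null(excluded_faces) && length(excluded_faces) > 0) {
    # arbitrary exclusion sets are handled by masking those faces out and
    # keeping the containment tests on the full mesh
    keep <- setdiff(seq_len(nrow(mesh$faces)), excluded_faces)
    sub <- triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                         mesh$label, validate = FALSE)
    sub_bvh <- build_bvh(sub)
    hit <- cpp_cyl_mesh_overlap(sub_bvh, cyl$base, cyl$axis, cyl$length,
                                cyl$radius, 0, containment = FALSE)
    if (!hit) {
      # containment against the full solid; a midpoint lying exactly on the
      # surface has ambiguous parity and counts as outside (zero overlap)
      mid <- cyl$base + cyl$axis * (cyl$length / 2)
      hit <- isTRUE(tryCatch(point_in_closed_mesh(mid, bvh = bvh),
                             error = function(e) FALSE))
      if (!hit && cyl$radius > GEOM_TOL && cyl$length > GEOM_TOL) {
        vids <- unique(as.integer(mesh$faces[excluded_faces, , drop = FALSE]))
        vv <- mesh$vertices[vids, , drop = FALSE]
        rel <- sweep(vv, 2, cyl$base)
        s <- as.numeric(rel %*% cyl$axis)
        rad2 <- rowSums((rel - outer(s, cyl$axis))^2)
        hit <- any(s > GEOM_TOL & s < cyl$length - GEOM_TOL &
                     rad2 < (cyl$radius - GEOM_TOL)^2)
      }
    }
  } else {
    hit <- cpp_cyl_mesh_overlap(bvh, cyl$base, cyl$axis, cyl$length,
                                cyl$radius, exclusion_radius)
  }
  witness <- NULL
  if (hit) witness <- find_witness(cyl, bvh)
  list(collides = as.logical(hit), witness = witness)
}

# deterministic interior-point search: axis samples then coarse disc grid;
# candidates that land exactly on the surface (degenerate parity) are skipped
find_witness <- function(cyl, bvh) {
  try_point <- function(p) {
    isTRUE(tryCatch(point_in_closed_mesh(p, bvh = bvh), error = function(e) FALSE))
  }
  ts <- c(0.5, 0.25, 0.75, 0.1, 0.9)
  for (t in ts) {
    p <- cyl$base + cyl$axis * (t * cyl$length)
    if (try_point(p)) return(p)
  }
  if (cyl$radius > 0) {
    e1 <- orthonormal_to(cyl$axis)
    e2 <- cross3(cyl$axis, e1)
    for (t in ts) for (fr in c(0.5, 0.9)) for (ph in seq(0, 2 * pi, length.out = 9)[-9]) {
      p <- cyl$base + cyl$axis * (t * cyl$length) +
        (fr * cyl$radius) * (cos(ph) * e1 + sin(ph) * e2)
      if (try_point(p)) return(p)
    }
  }
  NULL
}

#' Monte-Carlo overlap oracle
#'
#' Independent sampling check: draws `n_samples` points uniformly inside the
#' cylinder solid (tested against the mesh) and `n_samples` points uniformly
#' inside the mesh solid (rejection sampling in its bounding box, tested
#' against the cylinder).  Deterministic under `seed`.
#'
#' @param cyl a [cylinder]
#' @param mesh a closed `triangle_mesh`
#' @param n_samples points per direction
#' @param seed RNG seed
#' @return logical: any sampled point inside both solids
#' @export
overlap_oracle <- function(cyl, mesh, n_samples = 2000, seed = 1) {
  bvh <- build_bvh(mesh)
  local_seed(seed, {
    hit <- FALSE
    if (cyl$length > 0 && cyl$radius > 0) {
      u <- runif(n_samples); r <- cyl$radius * sqrt(runif(n_samples))
      ph <- runif(n_samples, 0, 2 * pi)
      e1 <- orthonormal_to(cyl$axis); e2 <- cross3(cyl$axis, e1)
      pts <- matrix(cyl$base, n_samples, 3, byrow = TRUE) +
        outer(u * cyl$length, cyl$axis) +
        outer(r * cos(ph), e1) + outer(r * sin(ph), e2)
      hit <- any(cpp_points_in_mesh(bvh, pts))
    }
    if (!hit) {
      lo <- apply(mesh$vertices, 2, min); hi <- apply(mesh$vertices, 2, max)
      got <- 0L; tries <- 0L
      while (got < n_samples && tries < 60L) {
        m <- max(n_samples * 4L, 256L)
        cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                      runif(m, lo[3], hi[3]))
        inside <- cpp_points_in_mesh(bvh, cand)
        pts <- cand[inside, , drop = FALSE]
        if (nrow(pts) > 0) {
          got <- got + nrow(pts)
          rel <- sweep(pts, 2, cyl$base)
          s <- as.numeric(rel %*% cyl$axis)
          rad2 <- rowSums((rel - outer(s, cyl$axis))^2)
          if (any(s >= 0 & s <= cyl$length & rad2 <= cyl$radius^2)) {
            hit <- TRUE
            break
          }
        }
        tries <- tries + 1L
      }
    }
    hit
  })
}

# run code with a temporary RNG state, restoring the caller's state after
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
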