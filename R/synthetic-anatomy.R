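# Synthetic dynamic RV anatomy.
#
# The cavity is an idealized truncated half-ellipsoid with a flattened medial
# (septal) sector: apex at the origin, long axis along +z, basal (tricuspid
# annulus) plane at z = long_axis_length.  The cross-section at normalized
# height u is a D-shape: a circular free-wall arc of radius R(u) with a flat
# septal chord, R(u) = R_base * sqrt(u * (2 - u)).  The free wall is offset
# outward by the wall thickness into a closed shell, the TV apparatus is a
# 2-mm annulus-plane slab plus a loft ("cone") from the chordae attachment
# points to the annulus ring, and the papillary muscles and moderator band
# are closed tapered cones / struts.  Contraction is an analytic advected
# field (radial + longitudinal), amplitude calibrated to the target ejection
# fraction by scalar root finding.

#' Configuration for the synthetic anatomy generator
#'
#' Defaults describe a dilated heart-failure RV: end-diastolic volume 283 mL,
#' ejection fraction 22%, 3.5-mm free wall, 2-mm tricuspid annulus slab,
#' 10 cardiac phases.
#'
#' @param edv_target end-diastolic cavity volume (mL)
#' @param ef_target ejection fraction (%), in (0, 100)
#' @param n_phases cardiac phases per cycle (>= 2)
#' @param wall_thickness free-wall thickness (mm)
#' @param tv_plane_thickness annulus slab thickness (mm)
#' @param annulus_radius tricuspid annulus ring radius (mm)
#' @param annulus_offset length-2 offset (mm) of the annulus centre in the
#'   basal plane: positive x away from the septum, negative y toward the
#'   inferior wall.  The default places the valve posterior-inferiorly, as
#'   in the real RV where the anterior basal septum faces the outflow
#'   tract, not the valve
#' @param long_axis_length apex-to-base distance (mm)
#' @param septal_half_angle half-angle of the flattened septal sector (deg)
#' @param pm_specs list of papillary-muscle specs: each a list with
#'   `name`, `phi_deg` (circumferential wall position; the septum centre is
#'   at 180), `u` (apicobasal attachment, 0 apex / 1 base), `base_radius`
#'   and `height` (mm)
#' @param moderator_band list with `septal_u`, `septal_psi` (position across
#'   the septum in `[0,1]`), `wall_phi_deg`, `wall_u`, `radius` (mm); `NULL`
#'   for no band
#' @param resolution `c(n_long, n_circ)` mesh resolution; `n_circ` is
#'   rounded to a multiple of 6 so sector boundaries fall on mesh columns
#' @param seed integer seed recorded with the anatomy
#' @return object of class `anatomy_config`
#' @export
anatomy_config <- function(edv_target = 283, ef_target = 22, n_phases = 10,
                           wall_thickness = 3.5, tv_plane_thickness = 2,
                           annulus_radius = 18, annulus_offset = c(8, -18),
                           long_axis_length = 95, septal_half_angle = 60,
                           pm_specs = default_pm_specs(),
                           moderator_band = default_moderator_band(),
                           resolution = c(96, 60), seed = 1) {
  if (edv_target <= 0) stop("edv_target must be > 0")
  if (ef_target < 0 || ef_target >= 100) stop("ef_target must be in [0, 100)")
  if (n_phases < 2) stop("n_phases must be >= 2")
  if (wall_thickness <= 0) stop("wall_thickness must be > 0")
  n_circ <- max(12L, 6L * round(resolution[2] / 6))
  cfg <- structure(list(
    edv_target = edv_target, ef_target = ef_target, n_phases = as.integer(n_phases),
    wall_thickness = wall_thickness, tv_plane_thickness = tv_plane_thickness,
    annulus_radius = annulus_radius,
    annulus_offset = rep(as.numeric(annulus_offset), length.out = 2),
    long_axis_length = long_axis_length,
    septal_half_angle = septal_half_angle * pi / 180,
    pm_specs = pm_specs, moderator_band = moderator_band,
    n_long = as.integer(resolution[1]), n_circ = as.integer(n_circ),
    seed = as.integer(seed)), class = "anatomy_config")
  cfg
}

#' Default papillary-muscle specification
#'
#' Three muscles: a large anterior PM on the anterior free wall, an inferior
#' (posterior) PM on the inferior wall, and a small septal PM, each a closed
#' tapered cone whose tip (the basal-most point) is the chordae tendineae
#' attachment point.
#' @export
default_pm_specs <- function() {
  list(
    list(name = "anterior", phi_deg = 75, u = 0.40, base_radius = 5.5, height = 25),
    list(name = "inferior", phi_deg = -75, u = 0.45, base_radius = 5.0, height = 22),
    list(name = "septal", phi_deg = 180, u = 0.55, base_radius = 4.0, height = 14))
}

#' Default moderator band: apical septum to anterior free wall strut
#'
#' The moderator band crosses the apical third of the RV, carrying the
#' right bundle branch from the septum to the anterior papillary muscle.
#' @export
default_moderator_band <- function() {
  list(septal_u = 0.28, septal_psi = 0.45, wall_phi_deg = 75, wall_u = 0.33,
       radius = 2.5)
}

# radius profile of the half-ellipsoid at normalized height u in [0, 1]
ell_scale <- function(u) sqrt(pmax(u * (2 - u), 0))

# D-shaped unit cross-section boundary: circle with a flat chord at
# x = -cos(alpha) for the sector |phi - pi| <= alpha
d_section <- function(phi, alpha) {
  x <- cos(phi)
  x[x < -cos(alpha)] <- -cos(alpha)
  cbind(x, sin(phi))
}

# area of the unit D-shape
d_section_area <- function(alpha) pi - (alpha - sin(alpha) * cos(alpha))

# surface point in the septal chart: u apicobasal, psi in [0,1] across the
# flat sector (0 = anterior edge at phi = pi - alpha)
septal_chart_point <- function(u, psi, R_base, L, alpha) {
  phi <- (pi - alpha) + psi * 2 * alpha
  s <- R_base * ell_scale(u)
  cbind(-s * cos(alpha), s * sin(phi), L * u)
}

# wall surface point at angle phi (free wall or septum)
wall_point <- function(u, phi_rad, R_base, L, alpha) {
  q <- d_section(phi_rad, alpha)
  s <- R_base * ell_scale(u)
  c(s * q[1], s * q[2], L * u)
}

#' Generate the end-diastolic labeled scene
#'
#' Builds the cavity, septum, free-wall shell, TV apparatus (annulus slab +
#' chordae-to-annulus cone), papillary muscles and moderator band, plus
#' landmarks, chordae points, and conduction-system seed paths (LBB and the
#' three left fascicles) on the septal surface.  The basal radius is
#' calibrated so the discrete cavity volume matches `edv_target` to well
#' under the 2% contract.
#'
#' @param config an [anatomy_config]
#' @return list with `scene` (a `labeled_scene`), `chordae_points` (one per
#'   PM), `conduction_paths` (named list of polyline matrices)
#' @export
generate_ed_scene <- function(config) {
  L <- config$long_axis_length
  alpha <- config$septal_half_angle
  a_unit <- d_section_area(alpha)
  # analytic first guess, then one exact affine correction of the xy scale
  R_base <- sqrt(config$edv_target * 1000 / (a_unit * L * 2 / 3))
  geo <- build_rv_geometry(config, R_base)
  v0 <- closed_mesh_volume(geo$cavity)
  R_base <- R_base * sqrt(config$edv_target / v0)
  geo <- build_rv_geometry(config, R_base)
  v1 <- closed_mesh_volume(geo$cavity)
  if (abs(v1 - config$edv_target) > 0.02 * config$edv_target) {
    stop("cavity volume calibration failed")
  }
  geo
}

build_rv_geometry <- function(config, R_base) {
  L <- config$long_axis_length
  alpha <- config$septal_half_angle
  n_long <- config$n_long
  n_circ <- config$n_circ

  # the annulus ring must fit inside the basal D-shape: check against the
  # free-wall arc and the septal chord (the two nearest boundaries)
  off <- config$annulus_offset
  if (config$annulus_radius + sqrt(sum(off^2)) >= R_base) {
    stop("annulus radius exceeds the basal cavity radius")
  }
  if (config$annulus_radius - off[1] >= R_base * cos(alpha)) {
    stop("annulus ring crosses the septal wall")
  }

  phi <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  u <- seq_len(n_long) / n_long
  q <- d_section(phi, alpha)

  # lateral surface vertices: apex + n_long rings of n_circ
  nv_ring <- n_long * n_circ
  verts <- matrix(0, 1 + nv_ring, 3)
  verts[1, ] <- c(0, 0, 0)
  for (i in seq_len(n_long)) {
    s <- R_base * ell_scale(u[i])
    rows <- 1 + (i - 1) * n_circ + seq_len(n_circ)
    verts[rows, ] <- cbind(s * q[, 1], s * q[, 2], L * u[i])
  }
  ridx <- function(i, j) 1L + (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L

  septal_col <- phi >= (pi - alpha) - 1e-9 & phi <= (pi + alpha) + 1e-9

  lat_faces <- list()
  lat_septal <- list()  # flag per face
  for (j in seq_len(n_circ)) {
    j2 <- (j %% n_circ) + 1L
    sep <- septal_col[j] && septal_col[j2]
    lat_faces[[length(lat_faces) + 1]] <- c(1L, ridx(1, j), ridx(1, j + 1))
    lat_septal[[length(lat_septal) + 1]] <- sep
    if (n_long >= 2) {
      for (i in seq_len(n_long - 1)) {
        lat_faces[[length(lat_faces) + 1]] <- c(ridx(i, j), ridx(i + 1, j), ridx(i, j + 1))
        lat_septal[[length(lat_septal) + 1]] <- sep
        lat_faces[[length(lat_faces) + 1]] <- c(ridx(i, j + 1), ridx(i + 1, j), ridx(i + 1, j + 1))
        lat_septal[[length(lat_septal) + 1]] <- sep
      }
    }
  }
  lat_faces <- do.call(rbind, lat_faces)
  lat_septal <- unlist(lat_septal)

  # basal cap (fan about the basal centroid)
  cap_centre_idx <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, L))
  cap_faces <- do.call(rbind, lapply(seq_len(n_circ), function(j) {
    c(cap_centre_idx, ridx(n_long, j + 1), ridx(n_long, j))
  }))

  cavity <- triangle_mesh(verts, rbind(lat_faces, cap_faces), "CAVITY",
                          validate = FALSE)
  cavity <- orient_mesh(cavity)

  septum <- submesh(cavity, lat_faces[lat_septal, , drop = FALSE], "SEPTUM")
  wall_patch <- lat_faces[!lat_septal, , drop = FALSE]
  rv_wall <- offset_shell(cavity, wall_patch, config$wall_thickness, "RV_WALL")

  # landmarks
  ann_c <- c(off[1], off[2], L)
  landmarks <- list(
    apex = c(0, 0, 0),
    tv_centre = ann_c,
    attach_anterior = as.numeric(wall_point(1, pi - alpha, R_base, L, alpha)),
    attach_posterior = as.numeric(wall_point(1, pi + alpha, R_base, L, alpha)))

  # papillary muscles + moderator band (single PM category, multi-component)
  pm_parts <- list()
  chordae <- list()
  for (spec in config$pm_specs) {
    att <- wall_point(spec$u, spec$phi_deg * pi / 180, R_base, L, alpha)
    if (spec$u <= 0 || spec$u >= 1) stop("PM attachment outside the cavity")
    target <- ann_c - c(0, 0, 12)  # aim just below the annulus centre
    dir <- (target - att)
    dir <- dir / sqrt(sum(dir^2))
    tip <- att + spec$height * dir
    if (tip[3] >= L) stop("PM tip outside the cavity (above the annulus)")
    # recess the base slightly into the wall so the disc covers its curvature
    base_c <- att - 1.0 * dir
    pm_parts[[length(pm_parts) + 1]] <-
      orient_mesh(cone_mesh(base_c, dir, spec$base_radius, tip, n_phi = 14,
                            label = "PM"))
    chordae[[spec$name]] <- tip
  }
  if (!is.null(config$moderator_band)) {
    mb <- config$moderator_band
    p_sep <- as.numeric(septal_chart_point(mb$septal_u, mb$septal_psi, R_base, L, alpha))
    p_wall <- wall_point(mb$wall_u, mb$wall_phi_deg * pi / 180, R_base, L, alpha)
    axis <- p_wall - p_sep
    len <- sqrt(sum(axis^2))
    # extend 1 mm beyond each wall for a robust attachment
    p0 <- p_sep - axis / len * 1.0
    pm_parts[[length(pm_parts) + 1]] <-
      orient_mesh(cylinder_solid_mesh(p0, axis, len + 2.0, mb$radius,
                                      n_phi = 12, label = "PM"))
  }

  # TV apparatus: 2-mm annulus slab + loft from chordae points to the ring
  n_ring <- 36
  slab <- orient_mesh(cylinder_solid_mesh(ann_c, c(0, 0, 1),
                                          config$tv_plane_thickness,
                                          config$annulus_radius,
                                          n_phi = n_ring, label = "TV"))
  tv_parts <- list(slab)
  if (length(chordae) > 0) {
    tv_parts[[2]] <- orient_mesh(tv_cone(ann_c, config$annulus_radius, n_ring,
                                         do.call(rbind, unname(chordae))))
  }
  tv <- merge_meshes(tv_parts, "TV")
  pm <- if (length(pm_parts) > 0) merge_meshes(pm_parts, "PM") else NULL

  structures <- list(SEPTUM = septum, RV_WALL = rv_wall, TV = tv, CAVITY = cavity)
  if (!is.null(pm)) structures$PM <- pm
  scene <- labeled_scene(structures, landmarks)

  paths <- conduction_paths(septum, R_base, L, alpha)

  list(scene = scene, chordae_points = chordae, conduction_paths = paths,
       R_base = R_base, cavity = cavity)
}

# extract a face subset as a reindexed mesh
submesh <- function(mesh, faces, label) {
  vids <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[vids] <- seq_along(vids)
  triangle_mesh(mesh$vertices[vids, , drop = FALSE],
                matrix(remap[faces], ncol = 3), label, validate = FALSE)
}

# closed shell: endocardial patch + outward-offset copy + rim band
offset_shell <- function(cavity, patch_faces, thickness, label) {
  vids <- sort(unique(as.integer(patch_faces)))
  remap <- integer(nrow(cavity$vertices))
  remap[vids] <- seq_along(vids)
  endo_v <- cavity$vertices[vids, , drop = FALSE]
  endo_f <- matrix(remap[patch_faces], ncol = 3)
  # outward normals from the full cavity surface (pointing away from the
  # cavity interior), restricted to patch vertices
  ctr <- colMeans(cavity$vertices)
  vn <- vertex_normals(cavity, toward = ctr)
  vn <- -vn  # away from the interior
  epi_v <- endo_v + thickness * vn[vids, , drop = FALSE]
  nv <- nrow(endo_v)
  # boundary loop edges of the patch (directed as they appear in faces)
  edges <- rbind(endo_f[, c(1, 2)], endo_f[, c(2, 3)], endo_f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- names(which(table(key) == 1L))
  bnd <- edges[key %in% once, , drop = FALSE]
  rim <- do.call(rbind, lapply(seq_len(nrow(bnd)), function(r) {
    a <- bnd[r, 1]; b <- bnd[r, 2]
    rbind(c(a, b, b + nv), c(a, b + nv, a + nv))
  }))
  f <- rbind(endo_f[, c(1, 3, 2)],        # reversed: outward = toward cavity
             endo_f + nv,                 # epicardial copy, original winding
             rim)
  mesh <- triangle_mesh(rbind(endo_v, epi_v), f, label, validate = FALSE)
  orient_mesh(mesh)
}

# loft from the annulus ring down to the chordae points ("cone" enclosing
# the valve leaflets and chordae); closed for >= 1 chordae points
tv_cone <- function(ann_c, radius, n_ring, chordae) {
  ph <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ring <- cbind(ann_c[1] + radius * cos(ph), ann_c[2] + radius * sin(ph),
                ann_c[3])
  nb <- nrow(chordae)
  bang <- atan2(chordae[, 2] - ann_c[2], chordae[, 1] - ann_c[1])
  ord <- order(bang)
  chordae <- chordae[ord, , drop = FALSE]
  bang <- bang[ord]
  # nearest-chordae assignment per ring vertex (angular distance)
  assign <- vapply(ph, function(a) {
    d <- abs(((a - bang + pi) %% (2 * pi)) - pi)
    which.min(d)
  }, integer(1))
  v <- rbind(ring, chordae, ann_c)
  ic <- n_ring + nb + 1L
  f <- list()
  nxt <- function(j) (j %% n_ring) + 1L
  for (j in seq_len(n_ring)) {
    f[[length(f) + 1]] <- c(ic, j, nxt(j))  # top disc
    f[[length(f) + 1]] <- c(j, nxt(j), n_ring + assign[j])
    aj <- assign[j]; aj2 <- assign[nxt(j)]
    if (aj2 != aj) {
      k <- aj
      while (k != aj2) {
        k2 <- (k %% nb) + 1L
        f[[length(f) + 1]] <- c(nxt(j), n_ring + k2, n_ring + k)
        k <- k2
      }
    }
  }
  if (nb >= 3) {
    # bottom cap: fan over the chordae polygon
    for (k in 2:(nb - 1)) {
      f[[length(f) + 1]] <- c(n_ring + 1L, n_ring + k, n_ring + k + 1L)
    }
  }
  triangle_mesh(v, do.call(rbind, f), "TV", validate = FALSE)
}

# conduction-system seed paths as polylines snapped to septal mesh vertices:
# the proximal LBB descends from the membranous high septum about a quarter
# of the apicobasal length; LAF runs anteriorly-apically, LPF inferiorly-
# apically, LSF mid-septally.
conduction_paths <- function(septum, R_base, L, alpha, n_pts = 12) {
  chart <- list(
    LBB = cbind(u = seq(0.98, 0.75, length.out = n_pts),
                psi = seq(0.52, 0.55, length.out = n_pts)),
    LAF = cbind(u = seq(0.75, 0.40, length.out = n_pts),
                psi = seq(0.52, 0.20, length.out = n_pts)),
    LPF = cbind(u = seq(0.75, 0.35, length.out = n_pts),
                psi = seq(0.55, 0.85, length.out = n_pts)),
    LSF = cbind(u = seq(0.73, 0.45, length.out = n_pts),
                psi = seq(0.45, 0.50, length.out = n_pts)))
  lapply(chart, function(cu) {
    pts <- septal_chart_point(cu[, "u"], cu[, "psi"], R_base, L, alpha)
    # snap to the nearest septal vertex so paths lie on the mesh surface
    sv <- septum$vertices
    snapped <- t(apply(pts, 1, function(p) {
      d2 <- (sv[, 1] - p[1])^2 + (sv[, 2] - p[2])^2 + (sv[, 3] - p[3])^2
      sv[which.min(d2), ]
    }))
    unname(snapped)  # duplicates possible on coarse meshes; kept so the
                     # polyline always carries its full point count
  })
}

#' Animate an end-diastolic scene through the cardiac cycle
#'
#' The displacement field combines radial contraction toward the long axis
#' with longitudinal shortening toward the apex, scaled per frame by
#' `w(t) = (1 - cos(2*pi*t)) / 2`; all structures are advected by the same
#' field, so topology is constant.  The amplitude is calibrated by scalar
#' root finding so the minimum cavity volume equals
#' `edv_target * (1 - ef_target / 100)` (within 1%; the calibration is in
#' practice exact because the field is affine per frame).
#'
#' @param ed result of [generate_ed_scene] (or its `$scene`)
#' @param config the [anatomy_config] used to build it
#' @return a `scene_sequence` of `config$n_phases` frames
#' @export
generate_motion <- function(ed, config) {
  scene <- if (inherits(ed, "labeled_scene")) ed else ed$scene
  cav <- scene$structures$CAVITY
  edv <- closed_mesh_volume(cav)
  esv_target <- edv * (1 - config$ef_target / 100)
  vol_at <- function(c_amp) {
    m <- advect_mesh(cav, 1, c_amp)
    closed_mesh_volume(m)
  }
  if (config$ef_target <= 1e-12) {
    c_amp <- 0
  } else {
    f <- function(c_amp) vol_at(c_amp) - esv_target
    lo <- 0; hi <- 0.95
    if (f(hi) > 0) stop("EF target unreachable: contraction cannot bracket the target volume")
    c_amp <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  t <- (seq_len(config$n_phases) - 1) / config$n_phases
  frames <- lapply(t, function(tt) {
    w <- (1 - cos(2 * pi * tt)) / 2
    structures <- lapply(scene$structures, advect_mesh, w = w, c_amp = c_amp)
    landmarks <- lapply(scene$landmarks, advect_points, w = w, c_amp = c_amp)
    labeled_scene(structures, landmarks)
  })
  seq_ <- scene_sequence(frames, phase = t)
  v <- frame_volumes(seq_)
  if (config$ef_target > 1e-12 &&
      abs(min(v) - esv_target) > 0.01 * esv_target) {
    stop("EF calibration failed to reach the target end-systolic volume")
  }
  seq_
}

# radial contraction (factor 1 - w*c) about the z long axis plus
# longitudinal shortening (factor 1 - w*c/2) toward the apex at z = 0
advect_points <- function(p, w, c_amp) {
  p <- matrix(as.numeric(p), ncol = 3)
  kr <- 1 - w * c_amp
  kz <- 1 - w * c_amp / 2
  out <- cbind(p[, 1] * kr, p[, 2] * kr, p[, 3] * kz)
  if (nrow(out) == 1) as.numeric(out) else out
}

advect_mesh <- function(mesh, w, c_amp) {
  triangle_mesh(advect_points(mesh$vertices, w, c_amp), mesh$faces,
                mesh$label, validate = FALSE)
}

#' Generate one synthetic patient
#'
#' @param config an [anatomy_config]
#' @return object of class `patient_anatomy`: `sequence`, `landmarks` (end
#'   diastole), `chordae_points`, `conduction_paths`, `config`
#' @export
generate_patient <- function(config) {
  ed <- generate_ed_scene(config)
  seq_ <- generate_motion(ed, config)
  structure(list(sequence = seq_, landmarks = ed$scene$landmarks,
                 chordae_points = ed$chordae_points,
                 conduction_paths = ed$conduction_paths,
                 config = config), class = "patient_anatomy")
}

#' @export
print.patient_anatomy <- function(x, ...) {
  cat(sprintf("<patient_anatomy: EDV %.1f mL, measured EF %.1f%%, %d phases>\n",
              max(frame_volumes(x$sequence)), measured_ef(x$sequence),
              length(x$sequence$frames)))
  invisible(x)
}

#' Default cohort variability (fractional SDs; EF absolute)
#' @export
default_variability <- function() {
  list(edv = 38 / 283, long_axis = 0.05, annulus = 0.05, ef_abs = 7)
}

#' Generate a synthetic patient cohort
#'
#' Size parameters receive log-normal multiplicative jitter (so they stay
#' positive) and the ejection fraction receives additive normal jitter,
#' clamped to `[3, 60]`%.  Papillary-muscle and moderator-band dimensions
#' scale with the cube root of the volume jitter.  Deterministic under
#' `seed`.
#'
#' @param n number of patients (>= 1)
#' @param base an [anatomy_config] giving the cohort means
#' @param variability list as [default_variability()]
#' @param seed integer seed
#' @return list of `patient_anatomy`
#' @export
generate_cohort <- function(n = 10, base = anatomy_config(),
                            variability = default_variability(), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  configs <- local_seed(seed, {
    lapply(seq_len(n), function(i) {
      f_edv <- exp(rnorm(1, 0, variability$edv))
      f_lax <- exp(rnorm(1, 0, variability$long_axis))
      f_ann <- exp(rnorm(1, 0, variability$annulus))
      ef <- min(60, max(3, base$ef_target + rnorm(1, 0, variability$ef_abs)))
      s <- f_edv^(1 / 3)
      pm <- lapply(base$pm_specs, function(p) {
        p$base_radius <- p$base_radius * s
        p$height <- p$height * s
        p
      })
      mb <- base$moderator_band
      if (!is.null(mb)) mb$radius <- mb$radius * s
      cfg <- base
      cfg$edv_target <- base$edv_target * f_edv
      cfg$long_axis_length <- base$long_axis_length * f_lax * s
      cfg$annulus_radius <- base$annulus_radius * f_ann * s
      cfg$annulus_offset <- base$annulus_offset * f_ann * s
      cfg$ef_target <- ef
      cfg$pm_specs <- pm
      cfg$moderator_band <- mb
      cfg$seed <- as.integer((seed + i) %% .Machine$integer.max)
      cfg
    })
  })
  lapply(configs, generate_patient)
}

# --- mesh orientation cleanup ----------------------------------------------

signed_volume6 <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
        a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]))
}

# Make a single-component closed mesh consistently outward-oriented.  Fast
# path: if no directed edge repeats, the winding is already consistent and
# only a global sign flip may be needed; otherwise repair by BFS over
# shared edges.
orient_mesh <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  dir_key <- c(paste(f[, 1], f[, 2]), paste(f[, 2], f[, 3]), paste(f[, 3], f[, 1]))
  if (!anyDuplicated(dir_key)) {
    if (signed_volume6(mesh$vertices, f) < 0) f <- f[, c(1, 3, 2)]
    return(triangle_mesh(mesh$vertices, f, mesh$label, validate = FALSE))
  }
  # BFS repair (construction defects only; rare)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(m), 3)
  idx <- split(seq_len(3 * m), key)
  visited <- rep(FALSE, m)
  flipped <- rep(FALSE, m)
  queue <- integer(m)
  edge_dir <- function(face_row, slot) {
    a <- f[face_row, c(1, 2, 3)[slot]]
    b <- f[face_row, c(2, 3, 1)[slot]]
    if (flipped[face_row]) c(b, a) else c(a, b)
  }
  for (start in seq_len(m)) {
    if (visited[start]) next
    head <- 1L; tail <- 1L
    queue[1] <- start
    visited[start] <- TRUE
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (slot in 1:3) {
        d <- edge_dir(cur, slot)
        occ <- idx[[paste(min(d), max(d))]]
        for (o in occ) {
          nb <- fid[o]
          if (nb == cur || visited[nb]) next
          nb_slot <- ((o - 1) %/% m) + 1
          dn <- edge_dir(nb, nb_slot)
          if (all(dn == d)) flipped[nb] <- TRUE
          visited[nb] <- TRUE
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  f2 <- f
  f2[flipped, ] <- f[flipped, c(1, 3, 2)]
  if (signed_volume6(mesh$vertices, f2) < 0) f2 <- f2[, c(1, 3, 2)]
  triangle_mesh(mesh$vertices, f2, mesh$label, validate = FALSE)
}
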