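# Virtual implantation engine: place a cylinder at every septal node,
# oriented along the inward surface normal, track it through the cardiac
# cycle, and classify per-structure collision.

#' Engine configuration
#'
#' @param exclusion_radius RV-wall faces whose centroid lies within this
#'   Euclidean distance (mm) of the device base are excluded from the
#'   surface test, preventing attachment-site self-intersection; the septum
#'   itself is never a collision target
#' @param per_frame_normals re-evaluate the implant axis from each frame's
#'   septal normal (default); `FALSE` keeps the end-diastolic axis
#' @param perturbation_angle maximum tilt (degrees) for
#'   [orientation_sensitivity()]
#' @param perturbation_samples orientation samples per site
#' @param seed RNG seed for perturbation sampling
#' @export
engine_config <- function(exclusion_radius = 10, per_frame_normals = TRUE,
                          perturbation_angle = 0, perturbation_samples = 1,
                          seed = 1) {
  if (exclusion_radius < 0) stop("exclusion_radius must be >= 0")
  if (perturbation_angle < 0) stop("perturbation_angle must be >= 0")
  structure(list(exclusion_radius = exclusion_radius,
                 per_frame_normals = per_frame_normals,
                 perturbation_angle = perturbation_angle,
                 perturbation_samples = as.integer(perturbation_samples),
                 seed = as.integer(seed)), class = "engine_config")
}

#' Implant sites of a patient: septal nodes with inward normals
#'
#' @param anatomy a `patient_anatomy`
#' @param frame frame index (default 1 = end diastole)
#' @return data.frame with `node`, `x`, `y`, `z`, `nx`, `ny`, `nz`
#' @export
implant_sites <- function(anatomy, frame = 1) {
  sc <- anatomy$sequence$frames[[frame]]
  sep <- sc$structures$SEPTUM
  n <- site_normals_frame(sc)
  data.frame(node = seq_len(nrow(sep$vertices)),
             x = sep$vertices[, 1], y = sep$vertices[, 2], z = sep$vertices[, 3],
             nx = n[, 1], ny = n[, 2], nz = n[, 3])
}

# area-weighted septal vertex normals oriented into the cavity
site_normals_frame <- function(scene) {
  sep <- scene$structures$SEPTUM
  cav <- scene$structures$CAVITY
  ref <- if (!is.null(cav)) colMeans(cav$vertices) else colMeans(sep$vertices)
  n <- vertex_normals(sep, toward = ref)
  if (any(!is.finite(n))) stop("septal mesh has isolated nodes (no incident faces)")
  n
}

#' Per-node septal unit normals for each frame
#'
#' Area-weighted average of incident-face normals, re-normalized and
#' sign-flipped to point toward the cavity centroid.  With
#' `per_frame_normals = FALSE` the end-diastolic normals are carried to all
#' frames.
#'
#' @param anatomy a `patient_anatomy`
#' @param config an [engine_config]
#' @return list of n x 3 matrices, one per frame
#' @export
site_normals <- function(anatomy, config = engine_config()) {
  frames <- anatomy$sequence$frames
  if (config$per_frame_normals) {
    lapply(frames, site_normals_frame)
  } else {
    n0 <- site_normals_frame(frames[[1]])
    rep(list(n0), length(frames))
  }
}

#' Track one implanted device through the cycle
#'
#' @param node septal node index
#' @param device a [device_spec]
#' @param anatomy a `patient_anatomy`
#' @param config an [engine_config]
#' @return list of [cylinder], one per frame; the base follows the deformed
#'   node position exactly
#' @export
place_and_track <- function(node, device, anatomy, config = engine_config()) {
  normals <- site_normals(anatomy, config)
  lapply(seq_along(anatomy$sequence$frames), function(f) {
    sep <- anatomy$sequence$frames[[f]]$structures$SEPTUM
    cylinder(sep$vertices[node, ], normals[[f]][node, ],
             device$length, device$diameter / 2)
  })
}

# prebuilt per-frame, per-category BVH handles (reused across devices)
anatomy_bvhs <- function(anatomy) {
  lapply(anatomy$sequence$frames, function(sc) {
    out <- list()
    for (k in COLLISION_CATEGORIES) {
      m <- sc$structures[[k]]
      if (!is.null(m)) out[[k]] <- build_bvh(m)
    }
    out
  })
}

#' Assess collision for every septal node of a patient
#'
#' For each frame and structure category the cylinder solid is tested
#' against the structure solid; the RV-wall test excludes faces within
#' `exclusion_radius` of the device base (the septum is a separate mesh and
#' never a target).  A site is positive for a category if it collides in at
#' least one frame, and positive for combined risk if any category is
#' positive.
#'
#' @param anatomy a `patient_anatomy`
#' @param device a [device_spec]
#' @param config an [engine_config]
#' @param bvhs optional prebuilt handles from `anatomy_bvhs()`
#' @param nodes optional subset of septal node indices
#' @param patient patient identifier recorded in the output
#' @return data.frame, one row per node: `patient`, `node`, `device`,
#'   `length_mm`, `diameter_mm`, logical `rv_wall`, `pm`, `tv`, `combined`,
#'   and integer phase bitmasks `frames_hit_rv_wall`, `frames_hit_pm`,
#'   `frames_hit_tv` (bit f-1 set when frame f collides)
#' @export
run_patient <- function(anatomy, device, config = engine_config(),
                        bvhs = NULL, nodes = NULL, patient = 1L) {
  if (is.null(bvhs)) bvhs <- anatomy_bvhs(anatomy)
  normals <- site_normals(anatomy, config)
  frames <- anatomy$sequence$frames
  n_all <- nrow(frames[[1]]$structures$SEPTUM$vertices)
  if (is.null(nodes)) nodes <- seq_len(n_all)
  radius <- device$diameter / 2
  hit <- list()
  for (k in COLLISION_CATEGORIES) {
    hit[[k]] <- matrix(FALSE, length(nodes), length(frames))
  }
  for (f in seq_along(frames)) {
    sep <- frames[[f]]$structures$SEPTUM
    bases <- sep$vertices[nodes, , drop = FALSE]
    axes <- normals[[f]][nodes, , drop = FALSE]
    for (k in COLLISION_CATEGORIES) {
      if (is.null(bvhs[[f]][[k]])) next
      excl <- if (k == "RV_WALL") config$exclusion_radius else 0
      hit[[k]][, f] <- cpp_assess_frame(bvhs[[f]][[k]], bases, axes,
                                        device$length, radius, excl)
    }
  }
  pow2 <- 2^(seq_along(frames) - 1)
  mask <- lapply(hit, function(h) as.integer(h %*% pow2))
  pos <- lapply(hit, function(h) rowSums(h) > 0)
  data.frame(patient = patient, node = nodes, device = device$name,
             length_mm = device$length, diameter_mm = device$diameter,
             rv_wall = pos$RV_WALL, pm = pos$PM, tv = pos$TV,
             combined = pos$RV_WALL | pos$PM | pos$TV,
             frames_hit_rv_wall = mask$RV_WALL,
             frames_hit_pm = mask$PM,
             frames_hit_tv = mask$TV)
}

#' Assess a single implant site
#'
#' @inheritParams run_patient
#' @param node septal node index
#' @return one-row data.frame as [run_patient()]
#' @export
assess_site <- function(node, device, anatomy, config = engine_config(),
                        bvhs = NULL, patient = 1L) {
  run_patient(anatomy, device, config, bvhs = bvhs, nodes = node,
              patient = patient)
}

#' Orientation-sensitivity analysis
#'
#' Re-runs the assessment with the implant axis tilted by an angle drawn
#' uniformly in `[0, perturbation_angle]` about a uniformly random azimuth
#' (independently per site and sample, fixed across frames of a sample).
#' Site risk is the fraction of sampled orientations that are
#' combined-positive.  Deterministic under `config$seed`.
#'
#' @inheritParams run_patient
#' @return data.frame with `node`, `risk` (fraction in `[0, 1]`), and the
#'   unperturbed `combined` flag
#' @export
orientation_sensitivity <- function(anatomy, device, config = engine_config(),
                                    bvhs = NULL, nodes = NULL) {
  if (config$perturbation_samples < 1) stop("perturbation_samples must be >= 1")
  if (is.null(bvhs)) bvhs <- anatomy_bvhs(anatomy)
  base_rec <- run_patient(anatomy, device, config, bvhs = bvhs, nodes = nodes)
  if (config$perturbation_angle <= 0) {
    return(data.frame(node = base_rec$node, risk = as.numeric(base_rec$combined),
                      combined = base_rec$combined))
  }
  normals <- site_normals(anatomy, config)
  frames <- anatomy$sequence$frames
  idx <- base_rec$node
  max_rad <- config$perturbation_angle * pi / 180
  radius <- device$diameter / 2
  pos_count <- local_seed(config$seed, {
    cnt <- integer(length(idx))
    for (s in seq_len(config$perturbation_samples)) {
      theta <- runif(length(idx), 0, max_rad)
      az <- runif(length(idx), 0, 2 * pi)
      any_hit <- rep(FALSE, length(idx))
      for (f in seq_along(frames)) {
        sep <- frames[[f]]$structures$SEPTUM
        bases <- sep$vertices[idx, , drop = FALSE]
        n <- normals[[f]][idx, , drop = FALSE]
        axes <- tilt_axes(n, theta, az)
        for (k in COLLISION_CATEGORIES) {
          if (is.null(bvhs[[f]][[k]])) next
          todo <- which(!any_hit)
          if (length(todo) == 0) break
          excl <- if (k == "RV_WALL") config$exclusion_radius else 0
          h <- cpp_assess_frame(bvhs[[f]][[k]], bases[todo, , drop = FALSE],
                                axes[todo, , drop = FALSE],
                                device$length, radius, excl)
          any_hit[todo[h]] <- TRUE
        }
      }
      cnt <- cnt + any_hit
    }
    cnt
  })
  data.frame(node = idx, risk = pos_count / config$perturbation_samples,
             combined = base_rec$combined)
}

# tilt unit normals n (rows) by theta about azimuth az in their tangent plane
tilt_axes <- function(n, theta, az) {
  out <- matrix(0, nrow(n), 3)
  for (i in seq_len(nrow(n))) {
    e1 <- orthonormal_to(n[i, ])
    e2 <- cross3(n[i, ], e1)
    out[i, ] <- cos(theta[i]) * n[i, ] +
      sin(theta[i]) * (cos(az[i]) * e1 + sin(az[i]) * e2)
  }
  out
}
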