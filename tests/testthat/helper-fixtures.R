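# Shared test helpers: coarse anatomies, random rigid transforms, and
# randomized collision scenes with a robustness margin.

coarse_config <- function(...) {
  anatomy_config(resolution = c(24, 18), ...)
}

# one coarse patient, built once per test file
coarse_patient <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_patient(coarse_config())
    cache
  }
})

random_rotation <- function() {
  ax <- rnorm(3)
  rotation_matrix(ax / sqrt(sum(ax^2)), runif(1, 0, 2 * pi))
}

transform_cylinder <- function(cyl, R, t) {
  cylinder(as.numeric(R %*% cyl$base) + t, as.numeric(R %*% cyl$axis),
           cyl$length, cyl$radius)
}

# apply one rigid transform to every frame and landmark of a patient
transform_patient <- function(an, R, t) {
  frames <- lapply(an$sequence$frames, function(sc) {
    labeled_scene(lapply(sc$structures, transform_mesh, rotation = R,
                         translation = t),
                  lapply(sc$landmarks, function(p) as.numeric(R %*% p) + t))
  })
  paths <- lapply(an$conduction_paths, function(p) {
    t(apply(p, 1, function(q) as.numeric(R %*% q) + t))
  })
  structure(list(sequence = scene_sequence(frames, an$sequence$phase),
                 landmarks = frames[[1]]$landmarks,
                 chordae_points = lapply(an$chordae_points,
                                         function(p) as.numeric(R %*% p) + t),
                 conduction_paths = paths, config = an$config),
            class = "patient_anatomy")
}

# a random closed mesh: rotated box, sphere, or solid cylinder
random_scene_mesh <- function() {
  kind <- sample(3, 1)
  m <- switch(kind,
              box_mesh(runif(3, 4, 18), c(0, 0, 0)),
              uv_sphere_mesh(runif(1, 3, 9), n_theta = 8, n_phi = 10),
              cylinder_solid_mesh(c(0, 0, -runif(1, 2, 6)), rnorm(3),
                                  runif(1, 5, 14), runif(1, 2, 6), n_phi = 10))
  m <- transform_mesh(m, random_rotation(), runif(3, -4, 4))
  lpmcollide:::orient_mesh(m)
}

random_test_cylinder <- function() {
  cylinder(runif(3, -15, 15), rnorm(3), runif(1, 1, 25), runif(1, 0.3, 5))
}

# is the scene robust, i.e. does the verdict survive shrinking/growing the
# device?  Used to keep randomized oracle comparisons away from grazing
# configurations at the sampling resolution.
robust_verdict <- function(cyl, mesh, margin = 0.15) {
  v0 <- cylinder_mesh_overlap(cyl, mesh)$collides
  for (f in c(1 - margin, 1 + margin)) {
    cs <- cylinder(cyl$base, cyl$axis, cyl$length * f, max(cyl$radius * f, 1e-6))
    if (cylinder_mesh_overlap(cs, mesh)$collides != v0) return(NA)
  }
  v0
}
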