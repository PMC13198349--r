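# Implantation engine: normals, tracking, and collision classification on
# fixtures with analytically known outcomes.

test_that("flat septum fixtures have uniform inward normals", {
  fx <- make_fixtures()$wall_hit
  n <- site_normals(fx)
  for (f in 1:2) {
    expect_equal(n[[f]], matrix(rep(c(0, 0, 1), each = 9), 9, 3),
                 tolerance = 1e-12)
  }
})

test_that("spherical septum normals are radial", {
  s <- uv_sphere_mesh(20, n_theta = 24, n_phi = 32, label = "SEPTUM")
  wall <- cube_mesh(2, c(90, 0, 0), "RV_WALL")
  lm <- list(apex = c(0, 0, -20), tv_centre = c(0, 0, 20),
             attach_anterior = c(20, 0, 0), attach_posterior = c(0, 20, 0))
  sc <- labeled_scene(list(SEPTUM = s, RV_WALL = wall), lm)
  n <- lpmcollide:::site_normals_frame(sc)
  radial <- -s$vertices / sqrt(rowSums(s$vertices^2))  # inward
  expect_lt(max(abs(n - radial)), 0.03)  # vertex-normal discretization
})

test_that("per-frame normals of a rigidly rotated sequence are rotated normals", {
  fx <- make_fixtures()$wall_hit
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  tr <- c(4, -5, 6)
  sc1 <- fx$sequence$frames[[1]]
  sc2 <- labeled_scene(lapply(sc1$structures, transform_mesh, rotation = R,
                              translation = tr),
                       lapply(sc1$landmarks, function(p) as.numeric(R %*% p) + tr))
  an <- structure(list(sequence = scene_sequence(list(sc1, sc2)),
                       landmarks = sc1$landmarks, chordae_points = list(),
                       conduction_paths = list(), config = NULL),
                  class = "patient_anatomy")
  n <- site_normals(an)
  expect_equal(n[[2]], n[[1]] %*% t(R), tolerance = 1e-9)
})

test_that("tracked cylinders follow the node trajectory exactly", {
  an <- coarse_patient()
  dev <- lpm_catalogue()[[1]]
  cyls <- place_and_track(17, dev, an)
  for (f in seq_along(cyls)) {
    sep <- an$sequence$frames[[f]]$structures$SEPTUM
    expect_identical(cyls[[f]]$base, unname(sep$vertices[17, ]))
    expect_equal(cyls[[f]]$length, dev$length)
    expect_equal(cyls[[f]]$radius, dev$diameter / 2)
  }
  # static fixture: identical cylinder in every frame
  fx <- make_fixtures()$wall_hit
  cyls <- place_and_track(5, dev, fx)
  expect_identical(cyls[[1]], cyls[[2]])
})

test_that("wall-hit fixture flags exactly the node under the wall block", {
  fx <- make_fixtures()$wall_hit
  exp <- attr(fx, "expected")
  hit_dev <- device_spec("probe16", exp$hit_length, diameter = 2 * exp$radius)
  rec <- run_patient(fx, hit_dev)
  expect_equal(which(rec$rv_wall), exp$hit_node)
  expect_equal(which(rec$combined), exp$hit_node)
  expect_false(any(rec$pm))
  expect_false(any(rec$tv))
  miss_dev <- device_spec("probe10", exp$miss_length, diameter = 2 * exp$radius)
  rec2 <- run_patient(fx, miss_dev)
  expect_false(any(rec2$combined))
  # degenerate device: nothing collides
  rec3 <- run_patient(fx, structure(list(name = "null", length = 0,
                                         diameter = 0, volume = 0),
                                    class = "device_spec"))
  expect_false(any(rec3$combined))
})

test_that("tv-graze fixture switches on at the known length threshold", {
  fx <- make_fixtures()$tv_graze
  exp <- attr(fx, "expected")
  below <- run_patient(fx, device_spec("b", exp$threshold_length - 0.2,
                                       diameter = 2 * exp$radius))
  above <- run_patient(fx, device_spec("a", exp$threshold_length + 0.2,
                                       diameter = 2 * exp$radius))
  expect_false(any(below$tv))
  expect_true(all(above$tv))
})

test_that("frame bitmasks are consistent with the positive flags", {
  an <- coarse_patient()
  rec <- run_patient(an, lpm_catalogue()[[3]])
  expect_identical(rec$rv_wall, rec$frames_hit_rv_wall > 0)
  expect_identical(rec$pm, rec$frames_hit_pm > 0)
  expect_identical(rec$tv, rec$frames_hit_tv > 0)
  expect_identical(rec$combined, rec$rv_wall | rec$pm | rec$tv)
  # determinism
  rec2 <- run_patient(an, lpm_catalogue()[[3]])
  expect_identical(rec, rec2)
})

test_that("combined positivity is monotone in device length at fixed radius", {
  an <- coarse_patient()
  lengths <- c(15, 25, 35, 45)
  recs <- lapply(lengths, function(L) {
    run_patient(an, device_spec(sprintf("L%d", L), L, diameter = 6.5))
  })
  for (i in seq_len(length(lengths) - 1)) {
    expect_true(all(recs[[i + 1]]$combined >= recs[[i]]$combined))
    expect_true(all(recs[[i + 1]]$rv_wall >= recs[[i]]$rv_wall))
  }
})

test_that("removing a structure category can only decrease combined risk", {
  an <- coarse_patient()
  dev <- lpm_catalogue()[[2]]
  full <- run_patient(an, dev)
  stripped <- an
  frames <- lapply(an$sequence$frames, function(sc) {
    labeled_scene(sc$structures[setdiff(names(sc$structures), "PM")],
                  sc$landmarks)
  })
  stripped$sequence <- scene_sequence(frames, an$sequence$phase)
  part <- run_patient(stripped, dev)
  expect_true(all(part$combined <= full$combined))
  expect_equal(mean(part$combined) <= mean(full$combined), TRUE)
})

test_that("orientation sensitivity reduces to the point assessment at zero tilt", {
  an <- coarse_patient()
  dev <- lpm_catalogue()[[1]]
  cfg0 <- engine_config(perturbation_angle = 0, perturbation_samples = 3)
  os0 <- orientation_sensitivity(an, dev, cfg0, nodes = 1:60)
  base <- run_patient(an, dev, nodes = 1:60)
  expect_equal(os0$risk, as.numeric(base$combined))
  cfg5 <- engine_config(perturbation_angle = 5, perturbation_samples = 4, seed = 3)
  os5a <- orientation_sensitivity(an, dev, cfg5, nodes = 1:60)
  os5b <- orientation_sensitivity(an, dev, cfg5, nodes = 1:60)
  expect_identical(os5a, os5b)
  expect_true(all(os5a$risk >= 0 & os5a$risk <= 1))
})
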