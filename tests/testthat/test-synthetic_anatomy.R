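# Synthetic anatomy generator: volume calibration, closure, motion, cohort.

test_that("end-diastolic cavity volume hits the target within 2%", {
  an <- coarse_patient()
  v <- closed_mesh_volume(an$sequence$frames[[1]]$structures$CAVITY)
  expect_lt(abs(v - 283) / 283, 0.02)
  ed2 <- generate_ed_scene(coarse_config(edv_target = 180, annulus_radius = 15,
                                         annulus_offset = c(5, -10)))
  v2 <- closed_mesh_volume(ed2$scene$structures$CAVITY)
  expect_lt(abs(v2 - 180) / 180, 0.02)
})

test_that("all collision-target structures are closed; septum is a surface patch", {
  sc <- coarse_patient()$sequence$frames[[1]]
  for (k in c("RV_WALL", "PM", "TV", "CAVITY")) {
    expect_true(is_closed_mesh(sc$structures[[k]]), label = k)
  }
  expect_gt(boundary_edge_count(sc$structures$SEPTUM), 0)
})

test_that("zero papillary muscles degenerate to the annulus slab alone", {
  cfg <- coarse_config(pm_specs = list(), moderator_band = NULL)
  ed <- generate_ed_scene(cfg)
  expect_null(ed$scene$structures$PM)
  tv <- ed$scene$structures$TV
  expect_true(is_closed_mesh(tv))
  # slab only: volume = pi r^2 * thickness
  expect_equal(closed_mesh_volume(tv) * 1000,
               pi * cfg$annulus_radius^2 * cfg$tv_plane_thickness,
               tolerance = 0.02)
})

test_that("free-wall shell volume matches the thin-shell approximation", {
  ed <- generate_ed_scene(coarse_config())
  wall_vol <- closed_mesh_volume(ed$scene$structures$RV_WALL) * 1000
  cap_area <- lpmcollide:::d_section_area(pi / 3) * ed$R_base^2
  endo_area <- mesh_area(ed$scene$structures$CAVITY) -
    mesh_area(ed$scene$structures$SEPTUM) - cap_area
  expect_lt(abs(wall_vol - endo_area * 3.5) / (endo_area * 3.5), 0.10)
})

test_that("TV cone apexes coincide with the chordae points", {
  an <- coarse_patient()
  tv <- an$sequence$frames[[1]]$structures$TV
  for (ch in an$chordae_points) {
    d <- min(sqrt(rowSums(sweep(tv$vertices, 2, ch)^2)))
    expect_lt(d, 1e-9)
  }
  # all cone vertices lie between the chordae level and the annulus slab
  zmax <- an$landmarks$tv_centre[3] + 2 + 1e-9
  zmin <- min(vapply(an$chordae_points, function(p) p[3], numeric(1))) - 1e-9
  expect_true(all(tv$vertices[, 3] >= zmin & tv$vertices[, 3] <= zmax))
})

test_that("conduction paths lie on the septal surface", {
  an <- coarse_patient()
  sep <- an$sequence$frames[[1]]$structures$SEPTUM
  bvh <- lpmcollide:::build_bvh(sep)
  for (nm in c("LBB", "LAF", "LPF", "LSF")) {
    p <- an$conduction_paths[[nm]]
    expect_gte(nrow(p), 10)
    expect_lt(max(lpmcollide:::cpp_points_mesh_dist(bvh, p)), 1e-9)
  }
})

test_that("motion calibration recovers target ejection fractions within 1%", {
  for (ef in c(10, 22, 40)) {
    cfg <- coarse_config(ef_target = ef)
    an <- generate_patient(cfg)
    expect_lt(abs(measured_ef(an$sequence) - ef), 1)
  }
})

test_that("zero EF target leaves every frame at end diastole", {
  cfg <- coarse_config(ef_target = 0)
  an <- generate_patient(cfg)
  v <- frame_volumes(an$sequence)
  expect_equal(max(v) - min(v), 0, tolerance = 1e-9)
  expect_identical(an$sequence$frames[[4]]$structures$CAVITY$vertices,
                   an$sequence$frames[[1]]$structures$CAVITY$vertices)
})

test_that("cavity volume is minimal at mid-cycle and varies smoothly", {
  an <- coarse_patient()
  v <- frame_volumes(an$sequence)
  expect_equal(which.min(v), 6)  # phase fraction 0.5 of 10 frames
  # single systolic trough: volume decreases to the minimum then rises
  expect_true(all(diff(v[1:6]) < 0))
  expect_true(all(diff(v[6:10]) > 0))
})

test_that("measured EF reproduces reference patients from two-frame volumes", {
  # scaled copies of one sphere mesh: volume ratio (and hence EF) is exact
  base <- uv_sphere_mesh(41.7, n_theta = 12, n_phi = 16, label = "CAVITY")
  two_frame_ef <- function(edv, esv) {
    s <- (esv / edv)^(1 / 3)
    sc1 <- list(CAVITY = base)
    sc2 <- list(CAVITY = triangle_mesh(base$vertices * s, base$faces, "CAVITY"))
    sep <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                         rbind(c(1, 2, 3)), "SEPTUM")
    wall <- cube_mesh(2, c(90, 0, 0), "RV_WALL")
    lm <- list(apex = c(0, 0, -50), tv_centre = c(0, 0, 50),
               attach_anterior = c(50, 0, 0), attach_posterior = c(0, 50, 0))
    mk <- function(s_) labeled_scene(c(list(SEPTUM = sep, RV_WALL = wall), s_), lm)
    measured_ef(scene_sequence(list(mk(sc1["CAVITY"]), mk(sc2["CAVITY"]))))
  }
  expect_equal(two_frame_ef(303, 228), 100 * (303 - 228) / 303, tolerance = 1e-9)
  expect_equal(round(two_frame_ef(303, 228)), 25)
  expect_equal(two_frame_ef(235, 216), 100 * (235 - 216) / 235, tolerance = 1e-9)
  expect_equal(round(two_frame_ef(235, 216)), 8)
  expect_equal(two_frame_ef(250, 250), 0)
})

test_that("cohort generation is deterministic and honors variability", {
  c1 <- generate_cohort(3, coarse_config(), seed = 5)
  c2 <- generate_cohort(3, coarse_config(), seed = 5)
  for (i in 1:3) {
    expect_identical(c1[[i]]$sequence$frames[[1]]$structures$CAVITY$vertices,
                     c2[[i]]$sequence$frames[[1]]$structures$CAVITY$vertices)
  }
  # zero variability: identical anatomies
  zv <- list(edv = 0, long_axis = 0, annulus = 0, ef_abs = 0)
  cz <- generate_cohort(2, coarse_config(), variability = zv, seed = 1)
  expect_identical(cz[[1]]$sequence$frames[[5]]$structures$CAVITY$vertices,
                   cz[[2]]$sequence$frames[[5]]$structures$CAVITY$vertices)
  # default variability: sample SD of EDV within a factor 2 of requested
  cd <- generate_cohort(10, coarse_config(), seed = 2)
  edv <- vapply(cd, function(a) max(frame_volumes(a$sequence)), numeric(1))
  expect_gt(sd(edv), 38 / 2)
  expect_lt(sd(edv), 38 * 2)
})
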