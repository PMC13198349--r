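# Mesh container, volume computation, and file round trips.

test_that("closed-mesh volume matches analytic solids and is rigid-invariant", {
  expect_equal(closed_mesh_volume(cube_mesh(10)), 1.0, tolerance = 1e-12)
  s <- uv_sphere_mesh(10, n_theta = 48, n_phi = 64)
  expect_equal(closed_mesh_volume(s), 4 / 3 * pi * 1e3 / 1000, tolerance = 5e-3)
  set.seed(7)
  m <- box_mesh(c(3, 11, 6), c(2, -4, 9))
  v0 <- closed_mesh_volume(m)
  for (i in 1:5) {
    m2 <- transform_mesh(m, random_rotation(), runif(3, -50, 50))
    expect_equal(closed_mesh_volume(m2), v0, tolerance = 1e-9)
  }
})

test_that("open meshes are rejected with the boundary edge count", {
  m <- cube_mesh(10)
  open_m <- triangle_mesh(m$vertices, m$faces[-1, ], "broken", validate = FALSE)
  expect_equal(boundary_edge_count(open_m), 3)
  expect_error(closed_mesh_volume(open_m), "3 boundary edges")
  expect_false(is_closed_mesh(open_m))
  expect_true(is_closed_mesh(m))
})

test_that("volume agrees with Monte-Carlo rejection sampling within 3 SE", {
  set.seed(42)
  m <- transform_mesh(uv_sphere_mesh(8, n_theta = 16, n_phi = 20),
                      random_rotation(), c(3, -2, 5))
  v_exact <- closed_mesh_volume(m) * 1000  # mm^3
  lo <- apply(m$vertices, 2, min)
  hi <- apply(m$vertices, 2, max)
  n <- 20000
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  p_hat <- mean(point_in_closed_mesh(pts, m))
  v_box <- prod(hi - lo)
  v_mc <- p_hat * v_box
  se <- v_box * sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(v_mc - v_exact), 3 * se)
})

test_that("write/read round trips preserve vertices bitwise in every format", {
  set.seed(1)
  m <- transform_mesh(cylinder_solid_mesh(c(0.1, -0.2, 0.3), c(1, 2, 3),
                                          17.123456789, 4.987654321, n_phi = 12),
                      random_rotation(), rnorm(3))
  dir <- withr::local_tempdir()
  for (fmt in c("obj", "ply", "vtk")) {
    p <- file.path(dir, paste0("m.", fmt))
    write_mesh(m, p, fmt)
    m2 <- read_mesh(p, fmt)
    expect_identical(m2$vertices, m$vertices, label = fmt)
    expect_identical(m2$faces, m$faces)
  }
  p <- file.path(dir, "m_bin.vtk")
  write_mesh(m, p, "vtk", binary = TRUE)
  m3 <- read_mesh(p, "vtk")
  expect_identical(m3$vertices, m$vertices)
  expect_identical(m3$faces, m$faces)
})

test_that("scene sequences survive a write/read round trip bitwise", {
  an <- coarse_patient()
  dir <- withr::local_tempdir()
  write_scene_sequence(an$sequence, dir, format = "vtk")
  seq2 <- read_scene_sequence(dir)
  expect_equal(length(seq2$frames), length(an$sequence$frames))
  expect_equal(seq2$phase, an$sequence$phase)
  for (f in c(1, 5)) {
    for (k in names(an$sequence$frames[[f]]$structures)) {
      expect_identical(seq2$frames[[f]]$structures[[k]]$vertices,
                       an$sequence$frames[[f]]$structures[[k]]$vertices)
    }
  }
})

test_that("frame topology mismatches and unknown categories are rejected", {
  dir <- withr::local_tempdir()
  cube <- cube_mesh(10, label = "RV_WALL")
  sep <- flat <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                               rbind(c(1, 2, 3)), "SEPTUM")
  write_mesh(cube, file.path(dir, "w0.ply"), "ply")
  # frame 2 wall has an extra vertex: same faces, different vertex count
  cube2 <- triangle_mesh(rbind(cube$vertices, c(99, 99, 99)), cube$faces, "RV_WALL",
                         validate = FALSE)
  write_mesh(cube2, file.path(dir, "w1.ply"), "ply")
  write_mesh(sep, file.path(dir, "s0.ply"), "ply")
  write_mesh(sep, file.path(dir, "s1.ply"), "ply")
  man <- data.frame(frame = c(0, 0, 1, 1),
                    category = c("RV_WALL", "SEPTUM", "RV_WALL", "SEPTUM"),
                    path = c("w0.ply", "s0.ply", "w1.ply", "s1.ply"))
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lm <- list(apex = c(0, 0, 0), tv_centre = c(0, 0, 1),
             attach_anterior = c(1, 0, 0), attach_posterior = c(0, 1, 0))
  jsonlite::write_json(list(phase = c(0, 0.5), landmarks = list(lm, lm)),
                       file.path(dir, "landmarks.json"), digits = NA)
  expect_error(read_scene_sequence(dir), "topology mismatch")
  man$category[1] <- "BANANA"
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_scene_sequence(dir), "unknown category")
})

test_that("identical frames of a labeled cube form a valid 2-frame sequence", {
  cube <- cube_mesh(10, label = "RV_WALL")
  sep <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)), "SEPTUM")
  lm <- list(apex = c(0, 0, 0), tv_centre = c(0, 0, 1),
             attach_anterior = c(1, 0, 0), attach_posterior = c(0, 1, 0))
  sc <- labeled_scene(list(SEPTUM = sep, RV_WALL = cube), lm)
  sq <- scene_sequence(list(sc, sc))
  expect_equal(length(sq$frames), 2)
  expect_equal(nrow(sq$frames[[2]]$structures$RV_WALL$vertices), 8)
  expect_error(labeled_scene(list(SEPTUM = sep), lm), "RV_WALL")
  expect_error(labeled_scene(list(SEPTUM = sep, RV_WALL = cube, XX = cube), lm),
               "unknown structure categories")
})
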