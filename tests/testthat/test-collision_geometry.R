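# Collision predicates: point containment, segment-triangle distance, and
# cylinder-mesh overlap against independent oracles.

test_that("point containment matches the half-space test on convex meshes", {
  set.seed(3)
  for (rep in 1:3) {
    m <- transform_mesh(uv_sphere_mesh(runif(1, 4, 8), n_theta = 6, n_phi = 8),
                        random_rotation(), runif(3, -3, 3))
    m <- lpmcollide:::orient_mesh(m)
    fn <- lpmcollide:::face_normals(m)
    fc <- lpmcollide:::face_centroids(m)
    lo <- apply(m$vertices, 2, min) - 2
    hi <- apply(m$vertices, 2, max) + 2
    n <- 3000
    pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                 runif(n, lo[3], hi[3]))
    inside_hs <- vapply(seq_len(n), function(i) {
      all(rowSums(fn * (matrix(pts[i, ], nrow(fc), 3, byrow = TRUE) - fc)) <= 1e-9)
    }, logical(1))
    expect_equal(point_in_closed_mesh(pts, m), inside_hs)
  }
  expect_true(point_in_closed_mesh(c(0, 0, 0), cube_mesh(10)))
  expect_false(point_in_closed_mesh(c(25, 0, 0), cube_mesh(10)))
})

test_that("segment-triangle distance is exact on analytic cases", {
  tri <- rbind(c(-5, -5, 0), c(5, -5, 0), c(0, 5, 0))
  # parallel segment above the plane, projection inside
  expect_equal(segment_triangle_distance(c(-1, 0, 3), c(1, 0, 3), tri), 3)
  # segment crossing the triangle
  expect_equal(segment_triangle_distance(c(0, 0, -1), c(0, 0, 1), tri), 0)
  # endpoint closest to a vertex
  expect_equal(segment_triangle_distance(c(0, 9, 0), c(0, 12, 0), tri), 4)
})

test_that("segment-triangle distance is symmetric and matches dual sampling", {
  set.seed(11)
  n_grid <- 60
  tt <- seq(0, 1, length.out = n_grid)
  bar <- expand.grid(u = tt, v = tt)
  bar <- bar[bar$u + bar$v <= 1, ]
  for (rep in 1:8) {
    a <- runif(3, -5, 5); b <- runif(3, -5, 5)
    tri <- matrix(runif(9, -5, 5), 3, 3)
    d <- segment_triangle_distance(a, b, tri)
    expect_equal(segment_triangle_distance(b, a, tri), d, tolerance = 1e-12)
    seg_pts <- outer(1 - tt, a) + outer(tt, b)
    tri_pts <- outer(1 - bar$u - bar$v, tri[1, ]) + outer(bar$u, tri[2, ]) +
      outer(bar$v, tri[3, ])
    # sampled minimum over all segment x triangle point pairs
    d2min <- min(vapply(seq_len(nrow(seg_pts)), function(i) {
      min((tri_pts[, 1] - seg_pts[i, 1])^2 + (tri_pts[, 2] - seg_pts[i, 2])^2 +
            (tri_pts[, 3] - seg_pts[i, 3])^2)
    }, numeric(1)))
    d_samp <- sqrt(d2min)
    expect_lte(d, d_samp + 1e-12)          # exact min cannot exceed sampled
    expect_lt(d_samp - d, 0.5)             # sampling resolution bound
  }
})

test_that("cylinder-mesh overlap handles the elementary cases", {
  cube <- cube_mesh(10)
  # far outside the bounding sphere
  far <- cylinder(c(100, 100, 100), c(1, 0, 0), 5, 2)
  expect_false(cylinder_mesh_overlap(far, cube)$collides)
  # axis passing straight through the cube, with a witness in both solids
  through <- cylinder(c(-20, 0, 0), c(1, 0, 0), 40, 1.5)
  res <- cylinder_mesh_overlap(through, cube)
  expect_true(res$collides)
  expect_false(is.null(res$witness))
  expect_true(point_in_closed_mesh(res$witness, cube))
  s <- sum((res$witness - through$base) * through$axis)
  r <- sqrt(sum(((res$witness - through$base) - s * through$axis)^2))
  expect_true(s >= 0 && s <= through$length && r <= through$radius)
  # cylinder fully containing the mesh
  fat <- cylinder(c(0, 0, -30), c(0, 0, 1), 60, 30)
  expect_true(cylinder_mesh_overlap(fat, cube)$collides)
  # mesh fully containing the cylinder
  tiny <- cylinder(c(-2, 0, 0), c(1, 0, 0), 4, 0.5)
  expect_true(cylinder_mesh_overlap(tiny, cube)$collides)
  # degenerate device
  nul <- cylinder(c(20, 0, 0), c(1, 0, 0), 0, 0)
  expect_false(cylinder_mesh_overlap(nul, cube)$collides)
})

test_that("overlap verdicts agree with the Monte-Carlo oracle on robust scenes", {
  set.seed(101)
  n_checked <- 0
  mism <- 0
  while (n_checked < 150) {
    mesh <- random_scene_mesh()
    cyl <- random_test_cylinder()
    v <- robust_verdict(cyl, mesh)
    if (is.na(v)) next
    n_checked <- n_checked + 1
    o <- overlap_oracle(cyl, mesh, n_samples = 1500, seed = n_checked)
    if (o != v) {
      # escalate the sampling resolution before declaring a disagreement:
      # small true overlaps are easily missed at the base sample count
      o <- overlap_oracle(cyl, mesh, n_samples = 60000, seed = n_checked + 1)
    }
    if (o != v) mism <- mism + 1
  }
  expect_equal(mism, 0)
})

test_that("oracle is deterministic and sane on trivial scenes", {
  cube <- cube_mesh(10)
  away <- cylinder(c(50, 0, 0), c(0, 1, 0), 5, 1)
  expect_false(overlap_oracle(away, cube, 200, seed = 1))
  inside <- cylinder(c(0, 0, -3), c(0, 0, 1), 6, 1)
  expect_true(overlap_oracle(inside, cube, 20, seed = 1))
  o1 <- overlap_oracle(cylinder(c(4, 0, 0), c(1, 0, 0), 6, 1.2), cube, 500, seed = 9)
  o2 <- overlap_oracle(cylinder(c(4, 0, 0), c(1, 0, 0), 6, 1.2), cube, 500, seed = 9)
  expect_identical(o1, o2)
})

test_that("overlap is invariant under rigid transforms of both solids", {
  set.seed(21)
  for (rep in 1:30) {
    mesh <- random_scene_mesh()
    cyl <- random_test_cylinder()
    v <- cylinder_mesh_overlap(cyl, mesh)$collides
    R <- random_rotation(); tr <- runif(3, -30, 30)
    v2 <- cylinder_mesh_overlap(transform_cylinder(cyl, R, tr),
                                transform_mesh(mesh, R, tr))$collides
    expect_identical(v2, v)
  }
})

test_that("growing radius or length never turns a collision off", {
  set.seed(31)
  for (rep in 1:30) {
    mesh <- random_scene_mesh()
    cyl <- random_test_cylinder()
    verdicts_r <- vapply(c(0.5, 1, 2, 4), function(f) {
      cylinder_mesh_overlap(cylinder(cyl$base, cyl$axis, cyl$length,
                                     cyl$radius * f), mesh)$collides
    }, logical(1))
    expect_true(all(diff(verdicts_r) >= 0))
    verdicts_l <- vapply(c(0.5, 1, 2, 4), function(f) {
      cylinder_mesh_overlap(cylinder(cyl$base, cyl$axis, cyl$length * f,
                                     cyl$radius), mesh)$collides
    }, logical(1))
    expect_true(all(diff(verdicts_l) >= 0))
  }
})

test_that("face exclusion disables only the surface test, never containment", {
  cube <- cube_mesh(10)
  # a cylinder crossing the -x face only; excluding all faces near the
  # crossing suppresses the surface hit, but the midpoint containment test
  # still fires because the midpoint is inside the cube
  cyl <- cylinder(c(-8, 0, 0), c(1, 0, 0), 8, 0.8)
  expect_true(cylinder_mesh_overlap(cyl, cube)$collides)
  all_faces <- seq_len(nrow(cube$faces))
  res <- cylinder_mesh_overlap(cyl, cube, excluded_faces = all_faces)
  expect_true(res$collides)
  # with the exclusion radius form: faces near the base are skipped, and a
  # short cylinder that only grazes those faces becomes negative
  graze <- cylinder(c(-5.5, 0, 0), c(1, 0, 0), 1, 0.8)
  expect_true(cylinder_mesh_overlap(graze, cube)$collides)
  expect_false(cylinder_mesh_overlap(graze, cube, exclusion_radius = 12)$collides)
})
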