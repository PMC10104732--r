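test_that("trivial fields produce trivial surfaces", {
  expect_equal(nrow(marching_cubes(array(0, c(3, 3, 3)), 0.5)$faces), 0L)

  # single interior voxel: a closed bubble with Euler characteristic 2
  f <- array(0, c(3, 3, 3))
  f[2, 2, 2] <- 1
  rep1 <- mesh_report(marching_cubes(f, 0.5))
  expect_equal(rep1$chi, 2)
  expect_true(rep1$watertight)
  expect_gt(rep1$volume, 0)
})

test_that("sphere surface area and volume converge to the analytic values", {
  errs <- sapply(c(1, 0.5), function(sp) {
    mesh <- marching_cubes(sphere_field(radius = 10, spacing = sp), 0)
    rep <- mesh_report(mesh)
    expect_true(rep$watertight)
    expect_equal(rep$chi, 2)
    c(
      area = abs(rep$area - 4 * pi * 100) / (4 * pi * 100),
      volume = abs(rep$volume - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000)
    )
  })
  expect_lt(errs["area", 1], 0.02)
  expect_lt(errs["volume", 1], 0.02)
  # halving the spacing shrinks both errors
  expect_lt(errs["area", 2], errs["area", 1])
  expect_lt(errs["volume", 2], errs["volume", 1])
})

test_that("an implicit torus reconstructs with genus-1 topology", {
  rep <- mesh_report(marching_cubes(torus_field(R = 8, r = 3, spacing = 1), 0))
  expect_true(rep$watertight)
  expect_equal(rep$chi, 0)
})

test_that("interior isosurfaces of random smooth fields are watertight", {
  set.seed(77)
  for (rep_i in 1:5) {
    f <- array(rnorm(10^3), c(10, 10, 10))
    for (s in 1:2) f <- ctffr:::box_smooth3(f)
    # clamp the boundary well below the isolevel so the surface stays interior
    f[c(1, 10), , ] <- -2
    f[, c(1, 10), ] <- -2
    f[, , c(1, 10)] <- -2
    mesh <- marching_cubes(f, isolevel = 0.05)
    if (!nrow(mesh$faces)) next
    rep <- mesh_report(mesh)
    expect_true(rep$watertight)
    expect_equal(rep$n_boundary_edges, 0L)
  }
})

test_that("mesh reports match closed-form combinatorics", {
  tet <- triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  )
  rep <- mesh_report(tet)
  expect_equal(rep$n_vertices, 4L)
  expect_equal(rep$n_edges, 6L)
  expect_equal(rep$n_faces, 4L)
  expect_equal(rep$chi, 2)
  expect_true(rep$watertight)
  expect_equal(abs(rep$volume), 1 / 6)

  # unit cube as 12 outward-wound triangles: area 6, volume 1
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  faces <- rbind(
    c(1, 3, 2), c(2, 3, 4), # z = 0
    c(5, 6, 7), c(6, 8, 7), # z = 1
    c(1, 2, 5), c(2, 6, 5), # y = 0
    c(3, 7, 4), c(4, 7, 8), # y = 1
    c(1, 5, 3), c(3, 5, 7), # x = 0
    c(2, 4, 6), c(4, 8, 6)  # x = 1
  )
  cube <- triangle_mesh(v, faces)
  repc <- mesh_report(cube)
  expect_equal(repc$area, 6)
  expect_equal(abs(repc$volume), 1)
  expect_true(repc$watertight)
})

test_that("Laplacian smoothing shrinks volume monotonically and keeps topology", {
  mesh <- marching_cubes(sphere_field(radius = 6, spacing = 1), 0)
  expect_identical(smooth_mesh(mesh, iterations = 0), mesh)
  vols <- vapply(0:3, function(it) {
    mesh_report(smooth_mesh(mesh, iterations = it, factor = 0.5))$volume
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
  chis <- vapply(0:3, function(it) {
    mesh_report(smooth_mesh(mesh, iterations = it, factor = 0.5))$chi
  }, numeric(1))
  expect_true(all(chis == 2))
})

test_that("capped stenosed lumens are closed genus-0 surfaces", {
  for (d in c(0, 0.3, 0.6)) {
    mask <- capped_lumen_mask(d = d)
    rep <- mesh_report(marching_cubes(mask))
    expect_true(rep$watertight)
    expect_equal(rep$chi, 2)
  }
})

test_that("lumen profiles recover radii to within half a voxel", {
  sp <- 0.4
  # uniform cylinder
  geom0 <- vessel_geometry(L = 20, R0 = 2, d = 0)
  prof0 <- extract_lumen_profile(lumen_truth_mask(geom0, spacing = sp))
  interior <- prof0$s > 2 & prof0$s < 18
  expect_true(all(abs(prof0$r[interior] - 2) <= sp / 2))

  # d = 0.5 throat
  geom5 <- vessel_geometry(L = 20, R0 = 2, d = 0.5)
  prof5 <- extract_lumen_profile(lumen_truth_mask(geom5, spacing = sp))
  expect_lt(abs(min(prof5$r) - 1), sp / 2)
})

test_that("mask pixel-count areas agree with mesh polygon-section areas", {
  mask <- capped_lumen_mask(d = 0.4, spacing = 0.5)
  mesh <- marching_cubes(mask)
  prof <- extract_lumen_profile(mask)
  interior <- which(prof$s > 3 & prof$s < max(prof$s) - 3)
  for (i in interior[seq(1, length(interior), by = 6)]) {
    a_mesh <- abs(mesh_section_area(mesh, prof$s[i]))
    expect_lt(abs(a_mesh - prof$area[i]) / prof$area[i], 0.25) # discretization tolerance
  }
})

test_that("meshes round-trip through STL and PLY", {
  tet <- triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  )
  stl <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tet, stl)
  back <- read_mesh(stl)
  expect_equal(nrow(back$faces), 4L)
  expect_equal(nrow(back$vertices), 4L)

  sph <- marching_cubes(sphere_field(radius = 4, spacing = 1), 0)
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(sph, ply)
  back2 <- read_mesh(ply)
  expect_identical(back2$faces, sph$faces)
  expect_lt(max(abs(back2$vertices - sph$vertices)), 1e-5)

  # STL stores 32-bit floats: vertices within single precision
  stl2 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(sph, stl2)
  back3 <- read_mesh(stl2)
  expect_equal(nrow(back3$faces), nrow(sph$faces))
  expect_lt(
    max(abs(range(back3$vertices) - range(sph$vertices))), 1e-5
  )

  # empty mesh: valid zero-triangle files
  emp <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  for (ext in c(".stl", ".ply")) {
    f <- withr::local_tempfile(fileext = ext)
    write_mesh(emp, f)
    expect_equal(nrow(read_mesh(f)$faces), 0L)
  }
})
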