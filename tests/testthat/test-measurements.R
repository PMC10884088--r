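# Imaging observables: strain, orifice area, voxel overlap, stent diameters.

test_that("diameter strain is the relative systolic expansion", {
  expect_equal(diameter_strain(25, 25), 0)
  expect_equal(diameter_strain(26, 25), 4.0)
  expect_equal(diameter_strain(24, 25), -4.0)
  expect_error(diameter_strain(26, 0), "d_dias")
  # a shrinking region is flagged, not rejected
  ms <- measurement_set(strain = c(annulus = -4, sinus = 2, STJ = 1))
  expect_equal(ms$nonphysiological, "annulus")
})

test_that("relative error is symmetric-free percent deviation", {
  expect_equal(relative_error(23, 23), 0)
  expect_equal(relative_error(21.85, 23), 5.0)
  expect_error(relative_error(1, 0), "nonzero")
})

test_that("spline orifice area recovers circle and ellipse areas", {
  expect_equal(orifice_area(circle_points(6, 24)), pi * 36,
               tolerance = 0.005)
  expect_equal(orifice_area(ellipse_points(7, 5, 24)), pi * 35,
               tolerance = 0.005)
  expect_error(orifice_area(circle_points(6, 24)[1:2, ]), "3 points")
  coll <- tibble::tibble(x_mm = 1:5, y_mm = 2 * (1:5), z_mm = 0)
  expect_error(orifice_area(coll), "collinear")
})

test_that("orifice area is rigid-motion invariant and scales quadratically", {
  pts <- ellipse_points(7, 5, 24)
  base <- orifice_area(pts)
  R <- rot3()
  m <- as.matrix(pts) %*% t(R)
  shift <- c(5, -2, 11)
  rotated <- tibble::tibble(x_mm = m[, 1] + shift[1],
                            y_mm = m[, 2] + shift[2],
                            z_mm = m[, 3] + shift[3])
  plane <- list(point = shift, normal = as.numeric(R %*% c(0, 0, 1)))
  expect_equal(orifice_area(rotated, plane), base, tolerance = 1e-9)
  for (s in c(0.5, 2)) {
    scaled <- dplyr::mutate(pts, x_mm = s * x_mm, y_mm = s * y_mm)
    expect_equal(orifice_area(scaled), s^2 * base, tolerance = 1e-9)
  }
})

test_that("voxelization reproduces an analytic box volume deterministically", {
  mesh <- box_mesh(c(0, 0, 0), c(20, 20, 20))
  g1 <- voxelize_surface(mesh)
  expect_lt(abs(grid_volume(g1) - 8000) / 8000, 0.02)
  g2 <- voxelize_surface(mesh)
  expect_identical(g1$values, g2$values)
  # open surface (missing face) is rejected
  open_mesh <- triangle_mesh(mesh$vertices, mesh$faces[-1, ])
  expect_error(voxelize_surface(open_mesh), "watertight")
})

test_that("voxelized cylinder volume approaches pi r^2 h", {
  mesh <- cylinder_mesh(radius = 8, height = 15, n_seg = 96)
  g <- voxelize_surface(mesh)
  expect_lt(abs(grid_volume(g) - pi * 64 * 15) / (pi * 64 * 15), 0.02)
})

test_that("Jaccard index obeys identity, disjointness and half overlap", {
  arrA <- array(FALSE, c(10, 10, 15)); arrA[, , 1:10] <- TRUE
  arrB <- array(FALSE, c(10, 10, 15)); arrB[, , 6:15] <- TRUE
  A <- occupancy_grid(arrA); B <- occupancy_grid(arrB)
  expect_equal(jaccard_index(A, A), 100)
  expect_equal(jaccard_index(A, B), 100 * 500 / 1500, tolerance = 1e-9)
  expect_equal(jaccard_index(A, B), jaccard_index(B, A))
  arrC <- array(FALSE, c(10, 10, 15)); arrC[, , 11:15] <- TRUE
  expect_equal(jaccard_index(occupancy_grid(arrA[, , 1:10, drop = FALSE]),
                             occupancy_grid(arrA[, , 1:10, drop = FALSE])),
               100)
  C <- occupancy_grid(arrC)
  arrA2 <- array(FALSE, c(10, 10, 15)); arrA2[, , 1:10] <- TRUE
  expect_equal(jaccard_index(occupancy_grid(arrA2), C), 0)
  # incomparable grids
  D <- occupancy_grid(arrA, origin = c(1, 0, 0))
  expect_error(jaccard_index(A, D), "not comparable")
  E <- occupancy_grid(array(FALSE, c(10, 10, 15)))
  expect_error(jaccard_index(E, E), "empty")
})

test_that("stent diameters recover cylinder and ellipse cross-sections", {
  cyl <- cylinder_points(diameter = 23, height = 20)
  d <- device_diameters(cyl)
  expect_equal(nrow(d), 3)
  expect_true(all(abs(d$d_max_mm - 23) < 0.1))
  expect_true(all(abs(d$d_min_mm - 23) < 0.1))
  expect_true(all(d$d_max_mm >= d$d_min_mm))
  ell <- cylinder_points(diameter = 24, height = 20, b = 22)
  de <- device_diameters(ell, levels = "mid")
  expect_equal(de$d_max_mm, 24, tolerance = 0.01)
  expect_equal(de$d_min_mm, 22, tolerance = 0.01)
  # a level outside the cloud extent has no points in its band
  expect_error(device_diameters(cyl, levels = "mid",
                                level_fractions = c(mid = 1.5)),
               "Empty band")
  expect_error(device_diameters(cyl[1:20, ]), "50")
})

test_that("measurement sets enforce strain/diameter consistency", {
  d_dias <- c(annulus = 25, sinus = 30, STJ = 27)
  d_sys <- c(annulus = 26, sinus = 30.6, STJ = 27.54)
  ms <- measurement_set(d_sys = d_sys, d_dias = d_dias)
  expect_equal(unname(ms$strain[["annulus"]]), 4.0)
  expect_equal(unname(ms$strain[["sinus"]]), 2.0)
  expect_error(
    measurement_set(d_sys = d_sys, d_dias = d_dias,
                    strain = c(annulus = 5, sinus = 2, STJ = 2)),
    "inconsistent")
  expect_error(measurement_set(), "observable")
})
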