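test_that("geometry thickness profile interpolates monotonically centre to edge", {
  g <- healthy_cornea_geometry()
  expect_equal(corneal_thickness(g, 0), g$central_thickness_um)
  expect_equal(corneal_thickness(g, g$corneal_diameter_mm / 2),
               g$peripheral_thickness_um)
  for (geom in list(healthy_cornea_geometry(), keratoconic_cornea_geometry())) {
    prof <- corneal_thickness(geom, seq(0, geom$corneal_diameter_mm / 2,
                                        length.out = 50))
    expect_true(all(diff(prof) >= 0))
  }
})

test_that("keratoconic geometry must thin centrally and thicken peripherally", {
  healthy <- healthy_cornea_geometry()
  expect_error(cornea_geometry(600, 750, 11.5, 7.8, "keratoconic",
                               reference = healthy),
               "central thickness")
  expect_error(cornea_geometry(450, 650, 11.5, 7.8, "keratoconic",
                               reference = healthy),
               "peripheral thickness")
  expect_error(cornea_geometry(550, 700, 16, 7.8), "half-diameter")
})

test_that("meshing hits the element budget and refines consistently", {
  m <- mesh_cornea(healthy_cornea_geometry(), 1024)
  expect_lte(abs(m$n_elements - 1024) / 1024, 0.1)
  expect_s3_class(m, "voct_mesh")

  coarse <- mesh_cornea(healthy_cornea_geometry(), 16)
  expect_gte(coarse$n_elements, 16 * 0.9)
  expect_error(mesh_cornea(healthy_cornea_geometry(), 8), "at least 16")

  # 4x refinement roughly quadruples the interior nodes
  fine <- mesh_cornea(healthy_cornea_geometry(), 4096)
  interior <- function(mm) {
    unname((mm$n_s - 1) * (mm$n_t - 1))
  }
  expect_equal(interior(fine) / interior(m), 4, tolerance = 0.15)

  d <- mesh_flat_disc(5, 550, 256)
  expect_lte(abs(d$n_elements - 256) / 256, 0.1)
})

test_that("static solve is linear, respects constraints, and vanishes without load", {
  mesh <- mesh_cornea(healthy_cornea_geometry(), 64)
  mat <- healthy_cornea_material()

  zero <- solve_static(mesh, mat, load_case(0))
  expect_equal(max(abs(zero$displacement)), 0)

  f1 <- solve_static(mesh, mat, load_case(2000))
  f2 <- solve_static(mesh, mat, load_case(4000))
  expect_equal(f2$displacement, 2 * f1$displacement, tolerance = 1e-9)

  soft <- solve_static(mesh, material_properties(mat$elastic_modulus_mpa / 2),
                       load_case(2000))
  expect_equal(soft$displacement, 2 * f1$displacement, tolerance = 1e-9)

  # clamped peripheral face is exactly fixed; axis is radially fixed
  expect_equal(max(abs(f1$displacement[mesh$clamped_nodes, ])), 0)
  expect_equal(max(abs(f1$displacement[mesh$axis_nodes, 1])), 0)
  expect_true(all(is.finite(f1$magnitude)))
})

test_that("solution magnitudes are invariant to the axial coordinate convention", {
  mesh <- mesh_flat_disc(5, 550, 64)
  flipped <- mesh
  flipped$nodes[, 2] <- -flipped$nodes[, 2]
  flipped$elems <- flipped$elems[, c(1, 4, 3, 2)] # restore positive winding
  a <- solve_static(mesh, healthy_cornea_material(), load_case(2000))
  b <- solve_static(flipped, healthy_cornea_material(), load_case(2000))
  expect_equal(b$magnitude, a$magnitude, tolerance = 1e-9)
  expect_equal(b$displacement[, 2], -a$displacement[, 2], tolerance = 1e-9)
})

test_that("deflection maximum sits on the corneal axis for both geometries", {
  load <- load_case(2000)
  healthy <- solve_static(mesh_cornea(healthy_cornea_geometry(), 256),
                          healthy_cornea_material(), load)
  kc <- solve_static(mesh_cornea(keratoconic_cornea_geometry(), 256),
                     keratoconic_cornea_material(), load)
  expect_equal(healthy$max_node_r_mm, 0)
  expect_equal(kc$max_node_r_mm, 0)
  expect_gt(kc$central_deflection_um, healthy$central_deflection_um)
})

test_that("deflection summary reduces to the modulus ratio on fixed geometry", {
  mesh <- mesh_cornea(healthy_cornea_geometry(), 64)
  load <- load_case(2000)
  stiff <- solve_static(mesh, material_properties(3.1), load)
  soft <- solve_static(mesh, material_properties(2.4), load)
  s_same <- deflection_summary(stiff, stiff)
  expect_equal(s_same$kc_to_healthy_ratio, 1)
  s <- deflection_summary(stiff, soft)
  expect_equal(s$kc_to_healthy_ratio, 3.1 / 2.4, tolerance = 1e-9)
})

test_that("exports produce well-formed VTK and CSV artefacts", {
  fld <- solve_static(mesh_flat_disc(5, 550, 64), healthy_cornea_material(),
                      load_case(2000))
  vtk <- tempfile(fileext = ".vtk")
  csv <- tempfile(fileext = ".csv")
  write_vtk(fld, vtk)
  lines <- readLines(vtk)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^VECTORS displacement", lines)))
  write_deflection_csv(fld, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), nrow(fld$mesh$nodes))
  expect_true(all(c("u_r_m", "u_z_m", "magnitude_m") %in% names(df)))
  unlink(c(vtk, csv))
})
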