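#' Material properties for the corneal model
#'
#' Linear isotropic elasticity. Defaults follow the corneal deformation model:
#' healthy cornea E = 3.1 MPa, keratoconic E = 2.4 MPa, Poisson's ratio 0.42,
#' density 1.038 g/cm^3 (density is carried for completeness; the static
#' solve does not use it).
#'
#' @param elastic_modulus_mpa tensile elastic modulus (MPa), > 0.
#' @param poisson_ratio dimensionless, in \[0, 0.5).
#' @param density_g_cm3 tissue density (g/cm^3).
#' @return a `material_properties` object.
#' @export
material_properties <- function(elastic_modulus_mpa,
                                poisson_ratio = 0.42,
                                density_g_cm3 = 1.038) {
  stopifnot(elastic_modulus_mpa > 0, poisson_ratio >= 0, poisson_ratio < 0.5,
            density_g_cm3 > 0)
  structure(list(elastic_modulus_mpa = elastic_modulus_mpa,
                 poisson_ratio = poisson_ratio,
                 density_g_cm3 = density_g_cm3),
            class = "material_properties")
}

#' @rdname material_properties
#' @export
healthy_cornea_material <- function() material_properties(3.1)

#' @rdname material_properties
#' @export
keratoconic_cornea_material <- function() material_properties(2.4)

#' Pressure load case
#'
#' Uniform intraocular pressure applied as a dead normal traction on the
#' posterior surface, with the peripheral face fully clamped (all displacement
#' components zero), modelling attachment to the stiff limbus. 2000 Pa is
#' about 20 mm Hg, a normal intraocular pressure.
#'
#' @param iop_pa intraocular pressure (Pa), >= 0 (zero gives the homogeneous
#'   problem).
#' @return a `load_case` object.
#' @export
load_case <- function(iop_pa = 2000) {
  stopifnot(is.numeric(iop_pa), length(iop_pa) == 1, iop_pa >= 0)
  structure(list(iop_pa = iop_pa, boundary = "clamped_peripheral_face"),
            class = "load_case")
}

# 2x2 Gauss quadrature data for the bilinear quad, in the corner order
# (-1,-1), (1,-1), (1,1), (-1,1).
quad_gauss_points <- function() {
  g <- 1 / sqrt(3)
  xi_n <- c(-1, 1, 1, -1)
  eta_n <- c(-1, -1, 1, 1)
  lapply(seq_len(4), function(k) {
    xi <- g * c(-1, 1, 1, -1)[k]
    eta <- g * c(-1, -1, 1, 1)[k]
    N <- 0.25 * (1 + xi * xi_n) * (1 + eta * eta_n)
    dNp <- cbind(0.25 * xi_n * (1 + eta * eta_n),
                 0.25 * eta_n * (1 + xi * xi_n))
    list(N = N, dNp = dNp)
  })
}

isotropic_D <- function(E, nu) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  c1 * rbind(c(1 - nu, nu, nu, 0),
             c(nu, 1 - nu, nu, 0),
             c(nu, nu, 1 - nu, 0),
             c(0, 0, 0, (1 - 2 * nu) / 2))
}

assemble_stiffness <- function(mesh, D) {
  gps <- quad_gauss_points()
  ne <- nrow(mesh$elems)
  ii <- integer(ne * 64); jj <- integer(ne * 64); vv <- numeric(ne * 64)
  pos <- 0L
  for (e in seq_len(ne)) {
    conn <- mesh$elems[e, ]
    xy <- mesh$nodes[conn, ]
    Ke <- matrix(0, 8, 8)
    for (gp in gps) {
      J <- crossprod(gp$dNp, xy)              # 2x2: d(r,z)/d(xi,eta)
      detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      Jinv <- rbind(c(J[2, 2], -J[1, 2]), c(-J[2, 1], J[1, 1])) / detJ
      dNg <- gp$dNp %*% t(Jinv)               # 4x2: dN/dr, dN/dz
      r_gp <- sum(gp$N * xy[, 1])
      B <- matrix(0, 4, 8)
      idx_r <- seq(1, 8, by = 2)
      idx_z <- seq(2, 8, by = 2)
      B[1, idx_r] <- dNg[, 1]
      B[2, idx_z] <- dNg[, 2]
      B[3, idx_r] <- gp$N / r_gp
      B[4, idx_r] <- dNg[, 2]
      B[4, idx_z] <- dNg[, 1]
      Ke <- Ke + crossprod(B, D %*% B) * (2 * pi * r_gp * detJ)
    }
    dofs <- as.vector(rbind(2 * conn - 1, 2 * conn))
    block <- pos + seq_len(64)
    ii[block] <- rep(dofs, times = 8)
    jj[block] <- rep(dofs, each = 8)
    vv[block] <- as.vector(Ke)
    pos <- pos + 64L
  }
  n_dof <- 2 * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n_dof, n_dof))
}

posterior_pressure_load <- function(mesh, p) {
  n_dof <- 2 * nrow(mesh$nodes)
  f <- numeric(n_dof)
  if (p == 0) return(f)
  g <- 1 / sqrt(3)
  post <- mesh$ids[, mesh$n_t + 1]
  inner <- mesh$ids[, max(mesh$n_t, 1)]
  for (i in seq_len(mesh$n_s)) {
    n1 <- post[i]; n2 <- post[i + 1]
    p1 <- mesh$nodes[n1, ]; p2 <- mesh$nodes[n2, ]
    tangent <- p2 - p1
    len <- sqrt(sum(tangent^2))
    nrm <- c(tangent[2], -tangent[1]) / len
    # orient the traction from the posterior surface into the solid
    ref <- (mesh$nodes[inner[i], ] + mesh$nodes[inner[i + 1], ]) / 2
    mid <- (p1 + p2) / 2
    if (sum(nrm * (ref - mid)) < 0) nrm <- -nrm
    for (xi in c(-g, g)) {
      N <- c((1 - xi) / 2, (1 + xi) / 2)
      r_gp <- N[1] * p1[1] + N[2] * p2[1]
      w <- p * 2 * pi * r_gp * (len / 2)
      f[2 * n1 - 1] <- f[2 * n1 - 1] + N[1] * w * nrm[1]
      f[2 * n1]     <- f[2 * n1]     + N[1] * w * nrm[2]
      f[2 * n2 - 1] <- f[2 * n2 - 1] + N[2] * w * nrm[1]
      f[2 * n2]     <- f[2 * n2]     + N[2] * w * nrm[2]
    }
  }
  f
}

#' Solve the static axisymmetric elasticity problem
#'
#' Small-strain linear isotropic elasticity on the meridian cross-section
#' (axisymmetric formulation, bilinear quadrilaterals, 2x2 Gauss quadrature).
#' The intraocular pressure is applied as a dead normal traction on the
#' posterior surface of the undeformed mesh; all displacement components are
#' fixed on the clamped peripheral face, and the radial component on the
#' symmetry axis. The symmetric positive-definite system is solved by sparse
#' Cholesky factorisation and the relative residual is verified below 1e-10.
#'
#' @param mesh a `voct_mesh` from [mesh_cornea()] or [mesh_flat_disc()].
#' @param material a [material_properties()].
#' @param load a [load_case()].
#' @return a `deflection_field`: nodal displacement matrix (metres, columns
#'   u_r and u_z), per-node deflection magnitude, the central deflection
#'   (largest magnitude over the axis nodes), the anterior apex-node
#'   deflection (`apex_deflection_um`, the observable compared against the
#'   plate closed form), and the location of the maximum, in micrometres at
#'   the interface.
#' @export
solve_static <- function(mesh, material, load) {
  stopifnot(inherits(mesh, "voct_mesh"), inherits(material, "material_properties"),
            inherits(load, "load_case"))
  D <- isotropic_D(material$elastic_modulus_mpa * 1e6, material$poisson_ratio)
  K <- assemble_stiffness(mesh, D)
  f <- posterior_pressure_load(mesh, load$iop_pa)
  n_dof <- 2 * nrow(mesh$nodes)
  fixed <- sort(unique(c(2 * mesh$clamped_nodes - 1, 2 * mesh$clamped_nodes,
                         2 * mesh$axis_nodes - 1)))
  if (length(fixed) == 0) {
    stop("singular system: no displacement constraints", call. = FALSE)
  }
  free <- setdiff(seq_len(n_dof), fixed)
  u <- numeric(n_dof)
  if (any(f[free] != 0)) {
    Kff <- K[free, free, drop = FALSE]
    sol <- tryCatch(Matrix::solve(Kff, f[free]),
                    error = function(e) stop("singular system: ", conditionMessage(e),
                                             call. = FALSE))
    u[free] <- as.numeric(sol)
    res <- sqrt(sum((as.numeric(Kff %*% u[free]) - f[free])^2)) /
      sqrt(sum(f[free]^2))
    if (res > 1e-10) {
      stop(sprintf("solver residual %.2e exceeds tolerance 1e-10", res),
           call. = FALSE)
    }
  }
  disp <- cbind(u_r = u[seq(1, n_dof, by = 2)], u_z = u[seq(2, n_dof, by = 2)])
  mag <- sqrt(rowSums(disp^2))
  max_node <- which.max(mag)
  # central deflection: largest magnitude over the axis (r = 0) nodes
  central_um <- max(mag[mesh$axis_nodes]) * 1e6
  structure(
    list(mesh = mesh, displacement = disp, magnitude = mag,
         central_deflection_um = central_um,
         apex_deflection_um = mag[mesh$apex_node] * 1e6,
         max_deflection_um = mag[max_node] * 1e6,
         max_node = max_node,
         max_node_r_mm = mesh$nodes[max_node, 1] * 1e3,
         material = material, load = load),
    class = "deflection_field")
}

#' @export
print.deflection_field <- function(x, ...) {
  cat(sprintf(paste0("<deflection_field> %d nodes; central deflection %.3f um; ",
                     "max %.3f um at r = %.3f mm\n"),
              nrow(x$displacement), x$central_deflection_um,
              x$max_deflection_um, x$max_node_r_mm))
  invisible(x)
}

#' Clamped circular plate closed form
#'
#' Kirchhoff thin-plate central deflection of a clamped uniform circular plate
#' under uniform pressure: w = p a^4 / (64 D), D = E h^3 / (12 (1 - nu^2)).
#' Serves as the independent verification oracle for the elasticity solver on
#' a flat uniform disc.
#'
#' @param radius_mm plate radius a (millimetres).
#' @param thickness_um plate thickness h (micrometres).
#' @param elastic_modulus_mpa E (MPa).
#' @param poisson_ratio nu.
#' @param pressure_pa p (Pa).
#' @return central deflection (micrometres).
#' @export
clamped_plate_reference <- function(radius_mm, thickness_um,
                                    elastic_modulus_mpa, poisson_ratio,
                                    pressure_pa) {
  a <- radius_mm * 1e-3
  h <- thickness_um * 1e-6
  E <- elastic_modulus_mpa * 1e6
  D <- E * h^3 / (12 * (1 - poisson_ratio^2))
  (pressure_pa * a^4 / (64 * D)) * 1e6
}

#' Healthy vs keratoconic deflection summary
#'
#' @param healthy_field,kc_field `deflection_field`s solved on comparable
#'   geometries.
#' @return list with the central deflections (micrometres), their KC/healthy
#'   ratio, and the radial location of each field's deflection maximum.
#' @export
deflection_summary <- function(healthy_field, kc_field) {
  stopifnot(inherits(healthy_field, "deflection_field"),
            inherits(kc_field, "deflection_field"))
  if (healthy_field$central_deflection_um == 0) {
    stop("healthy central deflection is zero; ratio undefined", call. = FALSE)
  }
  list(healthy_central_deflection_um = healthy_field$central_deflection_um,
       kc_central_deflection_um = kc_field$central_deflection_um,
       kc_to_healthy_ratio = kc_field$central_deflection_um /
         healthy_field$central_deflection_um,
       healthy_max_r_mm = healthy_field$max_node_r_mm,
       kc_max_r_mm = kc_field$max_node_r_mm)
}

#' Run the paired healthy/keratoconic corneal deflection cases
#'
#' Convenience driver: meshes both geometries, solves both static cases under
#' the same load, and summarises the central deflections.
#'
#' @param healthy_geometry,kc_geometry [cornea_geometry()] objects.
#' @param healthy_material,kc_material [material_properties()] objects.
#' @param load a [load_case()].
#' @param n_elements target mesh size per model.
#' @return list with both `deflection_field`s and the [deflection_summary()].
#' @export
cornea_deflection_comparison <- function(healthy_geometry = healthy_cornea_geometry(),
                                         kc_geometry = keratoconic_cornea_geometry(),
                                         healthy_material = healthy_cornea_material(),
                                         kc_material = keratoconic_cornea_material(),
                                         load = load_case(2000),
                                         n_elements = 1024) {
  healthy <- solve_static(mesh_cornea(healthy_geometry, n_elements),
                          healthy_material, load)
  kc <- solve_static(mesh_cornea(kc_geometry, n_elements), kc_material, load)
  list(healthy = healthy, kc = kc,
       summary = deflection_summary(healthy, kc))
}

#' Export a deflection field
#'
#' `write_vtk()` writes a legacy ASCII VTK unstructured grid (quad cells,
#' point-data displacement vector and magnitude); `write_deflection_csv()`
#' writes one row per node.
#'
#' @param field a `deflection_field`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vtk <- function(field, path) {
  stopifnot(inherits(field, "deflection_field"))
  mesh <- field$mesh
  n <- nrow(mesh$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "corneavoct deflection field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9e %.9e 0.0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  ne <- nrow(mesh$elems)
  writeLines(sprintf("CELLS %d %d", ne, ne * 5), con)
  writeLines(sprintf("4 %d %d %d %d",
                     mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                     mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("VECTORS displacement double", con)
  writeLines(sprintf("%.9e %.9e 0.0",
                     field$displacement[, 1], field$displacement[, 2]), con)
  writeLines(c("SCALARS magnitude double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9e", field$magnitude), con)
  invisible(path)
}

#' @rdname write_vtk
#' @export
write_deflection_csv <- function(field, path) {
  stopifnot(inherits(field, "deflection_field"))
  df <- data.frame(node = seq_len(nrow(field$mesh$nodes)),
                   r_m = field$mesh$nodes[, 1],
                   z_m = field$mesh$nodes[, 2],
                   u_r_m = field$displacement[, 1],
                   u_z_m = field$displacement[, 2],
                   magnitude_m = field$magnitude)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
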