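#' Corneal geometry for the deformation model
#'
#' The cornea is idealised as an axisymmetric meniscus-shaped cap: the
#' anterior surface is a sphere of radius `anterior_radius_mm`, the cap spans
#' `corneal_diameter_mm`, and the thickness (measured radially toward the
#' sphere centre) interpolates linearly in polar angle from
#' `central_thickness_um` at the apex to `peripheral_thickness_um` at the rim.
#' In keratoconus the centre thins while the periphery thickens, so a
#' keratoconic geometry must have a smaller central and no smaller peripheral
#' thickness than the healthy reference it is compared against.
#'
#' The default dimensions shipped by [healthy_cornea_geometry()] and
#' [keratoconic_cornea_geometry()] are synthetic stand-in values typical of
#' clinical pachymetry (healthy 550/700 um, KC 450/750 um, 11.5 mm diameter,
#' 7.8 mm anterior radius), not measurements of any specific eye.
#'
#' @param central_thickness_um apex thickness (micrometres).
#' @param peripheral_thickness_um rim thickness (micrometres).
#' @param corneal_diameter_mm cap diameter (millimetres).
#' @param anterior_radius_mm anterior radius of curvature (millimetres).
#' @param condition `"healthy"` or `"keratoconic"`.
#' @param reference optional healthy `cornea_geometry` against which a
#'   keratoconic geometry is validated.
#' @return a `cornea_geometry` object.
#' @export
cornea_geometry <- function(central_thickness_um, peripheral_thickness_um,
                            corneal_diameter_mm, anterior_radius_mm,
                            condition = c("healthy", "keratoconic"),
                            reference = NULL) {
  condition <- match.arg(condition)
  stopifnot(central_thickness_um > 0, peripheral_thickness_um > 0,
            corneal_diameter_mm > 0, anterior_radius_mm > 0)
  if (corneal_diameter_mm / 2 >= anterior_radius_mm) {
    stop("cap half-diameter must be smaller than the anterior radius", call. = FALSE)
  }
  if (central_thickness_um * 1e-3 >= anterior_radius_mm) {
    stop("thickness exceeds the anterior radius: degenerate geometry", call. = FALSE)
  }
  geom <- structure(
    list(central_thickness_um = central_thickness_um,
         peripheral_thickness_um = peripheral_thickness_um,
         corneal_diameter_mm = corneal_diameter_mm,
         anterior_radius_mm = anterior_radius_mm,
         condition = condition),
    class = "cornea_geometry")
  if (condition == "keratoconic" && !is.null(reference)) {
    if (central_thickness_um >= reference$central_thickness_um) {
      stop("keratoconic central thickness must be below the healthy reference",
           call. = FALSE)
    }
    if (peripheral_thickness_um < reference$peripheral_thickness_um) {
      stop("keratoconic peripheral thickness must be at least the healthy reference",
           call. = FALSE)
    }
  }
  geom
}

#' @rdname cornea_geometry
#' @export
healthy_cornea_geometry <- function() {
  cornea_geometry(550, 700, 11.5, 7.8, condition = "healthy")
}

#' @rdname cornea_geometry
#' @export
keratoconic_cornea_geometry <- function() {
  cornea_geometry(450, 750, 11.5, 7.8, condition = "keratoconic",
                  reference = healthy_cornea_geometry())
}

# Maximum polar angle of the cap (radians) measured from the axis at the
# anterior sphere centre.
cap_angle <- function(geom) {
  asin((geom$corneal_diameter_mm / 2) / geom$anterior_radius_mm)
}

#' Corneal thickness profile
#'
#' Thickness at a radial position, interpolating quadratically in polar angle
#' between the central and peripheral values. The quadratic form has zero
#' thickness gradient on the axis, so the meniscus is smooth at the apex (a
#' linear-in-angle profile would put a conical cusp there); it is monotone
#' from centre to edge.
#'
#' @param geom a [cornea_geometry()].
#' @param r_mm radial distance from the corneal axis (millimetres), vectorized.
#' @return thickness in micrometres.
#' @export
corneal_thickness <- function(geom, r_mm) {
  stopifnot(inherits(geom, "cornea_geometry"))
  if (any(r_mm < 0 | r_mm > geom$corneal_diameter_mm / 2 + 1e-9)) {
    stop("radial position outside the cap", call. = FALSE)
  }
  phi <- asin(pmin(r_mm / geom$anterior_radius_mm, 1))
  frac <- phi / cap_angle(geom)
  geom$central_thickness_um +
    (geom$peripheral_thickness_um - geom$central_thickness_um) * frac^2
}

structured_mesh <- function(node_fun, n_s, n_t) {
  # node_fun(i, j) -> c(r, z) in metres for i in 0..n_s (meridian),
  # j in 0..n_t (anterior -> posterior)
  ids <- matrix(0L, n_s + 1, n_t + 1)
  nodes <- matrix(0, (n_s + 1) * (n_t + 1), 2)
  k <- 0L
  for (i in 0:n_s) {
    for (j in 0:n_t) {
      k <- k + 1L
      ids[i + 1, j + 1] <- k
      nodes[k, ] <- node_fun(i, j)
    }
  }
  elems <- matrix(0L, n_s * n_t, 4)
  e <- 0L
  for (i in seq_len(n_s)) {
    for (j in seq_len(n_t)) {
      e <- e + 1L
      elems[e, ] <- c(ids[i, j], ids[i + 1, j], ids[i + 1, j + 1], ids[i, j + 1])
    }
  }
  list(ids = ids, nodes = nodes, elems = elems)
}

element_jacobians <- function(nodes, elems) {
  # detJ at the element centre; sign detects winding
  vapply(seq_len(nrow(elems)), function(e) {
    xy <- nodes[elems[e, ], ]
    dN_dxi <- c(-0.25, 0.25, 0.25, -0.25)
    dN_deta <- c(-0.25, -0.25, 0.25, 0.25)
    J <- rbind(c(sum(dN_dxi * xy[, 1]), sum(dN_dxi * xy[, 2])),
               c(sum(dN_deta * xy[, 1]), sum(dN_deta * xy[, 2])))
    J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  }, numeric(1))
}

finalize_mesh <- function(sm, n_s, n_t, target) {
  detJ <- element_jacobians(sm$nodes, sm$elems)
  if (all(detJ < 0)) {
    sm$elems <- sm$elems[, c(1, 4, 3, 2)]
    detJ <- -detJ
  }
  if (any(detJ <= 0)) {
    stop("mesh generation failed: non-positive element Jacobian (degenerate geometry?)",
         call. = FALSE)
  }
  ids <- sm$ids
  structure(
    list(nodes = sm$nodes, elems = sm$elems, ids = ids,
         n_s = n_s, n_t = n_t, n_elements = nrow(sm$elems),
         target_elements = target,
         anterior_nodes = ids[, 1],
         posterior_nodes = ids[, n_t + 1],
         axis_nodes = ids[1, ],
         clamped_nodes = ids[n_s + 1, ],
         apex_node = ids[1, 1]),
    class = "voct_mesh")
}

mesh_dims <- function(n_elements, aspect = 16) {
  n_t <- max(1L, round(sqrt(n_elements / aspect)))
  n_s <- max(4L, round(n_elements / n_t))
  c(n_s = n_s, n_t = n_t)
}

#' Mesh the corneal meridian cross-section
#'
#' Builds a structured axisymmetric quadrilateral mesh of the meridian:
#' `n_t` element layers through the thickness times `n_s` along the meridian,
#' chosen so the total is within 10% of `n_elements` (1024 by default,
#' 8 x 128). Element Jacobians are checked positive.
#'
#' @param geom a [cornea_geometry()].
#' @param n_elements target element count (>= 16).
#' @return a `voct_mesh`: node coordinates (metres, columns r and z), element
#'   connectivity, and index sets for the anterior/posterior surfaces, the
#'   symmetry axis, the clamped peripheral face, and the anterior apex node.
#' @export
mesh_cornea <- function(geom, n_elements = 1024) {
  stopifnot(inherits(geom, "cornea_geometry"))
  if (n_elements < 16) stop("n_elements must be at least 16", call. = FALSE)
  nd <- mesh_dims(n_elements)
  n_s <- nd["n_s"]; n_t <- nd["n_t"]
  Ra <- geom$anterior_radius_mm * 1e-3
  phi_max <- cap_angle(geom)
  tc <- geom$central_thickness_um * 1e-6
  tp <- geom$peripheral_thickness_um * 1e-6
  node_fun <- function(i, j) {
    phi <- phi_max * i / n_s
    th <- tc + (tp - tc) * (i / n_s)^2
    rho <- Ra - th * (j / n_t)
    c(rho * sin(phi), rho * cos(phi))
  }
  finalize_mesh(structured_mesh(node_fun, n_s, n_t), n_s, n_t, n_elements)
}

#' Mesh a flat uniform-thickness disc
#'
#' Axisymmetric mesh of a flat circular plate of radius `radius_mm` and
#' thickness `thickness_um`, used to verify the elasticity solver against the
#' clamped-plate closed form ([clamped_plate_reference()]). The posterior
#' (loaded) face is the lower surface.
#'
#' @param radius_mm plate radius (millimetres).
#' @param thickness_um plate thickness (micrometres).
#' @param n_elements target element count.
#' @return a `voct_mesh`.
#' @export
mesh_flat_disc <- function(radius_mm, thickness_um, n_elements = 1024) {
  stopifnot(radius_mm > 0, thickness_um > 0)
  if (n_elements < 16) stop("n_elements must be at least 16", call. = FALSE)
  nd <- mesh_dims(n_elements)
  n_s <- nd["n_s"]; n_t <- nd["n_t"]
  a <- radius_mm * 1e-3
  h <- thickness_um * 1e-6
  node_fun <- function(i, j) c(a * i / n_s, h * (1 - j / n_t))
  finalize_mesh(structured_mesh(node_fun, n_s, n_t), n_s, n_t, n_elements)
}

#' @export
print.voct_mesh <- function(x, ...) {
  cat(sprintf("<voct_mesh> %d elements (%d meridian x %d thickness), %d nodes\n",
              x$n_elements, x$n_s, x$n_t, nrow(x$nodes)))
  invisible(x)
}
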