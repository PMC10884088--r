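#' Aortic root geometry
#'
#' Holds the per-region diastolic diameters (annulus, sinus, sinotubular
#' junction), wall and leaflet thicknesses, the closed (diastolic) leaflet
#' free-edge point set, the valve plane and the maximal orifice radius the
#' free edge can reach when fully open. Diameters and coordinates are in
#' millimetres. Thickness defaults follow the usual uniform-thickness
#' assumption for CT-based models: 2 mm wall, 0.5 mm leaflets.
#'
#' @param diameters Named numeric: diastolic diameters (mm) for `annulus`,
#'   `sinus`, `STJ`; all > 0.
#' @param wall_thickness Wall thickness in mm (default 2).
#' @param leaflet_thickness Leaflet thickness in mm (default 0.5).
#' @param free_edge_points Tibble/data frame with columns `x_mm`, `y_mm`,
#'   `z_mm`: ordered closed-configuration leaflet free-edge points (>= 8).
#' @param max_orifice_radius Radius (mm) of the maximal-orifice circle in
#'   the valve plane.
#' @param valve_plane List with `point` (length-3) and `normal` (length-3,
#'   unit norm).
#' @return An object of class `root_geometry`.
#' @export
root_geometry <- function(diameters,
                          wall_thickness = 2,
                          leaflet_thickness = 0.5,
                          free_edge_points,
                          max_orifice_radius,
                          valve_plane = list(point = c(0, 0, 0),
                                             normal = c(0, 0, 1))) {
  regions <- c("annulus", "sinus", "STJ")
  if (!all(regions %in% names(diameters))) {
    abort("`diameters` must name annulus, sinus and STJ.")
  }
  diameters <- unlist(diameters)[regions]
  if (any(diameters <= 0)) abort("All diameters must be > 0.")
  if (wall_thickness <= 0 || leaflet_thickness <= 0) {
    abort("Thicknesses must be > 0.")
  }
  fe <- tibble::as_tibble(free_edge_points)
  if (!all(c("x_mm", "y_mm", "z_mm") %in% names(fe))) {
    abort("`free_edge_points` needs columns x_mm, y_mm, z_mm.")
  }
  if (nrow(fe) < 8) abort("At least 8 free-edge points are required.")
  n <- valve_plane$normal
  if (abs(sqrt(sum(n^2)) - 1) > 1e-9) {
    abort("Valve-plane normal must have unit norm.")
  }
  stopifnot_scalar_num(max_orifice_radius, "max_orifice_radius",
                       positive = TRUE)
  structure(list(
    diameters = diameters,
    wall_thickness = wall_thickness,
    leaflet_thickness = leaflet_thickness,
    free_edge_points = fe,
    max_orifice_radius = max_orifice_radius,
    valve_plane = list(point = as.numeric(valve_plane$point),
                       normal = as.numeric(n))
  ), class = "root_geometry")
}

#' @export
print.root_geometry <- function(x, ...) {
  cat("<root_geometry>\n")
  cat(sprintf("  diameters (mm): annulus %.1f, sinus %.1f, STJ %.1f\n",
              x$diameters[["annulus"]], x$diameters[["sinus"]],
              x$diameters[["STJ"]]))
  cat(sprintf("  wall %.1f mm, leaflet %.2f mm, %d free-edge points\n",
              x$wall_thickness, x$leaflet_thickness,
              nrow(x$free_edge_points)))
  invisible(x)
}

#' Default (template) aortic root geometry
#'
#' A representative geometry for a 23-mm-device recipient: annulus 23 mm,
#' sinus 30 mm, STJ 27 mm, a 12-point stenotic free edge with three-fold
#' (tri-leaflet) radial modulation around a 4 mm mean radius, and a
#' maximal-orifice circle at 85% of the annulus radius. Used as the
#' template the virtual-patient generator perturbs and as the anchor for
#' the leaflet-opening constant.
#'
#' @param annulus,sinus,stj Diastolic diameters in mm.
#' @param free_edge_radius Mean radius (mm) of the closed free edge.
#' @param n_points Number of free-edge points.
#' @return A [root_geometry].
#' @export
default_root_geometry <- function(annulus = 23, sinus = 30, stj = 27,
                                  free_edge_radius = 4, n_points = 12) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- free_edge_radius * (1 + 0.25 * sin(3 * th))
  root_geometry(
    diameters = c(annulus = annulus, sinus = sinus, STJ = stj),
    free_edge_points = tibble::tibble(
      x_mm = r * cos(th), y_mm = r * sin(th), z_mm = 0
    ),
    max_orifice_radius = 0.85 * annulus / 2
  )
}

#' Rigidly translate a geometry
#'
#' Shifts the free-edge points and valve-plane point by `offset`; all
#' observables derived from a geometry are invariant under this map.
#'
#' @param geom A [root_geometry].
#' @param offset Length-3 numeric, mm.
#' @return Translated [root_geometry].
#' @export
translate_geometry <- function(geom, offset) {
  offset <- as.numeric(offset)
  geom$free_edge_points <- dplyr::mutate(
    geom$free_edge_points,
    x_mm = .data$x_mm + offset[1],
    y_mm = .data$y_mm + offset[2],
    z_mm = .data$z_mm + offset[3]
  )
  geom$valve_plane$point <- geom$valve_plane$point + offset
  geom
}

# --- triangle meshes -------------------------------------------------------

#' Triangle surface mesh
#'
#' Minimal indexed triangle mesh: `vertices` is an n x 3 matrix (mm) and
#' `faces` an m x 3 integer matrix of 1-based vertex indices.
#'
#' @param vertices Numeric matrix, n x 3.
#' @param faces Integer matrix, m x 3.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) abort("`vertices` must be n x 3.")
  if (nrow(faces) < 1) abort("Mesh has no faces.")
  if (max(faces) > nrow(vertices) || min(faces) < 1) {
    abort("Face indices out of range.")
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# every edge must be shared by exactly two faces
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Axis-aligned box mesh
#'
#' @param lo,hi Length-3 corners in mm.
#' @return A watertight [triangle_mesh] with 12 faces.
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(20, 20, 20)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corners: 1:(000) 2:(100) 3:(010) 4:(110) 5:(001) 6:(101) 7:(011) 8:(111)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo
    c(5, 6, 8), c(5, 8, 7),   # z = hi
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(3, 7, 8), c(3, 8, 4),   # y = hi
    c(1, 5, 7), c(1, 7, 3),   # x = lo
    c(2, 4, 8), c(2, 8, 6)    # x = hi
  )
  triangle_mesh(v, f)
}

#' Closed cylinder mesh along z
#'
#' @param radius Radius in mm.
#' @param height Height in mm (base at z = 0).
#' @param n_seg Circumferential segments.
#' @param center xy-centre, length-2.
#' @return A watertight [triangle_mesh].
#' @export
cylinder_mesh <- function(radius, height, n_seg = 48, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring0 <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), 0)
  ring1 <- cbind(ring0[, 1], ring0[, 2], height)
  v <- rbind(ring0, ring1,
             c(center[1], center[2], 0), c(center[1], center[2], height))
  cb <- 2 * n_seg + 1  # bottom centre
  ct <- 2 * n_seg + 2  # top centre
  idx <- function(i) (i - 1) %% n_seg + 1
  f <- NULL
  for (i in seq_len(n_seg)) {
    j <- idx(i + 1)
    f <- rbind(f,
               c(i, j, n_seg + j), c(i, n_seg + j, n_seg + i), # side quads
               c(cb, j, i),                                    # bottom cap
               c(ct, n_seg + i, n_seg + j))                    # top cap
  }
  triangle_mesh(v, f)
}

# --- plane projection helpers ---------------------------------------------

# orthonormal in-plane basis (u, v) for a unit normal
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v, n = n)
}

# project 3-D points (matrix n x 3) to 2-D plane coordinates
project_to_plane <- function(pts, plane) {
  b <- plane_basis(plane$normal)
  rel <- sweep(as.matrix(pts), 2, as.numeric(plane$point))
  cbind(rel %*% b$u, rel %*% b$v)
}
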