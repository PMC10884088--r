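# shared fixtures, all built in code

circle_points <- function(r = 6, n = 24, z = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x_mm = r * cos(th), y_mm = r * sin(th), z_mm = z)
}

ellipse_points <- function(a = 7, b = 5, n = 24, z = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x_mm = a * cos(th), y_mm = b * sin(th), z_mm = z)
}

test_hemo <- function(p_sys = 129, p_dias = 61, hr = 71, grad = 40) {
  hemodynamic_record(p_sys, p_dias, hr, peak_gradient = grad)
}

# a hemodynamic record with equal phases (bypasses the constructor guard,
# used only to probe the zero-load limit)
degenerate_hemo <- function(p = 100, hr = 70) {
  structure(list(p_sys = p, p_dias = p, hr = hr, peak_gradient = 0,
                 co = NA_real_), class = "hemodynamic_record")
}

# cylinder-surface point cloud along z (deterministic rings)
cylinder_points <- function(diameter = 23, height = 20, n_ring = 60,
                            n_levels = 41, b = diameter) {
  th <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  zs <- seq(0, height, length.out = n_levels)
  purrr::map_dfr(zs, function(z) {
    tibble::tibble(x_mm = diameter / 2 * cos(th),
                   y_mm = b / 2 * sin(th), z_mm = z)
  })
}

# rotation matrix about a fixed axis/angle
rot3 <- function(axis = c(1, 2, 2) / 3, angle = 0.7) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
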