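#' Read and write ASCII STL surface meshes
#'
#' Minimal ASCII STL support for exchanging segmented surfaces. Vertices
#' are welded exactly (identical coordinate triplets share an index) on
#' read, so a watertight surface stays watertight through a round-trip.
#'
#' @param path File path.
#' @return `read_stl()`: a [triangle_mesh]. `write_stl()`: `path`,
#'   invisibly.
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0) {
    abort("Not a valid ASCII STL (vertex count not a multiple of 3).")
  }
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  key <- apply(xyz, 1, function(r) paste(format(r, digits = 17),
                                         collapse = ","))
  uk <- unique(key)
  idx <- match(key, uk)
  verts <- xyz[match(uk, key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' @rdname read_stl
#' @param mesh A [triangle_mesh].
#' @param name Solid name written to the header.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
    e1 <- b - a; e2 <- cc - a
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
      sprintf("      vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
      sprintf("      vertex %.17g %.17g %.17g", cc[1], cc[2], cc[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read and write occupancy grids as ASCII NRRD
#'
#' Text-encoded NRRD with the grid origin in `space origin` and spacing in
#' `spacings`; values are written 0/1.
#'
#' @param path File path.
#' @return `read_nrrd()`: an [occupancy_grid]. `write_nrrd()`: `path`,
#'   invisibly.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- which(lines == "")[1]
  if (is.na(blank)) abort("Malformed NRRD: missing header terminator.")
  hdr <- lines[seq_len(blank - 1)]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(ln)) abort(sprintf("Malformed NRRD: missing '%s'.", key))
    trimws(sub(paste0("^", key, ":\\s*"), "", ln[1]))
  }
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  spacings <- as.numeric(strsplit(get_field("spacings"), "\\s+")[[1]])
  org <- gsub("[()]", "", get_field("space origin"))
  origin <- as.numeric(strsplit(org, ",")[[1]])
  vals <- as.integer(strsplit(paste(lines[-seq_len(blank)], collapse = " "),
                              "\\s+")[[1]])
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sizes)) abort("Malformed NRRD: value count.")
  occupancy_grid(array(vals, dim = sizes), origin = origin,
                 spacing = spacings)
}

#' @rdname read_nrrd
#' @param grid An [occupancy_grid].
#' @export
write_nrrd <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(grid$values), collapse = " ")),
    sprintf("spacings: %s", paste(format(grid$spacing, digits = 15),
                                  collapse = " ")),
    "encoding: ascii",
    sprintf("space origin: (%s)", paste(format(grid$origin, digits = 15),
                                        collapse = ",")),
    ""), con)
  vals <- as.integer(grid$values)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read and write free-edge / point-cloud CSV files
#'
#' Comma-separated, dot-decimal, UTF-8 with the mandatory header
#' `x_mm,y_mm,z_mm`; points are ordered. Malformed rows are reported with
#' their line number.
#'
#' @param path File path.
#' @return `read_points_csv()`: tibble with `x_mm`, `y_mm`, `z_mm`.
#' @export
read_points_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d))) {
    abort(sprintf("'%s': header must contain x_mm,y_mm,z_mm.", path))
  }
  for (cn in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[cn]]))))
    if (length(bad)) {
      abort(sprintf("'%s': non-numeric value in column %s at data line %d.",
                    path, cn, bad[1]))
    }
    d[[cn]] <- as.numeric(d[[cn]])
  }
  tibble::as_tibble(d[need])
}

#' @rdname read_points_csv
#' @param points Data frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @export
write_points_csv <- function(points, path) {
  d <- as.data.frame(points)[, c("x_mm", "y_mm", "z_mm")]
  d[] <- lapply(d, function(x) format(x, digits = 12, trim = TRUE))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write patient records as JSON
#'
#' A patient record bundles the hemodynamics and the measurement set; the
#' geometry file carries regional diameters, thicknesses, the free-edge
#' points and the valve plane. Numbers are written at 12 significant
#' digits and round-trip exactly at that precision.
#'
#' @param path File path.
#' @return `read_patient_json()`: list with `hemo`
#'   ([hemodynamic_record]) and `measurements` ([measurement_set]).
#' @export
read_patient_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$hemo)) abort(sprintf("'%s': missing 'hemo' block.", path))
  hemo <- hemodynamic_record(j$hemo$p_sys, j$hemo$p_dias, j$hemo$hr,
                             peak_gradient = j$hemo$peak_gradient %||% 0,
                             co = j$hemo$co %||% NA_real_)
  m <- j$measurements
  if (is.null(m)) abort(sprintf("'%s': missing 'measurements'.", path))
  meas <- measurement_set(
    d_sys = if (!is.null(m$d_sys)) unlist(m$d_sys),
    d_dias = if (!is.null(m$d_dias)) unlist(m$d_dias),
    strain = if (!is.null(m$strain)) unlist(m$strain),
    orifice_area = m$orifice_area
  )
  list(hemo = hemo, measurements = meas)
}

#' @rdname read_patient_json
#' @param hemo A [hemodynamic_record].
#' @param measurements A [measurement_set].
#' @export
write_patient_json <- function(hemo, measurements, path) {
  payload <- list(
    hemo = list(p_sys = hemo$p_sys, p_dias = hemo$p_dias, hr = hemo$hr,
                peak_gradient = hemo$peak_gradient, co = hemo$co),
    measurements = list(
      d_sys = as.list(measurements$d_sys),
      d_dias = as.list(measurements$d_dias),
      strain = as.list(measurements$strain),
      orifice_area = measurements$orifice_area
    )
  )
  payload$measurements <-
    payload$measurements[!vapply(payload$measurements,
                                 function(x) is.null(x) || !length(x),
                                 logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read and write root geometry as JSON
#'
#' @param path File path.
#' @return `read_geometry_json()`: a [root_geometry].
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  root_geometry(
    diameters = unlist(j$diameters),
    wall_thickness = j$wall_thickness %||% 2,
    leaflet_thickness = j$leaflet_thickness %||% 0.5,
    free_edge_points = tibble::as_tibble(j$free_edge_points),
    max_orifice_radius = j$max_orifice_radius,
    valve_plane = list(point = j$valve_plane$point,
                       normal = j$valve_plane$normal)
  )
}

#' @rdname read_geometry_json
#' @param geom A [root_geometry].
#' @export
write_geometry_json <- function(geom, path) {
  jsonlite::write_json(list(
    diameters = as.list(geom$diameters),
    wall_thickness = geom$wall_thickness,
    leaflet_thickness = geom$leaflet_thickness,
    free_edge_points = geom$free_edge_points,
    max_orifice_radius = geom$max_orifice_radius,
    valve_plane = geom$valve_plane
  ), path, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(path)
}

#' Run configuration: read, write, hash
#'
#' The run configuration mirrors the identification protocol defaults (15
#' design samples over 0.8-15 MPa, CT voxel spacing 0.488 x 0.488 x 0.625
#' mm) plus the seed and noise parameters. `config_hash()` is a stable
#' polynomial hash of the canonical YAML serialisation, embedded in every
#' output for provenance.
#'
#' @param seed Integer seed.
#' @param n_samples Design budget.
#' @param E_range Modulus range, MPa.
#' @param regions Wall regions.
#' @param voxel_spacing CT-like spacing, mm.
#' @param noise List of noise parameters.
#' @return `run_config()`: a list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_samples = 15, E_range = c(0.8, 15),
                       regions = c("annulus", "sinus", "STJ"),
                       voxel_spacing = c(0.488, 0.488, 0.625),
                       noise = list(diameter_sd_mm = 0.244,
                                    area_rel = 0.03)) {
  if (n_samples < 3) abort("n_samples must be >= 3.")
  if (E_range[1] >= E_range[2]) abort("E_range must be increasing.")
  if (any(voxel_spacing <= 0)) abort("voxel_spacing must be positive.")
  structure(list(seed = seed, n_samples = n_samples,
                 E_range = as.numeric(E_range), regions = regions,
                 voxel_spacing = as.numeric(voxel_spacing), noise = noise),
            class = "run_config")
}

#' @rdname run_config
#' @param path File path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(seed = y$seed %||% 1,
             n_samples = y$n_samples %||% 15,
             E_range = unlist(y$E_range) %||% c(0.8, 15),
             regions = unlist(y$regions) %||% c("annulus", "sinus", "STJ"),
             voxel_spacing = unlist(y$voxel_spacing) %||%
               c(0.488, 0.488, 0.625),
             noise = y$noise %||% list(diameter_sd_mm = 0.244,
                                       area_rel = 0.03))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config), precision = 15)
  bytes <- utf8ToInt(s)
  # 31-bit polynomial rolling hash; stable across platforms
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write and read a virtual cohort as JSON-lines
#'
#' One patient per line: seed, ground truths, hemodynamics, geometry
#' summary and the noisy observables. Rewriting the same cohort yields a
#' byte-identical file.
#'
#' @param cohort List of `virtual_patient`s.
#' @param path File path.
#' @return `write_cohort_jsonl()`: `path` invisibly;
#'   `read_cohort_jsonl()`: tibble of records.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  lines <- vapply(cohort, function(p) {
    jsonlite::toJSON(list(
      seed = p$seed, E_wall = p$E_wall, E_leaflet = p$E_leaflet,
      calcification_factor = p$calcification_factor,
      hemo = list(p_sys = p$hemo$p_sys, p_dias = p$hemo$p_dias,
                  hr = p$hemo$hr, peak_gradient = p$hemo$peak_gradient),
      diameters = as.list(p$geometry$diameters),
      strain_noisy = as.list(p$measurements_noisy$strain),
      orifice_area_noisy = p$measurements_noisy$orifice_area
    ), auto_unbox = TRUE, digits = 12)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  purrr::map_dfr(lines, function(ln) {
    j <- jsonlite::fromJSON(ln)
    tibble::tibble(
      seed = j$seed, E_wall = j$E_wall, E_leaflet = j$E_leaflet,
      calcification_factor = j$calcification_factor,
      p_sys = j$hemo$p_sys, p_dias = j$hemo$p_dias, hr = j$hemo$hr,
      peak_gradient = j$hemo$peak_gradient,
      annulus_mm = j$diameters$annulus,
      strain_ann = j$strain_noisy$annulus,
      strain_sinus = j$strain_noisy$sinus,
      strain_stj = j$strain_noisy$STJ,
      orifice_area = j$orifice_area_noisy
    )
  })
}
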