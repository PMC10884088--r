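#' Material parameter sets
#'
#' A `material_params` object tags a constitutive law with its parameters.
#' Supported laws: `linear_elastic` (E \[MPa\], nu), `neo_hookean` (C10
#' \[MPa\], D1 \[1/MPa\]), `ogden2` (mu1, mu2 \[MPa\], alpha1, alpha2, D1),
#' and `johnson_cook` (A, B \[MPa\], n, optionally elastic E \[MPa\] and nu,
#' density \[kg/m^3\]). Fields irrelevant to the law are absent. Moduli are
#' stored in MPa; `E_gpa` is accepted at the constructor boundary and
#' converted.
#'
#' @param law One of `"linear_elastic"`, `"neo_hookean"`, `"ogden2"`,
#'   `"johnson_cook"`.
#' @param ... Named parameters for the law (see Details). `E_gpa` may be
#'   given instead of `E`.
#' @param label Optional free-text description.
#' @return An object of class `material_params` (a named list).
#' @export
#' @examples
#' material_params("neo_hookean", C10 = 67.7, D1 = 7.5e-3)
material_params <- function(law = c("linear_elastic", "neo_hookean",
                                    "ogden2", "johnson_cook"),
                            ..., label = NULL) {
  law <- match.arg(law)
  p <- list(...)
  if (!is.null(p$E_gpa)) {
    p$E <- p$E_gpa * 1000
    p$E_gpa <- NULL
  }
  p <- p[!vapply(p, is.null, logical(1))]
  allowed <- switch(law,
    linear_elastic = c("E", "nu"),
    neo_hookean    = c("C10", "D1"),
    ogden2         = c("mu1", "mu2", "alpha1", "alpha2", "D1"),
    johnson_cook   = c("A", "B", "n", "E", "nu", "density")
  )
  extra <- setdiff(names(p), allowed)
  if (length(extra)) {
    abort(sprintf("Fields %s are not part of the '%s' law.",
                  paste0("`", extra, "`", collapse = ", "), law))
  }
  obj <- structure(c(list(law = law), p, list(label = label)),
                   class = "material_params")
  validate_material_params(obj)
  obj
}

validate_material_params <- function(x) {
  law <- x$law
  chk <- function(cond, msg) if (!isTRUE(cond)) abort(msg)
  if (law == "linear_elastic") {
    chk(is.numeric(x$nu) && x$nu >= 0 && x$nu < 0.5,
        "Poisson ratio must satisfy 0 <= nu < 0.5.")
    if (!is.null(x$E) && !is.na(x$E)) chk(x$E > 0, "E must be > 0.")
  } else if (law == "neo_hookean") {
    chk(is.numeric(x$C10) && x$C10 > 0, "C10 must be > 0.")
    chk(is.numeric(x$D1) && x$D1 > 0, "D1 must be > 0.")
  } else if (law == "ogden2") {
    chk(all(is.numeric(c(x$mu1, x$mu2, x$alpha1, x$alpha2))),
        "Ogden parameters mu1, mu2, alpha1, alpha2 are required.")
    chk(x$alpha1 != 0 && x$alpha2 != 0, "Ogden exponents must be nonzero.")
  } else if (law == "johnson_cook") {
    chk(is.numeric(x$A) && x$A > 0, "Yield stress A must be > 0.")
    chk(is.numeric(x$B) && x$B >= 0, "Hardening parameter B must be >= 0.")
    chk(is.numeric(x$n) && x$n > 0 && x$n <= 1,
        "Hardening exponent must satisfy 0 < n <= 1.")
  }
  invisible(x)
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params: %s>\n", x$law))
  if (!is.null(x$label)) cat(" ", x$label, "\n")
  nums <- x[setdiff(names(x), c("law", "label"))]
  for (nm in names(nums)) {
    cat(sprintf("  %-8s %s\n", nm, format(nums[[nm]])))
  }
  invisible(x)
}

#' Look up a material in the shipped catalog
#'
#' The catalog holds the parameter sets used for every component of the
#' patient and device models: the aortic wall and native leaflets (linear
#' elastic, nu = 0.475, modulus left unset for calibration), calcific
#' plaques and device skirt/balloon (neo-Hookean), bioprosthetic
#' pericardium (2nd-order Ogden) and the cobalt-chromium stent frame
#' (elasticity plus Johnson-Cook hardening). Values entered in GPa are
#' converted to MPa on load.
#'
#' @param label Catalog key, one of `"aortic_wall"`, `"leaflet"`,
#'   `"calcification"`, `"pericardium"`, `"cobalt_chromium"`, `"skirt"`,
#'   `"balloon"`.
#' @param catalog_file Optional path to an alternative YAML catalog.
#' @return A [material_params] object.
#' @export
#' @examples
#' material_catalog("calcification")
material_catalog <- function(label, catalog_file = NULL) {
  cat_ <- read_material_catalog(catalog_file)
  if (!label %in% names(cat_)) {
    abort(sprintf("Unknown material label '%s'. Known: %s.",
                  label, paste(names(cat_), collapse = ", ")))
  }
  cat_[[label]]
}

#' Read a material catalog YAML file
#'
#' @param path Path to a catalog YAML; `NULL` uses the shipped catalog.
#' @return Named list of [material_params], one per label.
#' @export
read_material_catalog <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "materials.yaml", package = "rootcalib")
  # note: keys are read verbatim ("n" must be quoted in the YAML, which
  # would otherwise parse as a boolean under YAML 1.1)
  raw <- yaml::read_yaml(path)
  mats <- raw$materials
  out <- lapply(mats, function(m) {
    # an unquoted `n:` key round-trips through YAML 1.1 as the boolean FALSE
    names(m)[names(m) %in% c("FALSE", "no")] <- "n"
    lab <- m$label
    m$label <- NULL
    law <- m$law
    m$law <- NULL
    m <- m[!vapply(m, is.null, logical(1))]
    do.call(material_params, c(list(law = law), m, list(label = lab)))
  })
  out
}

#' Write a material catalog YAML file
#'
#' Round-trips with [read_material_catalog()]: parameter values are written
#' exactly and parse back to identical sets.
#'
#' @param catalog Named list of [material_params].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_material_catalog <- function(catalog, path) {
  entries <- lapply(catalog, function(m) {
    out <- m[setdiff(names(m), NULL)]
    class(out) <- NULL
    out
  })
  yaml::write_yaml(list(version = 1, materials = entries), path,
                   precision = 15)
  invisible(path)
}

#' Catalog as a tibble
#'
#' One row per material with law, parameters and label; absent fields are
#' `NA`.
#'
#' @inheritParams read_material_catalog
#' @return A tibble.
#' @export
material_table <- function(path = NULL) {
  cat_ <- read_material_catalog(path)
  purrr::imap_dfr(cat_, function(m, nm) {
    vals <- m[setdiff(names(m), c("law", "label"))]
    tibble::tibble(
      material = nm, law = m$law,
      !!!vals,
      label = m$label %||% NA_character_
    )
  })
}

#' Linear-elastic stress from strain
#'
#' Uniaxial mode returns `E * strain`. The `hoop_axially_constrained` mode
#' is the plane state of a pressurised cylinder with longitudinally fixed
#' ends (axial strain zero, so the axial stress is `nu * hoop stress`),
#' giving `sigma_theta = E * eps_theta / (1 - nu^2)`; its inverse is what
#' the reference wall model uses.
#'
#' @param params A `linear_elastic` [material_params] with `E` set.
#' @param strain Engineering strain (dimensionless), `|strain| < 0.5`.
#' @param mode `"uniaxial"` or `"hoop_axially_constrained"`.
#' @return Stress in MPa.
#' @export
#' @examples
#' m <- material_params("linear_elastic", E = 1, nu = 0.475)
#' linear_elastic_stress(m, 0.01)
linear_elastic_stress <- function(params, strain,
                                  mode = c("uniaxial",
                                           "hoop_axially_constrained")) {
  mode <- match.arg(mode)
  if (!inherits(params, "material_params") || params$law != "linear_elastic") {
    abort("`params` must be a linear_elastic material_params object.")
  }
  if (is.null(params$E) || is.na(params$E)) {
    abort("Modulus E is unset (calibrate it first).")
  }
  if (any(abs(strain) >= 0.5)) {
    abort("|strain| must be < 0.5 for the small-strain law.")
  }
  switch(mode,
    uniaxial = params$E * strain,
    hoop_axially_constrained = params$E * strain / (1 - params$nu^2)
  )
}

#' Incompressible neo-Hookean uniaxial Cauchy stress
#'
#' For the strain energy `W = C10 (I1 - 3)` under incompressible uniaxial
#' extension (`lambda, lambda^-1/2, lambda^-1/2`), the Cauchy stress is
#' `sigma = 2 C10 (lambda^2 - 1/lambda)`; zero at `lambda = 1` with
#' small-strain slope `6 C10`. `D1` is a stored volumetric parameter and
#' does not enter the incompressible form.
#'
#' @param params A `neo_hookean` [material_params].
#' @param stretch Principal stretch `lambda > 0` (vectorised).
#' @return Cauchy stress in MPa.
#' @export
neo_hookean_uniaxial_stress <- function(params, stretch) {
  if (!inherits(params, "material_params") || params$law != "neo_hookean") {
    abort("`params` must be a neo_hookean material_params object.")
  }
  if (any(stretch <= 0)) abort("`stretch` must be > 0.")
  2 * params$C10 * (stretch^2 - 1 / stretch)
}

#' Second-order Ogden uniaxial Cauchy stress
#'
#' Strain energy `W = sum_i 2 mu_i / alpha_i^2 (l1^a_i + l2^a_i + l3^a_i - 3)`
#' evaluated on the incompressible uniaxial stretch state gives the Cauchy
#' stress `sigma = sum_i (2 mu_i / alpha_i) (lambda^a_i - lambda^(-a_i/2))`.
#' Zero at `lambda = 1`. The volumetric `D1` is stored but unused here.
#'
#' @param params An `ogden2` [material_params].
#' @param stretch Principal stretch `lambda > 0` (vectorised).
#' @return Cauchy stress in MPa.
#' @export
ogden2_uniaxial_stress <- function(params, stretch) {
  if (!inherits(params, "material_params") || params$law != "ogden2") {
    abort("`params` must be an ogden2 material_params object.")
  }
  if (any(stretch <= 0)) abort("`stretch` must be > 0.")
  s <- 0
  for (i in 1:2) {
    mu <- params[[paste0("mu", i)]]
    al <- params[[paste0("alpha", i)]]
    s <- s + (2 * mu / al) * (stretch^al - stretch^(-al / 2))
  }
  s
}

# strain-energy densities of the uniaxial incompressible states; used by the
# derivative cross-checks (sigma = lambda dW/dlambda)
neo_hookean_uniaxial_energy <- function(params, stretch) {
  params$C10 * (stretch^2 + 2 / stretch - 3)
}

ogden2_uniaxial_energy <- function(params, stretch) {
  s <- 0
  for (i in 1:2) {
    mu <- params[[paste0("mu", i)]]
    al <- params[[paste0("alpha", i)]]
    s <- s + (2 * mu / al^2) * (stretch^al + 2 * stretch^(-al / 2) - 3)
  }
  s
}

#' Johnson-Cook quasi-static flow stress
#'
#' Flow stress `sigma_y = A + B * eps_p^n` as a function of equivalent
#' plastic strain. Rate and thermal terms are omitted: the device
#' deployment this law serves is simulated quasi-statically.
#'
#' @param params A `johnson_cook` [material_params].
#' @param plastic_strain Equivalent plastic strain, `>= 0` (vectorised).
#' @return Flow stress in MPa.
#' @export
#' @examples
#' m <- material_catalog("cobalt_chromium")
#' johnson_cook_flow_stress(m, 0)    # yield stress A
johnson_cook_flow_stress <- function(params, plastic_strain) {
  if (!inherits(params, "material_params") || params$law != "johnson_cook") {
    abort("`params` must be a johnson_cook material_params object.")
  }
  if (any(plastic_strain < 0)) abort("`plastic_strain` must be >= 0.")
  params$A + params$B * plastic_strain^params$n
}
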