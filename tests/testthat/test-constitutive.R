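# Constitutive law evaluators and the material catalog.

test_that("all stress evaluators vanish exactly in the undeformed state", {
  le <- material_params("linear_elastic", E = 5.6, nu = 0.475)
  nh <- material_catalog("calcification")
  og <- material_catalog("pericardium")
  jc <- material_catalog("cobalt_chromium")
  expect_identical(linear_elastic_stress(le, 0), 0)
  expect_identical(linear_elastic_stress(le, 0, "hoop_axially_constrained"), 0)
  expect_equal(neo_hookean_uniaxial_stress(nh, 1), 0)
  expect_equal(ogden2_uniaxial_stress(og, 1), 0)
  # flow stress at zero plastic strain is the yield stress, not zero
  expect_equal(johnson_cook_flow_stress(jc, 0), 465.0)
})

test_that("uniaxial linear elasticity is sigma = E * eps", {
  m <- material_params("linear_elastic", E = 1.0, nu = 0.3)
  expect_equal(linear_elastic_stress(m, 0.01), 0.01)
  m2 <- material_params("linear_elastic", E = 5.6, nu = 0.475)
  expect_equal(linear_elastic_stress(m2, 0.02), 0.112)
})

test_that("hoop mode matches a 3x3 compliance-matrix inversion", {
  # independent oracle: isotropic compliance in (r, theta, z); impose
  # sigma_r = 0, eps_z = 0 and solve for sigma_theta given eps_theta
  E <- 5.6; nu <- 0.475
  S <- matrix(c(1, -nu, -nu,
                -nu, 1, -nu,
                -nu, -nu, 1) / E, 3, 3, byrow = TRUE)
  # unknowns (sigma_theta, sigma_z); eps_z = 0 gives sigma_z = nu sigma_theta
  # and eps_theta = S[2,2] sigma_theta + S[2,3] sigma_z
  eps_theta <- 0.013
  A <- rbind(c(S[2, 2], S[2, 3]),
             c(S[3, 2], S[3, 3]))
  sol <- solve(A, c(eps_theta, 0))
  m <- material_params("linear_elastic", E = E, nu = nu)
  got <- linear_elastic_stress(m, eps_theta, "hoop_axially_constrained")
  expect_lt(abs(got - sol[1]) / abs(sol[1]), 1e-12)
  expect_equal(sol[2], nu * sol[1], tolerance = 1e-12)
})

test_that("hyperelastic stresses equal the strain-energy derivative", {
  # oracle: sigma = lambda * dW/dlambda by central difference on the
  # incompressible uniaxial energies, written out independently here
  W_nh <- function(C10, l) C10 * (l^2 + 2 / l - 3)
  W_og <- function(mu, al, l) {
    s <- 0
    for (i in 1:2) s <- s + (2 * mu[i] / al[i]^2) *
        (l^al[i] + 2 * l^(-al[i] / 2) - 3)
    s
  }
  nh <- material_catalog("calcification")
  og <- material_catalog("pericardium")
  h <- 1e-6
  for (l in c(0.9, 1.1, 1.3)) {
    sig_nh <- l * (W_nh(nh$C10, l + h) - W_nh(nh$C10, l - h)) / (2 * h)
    expect_lt(abs(neo_hookean_uniaxial_stress(nh, l) - sig_nh) /
                abs(sig_nh), 1e-6)
    mu <- c(og$mu1, og$mu2); al <- c(og$alpha1, og$alpha2)
    sig_og <- l * (W_og(mu, al, l + h) - W_og(mu, al, l - h)) / (2 * h)
    expect_lt(abs(ogden2_uniaxial_stress(og, l) - sig_og) /
                abs(sig_og), 1e-6)
  }
})

test_that("neo-Hookean small-strain stiffness is 6 C10", {
  nh <- material_params("neo_hookean", C10 = 67.7, D1 = 7.5e-3)
  h <- 1e-7
  slope <- (neo_hookean_uniaxial_stress(nh, 1 + h) -
              neo_hookean_uniaxial_stress(nh, 1 - h)) / (2 * h)
  expect_equal(slope, 6 * 67.7, tolerance = 1e-6)
})

test_that("Johnson-Cook flow stress follows the power hardening law", {
  jc <- material_catalog("cobalt_chromium")
  expect_equal(johnson_cook_flow_stress(jc, 0.1), 465 + 2140 * 0.1^0.73)
  s <- johnson_cook_flow_stress(jc, c(0, 0.1, 0.2))
  expect_true(all(diff(s) > 0))
  expect_error(johnson_cook_flow_stress(jc, -0.01), "plastic_strain")
})

test_that("the catalog serves the printed parameter sets", {
  calc <- material_catalog("calcification")
  expect_equal(calc$C10, 67.7)
  expect_equal(calc$D1, 7.5e-3)
  cob <- material_catalog("cobalt_chromium")
  expect_equal(cob$E, 238540)  # entered as 238.54 GPa
  expect_equal(cob$nu, 0.29)
  expect_equal(cob$A, 465.0)
  expect_equal(cob$B, 2140)
  expect_equal(cob$n, 0.73)
  expect_equal(cob$density, 7650)
  per <- material_catalog("pericardium")
  expect_equal(per$mu1, 0.96)
  expect_equal(per$alpha1, -56.5)
  expect_equal(per$mu2, 3.57)
  expect_equal(per$alpha2, 1.87)
  expect_equal(per$D1, 0.027)
  wall <- material_catalog("aortic_wall")
  expect_equal(wall$nu, 0.475)
  expect_true(is.null(wall$E) || is.na(wall$E))
  expect_equal(material_catalog("skirt")$C10, 1.7)
  expect_equal(material_catalog("balloon")$D1, 1.36e-3)
  expect_error(material_catalog("granite"), "Unknown material")
})

test_that("the catalog round-trips through YAML", {
  cat1 <- read_material_catalog()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_material_catalog(cat1, path)
  cat2 <- read_material_catalog(path)
  expect_identical(names(cat1), names(cat2))
  for (nm in names(cat1)) expect_equal(cat1[[nm]], cat2[[nm]])
})

test_that("parameter validation enforces the law invariants", {
  expect_error(material_params("linear_elastic", E = 5, nu = 0.5), "nu")
  expect_error(material_params("linear_elastic", E = -1, nu = 0.3), "E")
  expect_error(material_params("neo_hookean", C10 = -1, D1 = 0.1), "C10")
  expect_error(material_params("johnson_cook", A = 465, B = 2140, n = 1.5),
               "exponent")
  # fields irrelevant to a law are rejected
  expect_error(material_params("neo_hookean", C10 = 1, D1 = 1, A = 5),
               "not part")
  # wrong law tag at the evaluators
  nh <- material_params("neo_hookean", C10 = 1, D1 = 1)
  expect_error(linear_elastic_stress(nh, 0.1), "linear_elastic")
  expect_error(ogden2_uniaxial_stress(nh, 1.1), "ogden2")
  expect_error(neo_hookean_uniaxial_stress(nh, -0.5), "stretch")
})
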