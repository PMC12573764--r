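# AO backend: molecule I/O, integrals, J/K algebra, XC evaluation.

test_that("XYZ round trips preserve coordinates and malformed input errors", {
  m <- generate_fixture("diatomic", symbols = c("H", "H"), R = 0.74)
  expect_s3_class(m, "Molecule")
  expect_equal(sqrt(sum((m$coords[1, ] - m$coords[2, ])^2)), 0.74)

  p <- generate_fixture("polyene", n = 3)
  txt <- write_xyz(p, comment = "hexatriene")
  p2 <- read_xyz(txt)
  expect_equal(p2$coords, p$coords, tolerance = 1e-6)
  expect_identical(p2$symbols, p$symbols)

  expect_error(read_xyz("0\nempty\n"), "empty atom list")
  expect_error(read_xyz("2\nc\nH 0 0 0\n"), "mismatch")
  expect_error(read_xyz("1\nc\nH 0 zero 0\n"), "parse error")
  expect_error(molecule(character(0), matrix(0, 0, 3)), "empty")
  expect_error(molecule("H", rbind(c(0, 0, 0)), multiplicity = 1),
               "multiplicity")
})

test_that("nuclear repulsion matches the point-charge sum and S is normalized", {
  R_bohr <- 1.4
  m <- generate_fixture("diatomic", symbols = c("H", "H"),
                        R = bohr_to_ang(R_bohr))
  ints <- build_ao_integrals(m, "mini")
  expect_equal(ints$Vnn, 1 / 1.4, tolerance = 1e-10)
  expect_equal(diag(ints$S), rep(1, ints$M), tolerance = 1e-10)
  expect_lt(max(abs(ints$S - t(ints$S))), 1e-12)
  expect_lt(max(abs(ints$hcore - t(ints$hcore))), 1e-12)

  w <- water_mini()
  xyz <- ang_to_bohr(w$mol$coords)
  vnn <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    vnn <- vnn + w$mol$Z[i] * w$mol$Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  expect_equal(w$Vnn, vnn, tolerance = 1e-12)
})

test_that("contracted s-s overlap matches an independent Gaussian-product evaluation", {
  R <- 1.4  # bohr
  m <- generate_fixture("diatomic", symbols = c("H", "H"), R = bohr_to_ang(R))
  b <- build_basis(m, "mini")
  ints <- build_ao_integrals(m, b)
  # closed-form primitive Gaussian product overlap, evaluated independently
  a_ex <- b$alpha[1:3]
  cf <- b$coef[1:3]
  ov <- 0
  for (p in 1:3) for (q in 1:3) {
    ap <- a_ex[p]; aq <- a_ex[q]
    ov <- ov + cf[p] * cf[q] * (pi / (ap + aq))^1.5 *
      exp(-ap * aq / (ap + aq) * R^2)
  }
  expect_equal(ints$S[1, 2], ov, tolerance = 1e-8)
})

test_that("J and K are linear in P and Coulomb energies are nonnegative", {
  ints <- water_mini()
  set.seed(11)
  M <- ints$M
  P1 <- crossprod(matrix(rnorm(M * M), M)) / M  # positive semidefinite
  P2 <- matrix(rnorm(M * M), M); P2 <- (P2 + t(P2)) / 2
  jk1 <- jk_build(ints, P1)
  jk2 <- jk_build(ints, P2)
  jk12 <- jk_build(ints, P1 + 2 * P2)
  expect_equal(jk12$J, jk1$J + 2 * jk2$J, tolerance = 1e-10)
  expect_equal(jk12$K, jk1$K + 2 * jk2$K, tolerance = 1e-10)
  expect_gte(sum(P1 * jk1$J), 0)
  expect_lt(max(abs(jk1$J - t(jk1$J))), 1e-10)
  expect_lt(max(abs(jk1$K - t(jk1$K))), 1e-10)
})

test_that("dipole integrals shift by d * S_AO under rigid translation", {
  m1 <- generate_fixture("water")
  d_ang <- c(0.3, -0.2, 0.5)
  m2 <- molecule(m1$symbols, sweep(m1$coords, 2, d_ang, `+`))
  i1 <- build_ao_integrals(m1, "mini")
  i2 <- build_ao_integrals(m2, "mini")
  d_bohr <- ang_to_bohr(d_ang)
  for (k in 1:3) {
    expect_equal(i2$dip[[k]], i1$dip[[k]] + d_bohr[k] * i1$S,
                 tolerance = 1e-8)
  }
})

test_that("semilocal XC vanishes for HF and for zero densities", {
  ints <- water_mini()
  M <- ints$M
  det <- water_hf()
  P <- nocicoox:::.det_density(det)
  hf <- xc_eval(ints, P$Pa, P$Pb, "hf")
  expect_identical(hf$Exc, 0)
  expect_equal(hf$Vxc_a, matrix(0, M, M))
  g <- build_grid(ints$mol, ints$basis, "coarse")
  z <- xc_eval(g, matrix(0, M, M), matrix(0, M, M), "svwn5")
  expect_equal(z$Exc, 0, tolerance = 1e-14)
})

test_that("PBE exchange of a one-electron Gaussian density matches radial quadrature", {
  # single H atom, minimal basis: the 1s density is a known contraction;
  # compare the grid Exc (exchange only) against an independent 1D radial
  # quadrature of the closed-form density
  m <- molecule("H", rbind(c(0, 0, 0)), multiplicity = 2)
  b <- build_basis(m, "mini")
  ints <- build_ao_integrals(m, b)
  det <- run_scf(ints, "hf", scf_settings())
  P <- nocicoox:::.det_density(det)
  g <- build_grid(m, b, "fine")
  par <- list(x_slater = 0, x_pbe = 1, c_vwn5 = 0, c_pbe = 0)
  grid_ex <- nocicoox:::.cpp_xc_eval(unclass(b), g$points, g$weights,
                                     P$Pa, P$Pb, par)$Exc
  # independent radial quadrature (spin-polarized PBE exchange of rho_a)
  rho <- function(r) {
    phi <- sapply(r, function(ri) sum(b$coef * exp(-b$alpha * ri^2)))
    phi^2
  }
  drho <- function(r) {
    phi <- sapply(r, function(ri) sum(b$coef * exp(-b$alpha * ri^2)))
    dphi <- sapply(r, function(ri) sum(-2 * b$alpha * ri * b$coef *
                                         exp(-b$alpha * ri^2)))
    2 * phi * dphi
  }
  integrand <- function(r) {
    ra <- rho(r)
    # spin scaling: Ex[ra, 0] = Ex_unpol[2 ra]/2
    rr <- 2 * ra
    s2 <- (drho(r) * 2)^2 / (4 * (3 * pi^2)^(2 / 3) * rr^(8 / 3))
    kappa <- 0.804; mu <- 0.2195149727645171
    Fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
    ex <- -(3 / 4) * (3 / pi)^(1 / 3) * rr^(4 / 3) * Fx
    0.5 * ex * 4 * pi * r^2
  }
  ref <- integrate(integrand, 0, 30, rel.tol = 1e-10)$value
  expect_equal(grid_ex, ref, tolerance = 2e-5)
})

test_that("XC potentials are consistent with finite differences of the energy", {
  ints <- water_mini()
  det <- water_hf()
  P <- nocicoox:::.det_density(det)
  g <- build_grid(ints$mol, ints$basis, "coarse")
  set.seed(3)
  M <- ints$M
  dP <- matrix(rnorm(M * M, sd = 1e-5), M)
  dP <- (dP + t(dP)) / 2
  for (f in c("svwn5", "pbe")) {
    xc <- xc_eval(g, P$Pa, P$Pb, f)
    ep <- xc_eval(g, P$Pa + dP, P$Pb, f)$Exc
    em <- xc_eval(g, P$Pa - dP, P$Pb, f)$Exc
    expect_equal(sum(xc$Vxc_a * dP), (ep - em) / 2, tolerance = 1e-6)
    expect_lt(max(abs(xc$Vxc_a - t(xc$Vxc_a))), 1e-10)
  }
})

test_that("grid integrates the electron count accurately", {
  ints <- water_mini()
  det <- water_hf()
  P <- nocicoox:::.det_density(det)
  g <- build_grid(ints$mol, ints$basis, "medium")
  xc <- xc_eval(g, P$Pa, P$Pb, "svwn5")
  expect_equal(xc$n_alpha, det$n_alpha, tolerance = 1e-4)
  expect_equal(xc$n_beta, det$n_beta, tolerance = 1e-4)
})

test_that("unknown elements, functionals and bases raise configuration errors", {
  expect_error(molecule("Xx", rbind(c(0, 0, 0))), "unknown element")
  expect_error(functional_spec("b3lyp"), "unsupported functional")
  expect_error(build_basis(generate_fixture("water"), "def2-qzvpp"),
               "unknown basis family")
})
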