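# SCF engine: plain and constrained solutions, multiplier bracketing,
# IMOM, spin expectation values.

test_that("H2 restricted HF matches an independent dense fixed-point SCF", {
  ints <- h2_mini()
  det <- run_scf(ints, "hf", scf_settings())
  expect_true(det$converged)
  # independent oracle: damped fixed-point SCF in the orthonormal basis,
  # no DIIS, dense ERI array
  X <- nocicoox:::.invsqrtm_sym(ints$S)
  arr <- nocicoox:::eri_array(ints)
  M <- ints$M
  P <- matrix(0, M, M)
  for (it in 1:200) {
    J <- matrix(0, M, M); K <- matrix(0, M, M)
    for (p in 1:M) for (q in 1:M) {
      J[p, q] <- sum(arr[p, q, , ] * P)
      K[p, q] <- sum(arr[p, , , q] * P)
    }
    F <- ints$hcore + 2 * J - K
    Ft <- t(X) %*% F %*% X
    e <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    o <- order(e$values)
    Co <- (X %*% e$vectors[, o])[, 1, drop = FALSE]
    Pn <- tcrossprod(Co)
    if (max(abs(Pn - P)) < 1e-12) { P <- Pn; break }
    P <- Pn
  }
  Eref <- ints$Vnn + 2 * sum(P * ints$hcore) +
    sum(P * (2 * matrix(sapply(1:M, function(q) sapply(1:M, function(p)
      sum(arr[p, q, , ] * P))), M) -
        matrix(sapply(1:M, function(q) sapply(1:M, function(p)
          sum(arr[p, , , q] * P))), M)))
  expect_equal(det$E_HF, Eref, tolerance = 1e-8)
})

test_that("determinant invariants hold and restart reproduces the energy quickly", {
  ints <- water_mini()
  det <- water_hf()
  expect_lt(max(abs(t(det$Ca) %*% ints$S %*% det$Ca - diag(ints$M))), 1e-8)
  expect_equal(sum(det$occ_a), det$n_alpha)
  expect_equal(det$E_KS, det$E_HF)  # pure HF: the two stored energies agree
  # restart from the converged density
  det2 <- run_scf(ints, "hf",
                  scf_settings(guess = nocicoox:::.det_density(det)))
  expect_lte(det2$n_iter, 2)
  expect_equal(det2$E_HF, det$E_HF, tolerance = 1e-9)
})

test_that("unconstrained runs carry no multiplier and match plain SCF", {
  ints <- h2_mini()
  d1 <- run_scf(ints, "hf", scf_settings())
  expect_true(is.na(d1$lambda))
  d2 <- run_scf(ints, "hf", scf_settings(), constraint = NULL)
  expect_equal(d1$E_HF, d2$E_HF)
})

test_that("constrained SCF satisfies the constraint to the inner tolerance", {
  ints <- water_mini()
  g0 <- water_pbe0()
  no <- g0$n_alpha
  spec <- wc_single(ints$S, g0$Ca, no, no + 1, no, "alpha")
  det <- run_scf(ints, "pbe0",
                 scf_settings(guess = nocicoox:::.det_density(g0)),
                 constraint = spec)
  expect_true(det$converged)
  expect_lte(det$constraint_resid, 1e-10)
  expect_gt(det$E_KS, g0$E_KS)  # excited state above the ground state
  # aufbau on the perturbed spectrum: occupations fill the lowest levels
  expect_equal(which(det$occ_a > 0.5), seq_len(no))
  # stationarity of the perturbed Fock operator
  expect_lte(det$rms, 1e-7)
})

test_that("bracket_lambda solves trivial, bracketed and asymptotic targets", {
  # already satisfied at the start: one evaluation
  r0 <- bracket_lambda(function(l) list(value = 0.5, deriv = -1), 0.5)
  expect_equal(r0$iterations, 1)
  expect_equal(r0$lambda, 0)
  # smooth monotone crossing
  f <- function(l) list(value = tanh(-l), deriv = -1 / cosh(l)^2)
  r1 <- bracket_lambda(f, 0.7, tol = 1e-12)
  expect_true(r1$converged)
  expect_equal(tanh(-r1$lambda), 0.7, tolerance = 1e-11)
  # asymptotic approach (value saturates at the target)
  g <- function(l) list(value = 0.5 - 0.3 / (1 + l^2), deriv = 0.6 * l / (1 + l^2)^2)
  r2 <- bracket_lambda(g, 0.5, tol = 1e-10)
  expect_true(r2$converged)
  expect_lte(abs(g(r2$lambda)$value - 0.5), 1e-10)
})

test_that("multiplier solve is antisymmetric under (Wc, Nc) -> (-Wc, -Nc)", {
  ints <- water_mini()
  g0 <- water_hf()
  no <- g0$n_alpha
  spec <- wc_single(ints$S, g0$Ca, no, no + 1, no, "alpha")
  negspec <- spec
  negspec$Wc_a <- -spec$Wc_a
  negspec$Wc_b <- -spec$Wc_b
  negspec$Nc <- -spec$Nc
  P <- nocicoox:::.det_density(g0)
  d1 <- run_scf(ints, "hf", scf_settings(guess = P), constraint = spec)
  d2 <- run_scf(ints, "hf", scf_settings(guess = P), constraint = negspec)
  expect_equal(d2$lambda, -d1$lambda, tolerance = 1e-6)
  expect_equal(d2$E_HF, d1$E_HF, tolerance = 1e-8)
})

test_that("inner bracketing stays within a few iterations for a single excitation", {
  ints <- water_mini()
  g0 <- water_pbe0()
  no <- g0$n_alpha
  spec <- wc_single(ints$S, g0$Ca, no, no + 1, no, "alpha")
  det <- run_scf(ints, "pbe0",
                 scf_settings(guess = nocicoox:::.det_density(g0)),
                 constraint = spec)
  expect_true(det$converged)
  expect_lt(max(det$lambda_iters), 10)
})

test_that("spin expectation of single determinants", {
  ints <- water_mini()
  det <- water_hf()
  expect_equal(s2_single(det, ints$S), 0, tolerance = 1e-10)
  # one alpha orbital promoted with the remaining orbitals paired
  det2 <- det
  det2$occ_a[det$n_alpha] <- 0
  det2$occ_a[det$n_alpha + 1] <- 1
  expect_equal(s2_single(det2, ints$S), 1, tolerance = 1e-10)
  # random small unrestricted determinant vs the second-quantized oracle
  h4 <- h4_ints()
  d <- random_det(h4, 2, 1, seed = 21)
  pr <- biorthogonalize(d, d, h4$S)
  expand_I <- expand_determinant(d, h4$S)
  expect_equal(s2_single(d, h4$S),
               brute_force_element(expand_I, expand_I, "s_squared"),
               tolerance = 1e-10)
})

test_that("IMOM with an identity swap converges to the ground state", {
  ints <- water_mini()
  g0 <- water_hf()
  d <- run_imom(ints, "hf", scf_settings(), g0,
                swap = list(from = g0$n_alpha, to = g0$n_alpha,
                            spin = "alpha"))
  expect_true(d$converged)
  expect_equal(d$E_HF, g0$E_HF, tolerance = 1e-7)
})

test_that("IMOM excited solution lies above the ground state and is reproducible", {
  ints <- water_mini()
  g0 <- water_hf()
  no <- g0$n_alpha
  d <- run_imom(ints, "hf", scf_settings(), g0,
                swap = list(from = no, to = no + 1, spin = "alpha"))
  expect_true(d$converged)
  expect_gt(d$E_HF, g0$E_HF)
  # second independent run from the same reference converges to the same state
  d2 <- run_imom(ints, "hf", scf_settings(diis_size = 4), g0,
                 swap = list(from = no, to = no + 1, spin = "alpha"))
  expect_equal(d2$E_HF, d$E_HF, tolerance = 1e-6)
})

test_that("Fermi smearing fills degenerate levels evenly and anneals to integers", {
  ints <- h2_svb()
  d <- run_scf(ints, "hf", scf_settings(smear_K = 2000))
  expect_true(d$converged)
  expect_true(all(abs(d$occ_a - round(d$occ_a)) < 1e-8))
  d0 <- run_scf(ints, "hf", scf_settings())
  expect_equal(d$E_HF, d0$E_HF, tolerance = 1e-6)
})
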