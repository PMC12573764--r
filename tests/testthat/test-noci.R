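# NOCI engine: biorthogonalization, matrix elements, secular solution,
# gauge invariance, transition properties, spectra.

test_that("biorthogonalization of identical determinants gives unit singular values", {
  ints <- water_mini()
  det <- water_hf()
  pr <- biorthogonalize(det, det, ints$S)
  expect_equal(pr$alpha$sigma, rep(1, det$n_alpha), tolerance = 1e-10)
  expect_equal(pr$overlap, 1, tolerance = 1e-10)
  expect_equal(overlap_element(pr), pr$overlap)
})

test_that("biorthogonal invariants: descending sigma, trailing zeros, diagonal overlap", {
  h4 <- h4_ints()
  set.seed(31)
  dI <- random_det(h4, 2, 2)
  dJ <- random_det(h4, 2, 2)
  pr <- biorthogonalize(dI, dJ, h4$S)
  for (sp in list(pr$alpha, pr$beta)) {
    expect_true(all(diff(sp$sigma) <= 1e-12))
    expect_true(all(sp$sigma >= -1e-14))
    D <- t(sp$CtI) %*% h4$S %*% sp$CtJ
    expect_equal(D, diag(sp$sigma, length(sp$sigma)), tolerance = 1e-10)
    if (length(sp$zero_idx)) {
      expect_equal(sp$zero_idx, seq(length(sp$sigma) - length(sp$zero_idx) + 1,
                                    length(sp$sigma)))
    }
  }
  # rank deficiency by construction: replace an occupied orbital with an
  # S-orthogonal complement vector
  dK <- dI
  dK$occ_a <- c(1, 0, 1, 0)
  prz <- biorthogonalize(dI, dK, h4$S)
  expect_equal(length(prz$alpha$zero_idx), 1)
  expect_equal(overlap_element(prz), 0)
  # electron-count mismatch rejected
  dM <- random_det(h4, 3, 1)
  expect_error(biorthogonalize(dI, dM, h4$S), "incompatible")
})

test_that("overlap equals the determinant of the MO overlap matrices", {
  h4 <- h4_ints()
  set.seed(33)
  for (k in 1:5) {
    dI <- random_det(h4, 2, 1)
    dJ <- random_det(h4, 2, 1)
    pr <- biorthogonalize(dI, dJ, h4$S)
    SmoA <- t(dI$Ca[, 1:2]) %*% h4$S %*% dJ$Ca[, 1:2]
    SmoB <- t(dI$Cb[, 1, drop = FALSE]) %*% h4$S %*% dJ$Cb[, 1, drop = FALSE]
    expect_equal(overlap_element(pr), det(SmoA) * det(SmoB),
                 tolerance = 1e-10)
  }
})

test_that("matrix elements agree with the permutation-expansion oracle in every zero case", {
  h4 <- h4_ints()
  set.seed(37)
  dI <- random_det(h4, 2, 2)
  cases <- list(
    none = random_det(h4, 2, 2),
    one_alpha = within_occ(dI, occ_a = c(1, 0, 1, 0)),
    two_alpha = within_occ(dI, occ_a = c(0, 0, 1, 1)),
    one_each = within_occ(dI, occ_a = c(1, 0, 1, 0), occ_b = c(1, 0, 1, 0)),
    three = within_occ(dI, occ_a = c(0, 0, 1, 1), occ_b = c(1, 0, 1, 0))
  )
  eI <- expand_determinant(dI, h4$S)
  for (nm in names(cases)) {
    dJ <- cases[[nm]]
    pr <- biorthogonalize(dI, dJ, h4$S, 1e-7)
    eJ <- expand_determinant(dJ, h4$S)
    expect_equal(overlap_element(pr),
                 brute_force_element(eI, eJ, "overlap"),
                 tolerance = 1e-10, info = nm)
    expect_equal(hf_matrix_element(pr, NULL, h4),
                 brute_force_element(eI, eJ, "hamiltonian", h4),
                 tolerance = 1e-10, info = nm)
    expect_equal(s2_matrix_element(pr, dI, dJ, h4$S),
                 brute_force_element(eI, eJ, "s_squared"),
                 tolerance = 1e-10, info = nm)
  }
})

test_that("diagonal element reproduces the Hartree-Fock energy expression", {
  ints <- water_mini()
  det <- water_hf()
  pr <- biorthogonalize(det, det, ints$S)
  expect_equal(hf_matrix_element(pr, NULL, ints), det$E_HF, tolerance = 1e-9)
})

test_that("TDF correction modes behave as specified", {
  ints <- water_mini()
  # HF references: no correction in either mode
  dh <- water_hf()
  expect_equal(tdf_correction(dh, dh, dh$E_HF, 1, "determinant"), 0)
  expect_equal(tdf_correction(dh, dh, dh$E_HF, 1, "overlap"), 0)
  # KS reference: determinant-weighted diagonal restores E_KS exactly
  dk <- water_pbe0()
  corr <- tdf_correction(dk, dk, dk$E_HF, 1, "determinant")
  expect_equal(dk$E_HF + corr, dk$E_KS, tolerance = 1e-12)
  # orthogonal pair: both modes give zero
  expect_equal(tdf_correction(dk, dk, 0, 0, "determinant"), 0)
  expect_equal(tdf_correction(dk, dk, 0, 0, "overlap"), 0)
})

test_that("single-determinant NOCI returns the determinant itself", {
  ints <- water_mini()
  det <- water_pbe0()
  r <- assemble_and_solve(list(det), ints, "pbe0")
  expect_equal(length(r$energies), 1)
  expect_equal(r$energies[1], det$E_KS, tolerance = 1e-9)
  expect_equal(r$s2[1], s2_single(det, ints$S), tolerance = 1e-9)
})

test_that("H and S are gauge invariant under orbital sign flips and occupied rotations", {
  ints <- h2_svb()
  g <- run_scf(ints, "hf", scf_settings())
  no <- g$n_alpha
  P <- nocicoox:::.det_density(g)
  sa <- wc_single(ints$S, g$Ca, no, no + 1, no, "alpha")
  e1 <- run_scf(ints, "hf", scf_settings(guess = P), constraint = sa)
  dets <- list(g, e1)
  r0 <- assemble_and_solve(dets, ints, "hf")
  # flip the sign of one occupied orbital of the excited determinant
  e2 <- e1
  e2$Ca[, 1] <- -e2$Ca[, 1]
  r1 <- assemble_and_solve(list(g, e2), ints, "hf")
  expect_equal(r1$energies, r0$energies, tolerance = 1e-9)
  expect_equal(abs(r1$S), abs(r0$S), tolerance = 1e-9)
  # hermiticity
  expect_lt(max(abs(r0$H - t(r0$H))), 1e-9)
  # variational: lowest root below the lowest diagonal element
  expect_lte(r0$energies[1], min(diag(r0$H)) + 1e-12)
})

test_that("NOCI over unrelaxed singles equals CIS in the determinant basis", {
  ints <- water_mini()
  g <- water_hf()
  no <- g$n_alpha; M <- ints$M
  dets <- list(g)
  for (i in 1:no) for (a in (no + 1):M) {
    for (sp in c("a", "b")) {
      d <- g
      if (sp == "a") { d$occ_a[i] <- 0; d$occ_a[a] <- 1 }
      else { d$occ_b[i] <- 0; d$occ_b[a] <- 1 }
      dets[[length(dets) + 1]] <- d
    }
  }
  r <- assemble_and_solve(dets, ints, "hf")
  # independent reference: orthogonal Slater-Condon CI over the same configs
  h_mo <- t(g$Ca) %*% ints$hcore %*% g$Ca
  gmo <- nocicoox:::.ao2mo4(nocicoox:::eri_array(ints), g$Ca, g$Ca, g$Ca, g$Ca)
  cfgs <- list(list(alpha = 1:no, beta = 1:no))
  for (i in 1:no) for (a in (no + 1):M) {
    cfgs[[length(cfgs) + 1]] <- list(alpha = sort(c(setdiff(1:no, i), a)),
                                     beta = 1:no)
    cfgs[[length(cfgs) + 1]] <- list(alpha = 1:no,
                                     beta = sort(c(setdiff(1:no, i), a)))
  }
  n <- length(cfgs)
  H <- matrix(0, n, n)
  for (p in 1:n) for (q in p:n) {
    H[p, q] <- H[q, p] <- nocicoox:::.sc_element(cfgs[[p]], cfgs[[q]],
                                                 h_mo, gmo, ints$Vnn)
  }
  eref <- sort(eigen(H, symmetric = TRUE)$values)
  expect_equal(sort(r$energies), eref, tolerance = 1e-8)
})

test_that("spin purification splits the open-shell pair into singlet and triplet", {
  ints <- h2_svb()
  g <- run_scf(ints, "hf", scf_settings())
  no <- g$n_alpha
  P <- nocicoox:::.det_density(g)
  ea <- run_scf(ints, "hf", scf_settings(guess = P),
                constraint = wc_single(ints$S, g$Ca, no, no + 1, no, "alpha"))
  eb <- run_scf(ints, "hf", scf_settings(guess = P),
                constraint = wc_single(ints$S, g$Cb, no, no + 1, no, "beta"))
  r <- assemble_and_solve(list(ea, eb), ints, "hf")
  s2s <- sort(r$s2)
  expect_lt(abs(s2s[1] - 0), 0.05)
  expect_lt(abs(s2s[2] - 2), 0.05)
  # the two roots are split: the degenerate failure mode of an
  # overlap-weighted one-electron-only coupling does not occur
  expect_gt(abs(diff(r$energies)), 1e-3)
})

test_that("transition densities normalize and symmetry-forbidden lines are dark", {
  ints <- h2_svb()
  g <- run_scf(ints, "hf", scf_settings())
  no <- g$n_alpha
  P <- nocicoox:::.det_density(g)
  ea <- run_scf(ints, "hf", scf_settings(guess = P),
                constraint = wc_single(ints$S, g$Ca, no, no + 1, no, "alpha"))
  eb <- run_scf(ints, "hf", scf_settings(guess = P),
                constraint = wc_single(ints$S, g$Cb, no, no + 1, no, "beta"))
  dd <- run_scf(ints, "hf", scf_settings(guess = P),
                constraint = wc_double(ints$S, g$Ca, no, no, no + 1, no + 1,
                                       no))
  r <- assemble_and_solve(list(g, ea, eb, dd), ints, "hf")
  props <- transition_properties(r, ints)
  # gamma^{00} traces to the electron count
  tdgs <- nocicoox:::.pair_transition_density(
    biorthogonalize(g, g, ints$S))
  expect_equal(sum((tdgs$alpha + tdgs$beta) * ints$S), 2, tolerance = 1e-8)
  # H2: sigma-g -> double (g symmetry) is dipole-forbidden from the ground
  # state; the g/g transitions must carry zero oscillator strength
  dark <- props$osc_strength[which.max(abs(r$coef[4, ]))]
  expect_lt(abs(dark), 1e-6)
  expect_true(all(props$osc_strength >= -1e-12))
})

test_that("size consistency: two helium atoms at 100 Angstrom are additive", {
  mono <- build_ao_integrals(molecule("He", rbind(c(0, 0, 0))), "svb")
  gA <- run_scf(mono, "hf", scf_settings())
  PA <- nocicoox:::.det_density(gA)
  eA <- run_scf(mono, "hf", scf_settings(guess = PA),
                constraint = wc_single(mono$S, gA$Ca, 1, 2, 1, "alpha"))
  eAb <- run_scf(mono, "hf", scf_settings(guess = PA),
                 constraint = wc_single(mono$S, gA$Cb, 1, 2, 1, "beta"))
  rA <- assemble_and_solve(list(gA, eA, eAb), mono, "hf")
  # dimer at 100 A with product-state references composed from monomer blocks
  dim_ints <- build_ao_integrals(
    generate_fixture("diatomic", symbols = c("He", "He"), R = 100), "svb")
  Mm <- mono$M
  embed <- function(detX, detY) {
    blk <- function(A, B) {
      out <- matrix(0, 2 * Mm, 2 * Mm)
      out[1:Mm, 1:Mm] <- A
      out[(Mm + 1):(2 * Mm), (Mm + 1):(2 * Mm)] <- B
      out
    }
    list(Ca = blk(detX$Ca, detY$Ca), Cb = blk(detX$Cb, detY$Cb),
         occ_a = c(detX$occ_a, detY$occ_a), occ_b = c(detX$occ_b, detY$occ_b),
         n_alpha = detX$n_alpha + detY$n_alpha,
         n_beta = detX$n_beta + detY$n_beta)
  }
  dets <- list(embed(gA, gA), embed(eA, gA), embed(eAb, gA),
               embed(gA, eA), embed(gA, eAb))
  rAB <- assemble_and_solve(dets, dim_ints, "hf")
  expect_lt(abs(rAB$energies[1] - 2 * rA$energies[1]), 1e-6)
})

test_that("Voigt broadening reduces to a Gaussian and conserves stick areas", {
  sp <- broaden_spectrum(c(5), c(0.8), gaussian_hwhm = 0.15,
                         lorentzian_hwhm = 0)
  # pure Gaussian comparison on the same grid
  sigma <- 0.15 / sqrt(2 * log(2))
  ref <- 0.8 * exp(-(sp$energy_ev - 5)^2 / (2 * sigma^2)) /
    (sigma * sqrt(2 * pi))
  expect_equal(sp$intensity, ref, tolerance = 1e-8)
  # area equals the stick strength
  wide <- seq(-60, 70, length.out = 40000)
  voigt <- broaden_spectrum(c(3, 4.5), c(0.25, 0.6), 0.15, 0.15, grid = wide)
  area <- sum(voigt$intensity) * diff(wide[1:2])
  expect_equal(area, 0.85, tolerance = 0.01)
  expect_error(broaden_spectrum(5, 1, 0, 0), "widths")
  expect_error(broaden_spectrum(c(1, 2), 1), "length")
})
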