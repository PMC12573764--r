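# Tamm-Dancoff solver: closed-form checks, core restriction, CIS limit.

test_that("H2 minimal-basis CIS roots match the two-orbital closed forms", {
  ints <- h2_mini()
  det <- run_scf(ints, "hf", scf_settings())
  arr <- nocicoox:::eri_array(ints)
  C <- det$Ca
  mo <- nocicoox:::.ao2mo4(arr, C, C, C, C)
  de <- det$eps_a[2] - det$eps_a[1]
  w_singlet <- de + 2 * mo[1, 2, 1, 2] - mo[1, 1, 2, 2]
  w_triplet <- de - mo[1, 1, 2, 2]
  ts <- solve_tda(det, ints, "hf", n_roots = 1, spin = "singlet")
  tt <- solve_tda(det, ints, "hf", n_roots = 1, spin = "triplet")
  expect_equal(ts$omega[1], w_singlet, tolerance = 1e-10)
  expect_equal(tt$omega[1], w_triplet, tolerance = 1e-10)
  # amplitude normalization over both spin channels
  a <- ts$amplitudes[[1]]
  expect_equal(sum(a$alpha^2) + sum(a$beta^2), 1, tolerance = 1e-10)
})

test_that("TDA energies from a stable reference are nonnegative and sorted", {
  ints <- water_mini()
  det <- water_hf()
  td <- solve_tda(det, ints, "hf", n_roots = 8)
  expect_true(all(td$omega >= 0))
  expect_true(all(diff(td$omega) >= -1e-12))
})

test_that("occupied-space restriction zeroes all other amplitudes (core-valence separation)", {
  ints <- water_mini()
  det <- water_hf()
  td <- solve_tda(det, ints, "hf", n_roots = 2, occupied_restriction = 1L)
  for (k in seq_along(td$omega)) {
    X <- td$amplitudes[[k]]$alpha
    expect_true(all(abs(X[, -1]) == 0))
  }
  # core roots lie far above valence roots
  tv <- solve_tda(det, ints, "hf", n_roots = 1)
  expect_gt(td$omega[1], tv$omega[1])
  expect_error(solve_tda(det, ints, "hf", occupied_restriction = 99L),
               "occupied")
})

test_that("root count is clipped with a warning when the space is smaller", {
  ints <- h2_mini()
  det <- run_scf(ints, "hf", scf_settings())
  expect_warning(td <- solve_tda(det, ints, "hf", n_roots = 50),
                 "clipped")
  expect_equal(length(td$omega), 1)
})

test_that("unrestricted TDA block matrix contains the spin-adapted roots", {
  # for a closed-shell reference the unrestricted alpha/beta block matrix
  # must reproduce the union of singlet and triplet spin-adapted roots
  ints <- h2_mini()
  det <- run_scf(ints, "hf", scf_settings())
  det_u <- det
  det_u$Cb <- det$Cb + 0  # same orbitals, but force the unrestricted path
  attr(det_u, "force_unres") <- TRUE
  ws <- solve_tda(det, ints, "hf", n_roots = 1, spin = "singlet")$omega
  wt <- solve_tda(det, ints, "hf", n_roots = 1, spin = "triplet")$omega
  # perturb the beta coefficients by a sign flip (same determinant) so the
  # restricted detection fails and the block path runs
  det_u$Cb[, 1] <- -det_u$Cb[, 1]
  wu <- solve_tda(det_u, ints, "hf", n_roots = 2)$omega
  expect_equal(sort(wu), sort(c(ws, wt)), tolerance = 1e-8)
})

test_that("TDA roots table reports energies in eV with assignments", {
  ints <- water_mini()
  det <- water_hf()
  td <- solve_tda(det, ints, "hf", n_roots = 4)
  tb <- tda_table(td)
  expect_equal(nrow(tb), 4)
  expect_equal(tb$energy_ev, hartree_to_ev(td$omega))
  expect_true(all(tb$dominant_i <= det$n_alpha))
  expect_true(all(tb$dominant_a > det$n_alpha))
})
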