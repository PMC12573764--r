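# Constraint potentials: projector structure, trace identities,
# spin symmetry, invariances.

test_that("single-orbital constraint traces are -1/2 on the ground state and +1/2 on the target", {
  det <- water_hf()
  ints <- water_mini()
  no <- det$n_alpha
  spec <- wc_single(ints$S, det$Ca, no, no + 1, no, "alpha")
  expect_equal(spec$Nc, 0.5)
  P <- nocicoox:::.det_density(det)
  expect_equal(constraint_value(P, spec), -0.5, tolerance = 1e-10)
  # swap occupation i -> a in the alpha channel
  det2 <- det
  det2$occ_a[no] <- 0; det2$occ_a[no + 1] <- 1
  P2 <- nocicoox:::.det_density(det2)
  expect_equal(constraint_value(P2, spec), 0.5, tolerance = 1e-10)
  # beta density under an alpha-only constraint contributes nothing
  expect_equal(sum(P$Pb * spec$Wc_b), 0)
  # index validation
  expect_error(wc_single(ints$S, det$Ca, no + 1, no + 2, no), "not occupied")
  expect_error(wc_single(ints$S, det$Ca, 1, no, no), "not virtual")
})

test_that("double-excitation constraint traces hit -1 / +1 and seniority is enforced", {
  det <- water_hf()
  ints <- water_mini()
  no <- det$n_alpha
  spec <- wc_double(ints$S, det$Ca, no, no, no + 1, no + 1, no)
  expect_equal(spec$Nc, 1)
  expect_identical(spec$provenance$seniority, 0L)
  P <- nocicoox:::.det_density(det)
  expect_equal(constraint_value(P, spec), -1, tolerance = 1e-10)
  det2 <- det
  det2$occ_a[no] <- 0; det2$occ_a[no + 1] <- 1
  det2$occ_b[no] <- 0; det2$occ_b[no + 1] <- 1
  expect_equal(constraint_value(nocicoox:::.det_density(det2), spec), 1,
               tolerance = 1e-10)
  # seniority-two: intended configuration also sits at the target value
  s2a <- wc_double(ints$S, det$Ca, no - 1, no, no + 1, no + 1, no)
  det3 <- det
  det3$occ_a[no - 1] <- 0; det3$occ_a[no + 1] <- 1
  det3$occ_b[no] <- 0; det3$occ_b[no + 1] <- 1
  expect_equal(constraint_value(nocicoox:::.det_density(det3), s2a), 1,
               tolerance = 1e-10)
  # seniority > 2 rejected
  expect_error(wc_double(ints$S, det$Ca, no - 1, no, no + 1, no + 2, no),
               "seniority")
})

test_that("constraint value is linear and zero for the zero density", {
  det <- water_hf()
  ints <- water_mini()
  no <- det$n_alpha
  spec <- wc_single(ints$S, det$Ca, no, no + 1, no, "alpha")
  M <- ints$M
  z <- matrix(0, M, M)
  expect_identical(constraint_value(list(Pa = z, Pb = z), spec), 0)
  set.seed(5)
  P1 <- list(Pa = crossprod(matrix(rnorm(M * M), M)),
             Pb = crossprod(matrix(rnorm(M * M), M)))
  P2 <- list(Pa = crossprod(matrix(rnorm(M * M), M)),
             Pb = crossprod(matrix(rnorm(M * M), M)))
  expect_equal(constraint_value(list(Pa = P1$Pa + P2$Pa, Pb = P1$Pb + P2$Pb),
                                spec),
               constraint_value(P1, spec) + constraint_value(P2, spec),
               tolerance = 1e-10)
})

test_that("Wc is invariant under MO sign flips and projector parts are S-orthogonal", {
  det <- water_hf()
  ints <- water_mini()
  no <- det$n_alpha
  spec <- wc_single(ints$S, det$Ca, no, no + 1, no, "alpha")
  Cflip <- det$Ca
  Cflip[, no] <- -Cflip[, no]
  Cflip[, no + 1] <- -Cflip[, no + 1]
  spec2 <- wc_single(ints$S, Cflip, no, no + 1, no, "alpha")
  expect_equal(spec2$Wc_a, spec$Wc_a, tolerance = 1e-12)
  # occupied/virtual projector parts mutually S-orthogonal
  ov <- sum((spec$dPo_a %*% ints$S) * t(spec$dPv_a %*% ints$S))
  expect_lt(abs(ov), 1e-10)
  expect_lt(max(abs(spec$Wc_a - t(spec$Wc_a))), 1e-12)
})

test_that("TDA-derived constraints collapse to outer products and obey spin rules", {
  det <- water_hf()
  ints <- water_mini()
  no <- det$n_alpha
  M <- ints$M
  nv <- M - no
  X1 <- matrix(0, nv, no)
  X1[1, no] <- 1 / sqrt(2)  # HOMO -> LUMO, split over both spins
  spec <- wc_from_tda(ints$S, list(alpha = det$Ca, beta = det$Cb),
                      list(alpha = X1, beta = X1),
                      list(alpha = no, beta = no), "singlet")
  expect_equal(spec$Nc, 0)
  expect_equal(spec$Wc_a, spec$Wc_b, tolerance = 1e-12)
  expect_equal(spec$dPv_a, 0.5 * tcrossprod(det$Ca[, no + 1]),
               tolerance = 1e-12)
  tri <- wc_from_tda(ints$S, list(alpha = det$Ca, beta = det$Cb),
                     list(alpha = X1, beta = X1),
                     list(alpha = no, beta = no), "triplet")
  expect_equal(tri$Wc_a, -tri$Wc_b, tolerance = 1e-12)
  # ground-state trace equals minus the occupied weight
  P <- nocicoox:::.det_density(det)
  expect_equal(constraint_value(P, spec), -1, tolerance = 1e-10)
  # unnormalized amplitudes rejected
  expect_error(wc_from_tda(ints$S, list(alpha = det$Ca, beta = det$Cb),
                           list(alpha = X1, beta = 2 * X1),
                           list(alpha = no, beta = no)),
               "not normalized")
})

test_that("Wc is invariant under orbital rotations with counter-rotated amplitudes", {
  # rotating degenerate virtual orbitals while counter-rotating the
  # amplitudes describes the same physical transition density, so the
  # constraint projectors must not change
  det <- water_hf()
  ints <- water_mini()
  no <- det$n_alpha
  M <- ints$M
  nv <- M - no
  set.seed(9)
  X <- matrix(rnorm(nv * no), nv, no)
  X <- X / sqrt(2 * sum(X^2))
  th <- 0.37
  Q <- diag(nv)
  Q[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Crot <- det$Ca
  Crot[, (no + 1):M] <- Crot[, (no + 1):M] %*% Q
  Xrot <- t(Q) %*% X
  mk <- function(C, Xs) {
    wc_from_tda(ints$S, list(alpha = C, beta = C),
                list(alpha = Xs, beta = Xs),
                list(alpha = no, beta = no))
  }
  w_orig <- mk(det$Ca, X)
  w_rot <- mk(Crot, Xrot)
  expect_equal(w_rot$Wc_a, w_orig$Wc_a, tolerance = 1e-10)
})
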