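# Nonorthogonal configuration interaction engine.
#
# Pairwise biorthogonalization of reference determinants by singular
# value decomposition of the occupied-MO overlap, generalized
# Slater-Condon overlap/Hamiltonian matrix elements (case analysis over
# vanishing singular values), spin expectation matrix elements for
# collinear unrestricted determinants, the multistate-DFT
# transition-density-functional correction for Kohn-Sham references,
# secular solution with canonical orthogonalization, transition
# densities, oscillator strengths and Voigt-broadened spectra.

.occ_coef <- function(det, spin) {
  if (spin == "alpha") det$Ca[, det$occ_a > 0.5, drop = FALSE]
  else det$Cb[, det$occ_b > 0.5, drop = FALSE]
}

#' Biorthogonalize two determinants
#'
#' Singular value decomposition of the occupied-MO overlap per spin,
#' `S_MO = C_I^T S_AO C_J = U diag(sigma) V^T`, with transformed
#' coefficients `C_I U` and `C_J V` and the pair phase
#' `sign(det U * det V^T)`.  Singular values are non-negative and
#' descending, so zeros appear last; values below `sigma_threshold` are
#' flagged as zeros.
#'
#' @param det_I,det_J `Determinant` objects with integer occupations
#' @param S_AO AO overlap matrix
#' @param sigma_threshold orthogonality threshold for singular values
#' @return object of class `BiorthogonalPair`: per spin `sigma`, `CtI`,
#'   `CtJ`, `zero_idx`; plus `phase`, `overlap`, `S_red` (phase times the
#'   product of non-zero singular values) and `n_zero`
#' @export
biorthogonalize <- function(det_I, det_J, S_AO, sigma_threshold = 1e-6) {
  if (det_I$n_alpha != det_J$n_alpha || det_I$n_beta != det_J$n_beta) {
    stop("incompatible determinants: electron counts differ")
  }
  one_spin <- function(spin) {
    CI <- .occ_coef(det_I, spin)
    CJ <- .occ_coef(det_J, spin)
    if (ncol(CI) == 0) {
      return(list(sigma = numeric(0), CtI = CI, CtJ = CJ,
                  zero_idx = integer(0), phase = 1))
    }
    Smo <- t(CI) %*% S_AO %*% CJ
    sv <- svd(Smo)
    phase <- sign(det(sv$u) * det(sv$v))
    list(sigma = sv$d, CtI = CI %*% sv$u, CtJ = CJ %*% sv$v,
         zero_idx = which(sv$d < sigma_threshold), phase = phase)
  }
  a <- one_spin("alpha")
  b <- one_spin("beta")
  phase <- a$phase * b$phase
  nz <- length(a$zero_idx) + length(b$zero_idx)
  S_red <- phase *
    prod(a$sigma[setdiff(seq_along(a$sigma), a$zero_idx)]) *
    prod(b$sigma[setdiff(seq_along(b$sigma), b$zero_idx)])
  ov <- if (nz > 0) 0 else phase * prod(a$sigma) * prod(b$sigma)
  structure(list(alpha = a, beta = b, phase = phase, overlap = ov,
                 S_red = S_red, n_zero = nz,
                 sigma_threshold = sigma_threshold),
            class = "BiorthogonalPair")
}

#' Overlap matrix element of a biorthogonal pair
#'
#' `<Phi_I|Phi_J> = +- prod_i sigma_i^alpha prod_j sigma_j^beta`, zero
#' whenever any singular value is flagged zero.
#'
#' @param pair a `BiorthogonalPair`
#' @return numeric overlap
#' @export
overlap_element <- function(pair) pair$overlap

# weighted codensities (over non-zero singular values) and dyadics
.codensities <- function(pair) {
  per_spin <- function(s) {
    keep <- setdiff(seq_along(s$sigma), s$zero_idx)
    W <- if (length(keep)) {
      s$CtI[, keep, drop = FALSE] %*%
        (t(s$CtJ[, keep, drop = FALSE]) / s$sigma[keep])
    } else {
      matrix(0, nrow(s$CtI), nrow(s$CtI))
    }
    D <- lapply(s$zero_idx, function(k) tcrossprod(s$CtI[, k], s$CtJ[, k]))
    list(W = W, D = D)
  }
  a <- per_spin(pair$alpha)
  b <- per_spin(pair$beta)
  list(alpha = a, beta = b, W_tot = a$W + b$W)
}

# elementwise contraction sum(A_{mn} B_{mn})
.tr12 <- function(A, B) sum(A * B)

#' Hamiltonian matrix element between nonorthogonal determinants
#'
#' Generalized Slater-Condon rules in the biorthogonal representation,
#' with the case analysis over zero singular values: no zeros (full
#' expression including nuclear repulsion), one zero in either spin, two
#' zeros in one spin, one zero in each spin, and zero for three or more.
#' Exchange always enters with the full Hartree-Fock operator; the
#' reference functional only enters through the separate
#' transition-density-functional correction.
#'
#' @param pair a `BiorthogonalPair`
#' @param cod codensities from the pair (internal; pass `NULL` to
#'   recompute)
#' @param ints an `AOIntegrals`
#' @return `<Phi_I|H|Phi_J>` in Hartree
#' @export
hf_matrix_element <- function(pair, cod = NULL, ints) {
  if (is.null(cod)) cod <- .codensities(pair)
  za <- length(pair$alpha$zero_idx)
  zb <- length(pair$beta$zero_idx)
  nz <- za + zb
  if (nz >= 3 || za >= 3 || zb >= 3) return(0)
  h <- ints$hcore
  S_red <- pair$S_red
  if (nz == 0) {
    Wt <- cod$W_tot
    jk <- jk_build(ints, list(Wt, t(cod$alpha$W), t(cod$beta$W)))
    J <- jk$J[[1]]
    Ka <- jk$K[[2]]; Kb <- jk$K[[3]]
    e1 <- .tr12(Wt, h)
    e2 <- 0.5 * (.tr12(Wt, J) - .tr12(cod$alpha$W, Ka) -
                   .tr12(cod$beta$W, Kb))
    return(pair$overlap * (e1 + e2 + ints$Vnn))
  }
  if (nz == 1) {
    if (za == 1) {
      D <- cod$alpha$D[[1]]
      Wsame <- cod$alpha$W
    } else {
      D <- cod$beta$D[[1]]
      Wsame <- cod$beta$W
    }
    jk <- jk_build(ints, list(cod$W_tot, t(Wsame)))
    return(S_red * (.tr12(D, h) + .tr12(D, jk$J[[1]]) - .tr12(D, jk$K[[2]])))
  }
  # two zeros
  if (za == 2 || zb == 2) {
    Ds <- if (za == 2) cod$alpha$D else cod$beta$D
    jk <- jk_build(ints, list(Ds[[2]], t(Ds[[2]])))
    return(S_red * (.tr12(Ds[[1]], jk$J[[1]]) - .tr12(Ds[[1]], jk$K[[2]])))
  }
  # one zero in each spin: Coulomb-only coupling
  Da <- cod$alpha$D[[1]]; Db <- cod$beta$D[[1]]
  jk <- jk_build(ints, list(Db))
  S_red * .tr12(Da, jk$J[[1]])
}

#' Transition-density-functional correction for Kohn-Sham references
#'
#' Adds Kohn-Sham correlation content to the off-diagonal Hamiltonian.
#' `dEc[Phi] = E_KS[rho] - E_HF[Phi]` is the difference between the KS
#' and HF total energies evaluated with the same (KS) determinant.
#' Determinant-weighted mode:
#' `H_IJ/(E_HF_I + E_HF_J) * (dEc_I + dEc_J)`; overlap-weighted mode:
#' `S_IJ/2 * (dEc_I + dEc_J)`.  The determinant-weighted correction
#' restores the diagonal identity `H_II = E_KS[rho_I]` exactly.
#'
#' @param det_I,det_J `Determinant`s with `E_KS` and `E_HF` stored
#' @param hf_element `<Phi_I|H|Phi_J>`
#' @param overlap `<Phi_I|Phi_J>`
#' @param mode `"determinant"` or `"overlap"`
#' @return correction in Hartree (zero for pure HF references)
#' @export
tdf_correction <- function(det_I, det_J, hf_element, overlap,
                           mode = c("determinant", "overlap")) {
  mode <- match.arg(mode)
  dEc <- (det_I$E_KS - det_I$E_HF) + (det_J$E_KS - det_J$E_HF)
  if (abs(dEc) < 1e-14) return(0)
  if (mode == "determinant") {
    den <- det_I$E_HF + det_J$E_HF
    if (abs(den) < 1e-10) stop("degenerate normalization in determinant-weighted TDF")
    hf_element / den * dEc
  } else {
    overlap / 2 * dEc
  }
}

#' Spin-squared matrix element between nonorthogonal determinants
#'
#' For collinear (same-Sz) unrestricted determinants, from the operator
#' identity `S^2 = Sz(Sz+1) + S- S+` evaluated with generalized Wick
#' contractions in the biorthogonal representation.  Reduces to the
#' standard single-determinant expression on the diagonal.
#'
#' @param pair a `BiorthogonalPair` for (det_I, det_J)
#' @param det_I,det_J the determinants
#' @param S_AO AO overlap matrix
#' @return `<Phi_I|S^2|Phi_J>`
#' @export
s2_matrix_element <- function(pair, det_I, det_J, S_AO) {
  na <- det_I$n_alpha; nb <- det_I$n_beta
  sz <- (na - nb) / 2
  cod <- .codensities(pair)
  za <- length(pair$alpha$zero_idx)
  zb <- length(pair$beta$zero_idx)
  cross <- function(A, B) {
    # tr(A_orth B_orth) for AO-represented transition densities
    sum((A %*% S_AO) * t(B %*% S_AO))
  }
  if (za + zb == 0) {
    ov <- pair$overlap
    return(ov * (sz * (sz + 1) + nb) - ov * cross(cod$alpha$W, cod$beta$W))
  }
  if (za + zb == 1) {
    if (za == 1) {
      return(-pair$S_red * cross(cod$alpha$D[[1]], cod$beta$W))
    }
    return(-pair$S_red * cross(cod$alpha$W, cod$beta$D[[1]]))
  }
  if (za == 1 && zb == 1) {
    return(-pair$S_red * cross(cod$alpha$D[[1]], cod$beta$D[[1]]))
  }
  0
}

# pairwise one-particle transition density in the AO basis, per spin;
# NULL when more than one singular value vanishes
.pair_transition_density <- function(pair, cod = NULL) {
  if (is.null(cod)) cod <- .codensities(pair)
  za <- length(pair$alpha$zero_idx)
  zb <- length(pair$beta$zero_idx)
  if (za + zb == 0) {
    list(alpha = pair$overlap * cod$alpha$W, beta = pair$overlap * cod$beta$W)
  } else if (za == 1 && zb == 0) {
    list(alpha = pair$S_red * cod$alpha$D[[1]],
         beta = matrix(0, nrow(cod$alpha$W), ncol(cod$alpha$W)))
  } else if (zb == 1 && za == 0) {
    list(alpha = matrix(0, nrow(cod$beta$W), ncol(cod$beta$W)),
         beta = pair$S_red * cod$beta$D[[1]])
  } else {
    NULL
  }
}

#' Assemble and solve the NOCI secular problem
#'
#' Builds the pairwise overlap and Hamiltonian matrices over a list of
#' reference determinants (generalized Slater-Condon elements plus the
#' transition-density-functional correction for Kohn-Sham references),
#' solves the generalized eigenproblem `H C = S C E` by symmetric
#' orthogonalization -- discarding overlap eigenvalues below
#' `lin_dep_threshold` via canonical orthogonalization -- and computes
#' per-state spin expectation values.
#'
#' @param dets list of `Determinant`s with equal electron counts
#' @param ints an `AOIntegrals`
#' @param fn the reference `FunctionalSpec` (or name); `"hf"` disables
#'   the TDF correction
#' @param sigma_threshold singular-value orthogonality threshold
#' @param lin_dep_threshold canonical-orthogonalization cutoff on
#'   overlap eigenvalues
#' @param tdf_mode `"determinant"` or `"overlap"`
#' @return object of class `NOCIResult`: `energies` (Hartree,
#'   ascending), `coef` (S-normalized CI coefficients, one column per
#'   state), `H`, `S`, `s2` per state, `pair_info`, `n_discarded`
#' @export
assemble_and_solve <- function(dets, ints, fn = "hf",
                               sigma_threshold = 1e-6,
                               lin_dep_threshold = 1e-8,
                               tdf_mode = "determinant") {
  if (!inherits(fn, "FunctionalSpec")) fn <- functional_spec(fn)
  n <- length(dets)
  if (n < 1) stop("need at least one determinant")
  H <- matrix(0, n, n)
  S <- matrix(0, n, n)
  S2 <- matrix(0, n, n)
  pair_info <- list()
  use_tdf <- fn$semilocal
  for (i in seq_len(n)) {
    for (j in i:n) {
      pr <- biorthogonalize(dets[[i]], dets[[j]], ints$S, sigma_threshold)
      cod <- .codensities(pr)
      hij <- hf_matrix_element(pr, cod, ints)
      ov <- overlap_element(pr)
      if (use_tdf) {
        hij <- hij + tdf_correction(dets[[i]], dets[[j]], hij, ov,
                                    mode = tdf_mode)
      }
      s2ij <- s2_matrix_element(pr, dets[[i]], dets[[j]], ints$S)
      H[i, j] <- H[j, i] <- hij
      S[i, j] <- S[j, i] <- ov
      S2[i, j] <- S2[j, i] <- s2ij
      pair_info[[paste(i, j)]] <- list(n_zero = pr$n_zero,
                                       phase = pr$phase)
    }
  }
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- es$values > lin_dep_threshold
  if (!any(keep)) stop("all overlap eigenvalues below the linear-dependence threshold")
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Ht <- t(X) %*% H %*% X
  Ht <- (Ht + t(Ht)) / 2
  eh <- eigen(Ht, symmetric = TRUE)
  o <- order(eh$values)
  eh$values <- eh$values[o]
  eh$vectors <- eh$vectors[, o, drop = FALSE]
  C <- X %*% eh$vectors
  s2 <- vapply(seq_len(ncol(C)),
               function(k) as.numeric(t(C[, k]) %*% S2 %*% C[, k]),
               numeric(1))
  structure(
    list(energies = eh$values, coef = C, H = H, S = S, S2 = S2, s2 = s2,
         n_discarded = sum(!keep), dets = dets,
         sigma_threshold = sigma_threshold,
         lin_dep_threshold = lin_dep_threshold,
         tdf = if (use_tdf) tdf_mode else "none"),
    class = "NOCIResult"
  )
}

#' @export
print.NOCIResult <- function(x, ...) {
  cat(sprintf("NOCI over %d determinants (%d state(s) discarded)\n",
              length(x$dets), x$n_discarded))
  de <- hartree_to_ev(x$energies - x$energies[1])
  for (k in seq_along(x$energies)) {
    cat(sprintf("  state %2d  E = %.8f Ha  dE = %8.4f eV  <S^2> = %7.4f\n",
                k - 1, x$energies[k], de[k], x$s2[k]))
  }
  invisible(x)
}

#' Transition dipoles and oscillator strengths
#'
#' Assembles one-particle transition densities between the NOCI ground
#' state and each excited state from the pairwise biorthogonal
#' couplings, and forms length-gauge transition dipoles and oscillator
#' strengths `f = 2/3 dE |mu|^2` (atomic units).
#'
#' @param result a `NOCIResult`
#' @param ints an `AOIntegrals`
#' @return data.frame: state, dE (eV), transition dipole components
#'   (a.u.), oscillator strength
#' @export
transition_properties <- function(result, ints) {
  dets <- result$dets
  n <- length(dets)
  M <- ints$M
  nst <- length(result$energies)
  # cache pairwise transition densities for ordered pairs
  gam <- array(0, c(n, n, 2, M, M))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pr <- biorthogonalize(dets[[i]], dets[[j]], ints$S,
                          result$sigma_threshold)
    td <- .pair_transition_density(pr)
    if (!is.null(td)) {
      gam[i, j, 1, , ] <- td$alpha
      gam[i, j, 2, , ] <- td$beta
    }
  }
  out <- data.frame()
  C <- result$coef
  for (st in seq_len(nst)) {
    g <- matrix(0, M, M)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      w <- C[i, st] * C[j, 1]
      if (abs(w) < 1e-14) next
      g <- g + w * (gam[i, j, 1, , ] + gam[i, j, 2, , ])
    }
    mu <- -c(.tr12(g, ints$dip$x), .tr12(g, ints$dip$y), .tr12(g, ints$dip$z))
    if (st == 1) {
      # add the nuclear dipole on the diagonal
      xyz <- ang_to_bohr(ints$mol$coords)
      mu <- mu + colSums(xyz * ints$mol$Z)
    }
    dE <- result$energies[st] - result$energies[1]
    f <- if (st == 1) 0 else (2 / 3) * dE * sum(mu^2)
    out <- rbind(out, data.frame(
      state = st - 1, dE_ev = hartree_to_ev(dE),
      mu_x = mu[1], mu_y = mu[2], mu_z = mu[3],
      osc_strength = f))
  }
  out
}

#' Voigt-broadened spectrum from stick energies and strengths
#'
#' Each stick is convolved with a Voigt profile (Gaussian and Lorentzian
#' half-widths-at-half-maximum in eV) normalized to integrate to the
#' stick strength.
#'
#' @param energies_ev stick positions (eV)
#' @param strengths stick strengths
#' @param gaussian_hwhm,lorentzian_hwhm HWHM of the Gaussian and
#'   Lorentzian components (eV); one of them may be zero
#' @param grid evaluation energies (eV); defaults to a 2000-point grid
#'   padded around the sticks
#' @return data.frame `energy_ev`, `intensity`
#' @export
broaden_spectrum <- function(energies_ev, strengths, gaussian_hwhm = 0.15,
                             lorentzian_hwhm = 0.15, grid = NULL) {
  if (length(energies_ev) != length(strengths)) {
    stop("energy and strength lists differ in length")
  }
  if (gaussian_hwhm < 0 || lorentzian_hwhm < 0 ||
      (gaussian_hwhm == 0 && lorentzian_hwhm == 0)) {
    stop("broadening widths must be positive")
  }
  if (is.null(grid)) {
    pad <- 5 * (gaussian_hwhm + lorentzian_hwhm) + 0.5
    grid <- seq(min(energies_ev) - pad, max(energies_ev) + pad,
                length.out = 2000)
  }
  sigma <- gaussian_hwhm / sqrt(2 * log(2))
  gamma <- lorentzian_hwhm
  profile <- function(x) {
    if (sigma == 0) {
      return(gamma / (pi * (x^2 + gamma^2)))
    }
    out <- numeric(length(x))
    z <- (x + 1i * gamma) / (sigma * sqrt(2))
    # Faddeeva evaluation in the reliable range, Lorentzian-like
    # asymptotics far in the wings (|z| large)
    near <- Mod(z) < 12
    if (any(near)) {
      zn <- z[near]
      w <- exp(-zn^2) * (1 - pracma::erfz(-1i * zn))
      out[near] <- Re(w) / (sigma * sqrt(2 * pi))
    }
    if (any(!near)) {
      zf <- z[!near]
      w <- 1i / (sqrt(pi) * zf) * (1 + 1 / (2 * zf^2))
      out[!near] <- Re(w) / (sigma * sqrt(2 * pi))
    }
    out
  }
  intensity <- numeric(length(grid))
  for (k in seq_along(energies_ev)) {
    intensity <- intensity + strengths[k] * profile(grid - energies_ev[k])
  }
  data.frame(energy_ev = grid, intensity = intensity)
}
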