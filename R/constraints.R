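# Construction of density-constraint potentials Wc and target values Nc
# for orbital-optimized excitations.
#
# The constraint potential is the static (unrelaxed) part of a difference
# density, sandwiched with the AO overlap:
#   Wc^tau = S_AO (dP_virt^tau - dP_occ^tau) S_AO
# For TDA-derived constraints the difference densities come from the
# transition amplitudes and Nc = 0.  For explicit single-orbital
# transitions (the "Delta" flavour used for NOCI reference states) the
# difference densities are outer products of ground-state MO columns with
# a normalization factor of 1/2, giving Nc = 1/2; seniority-restricted
# doubles carry Nc = 1.

.constraint_spec <- function(Wc_a, Wc_b, Nc, dPv_a, dPv_b, dPo_a, dPo_b,
                             spin_mode, provenance) {
  structure(list(Wc_a = Wc_a, Wc_b = Wc_b, Nc = Nc,
                 dPv_a = dPv_a, dPv_b = dPv_b,
                 dPo_a = dPo_a, dPo_b = dPo_b,
                 spin_mode = spin_mode, provenance = provenance),
            class = "ConstraintSpec")
}

#' @export
print.ConstraintSpec <- function(x, ...) {
  cat(sprintf("ConstraintSpec: Nc = %g, spin mode '%s' (%s)\n",
              x$Nc, x$spin_mode,
              paste(deparse(x$provenance, width.cutoff = 60), collapse = "")))
  invisible(x)
}

#' Constraint from TDA transition amplitudes
#'
#' Builds the static difference densities from MO coefficients and
#' normalized TDA amplitudes (`sum_{ai,tau} X_ai^2 = 1`), giving
#' `Wc = S (dP_virt - dP_occ) S` per spin and a target value `Nc = 0`.
#' For singlet spin mode the two spin channels are identical; for
#' triplets `Wc^alpha = -Wc^beta`.
#'
#' @param S_AO AO overlap matrix
#' @param C MO coefficients: `list(alpha =, beta =)`
#' @param X amplitudes: `list(alpha =, beta =)`, each a (nvirt x nocc)
#'   matrix indexed (a, i)
#' @param occ occupied counts: `list(alpha =, beta =)`
#' @param spin_mode `"singlet"` or `"triplet"`
#' @return a `ConstraintSpec` with `Nc = 0`
#' @export
wc_from_tda <- function(S_AO, C, X, occ, spin_mode = "singlet") {
  nrm <- sum(vapply(X, function(x) sum(x^2), numeric(1)))
  if (abs(nrm - 1) > 1e-8) stop("TDA amplitudes not normalized")
  mk <- function(Cs, Xs, no) {
    if (is.null(Xs) || length(Xs) == 0) {
      z <- matrix(0, nrow(S_AO), nrow(S_AO))
      return(list(v = z, o = z))
    }
    M <- nrow(Cs)
    Co <- Cs[, seq_len(no), drop = FALSE]
    Cv <- Cs[, (no + 1):ncol(Cs), drop = FALSE]
    if (nrow(Xs) != ncol(Cv) || ncol(Xs) != no) {
      stop("amplitude/coefficient dimension mismatch")
    }
    dPv <- Cv %*% (Xs %*% t(Xs)) %*% t(Cv)
    dPo <- Co %*% (t(Xs) %*% Xs) %*% t(Co)
    list(v = dPv, o = dPo)
  }
  a <- mk(C$alpha, X$alpha, occ$alpha)
  b <- mk(C$beta, X$beta %||% X$alpha, occ$beta)
  Wa <- S_AO %*% (a$v - a$o) %*% S_AO
  Wb <- S_AO %*% (b$v - b$o) %*% S_AO
  if (spin_mode == "triplet") Wb <- -Wb
  .constraint_spec((Wa + t(Wa)) / 2, (Wb + t(Wb)) / 2, 0,
                   a$v, b$v, a$o, b$o, spin_mode,
                   list(kind = "tda"))
}

#' Single-orbital transition constraint
#'
#' Difference densities `dP_virt = 1/2 C_a C_a^T`, `dP_occ = 1/2 C_i
#' C_i^T` on one spin channel only, with target `Nc = 1/2`: the
#' converged solution depopulates orbital `i` and populates orbital `a`
#' in the chosen spin sector.
#'
#' @param S_AO AO overlap matrix
#' @param C MO coefficient matrix of the chosen spin
#' @param i occupied orbital index (in the reference determinant)
#' @param a virtual orbital index
#' @param n_occ number of occupied orbitals in that spin channel
#' @param spin `"alpha"` or `"beta"`
#' @return a `ConstraintSpec` with `Nc = 1/2`
#' @export
wc_single <- function(S_AO, C, i, a, n_occ, spin = "alpha") {
  if (i < 1 || i > n_occ) stop("index i = ", i, " is not occupied")
  if (a <= n_occ || a > ncol(C)) stop("index a = ", a, " is not virtual")
  dPv <- 0.5 * tcrossprod(C[, a])
  dPo <- 0.5 * tcrossprod(C[, i])
  W <- S_AO %*% (dPv - dPo) %*% S_AO
  W <- (W + t(W)) / 2
  z <- matrix(0, nrow(W), ncol(W))
  if (spin == "alpha") {
    .constraint_spec(W, z, 0.5, dPv, z, dPo, z, "alpha-only",
                     list(kind = "single", i = i, a = a, spin = "alpha"))
  } else {
    .constraint_spec(z, W, 0.5, z, dPv, z, dPo, "beta-only",
                     list(kind = "single", i = i, a = a, spin = "beta"))
  }
}

#' Double-excitation constraint (seniority zero or two)
#'
#' Spin-independent difference densities applied to both spin channels
#' with target `Nc = 1`.  Patterns are restricted to seniority zero
#' (`i = j`, `a = b`) and seniority two (exactly one coincident pair).
#' For the paired double (`i = j`, `a = b`) the difference densities are
#' `dP_virt = 1/2 C_a C_a^T`, `dP_occ = 1/2 C_i C_i^T`, so the fully
#' doubly-excited density sits exactly at the target value 1; for
#' seniority-two patterns the two listed orbitals enter with weight 1/2
#' each, which again places the intended configuration at value 1.
#'
#' @param S_AO AO overlap matrix
#' @param C MO coefficient matrix (shared by both spins)
#' @param i,j occupied orbital indices
#' @param a,b virtual orbital indices
#' @param n_occ number of occupied orbitals
#' @return a `ConstraintSpec` with `Nc = 1`
#' @export
wc_double <- function(S_AO, C, i, j, a, b, n_occ) {
  if (i > n_occ || j > n_occ || i < 1 || j < 1) stop("i, j must be occupied")
  if (a <= n_occ || b <= n_occ) stop("a, b must be virtual")
  seniority <- .double_seniority(i, j, a, b)
  if (is.na(seniority)) {
    stop("unsupported excitation pattern: only seniority 0 or 2 doubles")
  }
  if (seniority == 0) {
    dPv <- 0.5 * tcrossprod(C[, a])
    dPo <- 0.5 * tcrossprod(C[, i])
  } else {
    dPv <- 0.5 * (tcrossprod(C[, a]) + tcrossprod(C[, b]))
    dPo <- 0.5 * (tcrossprod(C[, i]) + tcrossprod(C[, j]))
  }
  W <- S_AO %*% (dPv - dPo) %*% S_AO
  W <- (W + t(W)) / 2
  .constraint_spec(W, W, 1, dPv, dPv, dPo, dPo, "singlet",
                   list(kind = "double", i = i, j = j, a = a, b = b,
                        seniority = seniority))
}

# seniority of a double-excitation pattern; NA if beyond two
.double_seniority <- function(i, j, a, b) {
  if (i == j && a == b) return(0L)
  if (xor(i == j, a == b)) return(2L)
  NA_integer_
}

#' Constraint value of a pair of spin densities
#'
#' `sum_tau Tr[P^tau Wc^tau]`, the quantity constrained to `Nc`.
#'
#' @param P list with `Pa` and `Pb` spin density matrices (or a single
#'   matrix used for both channels)
#' @param spec a `ConstraintSpec`
#' @return numeric constraint value
#' @export
constraint_value <- function(P, spec) {
  if (is.matrix(P)) P <- list(Pa = P, Pb = P)
  if (!all(dim(P$Pa) == dim(spec$Wc_a))) stop("dimension mismatch")
  sum(P$Pa * spec$Wc_a) + sum(P$Pb * spec$Wc_b)
}
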