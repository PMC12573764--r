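# Atomic-orbital backend interface: integrals, J/K builds, and
# exchange-correlation evaluation.  All quantities in Hartree atomic units.

#' Build atomic-orbital integrals
#'
#' Computes the AO overlap, core Hamiltonian (kinetic + nuclear
#' attraction), nuclear repulsion, dipole-moment integrals, and the full
#' set of two-electron repulsion integrals (packed, 8-fold symmetry,
#' Schwarz-screened) for a molecule.
#'
#' @param mol a `Molecule`
#' @param basis basis family name (see [build_basis()]) or a `BasisSet`
#' @param screen_tol integral screening threshold in a.u. (default 1e-10)
#' @return object of class `AOIntegrals` with fields `S`, `T`, `Vne`,
#'   `hcore`, `Vnn`, `dip` (list x/y/z), `eri` (packed vector), `M`,
#'   `basis`, `mol`
#' @export
build_ao_integrals <- function(mol, basis = "mini", screen_tol = 1e-10) {
  if (!inherits(basis, "BasisSet")) basis <- build_basis(mol, basis)
  xyz <- ang_to_bohr(mol$coords)
  one <- .cpp_one_electron(unclass(basis), xyz, as.numeric(mol$Z))
  eri <- .cpp_eri_packed(unclass(basis), screen_tol)
  Vnn <- 0
  n <- nrow(xyz)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        Vnn <- Vnn + mol$Z[i] * mol$Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      }
    }
  }
  structure(
    list(S = one$S, T = one$T, Vne = one$V, hcore = one$T + one$V,
         Vnn = Vnn, dip = list(x = one$dip_x, y = one$dip_y, z = one$dip_z),
         eri = eri, M = basis$M, basis = basis, mol = mol,
         screen_tol = screen_tol),
    class = "AOIntegrals"
  )
}

#' @export
print.AOIntegrals <- function(x, ...) {
  cat(sprintf("AOIntegrals: M = %d ('%s'), V_NN = %.8f Hartree\n",
              x$M, x$basis$name, x$Vnn))
  invisible(x)
}

#' Coulomb and exchange builds
#'
#' Forms J[P] and K[P] from the packed two-electron integrals for one or
#' more (not necessarily symmetric) density-like matrices.
#'
#' @param ints an `AOIntegrals`
#' @param P a matrix or list of matrices
#' @param thresh contribution screening threshold
#' @return for a single matrix, `list(J =, K =)`; for a list input,
#'   `list(J = list, K = list)`
#' @export
jk_build <- function(ints, P, thresh = 1e-14) {
  single <- is.matrix(P)
  Plist <- if (single) list(P) else P
  res <- .cpp_jk_build(ints$eri, ints$M, Plist, thresh)
  if (single) list(J = res$J[[1]], K = res$K[[1]]) else res
}

# dense ERI array for small problems (oracle, TDA transforms)
eri_array <- function(ints, guard = 42) {
  M <- ints$M
  if (M > guard) stop("dense ERI array requested for M = ", M,
                      " (guard ", guard, ")")
  arr <- array(0, c(M, M, M, M))
  pr <- function(i, j) if (i >= j) i * (i - 1) / 2 + j else j * (j - 1) / 2 + i
  e <- ints$eri
  for (i in 1:M) for (j in 1:i) {
    ij <- pr(i, j)
    for (k in 1:i) for (l in 1:k) {
      kl <- pr(k, l)
      if (kl > ij) next
      v <- e[(ij * (ij - 1)) / 2 + kl]
      arr[i, j, k, l] <- v; arr[j, i, k, l] <- v
      arr[i, j, l, k] <- v; arr[j, i, l, k] <- v
      arr[k, l, i, j] <- v; arr[l, k, i, j] <- v
      arr[k, l, j, i] <- v; arr[l, k, j, i] <- v
    }
  }
  arr
}

#' Exchange-correlation functional specification
#'
#' Supported: `"hf"` (pure exact exchange, no semilocal part), `"svwn5"`
#' (Slater exchange + VWN5 correlation), `"pbe"`, `"pbe0"` (25% exact
#' exchange), `"pbe50"` (50% exact exchange).
#'
#' @param name functional name (case-insensitive)
#' @return object of class `FunctionalSpec` with the global
#'   exact-exchange fraction `exx` and semilocal component scales
#' @export
functional_spec <- function(name) {
  nm <- tolower(name)
  par <- switch(nm,
    hf = list(exx = 1, x_slater = 0, x_pbe = 0, c_vwn5 = 0, c_pbe = 0),
    svwn5 = ,
    lda = list(exx = 0, x_slater = 1, x_pbe = 0, c_vwn5 = 1, c_pbe = 0),
    pbe = list(exx = 0, x_slater = 0, x_pbe = 1, c_vwn5 = 0, c_pbe = 1),
    pbe0 = list(exx = 0.25, x_slater = 0, x_pbe = 0.75, c_vwn5 = 0, c_pbe = 1),
    pbe50 = list(exx = 0.5, x_slater = 0, x_pbe = 0.5, c_vwn5 = 0, c_pbe = 1),
    stop("unsupported functional: ", name)
  )
  if (par$exx < 0 || par$exx > 1) stop("exact-exchange fraction out of [0,1]")
  structure(c(list(name = nm), par,
              list(semilocal = (par$x_slater + par$x_pbe +
                                  par$c_vwn5 + par$c_pbe) > 0)),
            class = "FunctionalSpec")
}

#' @export
print.FunctionalSpec <- function(x, ...) {
  cat(sprintf("FunctionalSpec '%s': %.0f%% exact exchange, semilocal: %s\n",
              x$name, 100 * x$exx, x$semilocal))
  invisible(x)
}

#' Evaluate the semilocal exchange-correlation energy and potential
#'
#' Numerical quadrature on a Becke-partitioned molecular grid.  For pure
#' Hartree-Fock specifications the semilocal contribution is identically
#' zero.
#'
#' @param grid a molecular grid from [build_grid()] (or an `AOIntegrals`,
#'   in which case a default grid is built and cached)
#' @param P_alpha,P_beta spin density matrices
#' @param fn a `FunctionalSpec`
#' @return `list(Exc =, Vxc_a =, Vxc_b =, n_alpha =, n_beta =)`; the last
#'   two are the numerically integrated electron counts (grid diagnostics)
#' @export
xc_eval <- function(grid, P_alpha, P_beta, fn) {
  if (!inherits(fn, "FunctionalSpec")) fn <- functional_spec(fn)
  if (!fn$semilocal) {
    M <- nrow(P_alpha)
    z <- matrix(0, M, M)
    return(list(Exc = 0, Vxc_a = z, Vxc_b = z,
                n_alpha = NA_real_, n_beta = NA_real_))
  }
  if (inherits(grid, "AOIntegrals")) grid <- default_grid(grid)
  par <- list(x_slater = fn$x_slater, x_pbe = fn$x_pbe,
              c_vwn5 = fn$c_vwn5, c_pbe = fn$c_pbe)
  .cpp_xc_eval(unclass(grid$basis), grid$points, grid$weights,
               P_alpha, P_beta, par)
}

# grid cache on an AOIntegrals object (environment-free: recompute)
default_grid <- function(ints, level = "medium") {
  build_grid(ints$mol, ints$basis, level = level)
}
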