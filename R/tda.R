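# Tamm-Dancoff (CIS-like) excitation solver.
#
# Kernel: orbital-energy differences + Hartree coupling + scaled exact
# exchange (the exchange fraction of the reference functional).  With
# 100% exact exchange this is exactly CIS.  Dense diagonalization with a
# size guard; the occupied space can be restricted to selected orbitals
# (core-valence separation for core excitations).

# successive-index AO->MO quarter transforms on a dense ERI array
.ao2mo4 <- function(arr, C1, C2, C3, C4) {
  M <- dim(arr)[1]
  t1 <- t(C1) %*% matrix(arr, M, M^3)                     # (p, nu lam sig)
  a1 <- array(t1, c(ncol(C1), M, M, M))
  a1 <- aperm(a1, c(2, 1, 3, 4))                          # (nu, p, lam, sig)
  t2 <- t(C2) %*% matrix(a1, M, ncol(C1) * M * M)
  a2 <- array(t2, c(ncol(C2), ncol(C1), M, M))            # (q, p, lam, sig)
  a2 <- aperm(a2, c(3, 1, 2, 4))                          # (lam, q, p, sig)
  t3 <- t(C3) %*% matrix(a2, M, ncol(C2) * ncol(C1) * M)
  a3 <- array(t3, c(ncol(C3), ncol(C2), ncol(C1), M))     # (r, q, p, sig)
  a3 <- aperm(a3, c(4, 1, 2, 3))                          # (sig, r, q, p)
  t4 <- t(C4) %*% matrix(a3, M, ncol(C3) * ncol(C2) * ncol(C1))
  a4 <- array(t4, c(ncol(C4), ncol(C3), ncol(C2), ncol(C1)))  # (s, r, q, p)
  aperm(a4, c(4, 3, 2, 1))                                # (p, q, r, s)
}

#' Solve the Tamm-Dancoff excitation problem
#'
#' @param det converged reference `Determinant`
#' @param ints an `AOIntegrals`
#' @param fn a `FunctionalSpec` (or name); only its exact-exchange
#'   fraction enters the coupling kernel
#' @param n_roots number of roots requested (clipped with a warning if it
#'   exceeds the excitation-space dimension)
#' @param occupied_restriction integer vector of allowed occupied spatial
#'   orbital indices (e.g. a single core orbital), or `NULL` for all
#' @param spin `"singlet"` or `"triplet"` coupling for spin-adapted
#'   (restricted closed-shell) references; ignored for unrestricted
#'   references, which use the full alpha/beta block matrix
#' @return object of class `TDAResult`: `omega` (Hartree, ascending),
#'   `amplitudes` (list per root with `alpha`/`beta` matrices indexed
#'   (a, i), normalized to unit total square norm), `assignments`,
#'   `restriction`, `spin_adapted`
#' @export
solve_tda <- function(det, ints, fn, n_roots = 5,
                      occupied_restriction = NULL, spin = "singlet") {
  if (!inherits(fn, "FunctionalSpec")) fn <- functional_spec(fn)
  cx <- fn$exx
  M <- ints$M
  restricted <- det$n_alpha == det$n_beta &&
    isTRUE(all.equal(det$Ca, det$Cb, tolerance = 1e-8))
  arr <- eri_array(ints)

  if (restricted) {
    no <- det$n_alpha
    oi <- seq_len(no)
    if (!is.null(occupied_restriction)) {
      if (!all(occupied_restriction %in% oi)) {
        stop("occupied restriction outside the occupied space")
      }
      oi <- sort(occupied_restriction)
    }
    Co <- det$Ca[, oi, drop = FALSE]
    Cv <- det$Ca[, (no + 1):M, drop = FALSE]
    nv <- ncol(Cv)
    eo <- det$eps_a[oi]; ev <- det$eps_a[(no + 1):M]
    ovov <- .ao2mo4(arr, Co, Cv, Co, Cv)      # (i a j b)
    oovv <- .ao2mo4(arr, Co, Co, Cv, Cv)      # (i j a b)
    nia <- length(oi) * nv
    A <- matrix(0, nia, nia)
    idx <- function(i, a) (i - 1) * nv + a
    for (i in seq_along(oi)) for (a in seq_len(nv)) {
      for (j in seq_along(oi)) for (b in seq_len(nv)) {
        v <- -cx * oovv[i, j, a, b]
        if (spin == "singlet") v <- v + 2 * ovov[i, a, j, b]
        if (i == j && a == b) v <- v + ev[a] - eo[i]
        A[idx(i, a), idx(j, b)] <- v
      }
    }
    A <- (A + t(A)) / 2
    e <- eigen(A, symmetric = TRUE)
    ord <- order(e$values)
    nr <- min(n_roots, nia)
    if (n_roots > nia) warning("n_roots clipped to ", nia)
    amps <- list(); assigns <- list()
    for (k in seq_len(nr)) {
      v <- e$vectors[, ord[k]]
      Xs <- matrix(0, nv, no)  # (a, i) over the full occupied range
      for (i in seq_along(oi)) for (a in seq_len(nv)) {
        Xs[a, oi[i]] <- v[idx(i, a)]
      }
      Xs <- Xs / sqrt(sum(Xs^2))
      sgn <- if (spin == "singlet") 1 else -1
      amps[[k]] <- list(alpha = Xs / sqrt(2), beta = sgn * Xs / sqrt(2))
      top <- which(abs(Xs) == max(abs(Xs)), arr.ind = TRUE)[1, ]
      assigns[[k]] <- list(i = unname(top[2]), a = unname(top[1]) + no,
                           weight = max(Xs^2))
    }
    res <- list(omega = e$values[ord][seq_len(nr)], amplitudes = amps,
                assignments = assigns,
                restriction = occupied_restriction %||% "full",
                spin_adapted = TRUE, spin = spin,
                n_occ = no, n_virt = nv)
  } else {
    # unrestricted: full alpha/beta block matrix
    blocks <- list(
      alpha = list(C = det$Ca, no = det$n_alpha, eps = det$eps_a),
      beta = list(C = det$Cb, no = det$n_beta, eps = det$eps_b)
    )
    sp <- list()
    for (tau in names(blocks)) {
      b <- blocks[[tau]]
      oi <- seq_len(b$no)
      if (!is.null(occupied_restriction)) oi <- sort(occupied_restriction)
      sp[[tau]] <- list(
        Co = b$C[, oi, drop = FALSE],
        Cv = b$C[, (b$no + 1):M, drop = FALSE],
        eo = b$eps[oi], ev = b$eps[(b$no + 1):M],
        oi = oi, no = b$no, nv = M - b$no
      )
    }
    dims <- vapply(sp, function(s) length(s$oi) * s$nv, numeric(1))
    ntot <- sum(dims)
    A <- matrix(0, ntot, ntot)
    off <- c(alpha = 0, beta = dims[["alpha"]])
    for (t1 in names(sp)) for (t2 in names(sp)) {
      s1 <- sp[[t1]]; s2 <- sp[[t2]]
      ovov <- .ao2mo4(arr, s1$Co, s1$Cv, s2$Co, s2$Cv)
      blk <- matrix(0, length(s1$oi) * s1$nv, length(s2$oi) * s2$nv)
      if (t1 == t2) oovv <- .ao2mo4(arr, s1$Co, s2$Co, s1$Cv, s2$Cv)
      for (i in seq_along(s1$oi)) for (a in seq_len(s1$nv)) {
        r <- (i - 1) * s1$nv + a
        for (j in seq_along(s2$oi)) for (b in seq_len(s2$nv)) {
          c_ <- (j - 1) * s2$nv + b
          v <- ovov[i, a, j, b]
          if (t1 == t2) {
            v <- v - cx * oovv[i, j, a, b]
            if (i == j && a == b) v <- v + s1$ev[a] - s1$eo[i]
          }
          blk[r, c_] <- v
        }
      }
      A[off[[t1]] + seq_len(nrow(blk)), off[[t2]] + seq_len(ncol(blk))] <- blk
    }
    A <- (A + t(A)) / 2
    e <- eigen(A, symmetric = TRUE)
    ord <- order(e$values)
    nr <- min(n_roots, ntot)
    if (n_roots > ntot) warning("n_roots clipped to ", ntot)
    amps <- list(); assigns <- list()
    for (k in seq_len(nr)) {
      v <- e$vectors[, ord[k]]
      Xa <- matrix(0, sp$alpha$nv, sp$alpha$no)
      Xb <- matrix(0, sp$beta$nv, sp$beta$no)
      for (i in seq_along(sp$alpha$oi)) for (a in seq_len(sp$alpha$nv)) {
        Xa[a, sp$alpha$oi[i]] <- v[(i - 1) * sp$alpha$nv + a]
      }
      for (i in seq_along(sp$beta$oi)) for (a in seq_len(sp$beta$nv)) {
        Xb[a, sp$beta$oi[i]] <- v[off[["beta"]] + (i - 1) * sp$beta$nv + a]
      }
      nn <- sqrt(sum(Xa^2) + sum(Xb^2))
      amps[[k]] <- list(alpha = Xa / nn, beta = Xb / nn)
      assigns[[k]] <- NULL
    }
    res <- list(omega = e$values[ord][seq_len(nr)], amplitudes = amps,
                assignments = assigns,
                restriction = occupied_restriction %||% "full",
                spin_adapted = FALSE, spin = NA_character_,
                n_occ = c(det$n_alpha, det$n_beta), n_virt = NA)
  }
  structure(res, class = "TDAResult")
}

#' @export
print.TDAResult <- function(x, ...) {
  cat("TDA roots (eV):\n")
  for (k in seq_along(x$omega)) {
    as_ <- x$assignments[[k]]
    lbl <- if (!is.null(as_)) {
      sprintf("  dominant %d -> %d (weight %.2f)", as_$i, as_$a, as_$weight)
    } else ""
    cat(sprintf("  %2d  %10.4f%s\n", k, hartree_to_ev(x$omega[k]), lbl))
  }
  invisible(x)
}

#' Roots table of a TDA calculation
#'
#' @param tda a `TDAResult`
#' @return data.frame with energies in eV and dominant assignments
#' @export
tda_table <- function(tda) {
  data.frame(
    root = seq_along(tda$omega),
    energy_ev = hartree_to_ev(tda$omega),
    dominant_i = vapply(tda$assignments,
                        function(a) if (is.null(a)) NA_real_ else a$i,
                        numeric(1)),
    dominant_a = vapply(tda$assignments,
                        function(a) if (is.null(a)) NA_real_ else a$a,
                        numeric(1)),
    weight = vapply(tda$assignments,
                    function(a) if (is.null(a)) NA_real_ else a$weight,
                    numeric(1))
  )
}
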