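# Becke-partitioned molecular quadrature grids.
#
# Radial: Gauss-Chebyshev (second kind) points mapped by the Becke
# transformation r = R (1+x)/(1-x) with element-dependent scale R.
# Angular: product quadrature, Gauss-Legendre in cos(theta) times a
# uniform trapezoid in phi (exact for spherical harmonics up to degree
# ~ n_theta).  Atomic cells: Becke fuzzy weights (three smoothing passes)
# with Bragg-Slater size adjustment.

.GRID_LEVELS <- list(
  coarse = list(nrad = 30, ntheta = 10),
  medium = list(nrad = 45, ntheta = 14),
  fine = list(nrad = 70, ntheta = 20)
)

#' Build a molecular integration grid
#'
#' @param mol a `Molecule`
#' @param basis a `BasisSet` (used for AO evaluation during XC passes)
#' @param level `"coarse"`, `"medium"` or `"fine"`, or a list with
#'   elements `nrad`, `ntheta`
#' @param prune_r distance (bohr) beyond the farthest nucleus past which
#'   points are dropped
#' @return object of class `MolGrid`: `points` (n x 3, bohr), `weights`
#' @export
build_grid <- function(mol, basis, level = "medium", prune_r = 12) {
  lv <- if (is.list(level)) level else .GRID_LEVELS[[level]]
  if (is.null(lv)) stop("unknown grid level")
  nrad <- lv$nrad; ntheta <- lv$ntheta
  nphi <- 2 * ntheta
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  phis <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  wphi <- 2 * pi / nphi

  xyz <- ang_to_bohr(mol$coords)
  natom <- nrow(xyz)
  bragg <- ang_to_bohr(.ELEMENTS$bragg[match(mol$symbols, .ELEMENTS$symbol)])

  # angular unit sphere
  st <- sqrt(pmax(0, 1 - gl$x^2))
  ang <- cbind(
    rep(st, each = nphi) * cos(rep(phis, ntheta)),
    rep(st, each = nphi) * sin(rep(phis, ntheta)),
    rep(gl$x, each = nphi)
  )
  wang <- rep(gl$w, each = nphi) * wphi  # integrates to 4*pi

  pts <- list(); wts <- list()
  for (ia in seq_len(natom)) {
    Rsc <- bragg[ia] * 0.5
    if (mol$symbols[ia] == "H") Rsc <- bragg[ia]  # Becke's H exception
    i <- seq_len(nrad)
    x <- cos(i * pi / (nrad + 1))
    wgc <- pi / (nrad + 1) * sin(i * pi / (nrad + 1))^2
    r <- Rsc * (1 + x) / (1 - x)
    drdx <- 2 * Rsc / (1 - x)^2
    wr <- wgc / sqrt(1 - x^2) * drdx * r^2
    keep <- r < prune_r + 0  # radial prune per atom
    r <- r[keep]; wr <- wr[keep]
    p <- matrix(0, length(r) * nrow(ang), 3)
    w <- numeric(length(r) * nrow(ang))
    k <- 1
    for (ir in seq_along(r)) {
      idx <- k:(k + nrow(ang) - 1)
      p[idx, ] <- sweep(ang * r[ir], 2, xyz[ia, ], `+`)
      w[idx] <- wr[ir] * wang
      k <- k + nrow(ang)
    }
    # Becke partition weights for this atom's shell of points
    w <- w * .becke_weights(p, xyz, bragg, ia)
    nz <- w > 1e-16
    pts[[ia]] <- p[nz, , drop = FALSE]
    wts[[ia]] <- w[nz]
  }
  structure(
    list(points = do.call(rbind, pts), weights = unlist(wts),
         basis = basis, mol = mol, level = lv),
    class = "MolGrid"
  )
}

# Becke fuzzy-cell weights with size adjustment, for points p and atom ia
.becke_weights <- function(p, xyz, bragg, ia) {
  natom <- nrow(xyz)
  if (natom == 1) return(rep(1, nrow(p)))
  d <- matrix(0, nrow(p), natom)
  for (a in seq_len(natom)) {
    d[, a] <- sqrt((p[, 1] - xyz[a, 1])^2 + (p[, 2] - xyz[a, 2])^2 +
                     (p[, 3] - xyz[a, 3])^2)
  }
  Pcell <- matrix(1, nrow(p), natom)
  for (a in 1:(natom - 1)) {
    for (b in (a + 1):natom) {
      Rab <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      mu <- (d[, a] - d[, b]) / Rab
      chi <- bragg[a] / bragg[b]
      u <- (chi - 1) / (chi + 1)
      aab <- u / (u^2 - 1)
      aab <- max(min(aab, 0.5), -0.5)
      nu <- mu + aab * (1 - mu^2)
      f <- nu
      for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
      sab <- 0.5 * (1 - f)
      Pcell[, a] <- Pcell[, a] * sab
      Pcell[, b] <- Pcell[, b] * (1 - sab)
    }
  }
  tot <- rowSums(Pcell)
  Pcell[, ia] / pmax(tot, 1e-300)
}

#' @export
print.MolGrid <- function(x, ...) {
  cat(sprintf("MolGrid: %d points (nrad %d, ntheta %d)\n",
              nrow(x$points), x$level$nrad, x$level$ntheta))
  invisible(x)
}
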