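# Built-in Gaussian basis sets.
#
# Two self-contained families generated from Slater-exponent tables with
# the universal three-Gaussian least-squares fit of a Slater 1s/2s/2p
# function (exponents scale as zeta^2):
#   "mini"  - minimal: one contracted function per occupied subshell
#   "svb"   - split-valence: valence contractions split into an inner
#             two-Gaussian part and a free outer primitive
#   "svb+d" - "svb" augmented with one diffuse s (and p for Li-Ne) shell
# All basis functions are Cartesian Gaussians.

.FIT_1S_A <- c(2.227660584, 0.405771156, 0.109818000)
.FIT_1S_D <- c(0.154328967, 0.535328142, 0.444634542)
.FIT_2SP_A <- c(0.994203000, 0.231031000, 0.075138600)
.FIT_2S_D <- c(-0.099967230, 0.399512830, 0.700115470)
.FIT_2P_D <- c(0.155916270, 0.607683720, 0.391957390)

.ZETAS <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"),
  z1s = c(1.24, 1.69, 2.69, 3.68, 4.68, 5.67, 6.67, 7.66, 8.65, 9.64),
  z2sp = c(NA, NA, 0.80, 1.15, 1.50, 1.72, 1.95, 2.25, 2.55, 2.88),
  stringsAsFactors = FALSE
)

.dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# primitive cartesian Gaussian normalization constant
.prim_norm <- function(a, l, m, n) {
  L <- l + m + n
  (2 * a / pi)^0.75 * (4 * a)^(L / 2) /
    sqrt(.dfact(2 * l - 1) * .dfact(2 * m - 1) * .dfact(2 * n - 1))
}

# same-center overlap of two primitives with identical powers
.prim_pair_overlap <- function(a, b, l, m, n) {
  L <- l + m + n
  .dfact(2 * l - 1) * .dfact(2 * m - 1) * .dfact(2 * n - 1) *
    (pi / (a + b))^1.5 / (2 * (a + b))^L
}

# normalize a contraction: coefficients d over exponents alpha, powers lmn
.contract <- function(alpha, d, l, m, n) {
  cf <- d * vapply(alpha, .prim_norm, numeric(1), l = l, m = m, n = n)
  s <- 0
  for (p in seq_along(alpha)) {
    for (q in seq_along(alpha)) {
      s <- s + cf[p] * cf[q] * .prim_pair_overlap(alpha[p], alpha[q], l, m, n)
    }
  }
  cf / sqrt(s)
}

# shell list for one element: list of (l, alpha, d) entries
.element_shells <- function(sym, family) {
  zrow <- .ZETAS[.ZETAS$symbol == sym, ]
  if (nrow(zrow) == 0) stop("no basis parameters for element ", sym)
  a1 <- .FIT_1S_A * zrow$z1s^2
  sh <- list()
  add <- function(l, alpha, d) sh[[length(sh) + 1]] <<- list(l = l, alpha = alpha, d = d)
  heavy <- !is.na(zrow$z2sp)
  if (heavy) a2 <- .FIT_2SP_A * zrow$z2sp^2
  if (family == "mini") {
    add(0, a1, .FIT_1S_D)
    if (heavy) {
      add(0, a2, .FIT_2S_D)
      add(1, a2, .FIT_2P_D)
    }
  } else if (family %in% c("svb", "svb+d")) {
    if (!heavy) {
      add(0, a1[1:2], .FIT_1S_D[1:2])
      add(0, a1[3], 1)
    } else {
      add(0, a1, .FIT_1S_D)
      add(0, a2[1:2], .FIT_2S_D[1:2])
      add(0, a2[3], 1)
      add(1, a2[1:2], .FIT_2P_D[1:2])
      add(1, a2[3], 1)
    }
    if (family == "svb+d") {
      aout <- if (heavy) a2[3] else a1[3]
      add(0, aout / 3.5, 1)
      if (heavy) add(1, aout / 3.5, 1)
    }
  } else {
    stop("unknown basis family: ", family)
  }
  sh
}

#' Build a basis set for a molecule
#'
#' @param mol a `Molecule`
#' @param name basis family: `"mini"`, `"svb"` or `"svb+d"`
#' @return object of class `BasisSet`: flat per-function arrays (centers in
#'   bohr, Cartesian powers, primitive exponents/coefficients) plus labels
#' @export
build_basis <- function(mol, name = "mini") {
  centers <- list(); powers <- list(); alpha <- c(); coef <- c()
  prim_offset <- c(); nprim <- c(); labels <- c(); atom_of <- c()
  cart <- list(`0` = rbind(c(0, 0, 0)),
               `1` = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  pname <- list(`0` = "s", `1` = c("px", "py", "pz"))
  xyz_bohr <- ang_to_bohr(mol$coords)
  for (ia in seq_along(mol$symbols)) {
    shells <- .element_shells(mol$symbols[ia], name)
    for (sh in shells) {
      comps <- cart[[as.character(sh$l)]]
      for (ic in seq_len(nrow(comps))) {
        lmn <- comps[ic, ]
        cf <- .contract(sh$alpha, sh$d, lmn[1], lmn[2], lmn[3])
        centers[[length(centers) + 1]] <- xyz_bohr[ia, ]
        powers[[length(powers) + 1]] <- lmn
        prim_offset <- c(prim_offset, length(alpha))
        nprim <- c(nprim, length(sh$alpha))
        alpha <- c(alpha, sh$alpha)
        coef <- c(coef, cf)
        labels <- c(labels, sprintf("%s%d %s", mol$symbols[ia], ia,
                                    pname[[as.character(sh$l)]][ic]))
        atom_of <- c(atom_of, ia)
      }
    }
  }
  structure(
    list(centers = do.call(rbind, centers),
         powers = matrix(as.integer(unlist(powers)), ncol = 3, byrow = TRUE),
         prim_offset = as.integer(prim_offset),
         nprim = as.integer(nprim),
         alpha = alpha, coef = coef,
         labels = labels, atom_of = atom_of,
         M = length(labels), name = name),
    class = "BasisSet"
  )
}

#' @export
print.BasisSet <- function(x, ...) {
  cat(sprintf("BasisSet '%s': %d functions, %d primitives\n",
              x$name, x$M, length(x$alpha)))
  invisible(x)
}
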