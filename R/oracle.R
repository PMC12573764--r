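# Brute-force reference implementations for few-electron systems.
#
# A Slater determinant over nonorthogonal AO-based orbitals is expanded
# in the symmetrically orthogonalized AO basis: the amplitude of each
# occupation bitstring is the corresponding minor (subdeterminant) of
# the orthonormal-basis coefficient matrix.  Overlap, Hamiltonian and
# S^2 matrix elements are then evaluated term-by-term with the ordinary
# (orthogonal) Slater-Condon rules / second-quantized operator algebra.
# Deliberately independent of the biorthogonal NOCI code path.

.sqrtm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

.invsqrtm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Expand a determinant in the orthonormalized AO basis
#'
#' @param det a `Determinant` (or `list(Ca =, Cb =, occ_a =, occ_b =)`)
#' @param S_AO AO overlap matrix
#' @param guard maximum number of spin orbitals (2M) allowed
#' @return object of class `OrthoExpansion`: amplitudes with the
#'   occupied orthonormal-orbital index sets per spin
#' @export
expand_determinant <- function(det, S_AO, guard = 14) {
  M <- nrow(S_AO)
  if (2 * M > guard) stop("expansion size guard exceeded (", 2 * M,
                          " spin orbitals)")
  Sh <- .sqrtm_sym(S_AO)
  one_spin <- function(C, occ) {
    Co <- C[, occ > 0.5, drop = FALSE]
    n <- ncol(Co)
    Chat <- Sh %*% Co
    if (n == 0) {
      return(list(sets = list(integer(0)), amps = 1))
    }
    sets <- utils::combn(M, n, simplify = FALSE)
    amps <- vapply(sets, function(K) det(Chat[K, , drop = FALSE]), numeric(1))
    list(sets = sets, amps = amps)
  }
  a <- one_spin(det$Ca, det$occ_a)
  b <- one_spin(det$Cb, det$occ_b)
  terms <- list(); amps <- numeric(0)
  for (i in seq_along(a$sets)) {
    if (abs(a$amps[i]) < 1e-14) next
    for (j in seq_along(b$sets)) {
      if (abs(b$amps[j]) < 1e-14) next
      terms[[length(terms) + 1]] <- list(alpha = a$sets[[i]],
                                         beta = b$sets[[j]])
      amps <- c(amps, a$amps[i] * b$amps[j])
    }
  }
  structure(list(terms = terms, amps = amps, M = M), class = "OrthoExpansion")
}

# parity-aware Slater-Condon rules between two spin-orbital configs.
# Config: list(alpha = sorted ints, beta = sorted ints).  h: orthonormal
# one-electron matrix; g: orthonormal ERI array (chemist (pq|rs)).
.sc_element <- function(K, L, h, g, Vnn) {
  # spin-orbital lists as (spin, orbital); encode spin alpha=0, beta=1
  ka <- K$alpha; kb <- K$beta; la <- L$alpha; lb <- L$beta
  if (length(ka) != length(la) || length(kb) != length(lb)) return(0)
  da <- c(setdiff(ka, la), setdiff(kb, lb) + 1000L)
  db <- c(setdiff(la, ka), setdiff(lb, kb) + 1000L)
  nd <- length(da)
  if (nd > 2) return(0)
  # parity to bring differing orbitals to matching positions
  pos <- function(x, ann_a, ann_b) {
    # position of spin orbital x in the full (alpha then beta) list
    if (x < 1000L) match(x, ann_a) else length(ann_a) + match(x - 1000L, ann_b)
  }
  spin_of <- function(x) if (x < 1000L) 0L else 1L
  orb_of <- function(x) if (x < 1000L) x else x - 1000L
  g_so <- function(p, q, r, s) {
    # antisymmetrized <pq||rs> (physicist) over spin orbitals
    v <- 0
    if (spin_of(p) == spin_of(r) && spin_of(q) == spin_of(s)) {
      v <- v + g[orb_of(p), orb_of(r), orb_of(q), orb_of(s)]
    }
    if (spin_of(p) == spin_of(s) && spin_of(q) == spin_of(r)) {
      v <- v - g[orb_of(p), orb_of(s), orb_of(q), orb_of(r)]
    }
    v
  }
  h_so <- function(p, q) {
    if (spin_of(p) != spin_of(q)) 0 else h[orb_of(p), orb_of(q)]
  }
  all_K <- c(ka, kb + 1000L)
  all_L <- c(la, lb + 1000L)
  if (nd == 0) {
    e <- Vnn
    for (p in all_K) e <- e + h_so(p, p)
    np <- length(all_K)
    if (np >= 2) {
      for (i in 1:(np - 1)) for (j in (i + 1):np) {
        e <- e + g_so(all_K[i], all_K[j], all_K[i], all_K[j])
      }
    }
    return(e)
  }
  if (nd == 1) {
    p <- da[1]; r <- db[1]
    sgn <- (-1)^(pos(p, ka, kb) + pos(r, la, lb))
    e <- h_so(p, r)
    for (q in all_K) {
      if (q == p) next
      e <- e + g_so(p, q, r, q)
    }
    return(sgn * e)
  }
  # nd == 2
  p1 <- da[1]; p2 <- da[2]; r1 <- db[1]; r2 <- db[2]
  sgn <- (-1)^(pos(p1, ka, kb) + pos(p2, ka, kb) +
                 pos(r1, la, lb) + pos(r2, la, lb))
  sgn * g_so(p1, p2, r1, r2)
}

# apply S+ = sum_p a+_{p,alpha} a_{p,beta} to a configuration
.apply_splus <- function(cfg) {
  out <- list()
  for (p in cfg$beta) {
    if (p %in% cfg$alpha) next
    # a_{p beta}: sign from passing alpha block and preceding beta orbitals
    sgn <- (-1)^(length(cfg$alpha) + (match(p, cfg$beta) - 1))
    nb <- setdiff(cfg$beta, p)
    # a+_{p alpha}: insert into alpha list
    sgn <- sgn * (-1)^(sum(cfg$alpha < p))
    out[[length(out) + 1]] <- list(cfg = list(alpha = sort(c(cfg$alpha, p)),
                                              beta = nb),
                                   sign = sgn)
  }
  out
}

.cfg_key <- function(cfg) {
  paste(paste(cfg$alpha, collapse = ","), "|",
        paste(cfg$beta, collapse = ","))
}

#' Brute-force matrix element between expanded determinants
#'
#' @param exp_I,exp_J `OrthoExpansion`s in the same orthonormal basis
#' @param operator `"overlap"`, `"hamiltonian"` or `"s_squared"`
#' @param ints an `AOIntegrals` (required for `"hamiltonian"`)
#' @return numeric matrix element
#' @export
brute_force_element <- function(exp_I, exp_J,
                                operator = c("overlap", "hamiltonian",
                                             "s_squared"),
                                ints = NULL) {
  operator <- match.arg(operator)
  if (exp_I$M != exp_J$M) stop("expansions in different bases")
  M <- exp_I$M
  keyI <- vapply(exp_I$terms, .cfg_key, character(1))
  keyJ <- vapply(exp_J$terms, .cfg_key, character(1))
  if (operator == "overlap") {
    m <- match(keyJ, keyI)
    ok <- !is.na(m)
    return(sum(exp_I$amps[m[ok]] * exp_J$amps[ok]))
  }
  if (operator == "hamiltonian") {
    if (is.null(ints)) stop("hamiltonian operator needs integrals")
    X <- .invsqrtm_sym(ints$S)
    h <- t(X) %*% ints$hcore %*% X
    g <- .ao2mo4(eri_array(ints, guard = 8), X, X, X, X)
    e <- 0
    for (i in seq_along(exp_I$terms)) {
      for (j in seq_along(exp_J$terms)) {
        e <- e + exp_I$amps[i] * exp_J$amps[j] *
          .sc_element(exp_I$terms[[i]], exp_J$terms[[j]], h, g, ints$Vnn)
      }
    }
    return(e)
  }
  # s_squared: Sz(Sz+1) <I|J> + <S+ I|S+ J>
  na <- length(exp_I$terms[[1]]$alpha)
  nb <- length(exp_I$terms[[1]]$beta)
  sz <- (na - nb) / 2
  m <- match(keyJ, keyI)
  ok <- !is.na(m)
  ov <- sum(exp_I$amps[m[ok]] * exp_J$amps[ok])
  splus_map <- function(ex) {
    env <- new.env()
    for (i in seq_along(ex$terms)) {
      for (t in .apply_splus(ex$terms[[i]])) {
        k <- .cfg_key(t$cfg)
        prev <- if (exists(k, envir = env, inherits = FALSE)) {
          get(k, envir = env)
        } else 0
        assign(k, prev + t$sign * ex$amps[i], envir = env)
      }
    }
    env
  }
  eI <- splus_map(exp_I)
  eJ <- splus_map(exp_J)
  acc <- 0
  for (k in ls(eJ)) {
    if (exists(k, envir = eI, inherits = FALSE)) {
      acc <- acc + get(k, envir = eI) * get(k, envir = eJ)
    }
  }
  sz * (sz + 1) * ov + acc
}

#' Full configuration interaction on a small system
#'
#' Exact diagonalization over all determinants with the given spin
#' occupations, in the orthonormalized AO basis.
#'
#' @param ints an `AOIntegrals`
#' @param n_alpha,n_beta electron counts
#' @param guard maximum number of spin orbitals
#' @return `list(energies =, configs =, vectors =)` with energies
#'   ascending
#' @export
full_ci <- function(ints, n_alpha, n_beta, guard = 14) {
  M <- ints$M
  if (2 * M > guard) stop("full CI size guard exceeded")
  X <- .invsqrtm_sym(ints$S)
  h <- t(X) %*% ints$hcore %*% X
  g <- .ao2mo4(eri_array(ints, guard = 8), X, X, X, X)
  sa <- if (n_alpha > 0) utils::combn(M, n_alpha, simplify = FALSE) else
    list(integer(0))
  sb <- if (n_beta > 0) utils::combn(M, n_beta, simplify = FALSE) else
    list(integer(0))
  cfgs <- list()
  for (A in sa) for (B in sb) {
    cfgs[[length(cfgs) + 1]] <- list(alpha = A, beta = B)
  }
  n <- length(cfgs)
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    H[i, j] <- H[j, i] <- .sc_element(cfgs[[i]], cfgs[[j]], h, g, ints$Vnn)
  }
  e <- eigen(H, symmetric = TRUE)
  o <- order(e$values)
  list(energies = e$values[o], configs = cfgs,
       vectors = e$vectors[, o, drop = FALSE])
}
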