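# Self-consistent field engine: unrestricted HF/KS with DIIS, optional
# Fermi smearing, density-constraint Lagrange multiplier (inner
# bracketing loop on lambda_c), and an IMOM driver for comparison states.

#' SCF settings
#'
#' @param conv_rms convergence threshold on RMS([F,P]) in a.u.
#' @param max_iter maximum macro-iterations
#' @param diis_size DIIS subspace size
#' @param lambda_tol constraint-residual tolerance for the inner
#'   multiplier solve
#' @param smear_K electronic temperature in Kelvin for Fermi smearing
#'   (`NULL` = integer occupations); smeared runs are annealed to integer
#'   occupations before the final energy evaluation
#' @param grid_level exchange-correlation grid level (see [build_grid()])
#' @param guess `"core"` or a list `list(Pa =, Pb =)` of starting densities
#' @param verbose 0 silent, 1 per-iteration log lines
#' @return object of class `SCFSettings`
#' @export
scf_settings <- function(conv_rms = 1e-7, max_iter = 200, diis_size = 8,
                         lambda_tol = 1e-10, smear_K = NULL,
                         grid_level = "medium", guess = "core", verbose = 0) {
  stopifnot(conv_rms > 0, max_iter > 0, lambda_tol > 0)
  structure(list(conv_rms = conv_rms, max_iter = max_iter,
                 diis_size = diis_size, lambda_tol = lambda_tol,
                 smear_K = smear_K, grid_level = grid_level, guess = guess,
                 verbose = verbose),
            class = "SCFSettings")
}

# symmetric (Loewdin) orthogonalizer; canonical when near-singular
.orthogonalizer <- function(S, lin_dep = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > lin_dep * max(e$values)
  if (all(keep)) {
    e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  } else {
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
  }
}

# occupations: integer aufbau or Fermi-Dirac at temperature kT (Hartree)
.occupations <- function(eps, n_occ, kT = NULL) {
  n <- length(eps)
  occ <- numeric(n)
  if (n_occ == 0) return(occ)
  if (is.null(kT) || kT <= 0) {
    occ[order(eps)[seq_len(n_occ)]] <- 1
    return(occ)
  }
  f <- function(mu) sum(1 / (1 + exp(pmin((eps - mu) / kT, 500)))) - n_occ
  lo <- min(eps) - 10 * kT - 1
  hi <- max(eps) + 10 * kT + 1
  mu <- uniroot(f, c(lo, hi), tol = 1e-13)$root
  1 / (1 + exp(pmin((eps - mu) / kT, 500)))
}

.density_from <- function(C, occ) {
  Co <- C[, occ > 1e-14, drop = FALSE]
  o <- occ[occ > 1e-14]
  Co %*% (t(Co) * o)
}

# diagonalize F in orthonormal basis; return C (AO), eps ascending
.solve_fock <- function(F, X) {
  Ft <- t(X) %*% F %*% X
  Ft <- (Ft + t(Ft)) / 2
  e <- eigen(Ft, symmetric = TRUE)
  o <- order(e$values)
  list(C = X %*% e$vectors[, o, drop = FALSE], eps = e$values[o])
}

#' Solve for a constraint Lagrange multiplier by safeguarded bracketing
#'
#' Finds `lambda` with `|value(lambda) - Nc| <= tol` for a monotone
#' constraint-value function.  Uses Newton steps from the analytic
#' derivative when supplied, guarded by a bracket; when the target is
#' approached asymptotically (no sign change), a power-law tail model
#' extrapolates the multiplier.  The iteration count equals the number of
#' function evaluations (one perturbed-Fock diagonalization each).
#'
#' @param fn function of `lambda` returning `list(value =, deriv =)` (the
#'   derivative may be `NULL`)
#' @param Nc constraint target value
#' @param tol residual tolerance (default 1e-10)
#' @param lambda0 starting multiplier
#' @param step initial bracket expansion step
#' @param max_iter maximum evaluations
#' @param lambda_max magnitude cap for the multiplier
#' @return `list(lambda, value, resid, iterations, converged)`
#' @export
bracket_lambda <- function(fn, Nc, tol = 1e-10, lambda0 = 0, step = 0.5,
                           max_iter = 80, lambda_max = 1e8) {
  evals <- 0
  ev <- function(l) {
    evals <<- evals + 1
    r <- fn(l)
    list(l = l, v = r$value, d = r$deriv)
  }
  cur <- ev(lambda0)
  if (abs(cur$v - Nc) <= tol) {
    return(list(lambda = lambda0, value = cur$v, resid = abs(cur$v - Nc),
                iterations = evals, converged = TRUE))
  }
  # direction of decreasing residual: value is monotone in lambda
  d <- cur$d
  if (is.null(d) || !is.finite(d) || d == 0) {
    probe <- ev(lambda0 + step)
    d <- (probe$v - cur$v) / step
    if (abs(probe$v - Nc) < abs(cur$v - Nc)) cur <- probe
  }
  dir <- if ((Nc - cur$v) / d > 0) 1 else -1  # move lambda this way
  lo <- cur; hi <- NULL  # hi: point on the far side (sign change)
  prev <- NULL
  lam <- cur$l
  stp <- step * dir
  while (evals < max_iter) {
    if (!is.null(hi)) {
      # bracketed: Newton from the better endpoint, bisection fallback
      base <- if (abs(lo$v - Nc) < abs(hi$v - Nc)) lo else hi
      cand <- NA
      if (!is.null(base$d) && is.finite(base$d) && base$d != 0) {
        cand <- base$l - (base$v - Nc) / base$d
      }
      inside <- is.finite(cand) &&
        cand > min(lo$l, hi$l) && cand < max(lo$l, hi$l)
      if (!inside) cand <- (lo$l + hi$l) / 2
      nxt <- ev(cand)
      if (abs(nxt$v - Nc) <= tol) {
        return(list(lambda = nxt$l, value = nxt$v, resid = abs(nxt$v - Nc),
                    iterations = evals, converged = TRUE))
      }
      if (sign(nxt$v - Nc) == sign(lo$v - Nc)) lo <- nxt else hi <- nxt
    } else {
      # no sign change yet: expand, or extrapolate along the tail
      prev <- cur
      resid_prev <- abs(prev$v - Nc)
      lam_next <- lam + stp
      # tail model once two informative points exist
      if (!is.null(prev) && abs(lam) > abs(step) && resid_prev > 0) {
        # Newton suggestion first
        if (!is.null(cur$d) && is.finite(cur$d) && abs(cur$d) > 1e-300) {
          nl <- cur$l - (cur$v - Nc) / cur$d
          if (is.finite(nl) && (nl - cur$l) * dir > 0) {
            lam_next <- if (abs(nl - cur$l) > 100 * abs(stp)) {
              cur$l + 100 * abs(stp) * dir
            } else nl
          }
        }
      }
      if (abs(lam_next) > lambda_max) lam_next <- lambda_max * dir
      nxt <- ev(lam_next)
      if (abs(nxt$v - Nc) <= tol) {
        return(list(lambda = nxt$l, value = nxt$v, resid = abs(nxt$v - Nc),
                    iterations = evals, converged = TRUE))
      }
      if (sign(nxt$v - Nc) != sign(cur$v - Nc)) {
        lo <- cur; hi <- nxt
      } else {
        # still same side
        r_old <- abs(cur$v - Nc); r_new <- abs(nxt$v - Nc)
        if (r_new < r_old && abs(nxt$l) > 0 && abs(cur$l) > 0 &&
            abs(nxt$l) != abs(cur$l) && r_new > 0) {
          # power-law tail: resid ~ A/|lambda|^p -> jump to tol level
          p <- log(r_old / r_new) / log(abs(nxt$l) / abs(cur$l))
          if (is.finite(p) && p > 0.1) {
            lam_jump <- abs(nxt$l) * (r_new / tol)^(1 / p)
            lam_jump <- min(lam_jump, abs(nxt$l) * 1000, lambda_max)
            stp <- (lam_jump - abs(nxt$l)) * dir
            if (abs(stp) < abs(step)) stp <- step * dir
          } else {
            stp <- 2 * stp
          }
        } else {
          stp <- 2 * stp
        }
        cur <- nxt
        lam <- cur$l
        if (abs(lam) >= lambda_max && abs(nxt$v - Nc) > tol) {
          return(list(lambda = lam, value = nxt$v, resid = abs(nxt$v - Nc),
                      iterations = evals, converged = FALSE))
        }
      }
    }
  }
  best <- if (!is.null(hi)) {
    if (abs(lo$v - Nc) < abs(hi$v - Nc)) lo else hi
  } else cur
  list(lambda = best$l, value = best$v, resid = abs(best$v - Nc),
       iterations = evals, converged = FALSE)
}

# constraint value for given densities (exported wrapper lives in
# constraints.R); internal fast path
.cvalue <- function(Pa, Pb, spec) {
  v <- 0
  if (!is.null(spec$Wc_a)) v <- v + sum(Pa * spec$Wc_a)
  if (!is.null(spec$Wc_b)) v <- v + sum(Pb * spec$Wc_b)
  v
}

# Fock and energy pieces from densities
.fock_energy <- function(ints, fn, Pa, Pb, grid) {
  jk <- jk_build(ints, list(Pa, Pb))
  J <- jk$J[[1]] + jk$J[[2]]
  Ka <- jk$K[[1]]; Kb <- jk$K[[2]]
  xc <- xc_eval(grid, Pa, Pb, fn)
  E_one <- sum((Pa + Pb) * ints$hcore)
  E_J <- 0.5 * sum((Pa + Pb) * J)
  E_Kfull <- -0.5 * (sum(Pa * Ka) + sum(Pb * Kb))
  E_HF <- ints$Vnn + E_one + E_J + E_Kfull
  E_KS <- ints$Vnn + E_one + E_J + fn$exx * E_Kfull + xc$Exc
  Fa <- ints$hcore + J - fn$exx * Ka + xc$Vxc_a
  Fb <- ints$hcore + J - fn$exx * Kb + xc$Vxc_b
  list(Fa = Fa, Fb = Fb, E_KS = E_KS, E_HF = E_HF, Exc = xc$Exc)
}

.diis_new <- function(size) {
  env <- new.env()
  env$F <- list(); env$E <- list(); env$size <- size
  env
}

.diis_push_extrapolate <- function(d, Fmat, err) {
  d$F[[length(d$F) + 1]] <- Fmat
  d$E[[length(d$E) + 1]] <- err
  if (length(d$F) > d$size) {
    d$F <- d$F[-1]; d$E <- d$E[-1]
  }
  n <- length(d$F)
  if (n < 2) return(Fmat)
  B <- matrix(0, n + 1, n + 1)
  for (i in 1:n) for (j in 1:n) B[i, j] <- sum(d$E[[i]] * d$E[[j]])
  B[n + 1, 1:n] <- -1; B[1:n, n + 1] <- -1
  rhs <- c(rep(0, n), -1)
  c_ <- tryCatch(solve(B, rhs), error = function(e) NULL)
  if (is.null(c_) || any(!is.finite(c_))) {
    d$F <- d$F[n]; d$E <- d$E[n]
    return(Fmat)
  }
  out <- 0
  for (i in 1:n) out <- out + c_[i] * d$F[[i]]
  out
}

#' Run a (constrained) self-consistent field calculation
#'
#' Unrestricted Hartree-Fock or Kohn-Sham SCF with DIIS convergence
#' acceleration.  When a `ConstraintSpec` is supplied, the density
#' constraint `sum_tau Tr[P^tau Wc^tau] = Nc` is enforced through a
#' Lagrange multiplier re-solved by [bracket_lambda()] inside every
#' macro-iteration; DIIS then extrapolates the perturbed Fock matrix
#' `F + lambda_c Wc`.  Occupations follow the aufbau principle on the
#' perturbed spectrum (optionally Fermi-smeared, annealed to integer
#' occupations before the final energies).
#'
#' Non-convergence is returned as a result object with
#' `converged = FALSE` carrying last-iteration diagnostics, not as an
#' error, so geometry scans can record disappearing states.
#'
#' @param ints an `AOIntegrals`
#' @param fn a `FunctionalSpec` (or name)
#' @param settings an `SCFSettings`
#' @param constraint a `ConstraintSpec` or `NULL`
#' @param label free-form provenance label stored on the result
#' @return object of class `Determinant`: MO coefficients, occupations
#'   and orbital energies per spin, the Kohn-Sham total energy
#'   `E_KS` and the Hartree-Fock-expression energy `E_HF` evaluated with
#'   the same orbitals, the optimized multiplier `lambda` (if
#'   constrained), convergence diagnostics
#' @export
run_scf <- function(ints, fn, settings = scf_settings(), constraint = NULL,
                    label = "") {
  if (!inherits(fn, "FunctionalSpec")) fn <- functional_spec(fn)
  ns <- .spin_counts(ints$mol)
  na <- unname(ns[1]); nb <- unname(ns[2])
  X <- .orthogonalizer(ints$S)
  grid <- if (fn$semilocal) build_grid(ints$mol, ints$basis,
                                       level = settings$grid_level) else NULL

  # initial guess
  if (is.list(settings$guess)) {
    Pa <- settings$guess$Pa; Pb <- settings$guess$Pb
  } else {
    sol <- .solve_fock(ints$hcore, X)
    Pa <- .density_from(sol$C, .occupations(sol$eps, na))
    Pb <- .density_from(sol$C, .occupations(sol$eps, nb))
  }

  kT <- if (!is.null(settings$smear_K)) settings$smear_K * 3.166811563e-6
        else NULL
  diis <- .diis_new(settings$diis_size)
  lambda <- if (!is.null(constraint)) 0 else NA_real_
  lambda_iters <- integer(0)
  conv <- FALSE; rms <- NA_real_; it <- 0
  Ca <- Cb <- NULL; eps_a <- eps_b <- NULL
  occ_a <- occ_b <- NULL
  fe <- NULL
  anneal_stage <- 0
  dp_last <- Inf  # density change of the previous step

  for (it in seq_len(settings$max_iter)) {
    fe <- .fock_energy(ints, fn, Pa, Pb, grid)
    Fa <- fe$Fa; Fb <- fe$Fb
    if (!is.null(constraint)) {
      cf <- function(l) {
        sa <- .solve_fock(Fa + l * constraint$Wc_a, X)
        sb <- .solve_fock(Fb + l * constraint$Wc_b, X)
        oa <- .occupations(sa$eps, na, kT)
        ob <- .occupations(sb$eps, nb, kT)
        Pa_ <- .density_from(sa$C, oa)
        Pb_ <- .density_from(sb$C, ob)
        val <- .cvalue(Pa_, Pb_, constraint)
        # analytic derivative: second-order response of the aufbau density
        dv <- 0
        for (sp in list(list(s = sa, o = oa, W = constraint$Wc_a),
                        list(s = sb, o = ob, W = constraint$Wc_b))) {
          if (all(abs(sp$W) < 1e-300)) next
          Wmo <- t(sp$s$C) %*% sp$W %*% sp$s$C
          oi <- which(sp$o > 0.5); vi <- which(sp$o <= 0.5)
          if (length(oi) && length(vi)) {
            de <- outer(sp$s$eps[oi], sp$s$eps[vi], `-`)
            de[abs(de) < 1e-8] <- -1e-8
            dv <- dv + 2 * sum(Wmo[oi, vi, drop = FALSE]^2 / de)
          }
        }
        list(value = val, deriv = dv)
      }
      sol_l <- bracket_lambda(cf, constraint$Nc, tol = settings$lambda_tol,
                              lambda0 = lambda)
      lambda <- sol_l$lambda
      lambda_iters <- c(lambda_iters, sol_l$iterations)
      Fa <- Fa + lambda * constraint$Wc_a
      Fb <- Fb + lambda * constraint$Wc_b
    }
    # DIIS on the (perturbed) Fock matrix
    erra <- t(X) %*% (Fa %*% Pa %*% ints$S - ints$S %*% Pa %*% Fa) %*% X
    errb <- t(X) %*% (Fb %*% Pb %*% ints$S - ints$S %*% Pb %*% Fb) %*% X
    err <- rbind(erra, errb)
    rms <- sqrt(mean(err^2))
    if (settings$verbose > 0) {
      message(sprintf(
        "iter %3d  E_KS = %.10f  rms = %.3e  lambda = %s", it, fe$E_KS, rms,
        if (is.na(lambda)) "-" else sprintf("%.6g", lambda)))
    }
    if (rms <= settings$conv_rms && dp_last <= 1e-5) {
      if (!is.null(kT) && kT > 0) {
        # anneal the smearing temperature toward integer occupations
        kT <- kT / 4
        if (kT < 10 * 3.166811563e-6) kT <- NULL
        diis <- .diis_new(settings$diis_size)
        anneal_stage <- anneal_stage + 1
      } else {
        conv <- TRUE
      }
    }
    Fstack <- .diis_push_extrapolate(diis, rbind(Fa, Fb), err)
    M <- ints$M
    Fa_x <- Fstack[1:M, , drop = FALSE]
    Fb_x <- Fstack[(M + 1):(2 * M), , drop = FALSE]
    sa <- .solve_fock(Fa_x, X)
    sb <- .solve_fock(Fb_x, X)
    occ_a <- .occupations(sa$eps, na, kT)
    occ_b <- .occupations(sb$eps, nb, kT)
    Ca <- sa$C; Cb <- sb$C
    eps_a <- sa$eps; eps_b <- sb$eps
    if (conv) break
    Pa_new <- .density_from(Ca, occ_a)
    Pb_new <- .density_from(Cb, occ_b)
    dp_last <- max(abs(Pa_new - Pa), abs(Pb_new - Pb))
    Pa <- Pa_new
    Pb <- Pb_new
  }

  # final densities/energies from the last diagonalization
  Pa <- .density_from(Ca, occ_a)
  Pb <- .density_from(Cb, occ_b)
  if (!is.null(constraint) && conv) {
    # final clean-up solve of the multiplier on the unextrapolated Fock
    fe2 <- .fock_energy(ints, fn, Pa, Pb, grid)
    cf2 <- function(l) {
      sa <- .solve_fock(fe2$Fa + l * constraint$Wc_a, X)
      sb <- .solve_fock(fe2$Fb + l * constraint$Wc_b, X)
      Pa_ <- .density_from(sa$C, .occupations(sa$eps, na))
      Pb_ <- .density_from(sb$C, .occupations(sb$eps, nb))
      assign("last", list(sa = sa, sb = sb, Pa = Pa_, Pb = Pb_),
             envir = cl_env)
      list(value = .cvalue(Pa_, Pb_, constraint), deriv = NULL)
    }
    cl_env <- new.env()
    sol_f <- bracket_lambda(cf2, constraint$Nc, tol = settings$lambda_tol,
                            lambda0 = lambda)
    lambda <- sol_f$lambda
    lambda_iters <- c(lambda_iters, sol_f$iterations)
    lf <- get("last", envir = cl_env)
    Ca <- lf$sa$C; Cb <- lf$sb$C
    eps_a <- lf$sa$eps; eps_b <- lf$sb$eps
    occ_a <- .occupations(eps_a, na); occ_b <- .occupations(eps_b, nb)
    Pa <- lf$Pa; Pb <- lf$Pb
  }
  fe_fin <- .fock_energy(ints, fn, Pa, Pb, grid)
  res <- structure(
    list(Ca = Ca, Cb = Cb, occ_a = occ_a, occ_b = occ_b,
         eps_a = eps_a, eps_b = eps_b,
         E_KS = fe_fin$E_KS, E_HF = fe_fin$E_HF,
         lambda = lambda, Nc = constraint$Nc %||% NA_real_,
         constraint = constraint,
         constraint_resid = if (is.null(constraint)) NA_real_ else
           abs(.cvalue(Pa, Pb, constraint) - constraint$Nc),
         converged = conv, n_iter = it, rms = rms,
         lambda_iters = lambda_iters,
         n_alpha = na, n_beta = nb, fn_name = fn$name, label = label),
    class = "Determinant"
  )
  res
}

#' @export
print.Determinant <- function(x, ...) {
  cat(sprintf(
    "Determinant%s: E_KS = %.10f, E_HF = %.10f, %s after %d iterations\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    x$E_KS, x$E_HF,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (!is.na(x$lambda)) {
    cat(sprintf("  constrained: lambda = %.6g, residual = %.2e (Nc = %g)\n",
                x$lambda, x$constraint_resid, x$Nc))
  }
  invisible(x)
}

# density matrices of a determinant
.det_density <- function(det) {
  list(Pa = .density_from(det$Ca, det$occ_a),
       Pb = .density_from(det$Cb, det$occ_b))
}

#' Spin expectation value of a single determinant
#'
#' Standard unrestricted-determinant expression
#' `<S^2> = Sz(Sz+1) + N_beta - sum_ij |<phi_i^alpha|phi_j^beta>|^2`.
#'
#' @param det a `Determinant`
#' @param S_AO the AO overlap matrix
#' @return numeric `<S^2>`
#' @export
s2_single <- function(det, S_AO) {
  Coa <- det$Ca[, det$occ_a > 0.5, drop = FALSE]
  Cob <- det$Cb[, det$occ_b > 0.5, drop = FALSE]
  na <- ncol(Coa); nb <- ncol(Cob)
  sz <- (na - nb) / 2
  ov <- t(Coa) %*% S_AO %*% Cob
  sz * (sz + 1) + nb - sum(ov^2)
}

#' Excited-state SCF by the initial maximum overlap method (IMOM)
#'
#' Starts from a reference determinant with one occupied/virtual pair
#' swapped in one spin channel; at every iteration the occupied orbitals
#' are chosen as those with the largest projection onto the *initial*
#' swapped reference set (IMOM).  Non-convergence is reported as a
#' result object, not an error: disappearance of such solutions along a
#' scan is data.
#'
#' @param ints an `AOIntegrals`
#' @param fn a `FunctionalSpec` (or name)
#' @param settings an `SCFSettings`
#' @param reference a converged ground-state `Determinant`
#' @param swap `list(from = i, to = a, spin = "alpha"|"beta")` occupied
#'   index `i` replaced by virtual index `a`; `from == to` means no swap
#' @param label provenance label
#' @return a `Determinant` (with `converged` status)
#' @export
run_imom <- function(ints, fn, settings = scf_settings(), reference, swap,
                     label = "") {
  if (!inherits(fn, "FunctionalSpec")) fn <- functional_spec(fn)
  ns <- .spin_counts(ints$mol)
  na <- unname(ns[1]); nb <- unname(ns[2])
  X <- .orthogonalizer(ints$S)
  grid <- if (fn$semilocal) build_grid(ints$mol, ints$basis,
                                       level = settings$grid_level) else NULL

  occ_idx <- list(alpha = which(reference$occ_a > 0.5),
                  beta = which(reference$occ_b > 0.5))
  Cref <- list(alpha = reference$Ca, beta = reference$Cb)
  if (!is.null(swap) && swap$from != swap$to) {
    oi <- occ_idx[[swap$spin]]
    oi[oi == swap$from] <- swap$to
    occ_idx[[swap$spin]] <- oi
  }
  ref_occ <- list(alpha = Cref$alpha[, occ_idx$alpha, drop = FALSE],
                  beta = Cref$beta[, occ_idx$beta, drop = FALSE])
  sel <- function(C, ref) {
    # projection norms of each candidate orbital onto the reference span
    O <- t(ref) %*% ints$S %*% C
    colSums(O^2)
  }
  Pa <- ref_occ$alpha %*% t(ref_occ$alpha)
  Pb <- ref_occ$beta %*% t(ref_occ$beta)
  diis <- .diis_new(settings$diis_size)
  conv <- FALSE; rms <- NA_real_
  Ca <- Cb <- NULL; eps_a <- eps_b <- NULL; occ_a <- occ_b <- NULL
  fe <- NULL
  dp_last <- Inf
  for (it in seq_len(settings$max_iter)) {
    fe <- .fock_energy(ints, fn, Pa, Pb, grid)
    erra <- t(X) %*% (fe$Fa %*% Pa %*% ints$S - ints$S %*% Pa %*% fe$Fa) %*% X
    errb <- t(X) %*% (fe$Fb %*% Pb %*% ints$S - ints$S %*% Pb %*% fe$Fb) %*% X
    err <- rbind(erra, errb)
    rms <- sqrt(mean(err^2))
    if (rms <= settings$conv_rms && dp_last <= 1e-5) conv <- TRUE
    Fstack <- .diis_push_extrapolate(diis, rbind(fe$Fa, fe$Fb), err)
    M <- ints$M
    sa <- .solve_fock(Fstack[1:M, , drop = FALSE], X)
    sb <- .solve_fock(Fstack[(M + 1):(2 * M), , drop = FALSE], X)
    pa <- sel(sa$C, ref_occ$alpha)
    pb <- sel(sb$C, ref_occ$beta)
    occ_a <- numeric(M); occ_a[order(pa, decreasing = TRUE)[seq_len(na)]] <- 1
    occ_b <- numeric(M); occ_b[order(pb, decreasing = TRUE)[seq_len(nb)]] <- 1
    Ca <- sa$C; Cb <- sb$C; eps_a <- sa$eps; eps_b <- sb$eps
    if (conv) break
    Pa_new <- .density_from(Ca, occ_a)
    Pb_new <- .density_from(Cb, occ_b)
    dp_last <- max(abs(Pa_new - Pa), abs(Pb_new - Pb))
    Pa <- Pa_new
    Pb <- Pb_new
  }
  Pa <- .density_from(Ca, occ_a)
  Pb <- .density_from(Cb, occ_b)
  fe_fin <- .fock_energy(ints, fn, Pa, Pb, grid)
  structure(
    list(Ca = Ca, Cb = Cb, occ_a = occ_a, occ_b = occ_b,
         eps_a = eps_a, eps_b = eps_b,
         E_KS = fe_fin$E_KS, E_HF = fe_fin$E_HF,
         lambda = NA_real_, Nc = NA_real_, constraint = NULL,
         constraint_resid = NA_real_,
         converged = conv, n_iter = it, rms = rms,
         lambda_iters = integer(0),
         n_alpha = na, n_beta = nb, fn_name = fn$name, label = label),
    class = "Determinant"
  )
}
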