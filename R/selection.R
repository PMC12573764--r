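# Enumeration of the reference-determinant space: orbital-energy-window
# selection, seniority-restricted doubles, and spin-flip partner
# expansion into SCF task lists.

.space_df <- function(rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(df) <- NULL
  df
}

#' Enumerate an excitation space by orbital-energy windows
#'
#' Contains the ground-state pattern, all single excitations with orbital
#' energy gap `eps_a - eps_i <= de_max`, and all seniority-zero and
#' seniority-two double excitations whose summed orbital-energy gap
#' (each orbital counted with its excitation multiplicity) stays within
#' `de_max`.  Listing order is by nondecreasing gap; degenerate gaps are
#' broken by ascending orbital indices for determinism.
#'
#' @param eps orbital energies (Hartree), sorted within the occupied and
#'   virtual blocks
#' @param n_occ number of occupied orbitals
#' @param de_max_ev selection threshold in eV
#' @param window optional `list(occ =, virt =)` index sets restricting
#'   the participating orbitals
#' @return object of class `ExcitationSpace`: a data.frame with columns
#'   `type`, `i`, `j`, `a`, `b`, `seniority`, `gap_ev`, `needs_flip`
#' @export
enumerate_space <- function(eps, n_occ, de_max_ev, window = NULL) {
  M <- length(eps)
  if (n_occ < 1 || n_occ >= M) stop("need at least one occupied and one virtual orbital")
  occ_idx <- window$occ %||% seq_len(n_occ)
  virt_idx <- window$virt %||% ((n_occ + 1):M)
  if (length(occ_idx) == 0 || length(virt_idx) == 0) {
    stop("empty occupied or virtual window")
  }
  de_max <- ev_to_hartree(de_max_ev)
  rows <- list(list(type = "ground", i = NA_integer_, j = NA_integer_,
                    a = NA_integer_, b = NA_integer_, seniority = NA_integer_,
                    gap_ev = 0, needs_flip = FALSE))
  add <- function(type, i, j, a, b, sen, gap, flip) {
    rows[[length(rows) + 1]] <<- list(type = type, i = i, j = j, a = a, b = b,
                                      seniority = sen,
                                      gap_ev = hartree_to_ev(gap),
                                      needs_flip = flip)
  }
  for (i in occ_idx) for (a in virt_idx) {
    gap <- eps[a] - eps[i]
    if (gap <= de_max) add("single", i, NA_integer_, a, NA_integer_, 1L, gap, TRUE)
  }
  # seniority 0: i = j, a = b
  for (i in occ_idx) for (a in virt_idx) {
    gap <- 2 * (eps[a] - eps[i])
    if (gap <= de_max) add("double", i, i, a, a, 0L, gap, FALSE)
  }
  # seniority 2: i = j, a < b
  for (i in occ_idx) {
    va <- virt_idx
    if (length(va) >= 2) {
      for (p in seq_len(length(va) - 1)) for (q in (p + 1):length(va)) {
        a <- va[p]; b <- va[q]
        gap <- eps[a] + eps[b] - 2 * eps[i]
        if (gap <= de_max) add("double", i, i, a, b, 2L, gap, TRUE)
      }
    }
  }
  # seniority 2: i < j, a = b
  if (length(occ_idx) >= 2) {
    for (p in seq_len(length(occ_idx) - 1)) for (q in (p + 1):length(occ_idx)) {
      i <- occ_idx[p]; j <- occ_idx[q]
      for (a in virt_idx) {
        gap <- 2 * eps[a] - eps[i] - eps[j]
        if (gap <= de_max) add("double", i, j, a, a, 2L, gap, TRUE)
      }
    }
  }
  df <- .space_df(rows)
  # canonical ordering: ground first, then by gap, then indices
  dfg <- df[df$type == "ground", , drop = FALSE]
  dfr <- df[df$type != "ground", , drop = FALSE]
  o <- order(dfr$gap_ev, dfr$i, dfr$j, dfr$a, dfr$b)
  df <- rbind(dfg, dfr[o, , drop = FALSE])
  rownames(df) <- NULL
  # drop duplicates from degenerate-orbital canonicalization
  key <- with(df, paste(type, i, j, a, b))
  df <- df[!duplicated(key), , drop = FALSE]
  class(df) <- c("ExcitationSpace", "data.frame")
  df
}

#' Manually defined excitation space
#'
#' @param patterns list of pattern lists with fields `type`
#'   (`"single"`/`"double"`), `i`, `j`, `a`, `b`
#' @param eps optional orbital energies to attach gaps
#' @return an `ExcitationSpace`
#' @export
excitation_space <- function(patterns, eps = NULL) {
  rows <- list(list(type = "ground", i = NA_integer_, j = NA_integer_,
                    a = NA_integer_, b = NA_integer_, seniority = NA_integer_,
                    gap_ev = 0, needs_flip = FALSE))
  for (p in patterns) {
    if (p$type == "single") {
      gap <- if (is.null(eps)) NA_real_ else hartree_to_ev(eps[p$a] - eps[p$i])
      rows[[length(rows) + 1]] <- list(type = "single", i = p$i,
                                       j = NA_integer_, a = p$a,
                                       b = NA_integer_, seniority = 1L,
                                       gap_ev = gap, needs_flip = TRUE)
    } else {
      sen <- .double_seniority(p$i, p$j, p$a, p$b)
      if (is.na(sen)) stop("unsupported double-excitation pattern")
      gap <- if (is.null(eps)) NA_real_ else
        hartree_to_ev(eps[p$a] + eps[p$b] - eps[p$i] - eps[p$j])
      rows[[length(rows) + 1]] <- list(type = "double", i = p$i, j = p$j,
                                       a = p$a, b = p$b, seniority = sen,
                                       gap_ev = gap,
                                       needs_flip = (sen == 2L))
    }
  }
  df <- .space_df(rows)
  class(df) <- c("ExcitationSpace", "data.frame")
  df
}

#' Reference excitation space for polyene-type systems
#'
#' The classic four-orbital space over HOMO-1, HOMO, LUMO, LUMO+1:
#' all four singles, the three low seniority-zero doubles, and the two
#' seniority-two doubles.
#'
#' @param n_occ index of the HOMO (number of occupied spatial orbitals)
#' @param eps optional orbital energies to attach gaps
#' @return an `ExcitationSpace` with 10 patterns (incl. ground state)
#' @export
polyene_space <- function(n_occ, eps = NULL) {
  h <- n_occ; h1 <- n_occ - 1; l <- n_occ + 1; l1 <- n_occ + 2
  excitation_space(list(
    list(type = "single", i = h, a = l),
    list(type = "single", i = h, a = l1),
    list(type = "single", i = h1, a = l),
    list(type = "single", i = h1, a = l1),
    list(type = "double", i = h, j = h, a = l, b = l),
    list(type = "double", i = h, j = h, a = l1, b = l1),
    list(type = "double", i = h1, j = h1, a = l, b = l),
    list(type = "double", i = h, j = h, a = l, b = l1),
    list(type = "double", i = h1, j = h, a = l, b = l)
  ), eps = eps)
}

#' Expand an excitation space into determinant SCF tasks
#'
#' Spin-contaminated singles yield an alpha-channel task plus its
#' spin-flipped (beta-channel) partner.  Seniority-zero doubles are
#' spin-restricted (one task).  Seniority-two doubles are spin-restricted
#' under the density-constraint method (one task) but break spin symmetry
#' under IMOM (two tasks).  The ground state contributes one task.
#'
#' @param space an `ExcitationSpace`
#' @param method `"coox"` or `"imom"`
#' @return data.frame of tasks with columns of `space` plus `spin`
#' @export
expand_with_spin_flips <- function(space, method = c("coox", "imom")) {
  method <- match.arg(method)
  out <- list()
  add <- function(row, spin) {
    row$spin <- spin
    out[[length(out) + 1]] <<- row
  }
  for (k in seq_len(nrow(space))) {
    row <- as.list(space[k, , drop = FALSE])
    if (row$type == "ground") {
      add(row, "none")
    } else if (row$type == "single") {
      add(row, "alpha")
      add(row, "beta")
    } else if (row$seniority == 0) {
      add(row, "both")
    } else {  # seniority 2
      if (method == "coox") {
        add(row, "both")
      } else {
        add(row, "alpha")
        add(row, "beta")
      }
    }
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  rownames(df) <- NULL
  df
}
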