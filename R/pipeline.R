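# Run orchestration: configuration handling, the single-point pipeline
# (ground SCF -> excitation-space selection -> reference-state SCFs ->
# NOCI -> properties), geometry scans with density continuation, and
# file output (JSON results, CSV manifests and spectra).

#' Assemble a run configuration
#'
#' @param molecule an XYZ file path, an XYZ text block, a `Molecule`, or
#'   a fixture description `list(family =, ...)` for
#'   [generate_fixture()]
#' @param basis basis family name
#' @param functional functional name (see [functional_spec()])
#' @param method `"noci-coox"`, `"noci-imom"`, `"coox"` or `"tda"`
#' @param de_max_ev excitation-space selection threshold (eV)
#' @param window optional orbital window `list(occ =, virt =)`
#' @param space `"auto"` for energy-window enumeration or `"polyene"`
#'   for the four-orbital reference space
#' @param sigma_threshold singular-value orthogonality threshold
#' @param lin_dep_threshold canonical-orthogonalization cutoff
#' @param tdf_mode `"determinant"` or `"overlap"`
#' @param charge,multiplicity molecular state
#' @param scan optional `list(param =, grid =)`: fixture parameter swept
#'   over a monotone grid
#' @param scf list of [scf_settings()] overrides
#' @param outdir output directory or `NULL`
#' @param seed random seed recorded for provenance
#' @param verbose verbosity level
#' @return a `RunConfig` list
#' @export
run_config <- function(molecule, basis = "mini", functional = "hf",
                       method = "noci-coox", de_max_ev = 15,
                       window = NULL, space = "auto",
                       sigma_threshold = 1e-6, lin_dep_threshold = 1e-8,
                       tdf_mode = "determinant", charge = 0,
                       multiplicity = NULL, scan = NULL, scf = list(),
                       outdir = NULL, seed = 1L, verbose = 0) {
  stopifnot(sigma_threshold > 0, lin_dep_threshold > 0, de_max_ev > 0)
  if (!is.null(scan)) {
    g <- scan$grid
    if (length(g) > 1 && !(all(diff(g) > 0) || all(diff(g) < 0))) {
      stop("scan grid must be monotone")
    }
  }
  structure(
    list(molecule = molecule, basis = basis, functional = functional,
         method = method, de_max_ev = de_max_ev, window = window,
         space = space, sigma_threshold = sigma_threshold,
         lin_dep_threshold = lin_dep_threshold, tdf_mode = tdf_mode,
         charge = charge, multiplicity = multiplicity, scan = scan,
         scf = scf, outdir = outdir, seed = seed, verbose = verbose),
    class = "RunConfig"
  )
}

#' Read a run configuration from YAML
#' @param path YAML file path
#' @return a `RunConfig`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.resolve_molecule <- function(cfg) {
  m <- cfg$molecule
  if (inherits(m, "Molecule")) return(m)
  if (is.list(m)) {
    args <- m; args$family <- NULL
    return(do.call(generate_fixture, c(list(family = m$family), args)))
  }
  read_xyz(m, charge = cfg$charge, multiplicity = cfg$multiplicity)
}

.scf_from_cfg <- function(cfg, guess = "core") {
  args <- cfg$scf
  args$guess <- guess
  args$verbose <- cfg$verbose
  do.call(scf_settings, args)
}

# run the reference-determinant tasks of an excitation space
.run_reference_states <- function(tasks, ground, ints, fn, cfg,
                                  guess = NULL) {
  dets <- list()
  status <- character(nrow(tasks))
  base_guess <- guess %||% .det_density(ground)
  for (k in seq_len(nrow(tasks))) {
    tk <- tasks[k, ]
    lbl <- if (tk$type == "ground") "ground" else {
      sprintf("%s %s->%s%s [%s]", tk$type,
              if (tk$type == "double") paste(tk$i, tk$j, sep = ",") else tk$i,
              if (tk$type == "double") paste(tk$a, tk$b, sep = ",") else tk$a,
              "", tk$spin)
    }
    if (tk$type == "ground") {
      dets[[length(dets) + 1]] <- ground
      status[k] <- "converged"
      next
    }
    st <- .scf_from_cfg(cfg, guess = base_guess)
    if (cfg$method %in% c("noci-coox", "coox")) {
      no <- ground$n_alpha
      spec <- if (tk$type == "single") {
        Cspin <- if (tk$spin == "alpha") ground$Ca else ground$Cb
        wc_single(ints$S, Cspin, tk$i, tk$a, no, spin = tk$spin)
      } else {
        wc_double(ints$S, ground$Ca, tk$i, tk$j, tk$a, tk$b, no)
      }
      d <- run_scf(ints, fn, st, constraint = spec, label = lbl)
    } else {
      swap <- if (tk$type == "single") {
        list(from = tk$i, to = tk$a, spin = tk$spin)
      } else if (tk$seniority == 0) {
        # paired double: swap in both channels sequentially
        NULL
      } else {
        list(from = tk$i, to = tk$a, spin = tk$spin)
      }
      d <- if (tk$type == "double") {
        .run_imom_double(ints, fn, st, ground, tk, lbl)
      } else {
        run_imom(ints, fn, st, ground, swap, label = lbl)
      }
    }
    if (isTRUE(d$converged)) {
      dets[[length(dets) + 1]] <- d
      status[k] <- "converged"
    } else {
      status[k] <- "failed"
      warning("reference state '", lbl, "' did not converge; excluded")
    }
  }
  list(dets = dets, status = status)
}

# IMOM double excitations: swap both affected spin channels
.run_imom_double <- function(ints, fn, st, ground, tk, lbl) {
  ref <- ground
  occ_a <- which(ref$occ_a > 0.5)
  occ_b <- which(ref$occ_b > 0.5)
  if (tk$seniority == 0) {
    occ_a[occ_a == tk$i] <- tk$a
    occ_b[occ_b == tk$i] <- tk$a
  } else if (tk$i == tk$j) {  # i2 -> a,b
    if (tk$spin == "alpha") {
      occ_a[occ_a == tk$i] <- tk$a
      occ_b[occ_b == tk$i] <- tk$b
    } else {
      occ_a[occ_a == tk$i] <- tk$b
      occ_b[occ_b == tk$i] <- tk$a
    }
  } else {  # i,j -> a2
    if (tk$spin == "alpha") {
      occ_a[occ_a == tk$i] <- tk$a
      occ_b[occ_b == tk$j] <- tk$a
    } else {
      occ_a[occ_a == tk$j] <- tk$a
      occ_b[occ_b == tk$i] <- tk$a
    }
  }
  # emulate the double swap through a modified reference determinant
  ref2 <- ref
  ref2$occ_a <- numeric(length(ref$occ_a)); ref2$occ_a[occ_a] <- 1
  ref2$occ_b <- numeric(length(ref$occ_b)); ref2$occ_b[occ_b] <- 1
  run_imom(ints, fn, st, ref2, swap = list(from = 1, to = 1, spin = "alpha"),
           label = lbl)
}

#' Run the full pipeline for one geometry
#'
#' Ground SCF, (TDA where required), excitation-space enumeration,
#' reference-state SCFs, NOCI assembly and solution, and transition
#' properties.  Individual reference-state failures are recorded and the
#' corresponding determinants excluded; a ground-state SCF failure is an
#' error.
#'
#' @param cfg a `RunConfig`
#' @return list with `ground`, `space`, `tasks`, `status`, `noci`,
#'   `properties`, `config`; results are also written to `cfg$outdir`
#'   when set
#' @export
run_pipeline <- function(cfg) {
  set.seed(cfg$seed)
  mol <- .resolve_molecule(cfg)
  fn <- functional_spec(cfg$functional)
  ints <- build_ao_integrals(mol, cfg$basis)
  ground <- run_scf(ints, fn, .scf_from_cfg(cfg), label = "ground")
  if (!ground$converged) {
    stop("ground-state SCF failed (rms ", signif(ground$rms, 3),
         " after ", ground$n_iter, " iterations)")
  }
  if (cfg$method == "tda") {
    tda <- solve_tda(ground, ints, fn, n_roots = 10)
    out <- list(ground = ground, tda = tda, table = tda_table(tda),
                config = cfg)
    .write_outputs(out, cfg)
    return(invisible(out))
  }
  space <- if (identical(cfg$space, "polyene")) {
    polyene_space(ground$n_alpha, eps = ground$eps_a)
  } else {
    enumerate_space(ground$eps_a, ground$n_alpha, cfg$de_max_ev,
                    window = cfg$window)
  }
  method_kind <- if (cfg$method == "noci-imom") "imom" else "coox"
  tasks <- expand_with_spin_flips(space, method = method_kind)
  rs <- .run_reference_states(tasks, ground, ints, fn, cfg)
  if (cfg$method == "coox") {
    # plain constrained-SCF energies, no configuration interaction
    tab <- data.frame(
      label = vapply(rs$dets, function(d) d$label, character(1)),
      E_KS = vapply(rs$dets, function(d) d$E_KS, numeric(1)))
    tab$dE_ev <- round(hartree_to_ev(tab$E_KS - ground$E_KS), 4)
    out <- list(ground = ground, space = space, tasks = tasks,
                status = rs$status, table = tab, config = cfg)
    .write_outputs(out, cfg)
    return(invisible(out))
  }
  noci <- assemble_and_solve(rs$dets, ints, fn,
                             sigma_threshold = cfg$sigma_threshold,
                             lin_dep_threshold = cfg$lin_dep_threshold,
                             tdf_mode = cfg$tdf_mode)
  props <- transition_properties(noci, ints)
  out <- list(ground = ground, space = space, tasks = tasks,
              status = rs$status, noci = noci, properties = props,
              config = cfg)
  .write_outputs(out, cfg)
  invisible(out)
}

.write_outputs <- function(out, cfg) {
  if (is.null(cfg$outdir)) return(invisible(NULL))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_ser <- unclass(cfg)
  cfg_ser$molecule <- if (inherits(cfg$molecule, "Molecule")) {
    write_xyz(cfg$molecule)
  } else cfg$molecule
  cfg_ser$window <- NULL
  cfg_ser$outdir <- NULL
  payload <- list(config = cfg_ser)
  if (!is.null(out$noci)) {
    payload$energies_hartree <- out$noci$energies
    payload$excitations_ev <-
      round(hartree_to_ev(out$noci$energies - out$noci$energies[1]), 4)
    payload$s2 <- out$noci$s2
    payload$ci_coefficients <- out$noci$coef
    payload$task_status <- out$status
    payload$n_discarded <- out$noci$n_discarded
    ref_info <- lapply(out$noci$dets, function(d) {
      list(label = d$label, E_KS = d$E_KS, E_HF = d$E_HF,
           lambda = d$lambda, n_iter = d$n_iter)
    })
    payload$reference_states <- ref_info
  }
  if (!is.null(out$tda)) payload$tda_ev <- hartree_to_ev(out$tda$omega)
  jsonlite::write_json(payload, file.path(cfg$outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(out$space)) {
    utils::write.csv(as.data.frame(out$space),
                     file.path(cfg$outdir, "space.csv"), row.names = FALSE)
  }
  if (!is.null(out$properties)) {
    utils::write.csv(out$properties,
                     file.path(cfg$outdir, "transitions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$table)) {
    nm <- if (!is.null(out$tda)) "tda_roots.csv" else "states.csv"
    utils::write.csv(out$table, file.path(cfg$outdir, nm),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run a geometry scan with density continuation
#'
#' Processes the scan grid in order; each point's SCF starts from the
#' previous point's converged ground-state density.  Per-point
#' convergence status, NOCI energies and spin expectations are
#' tabulated; disappearance of a reference solution is a recorded
#' status, not an error.
#'
#' @param cfg a `RunConfig` whose `molecule` is a fixture description
#'   and whose `scan` names one fixture parameter and its grid
#' @return list with `points` (per-point pipeline outputs) and `summary`
#'   (one row per grid point)
#' @export
run_scan <- function(cfg) {
  if (is.null(cfg$scan)) {
    out <- run_pipeline(cfg)
    return(invisible(list(points = list(out), summary = NULL)))
  }
  stopifnot(is.list(cfg$molecule), !is.null(cfg$molecule$family))
  grid <- cfg$scan$grid
  par <- cfg$scan$param
  points <- list()
  rows <- list()
  prev_guess <- NULL
  fn <- functional_spec(cfg$functional)
  for (k in seq_along(grid)) {
    mdesc <- cfg$molecule
    mdesc[[par]] <- grid[k]
    cfgk <- cfg
    cfgk$molecule <- mdesc
    cfgk$outdir <- NULL
    mol <- .resolve_molecule(cfgk)
    ints <- build_ao_integrals(mol, cfg$basis)
    st <- .scf_from_cfg(cfg, guess = prev_guess %||% "core")
    ground <- run_scf(ints, fn, st, label = sprintf("ground @ %g", grid[k]))
    if (!ground$converged) {
      rows[[k]] <- data.frame(point = grid[k], status = "ground-failed",
                              E0 = NA_real_)
      points[[k]] <- list(ground = ground)
      prev_guess <- NULL
      next
    }
    prev_guess <- .det_density(ground)
    space <- if (identical(cfg$space, "polyene")) {
      polyene_space(ground$n_alpha, eps = ground$eps_a)
    } else {
      enumerate_space(ground$eps_a, ground$n_alpha, cfg$de_max_ev,
                      window = cfg$window)
    }
    method_kind <- if (cfg$method == "noci-imom") "imom" else "coox"
    tasks <- expand_with_spin_flips(space, method = method_kind)
    rs <- .run_reference_states(tasks, ground, ints, fn, cfgk)
    noci <- tryCatch(
      assemble_and_solve(rs$dets, ints, fn,
                         sigma_threshold = cfg$sigma_threshold,
                         lin_dep_threshold = cfg$lin_dep_threshold,
                         tdf_mode = cfg$tdf_mode),
      error = function(e) NULL
    )
    nst <- min(4, if (is.null(noci)) 0 else length(noci$energies))
    row <- data.frame(point = grid[k],
                      status = paste(rs$status, collapse = ";"),
                      E0 = if (nst >= 1) noci$energies[1] else NA_real_)
    for (s in seq_len(max(nst - 1, 0))) {
      row[[paste0("dE", s, "_ev")]] <-
        hartree_to_ev(noci$energies[s + 1] - noci$energies[1])
      row[[paste0("s2_", s)]] <- noci$s2[s + 1]
    }
    rows[[k]] <- row
    points[[k]] <- list(ground = ground, tasks = tasks, status = rs$status,
                        noci = noci)
  }
  nm <- unique(unlist(lapply(rows, names)))
  summary <- do.call(rbind, lapply(rows, function(r) {
    for (n in setdiff(nm, names(r))) r[[n]] <- NA
    r[nm]
  }))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(cfg$outdir, "scan.csv"),
                     row.names = FALSE)
  }
  invisible(list(points = points, summary = summary))
}
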