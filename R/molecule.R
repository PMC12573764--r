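# Molecular geometry container and XYZ input/output.

.ELEMENTS <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"),
  Z = 1:10,
  # Bragg-Slater radii (Angstrom) for Becke partitioning; H widened per
  # common practice, He/Ne assigned covalent-like values.
  bragg = c(0.35, 0.31, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.38),
  stringsAsFactors = FALSE
)

.element_Z <- function(sym) {
  i <- match(sym, .ELEMENTS$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(sym[is.na(i)], collapse = ", "))
  }
  .ELEMENTS$Z[i]
}

#' Construct a molecule
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom
#' @param charge total charge in units of e
#' @param multiplicity spin multiplicity 2S+1; by default the lowest value
#'   consistent with electron-count parity (1 for even, 2 for odd counts)
#' @return object of class `Molecule` with fields `symbols`, `coords`
#'   (Angstrom), `charge`, `multiplicity`, `Z`, `n_electrons`
#' @export
molecule <- function(symbols, coords, charge = 0, multiplicity = NULL) {
  coords <- as.matrix(coords)
  if (length(symbols) == 0) stop("empty atom list")
  if (nrow(coords) != length(symbols) || ncol(coords) != 3) {
    stop("coordinate count does not match element count")
  }
  Z <- .element_Z(symbols)
  nel <- sum(Z) - charge
  if (nel <= 0) stop("no electrons left at this charge")
  if (is.null(multiplicity)) multiplicity <- if (nel %% 2 == 0) 1L else 2L
  if ((nel - (multiplicity - 1)) %% 2 != 0) {
    stop("multiplicity ", multiplicity,
         " inconsistent with electron count ", nel)
  }
  if (multiplicity < 1 || multiplicity - 1 > nel) {
    stop("impossible multiplicity")
  }
  structure(
    list(symbols = symbols, coords = coords, charge = charge,
         multiplicity = as.integer(multiplicity), Z = Z, n_electrons = nel),
    class = "Molecule"
  )
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("Molecule: %d atoms, charge %+d, multiplicity %d\n",
              length(x$symbols), x$charge, x$multiplicity))
  for (i in seq_along(x$symbols)) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$symbols[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  }
  invisible(x)
}

# electron counts per spin from charge/multiplicity
.spin_counts <- function(mol) {
  nel <- mol$n_electrons
  s2 <- mol$multiplicity - 1L  # 2 Sz
  na <- (nel + s2) / 2
  nb <- (nel - s2) / 2
  if (na != round(na)) stop("inconsistent electron count / multiplicity")
  c(n_alpha = as.integer(na), n_beta = as.integer(nb))
}

#' Read a molecule from XYZ text
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' `symbol x y z` line per atom with coordinates in Angstrom.
#'
#' @param text character scalar holding an XYZ block, or a file path
#' @param charge,multiplicity passed to [molecule()]
#' @return a `Molecule`
#' @export
read_xyz <- function(text, charge = 0, multiplicity = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  }
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 1) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: expected atom count")
  if (n < 1) stop("empty atom list")
  if (length(lines) < n + 2) {
    stop("XYZ count mismatch: header says ", n, " atoms, got ",
         max(0, length(lines) - 2), " coordinate lines")
  }
  syms <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- trimws(lines[i + 2])
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 4) {
      stop("XYZ parse error at line ", i + 2, ": '", ln, "'")
    }
    vals <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(vals)) {
      stop("XYZ parse error at line ", i + 2, ": non-numeric coordinate")
    }
    syms[i] <- parts[1]
    xyz[i, ] <- vals
  }
  molecule(syms, xyz, charge = charge, multiplicity = multiplicity)
}

#' Write a molecule as XYZ text
#'
#' @param mol a `Molecule`
#' @param file optional path; if `NULL` the XYZ block is returned as a string
#' @param comment comment line content
#' @return XYZ text, invisibly when written to file
#' @export
write_xyz <- function(mol, file = NULL, comment = "") {
  lines <- c(
    as.character(length(mol$symbols)), comment,
    vapply(seq_along(mol$symbols), function(i) {
      sprintf("%-2s %16.10f %16.10f %16.10f", mol$symbols[i],
              mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3])
    }, character(1))
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
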