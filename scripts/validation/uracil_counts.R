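#!/usr/bin/env Rscript
# Long-running validation: excitation-space size for uracil at a
# 14 eV selection window, split by seniority, plus the lowest NOCI
# excitation energies in vacuum.  The geometry below is a synthetic
# idealized planar ring built from standard bond lengths and angles
# (not an optimized structure).

suppressMessages(library(nocicoox))

# synthetic planar uracil: ring N1-C2(=O)-N3-C4(=O)-C5=C6, H on N1,
# N3, C5, C6.  Standard lengths (Angstrom): ring ~1.38, C=O 1.22,
# N-H 1.01, C-H 1.08.
ring_r <- 1.38 / (2 * sin(pi / 6))
ang <- seq(90, 90 + 300, by = 60) * pi / 180
ring <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
sym <- c("N", "C", "N", "C", "C", "C")  # N1 C2 N3 C4 C5 C6
outward <- ring / sqrt(rowSums(ring^2))
coords <- ring
symbols <- sym
add <- function(s, xyz) {
  symbols <<- c(symbols, s)
  coords <<- rbind(coords, xyz)
}
add("O", ring[2, ] + 1.22 * outward[2, ])  # C2=O
add("O", ring[4, ] + 1.22 * outward[4, ])  # C4=O
add("H", ring[1, ] + 1.01 * outward[1, ])  # N1-H
add("H", ring[3, ] + 1.01 * outward[3, ])  # N3-H
add("H", ring[5, ] + 1.08 * outward[5, ])  # C5-H
add("H", ring[6, ] + 1.08 * outward[6, ])  # C6-H
uracil <- molecule(symbols, coords)

ints <- build_ao_integrals(uracil, "svb")
g <- run_scf(ints, "pbe0", scf_settings(grid_level = "medium"))
stopifnot(g$converged)
sp <- enumerate_space(g$eps_a, g$n_alpha, 14)
cat("singles:", sum(sp$type == "single"), "\n")
cat("seniority-0 doubles:", sum(sp$type == "double" & sp$seniority == 0),
    "\n")
cat("seniority-2 doubles:", sum(sp$type == "double" & sp$seniority == 2),
    "\n")
tasks <- expand_with_spin_flips(sp, "coox")
cat("total constrained configurations (incl. ground):", nrow(tasks), "\n")

# vacuum excitation energies over the enumerated space (heavy)
cfg <- run_config(uracil, basis = "svb", functional = "pbe0",
                  method = "noci-coox", de_max_ev = 14,
                  scf = list(grid_level = "coarse"))
out <- run_pipeline(cfg)
print(out$noci)
print(out$properties)
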