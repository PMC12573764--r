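#!/usr/bin/env Rscript
# Long-running validation: convergence of the butadiene bright/dark
# excitation energies with the orbital-energy selection window.
# Sweeps de_max from 10 to 20 eV with PBE0 split-valence references and
# tabulates the lowest NOCI roots and configuration counts; the dark
# state drops sharply once the paired HOMO^2 -> LUMO^2 double enters
# the space.

suppressMessages(library(nocicoox))

rows <- list()
for (de in seq(10, 20, by = 1)) {
  cfg <- run_config(list(family = "polyene", n = 2), basis = "svb",
                    functional = "pbe0", method = "noci-coox",
                    de_max_ev = de, scf = list(grid_level = "medium"))
  out <- tryCatch(run_pipeline(cfg), error = function(e) NULL)
  if (is.null(out)) next
  nst <- length(out$noci$energies)
  singl <- which(out$noci$s2 < 0.5)
  ex <- hartree_to_ev(out$noci$energies - out$noci$energies[1])
  rows[[length(rows) + 1]] <- data.frame(
    de_max_ev = de, n_config = length(out$noci$dets),
    E1_ev = if (length(singl) > 1) ex[singl[2]] else NA,
    E2_ev = if (length(singl) > 2) ex[singl[3]] else NA)
  print(rows[[length(rows)]])
}
tab <- do.call(rbind, rows)
write.csv(tab, "butadiene_demax.csv", row.names = FALSE)
cat("wrote butadiene_demax.csv\n")
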