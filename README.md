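# nocicoox

Excited-state electronic structure by **nonorthogonal configuration
interaction over constraint-based orbital-optimized determinants**
(NOCI-COOX), as a reusable R library with a thin command-line front
end.

## The problem and who this is for

Linear-response methods (CIS, TDA-TDDFT) describe excited states as
single substitutions out of one frozen ground-state calculation.  They
miss orbital relaxation, fail for states with double-excitation
character (the classic dark 2¹Ag state of polyenes), and cannot open a
gap between S0 and S1 at conical intersections.  Delta-SCF methods
relax orbitals but collapse variationally, lose solutions along
geometry scans, and produce spin-contaminated determinants.

This package implements a three-stage workflow for users studying such
states on small molecules:

1. **COOX** — excited determinants are optimized by constraining the
   density against static projectors built from ground-state orbitals,

   `Tr[P^tau Wc^tau] = Nc`,  `Wc = S_AO (dP_virt - dP_occ) S_AO`,

   enforced through a Lagrange multiplier added to the Fock operator.
   Occupations always follow the aufbau principle on the perturbed
   spectrum, so there is no variational collapse.  A single
   spin-orbital transition i→a uses `dP = 1/2 C C^T` projectors with
   `Nc = 1/2`; paired and seniority-two doubles use `Nc = 1`;
   Tamm-Dancoff amplitude projectors use `Nc = 0`.
2. **NOCI** — the mutually nonorthogonal relaxed determinants (each
   spin-contaminated single together with its spin-flipped partner,
   selected automatically by an orbital-energy window) span a secular
   problem `H C = S C E`.  Matrix elements come from generalized
   Slater-Condon rules in a pairwise biorthogonal basis (SVD of the
   occupied-MO overlap), including all vanishing-singular-value cases.
   Diagonalization yields spin-purified states, `<S^2>` per state,
   transition densities, oscillator strengths and Voigt-broadened
   spectra.
3. **Kohn-Sham correction** — for DFT references, a
   transition-density-functional term adds the KS correlation content
   `dEc[Phi] = E_KS[rho] - E_HF[Phi]` to the off-diagonal elements
   (determinant-weighted by default), keeping `H_II = E_KS[rho_I]`
   exactly.

Everything below the method layer is self-contained: a
McMurchie-Davidson Gaussian integral engine (Rcpp), built-in minimal
and split-valence basis families for H–Ne, SVWN5/PBE/PBE0/PBE50
exchange-correlation on Becke grids, a TDA/CIS solver, an IMOM
(initial maximum overlap) driver for comparison, and brute-force
permutation-expansion oracles used by the test suite.

## Worked example

Lowest excitations of water with PBE0 references in the built-in
minimal basis: the HOMO→LUMO alpha-channel determinant, its
spin-flipped partner, and the paired HOMO²→LUMO² double, all relaxed
under density constraints and coupled by NOCI.

```r
library(nocicoox)

mol  <- generate_fixture("water")
ints <- build_ao_integrals(mol, "mini")

ground <- run_scf(ints, "pbe0", scf_settings())
no <- ground$n_alpha
guess <- scf_settings(guess = nocicoox:::.det_density(ground))

sa <- run_scf(ints, "pbe0", guess,
              constraint = wc_single(ints$S, ground$Ca, no, no + 1, no, "alpha"))
sb <- run_scf(ints, "pbe0", guess,
              constraint = wc_single(ints$S, ground$Cb, no, no + 1, no, "beta"))
dd <- run_scf(ints, "pbe0", guess,
              constraint = wc_double(ints$S, ground$Ca, no, no, no + 1, no + 1, no))

res <- assemble_and_solve(list(ground, sa, sb, dd), ints, "pbe0")
print(res)
#> NOCI over 4 determinants (0 state(s) discarded)
#>   state  0  E = -75.24678813 Ha  dE =   0.0000 eV  <S^2> =  0.0000
#>   state  1  E = -74.86978942 Ha  dE =  10.2587 eV  <S^2> =  2.0000
#>   state  2  E = -74.80142428 Ha  dE =  12.1190 eV  <S^2> =  0.0140
#>   state  3  E = -74.16571289 Ha  dE =  29.4176 eV  <S^2> =  0.0000
```

The two broken-symmetry single-excitation determinants each carry
`<S^2> ≈ 1`; diagonalization splits them into a clean triplet
(10.26 eV, `<S^2> = 2.000`) and singlet (12.12 eV, `<S^2> = 0.014`) —
the spin purification that a single determinant cannot deliver.  The
constrained SCFs themselves report their multiplier and constraint
residual:

```r
print(sa)
#> Determinant: E_KS = -74.8356068539, E_HF = -74.5470515879, converged after 9 iterations
#>   constrained: lambda = -1.5, residual = 7.22e-15 (Nc = 0.5)
```

Transition dipoles and oscillator strengths follow from the NOCI
transition densities, and `broaden_spectrum()` convolves the sticks
with Voigt profiles:

```r
transition_properties(res, ints)
#>   state    dE_ev  ...  osc_strength
#> 1     0  0.00000         0.0000e+00
#> 2     1 10.25866         2.1077e-28   # triplet: spin-forbidden
#> 3     2 12.11897         2.4728e-03
#> 4     3 29.41756         1.7154e-03
```

The same workflow runs from the shell via the bundled script
(`inst/scripts/noci-coox run|scan|spectrum|fixtures`) on YAML
configurations, with automatic excitation-space selection
(`de_max_ev`), geometry scans with density continuation, and JSON/CSV
output.  Larger demonstrations live in `scripts/validation/`.

See `vignettes/noci-coox-methods.Rmd` for the model, the multiplier
solver, all tunable parameters, and known limitations.

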