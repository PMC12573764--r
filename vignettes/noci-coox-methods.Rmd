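---
title: "Methods: nonorthogonal CI over constraint-based orbital-optimized states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonorthogonal CI over constraint-based orbital-optimized states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Excited electronic states with orbital relaxation, double-excitation
character, or strong spin contamination are poorly described by linear
response on top of a single ground-state calculation.  This package
takes a different route in three stages.

**1. Constraint-based orbital optimization (COOX).**  An excited
determinant is obtained from a ground-state SCF solution by enforcing a
density constraint

$$\sum_\tau \mathrm{Tr}\,[\mathbf{P}^\tau \mathbf{W}_c^\tau] = N_c,
\qquad
\mathbf{W}_c^\tau = \mathbf{S}_{AO}\,
(\Delta\mathbf{P}^{\mathrm{virt},\tau} -
 \Delta\mathbf{P}^{\mathrm{occ},\tau})\,\mathbf{S}_{AO},$$

where the difference densities $\Delta\mathbf{P}$ are *static*
projectors built from ground-state MOs: either from Tamm–Dancoff
transition amplitudes (target $N_c = 0$), or from explicit orbital
selections.  A single spin-orbital transition $i^\alpha \to a^\alpha$
uses $\Delta\mathbf{P}^{\mathrm{virt}} = \tfrac12 C_a C_a^T$,
$\Delta\mathbf{P}^{\mathrm{occ}} = \tfrac12 C_i C_i^T$ in one spin
channel with $N_c = \tfrac12$; paired and seniority-two double
excitations carry $N_c = 1$.  The constraint enters the SCF through a
Lagrange multiplier $\lambda_c$ added to the Fock operator,
$\mathbf{F} + \lambda_c \mathbf{W}_c$, and occupations always follow
the aufbau principle *on the perturbed spectrum* — this is what makes
the approach robust against the variational collapse that plagues
non-aufbau delta-SCF schemes.

**2. Nonorthogonal configuration interaction (NOCI).**  The relaxed
determinants from different constraints are mutually nonorthogonal.
Solving the secular problem $\mathbf{H}\mathbf{C} =
\mathbf{S}\mathbf{C}\mathbf{E}$ over this set recovers
ground/excited-state mixing and, crucially, spin purification: each
spin-contaminated single excitation is included together with its
spin-flipped partner, and diagonalization produces approximate singlet
and triplet eigenstates.  Matrix elements are evaluated in a pairwise
biorthogonal basis obtained from the singular value decomposition of
the occupied-MO overlap; generalized Slater–Condon rules then reduce
every Hamiltonian element to traces over weighted codensity and dyadic
matrices, with a case analysis over vanishing singular values (zero,
one, two in one spin, one per spin, otherwise null).

**3. Kohn–Sham correction.**  For DFT references the bare Hamiltonian
elements are Hartree–Fock-like.  A transition-density-functional
correction adds the Kohn–Sham correlation content:
$\Delta E_c[\Phi] = E_{KS}[\rho_\Phi] - E_{HF}[\Phi]$ is the difference
of the two total energies evaluated with the *same* orbitals, and the
default determinant-weighted form scales the pair element by
$(\Delta E_c^I + \Delta E_c^J)/(E_{HF}^I + E_{HF}^J)$.  Both energies
include the nuclear repulsion; with this convention the corrected
diagonal reproduces $E_{KS}[\rho_I]$ exactly, which we enforce as an
invariant in the test suite.  An overlap-weighted variant is available
(`tdf_mode = "overlap"`).  A simpler effective Hamiltonian built only
from constraint eigenvalue relations is *not* used here: when a
determinant and its spin-flip partner become orthogonal it provides no
two-electron coupling between them, so the singlet/triplet pair would
stay spuriously degenerate.  The biorthogonal two-zero matrix elements
retain exactly that coupling.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `conv_rms` | 1e-7 | a.u. | SCF convergence on RMS([F,P]) |
| `lambda_tol` | 1e-10 | — | residual of the constraint value |
| `de_max_ev` | 15 | eV | orbital-energy selection window |
| `sigma_threshold` | 1e-6 | — | singular values below this count as zeros |
| `lin_dep_threshold` | 1e-8 | — | overlap eigenvalue cutoff (canonical orthogonalization) |
| `smear_K` | off | K | Fermi smearing temperature (annealed to 0 before final energies) |
| `grid_level` | medium | — | XC quadrature (nrad x ntheta: 30x10, 45x14, 70x20) |

The selection window counts each orbital with its excitation
multiplicity ($\sum_{a\in exc}\varepsilon_a - \sum_{i\in
exc}\varepsilon_i \le \Delta\varepsilon_{max}$) and can be combined
with an explicit occupied/virtual index window.  Degenerate gaps are
ordered by ascending orbital indices so that scans are reproducible.
The singular-value threshold defaults to 1e-6; very large reference
spaces can develop near-linear dependencies for which a looser value
is advisable, and any states discarded by the overlap cutoff are
reported on the result object.

## The multiplier solve

The constraint value $c(\lambda) = \sum_\tau \mathrm{Tr}
[\mathbf{P}^\tau(\lambda)\mathbf{W}_c^\tau]$ is monotone in $\lambda$
but comes in two regimes.  For many single excitations the target
$N_c$ sits on a *plateau* of $c(\lambda)$ (past an orbital crossing the
aufbau density meets the constraint exactly), and a bracketed Newton
iteration — the analytic derivative follows from first-order
perturbation theory of the aufbau density — lands on it within a
handful of diagonalizations.  When the target is the supremum of
$c(\lambda)$ (typical for paired doubles, where the frozen projector
can only be approached asymptotically), the residual decays like a
power of $1/\lambda$; the solver detects this, fits the tail from two
consecutive points, and jumps directly to the multiplier magnitude
meeting the requested residual.  Plain bisection was rejected for the
inner loop: it cannot reach a 1e-10 residual within the handful of
iterations per macro-cycle that makes the nested-loop design
affordable.  The iteration count of every inner solve is recorded on
the result (`lambda_iters`), and the acceptance suite asserts that the
single-excitation solve stays below ten.

DIIS extrapolates the *perturbed* Fock matrix
$\mathbf{F} + \lambda_c\mathbf{W}_c$, with the commutator error
evaluated in the orthonormalized basis.  Convergence requires both a
small commutator and a small density change between macro-iterations;
the latter guards against premature termination right after an
occupation rearrangement, where old and new densities can commute with
the same Fock matrix.  After convergence the multiplier is re-solved
once on the unextrapolated Fock matrix so the reported residual is
meaningful.  Non-convergence is returned as a status object carrying
the last iterate, not as an error — the disappearance of reference
solutions along a scan is data, and the scan driver records it per
point.

## Restricted and unrestricted states

There is a single spin-unrestricted SCF code path; closed-shell
(restricted) solutions arise as its spin-symmetric fixed point when
the initial guess and the constraint are spin-symmetric.  Single
excitations constrain one spin channel only and are therefore strongly
spin-contaminated ($\langle S^2\rangle \approx 1$); their spin-flipped
partners are generated by swapping the channel labels, so the pair is
symmetric to machine precision.  Paired doubles and seniority-two
doubles under the density constraint are spin-restricted (one
determinant each), which is why the classic four-orbital reference
space expands to 14 determinants here versus 16 with the
maximum-overlap comparison driver, whose seniority-two states break
spin symmetry.

The spin expectation matrix elements between nonorthogonal collinear
determinants are derived from the operator identity $\hat S^2 = S_z(S_z
+ 1) + \hat S_-\hat S_+$ with generalized Wick contractions in the
biorthogonal representation, including the one- and two-zero cases.
Because the derivation is easy to get subtly wrong (orderings and
phases), the implementation is certified against a brute-force oracle:
determinants are expanded into orthonormal-basis occupation strings via
minors of the coefficient matrix, and all operators are applied with
ordinary second-quantized algebra.  The oracle shares no code with the
biorthogonal path and is exercised over randomized determinant pairs
covering every zero-singular-value class at a 1e-10 tolerance.

## Atomic-orbital backend

The package ships a self-contained McMurchie–Davidson Gaussian
integral engine (overlap, kinetic, nuclear attraction, dipole,
two-electron integrals with Schwarz screening, Coulomb/exchange
builds) and two basis-set families generated in code from
Slater-exponent tables with a universal three-Gaussian fit: a minimal
basis (`"mini"`), a split-valence basis (`"svb"`, inner two primitives
contracted, outer primitive free), and a diffuse-augmented variant
(`"svb+d"`, one extra even-tempered s/p shell).  Internally everything
is in Hartree and bohr; geometries are read and written in Angstrom
and excitation thresholds given in eV.  Semilocal
exchange–correlation (Slater+VWN5, PBE, and global hybrids with 25%
or 50% exact exchange) is integrated on Becke-partitioned molecular
grids (Gauss–Chebyshev radial map, Gauss–Legendre x uniform-phi
angular product); the correlation potentials are analytic, with the
derivative code generated symbolically from the closed-form energy
expressions and validated against finite differences.  Coulomb
integrals are always evaluated analytically — no density fitting — as
resolution-of-identity errors in the two-electron integrals propagate
badly through the nonorthogonal matrix elements.

Exchange inside the NOCI matrix elements is always the full
Hartree–Fock operator regardless of the reference functional; the
functional enters only through the transition-density-functional
correction.

The Tamm–Dancoff solver uses the hybrid-exchange kernel (orbital-energy
differences + Hartree coupling + the functional's exact-exchange
fraction); the semilocal exchange–correlation kernel is omitted.  With
100% exact exchange this is exactly CIS.  TDA here serves to seed
constraint difference densities and as a comparison method, for which
the amplitude structure matters more than absolute kernel energies.
Diagonalization is dense with a size guard; all in-scope problems are
far below iterative-solver territory.

## What the generated fixtures emulate

All test geometries are generated in code: diatomics at prescribed
separations, water, planar all-E polyene chains with alternating
double/single bonds, butadiene with a bond-length-alternation
displacement, and 90-degree-twisted ethylene with one pyramidalized
CH2 group.  These are idealized standard-geometry structures, not
optimized ones, and the built-in basis sets are compact.  Passing
tests therefore demonstrate the *internal correctness* of the
machinery (matrix elements to 1e-10 against brute force, CIS
equivalence to 1e-8, exact diagonal identities, size consistency to
1e-6 Hartree) and the *qualitative physics* (singlet/triplet
purification, the dark doubly-excited state dropping below the bright
state in longer polyenes, smooth constrained dissociation curves where
maximum-overlap branches vanish).  They do not certify quantitative
agreement with large-basis reference data on optimized geometries:
absolute excitation energies in these small bases are systematically
too high, and properties sensitive to diffuse functions (anion-like
charge-transfer states) shift with the basis.  The lithium fluoride
worked example illustrates this concretely: the vanishing of the
sigma->sigma* maximum-overlap branch and the accompanying drop of
$\langle S^2\rangle$ from 1 toward ~0.65 reproduce, but the critical
separation depends on the basis (about 3.35 Angstrom in `svb+d`).

## Problem sizes in the validation suite

The acceptance tests run, on one CPU: the randomized oracle comparison
on 2–4-electron chains (about two hundred determinant pairs); water in
the minimal basis for CIS equivalence, diagonal identities and the
multiplier iteration bound; H2 split-valence for spin purification;
two helium atoms at 100 Angstrom for size consistency; a lithium
fluoride scan over 3.0–3.5 Angstrom with the diffuse-augmented basis;
and the n = 5 polyene (C10H12, 114 basis functions) with 50%-exact-
exchange references over the classic four-orbital space on a coarse
quadrature grid.  These sizes were chosen as the smallest systems that
still exhibit each phenomenon.

## Known limitations

- Basis sets are limited to the built-in H–Ne families; no effective
  core potentials, no f-functions, no periodic systems.
- Range-separated hybrids and meta-GGAs are not implemented; the
  functional ladder stops at global PBE hybrids and LSDA.
- The TDA kernel omits semilocal fxc (documented above).
- Spin purification by one flipped partner per single excitation is
  partial; strongly contaminated references (long polyene chains at
  high exact exchange) retain visible contamination in the final
  states.
- No analytic nuclear gradients; scans are over generated geometries.
- Spin-orbit coupling and relativistic Hamiltonians are out of scope;
  core-excitation workflows run in the nonrelativistic variant via the
  core-restricted TDA occupied window.
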