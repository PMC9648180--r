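---
title: "Methods: spin-free reduced density matrices from configuration interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spin-free reduced density matrices from configuration interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The molecular electronic Hamiltonian contains at most two-particle
interactions, so the two-electron reduced density matrix (2-RDM)
$\Gamma_{prsq}$ carries everything needed to evaluate the energy or any
other one- or two-electron property of a wavefunction — at a cost of at
most $M^4$ numbers for $M$ spatial orbitals, against the combinatorial
size of the configuration-interaction (CI) expansion itself. `cirdm`
implements the full pipeline that makes this useful in practice:

* a string-based full-CI (FCI) engine with bitwise Slater–Condon rules
  and Davidson iterative diagonalization;
* construction of the spin-free 2-RDM from any determinant expansion by
  four interchangeable strategies, including an $O(N_{SD} M^2)$ build
  that exploits the FCI string structure and a binary-search variant for
  general selected-CI expansions;
* truncated CI($n$) and Monte Carlo configuration interaction (MCCI) as
  sources of compact approximate wavefunctions;
* Löwdin spin projection to expand spin-pure configuration state
  functions (CSFs) into determinants;
* the comparison metrics used to appraise approximate wavefunctions:
  multireference character and unnormalized root-sum-square errors.

## Hamiltonian and conventions

With spatial orbitals $p,q,r,s$ and spins $\sigma,\sigma'$,

$$H = E_\mathrm{core}
  + \sum_{pq\sigma} h_{pq}\, a^\dagger_{p\sigma} a_{q\sigma}
  + \tfrac12 \sum_{prqs\,\sigma\sigma'} \langle pr|qs\rangle\,
    a^\dagger_{p\sigma} a^\dagger_{r\sigma'} a_{s\sigma'} a_{q\sigma}.$$

Integrals enter via FCIDUMP files (chemists' $(pq|rs)$ on disk, 1-based
indices, 8-fold permutational symmetry of real orbitals). Internally all
matrix-element code uses physicists' notation
$\langle pr|qs\rangle = (pq|rs)$; `convert_notation()` is an involution
applied at the I/O boundary. Frozen doubly occupied orbitals are folded
into an effective active-space Hamiltonian (`fold_frozen_core()`): their
mean field augments $h$ and a constant shifts $E_\mathrm{core}$, so the
folded FCI energy equals the unfolded energy with those orbitals held
doubly occupied (tested against restricted dense diagonalization).

The density matrices follow the convention in which **no** factor
$\tfrac12$ is absorbed into the 2-RDM (tag `"eq7-no-half"`):

$$\gamma_{pq} = \sum_\sigma \langle\Psi|a^\dagger_{p\sigma}
    a_{q\sigma}|\Psi\rangle,\qquad
  \Gamma_{prsq} = \sum_{\sigma\sigma'} \langle\Psi|a^\dagger_{p\sigma}
    a^\dagger_{r\sigma'} a_{s\sigma'} a_{q\sigma}|\Psi\rangle,$$
$$E = \sum_{pq} h_{pq}\gamma_{pq}
  + \tfrac12\sum_{prsq}\langle pr|qs\rangle \Gamma_{prsq}
  + E_\mathrm{core},\qquad
  \gamma_{pq} = \frac{1}{N_e-1}\sum_r \Gamma_{prrq}.$$

`energy_from_rdms()` refuses a 2-RDM carrying any other convention tag,
and the energy identity (contraction reproduces the variational
eigenvalue to 1e-9) is asserted in the acceptance suite — it is the
package's own validation of the derivation, exactly as one validates a
2-RDM code in practice.

## Determinants, strings, signs

A determinant is an (α-string, β-string) pair of bitmasks over spatial
orbitals; bit $p-1$ set means orbital $p$ occupied for that spin. R
integers are 32-bit, so $M \le 31$ per string — ample for everything the
package enumerates (the largest counted space uses $M = 28$, and
counting never enumerates determinants). Occupied-orbital extraction
uses the clear-lowest-bit idiom and excitation degrees come from
popcounts of XORs, mirroring the `popcnt`/`trailz` hardware approach.

The canonical operator order is **spin then orbital**: all α creation
operators (ascending orbital) before all β. Every sign in the package —
maximum-coincidence signs Θ for Slater–Condon elements, and the signs of
all 2-RDM updates — is defined relative to this order, computed by
counting occupied orbitals strictly between hole and particle positions,
with sequential intermediate-string bookkeeping for double
substitutions. Because published pseudocode for the update rules was not
machine-readable in our source material, the four delta-gated operator
arrangements for two-difference pairs, the spectator loop for
one-difference pairs, and the Coulomb/exchange diagonal terms were
re-derived from the definition of $\Gamma$ plus the anticommutation
relations, and are *certified* in the test suite against a brute-force
second-quantization oracle (explicit operator strings on ≤ 8 spin
orbitals, written independently of the bitwise code).

## String FCI and the sigma build

For each spin channel, `enumerate_strings()` generates the
$\binom{M}{n}$ strings in ascending bitmask order and (optionally)
tabulates every single and double excitation with its target address,
hole/particle orbitals and sign. The CI vector lives on the α×β grid
with the 1-based addressing
$\mathrm{FCI_{loc}} = (\beta_\mathrm{loc}-1)\,\alpha_\mathrm{total} +
\alpha_\mathrm{loc}$.

`sigma()` applies $H$ without forming it: diagonal terms from per-string
partial energies plus a cross-channel Coulomb bilinear form; same-spin
doubles from precomputed table entries (independent of the other
channel); same-spin singles with a vectorized Coulomb coupling to the
other channel's occupation matrix; and mixed-spin doubles as products of
one single from each channel. Symmetry restriction works by masking the
grid to determinants whose string-irrep XOR equals the target irrep;
since a symmetric Hamiltonian cannot mix irreps, Davidson iterations
stay in the subspace (the preconditioned residual is projected
explicitly).

`davidson()` defaults: residual tolerance 1e-9, diagonal preconditioner
with the level shift clipped at 1e-4 (clipping harder amplifies
round-off in converged residual components), subspace capped at 20
vectors per root before a restart from the current Ritz vectors, and a
deterministic unit-vector guess at the smallest diagonal entries unless
warm-started. Correction vectors are normalized before
reorthogonalization so that late, small corrections are not discarded;
degeneracies are handled by comparing only energies and invariant
subspaces in tests.

## 2-RDM construction strategies

* **Strategy 1** (transparent all-pairs): every ordered determinant pair,
  with each maximum-coincidence sign recomputed from explicit
  spin-orbital permutation parity.
* **Strategy 2** (bitwise): same loop, signs and hole/particle data from
  the bit machinery.
* **Strategy 3** (`i ≤ j`): only ordered pairs $i \le j$; each
  off-diagonal contribution is added together with its hermitian image
  $\Gamma_{qspr} \leftarrow \Gamma_{prsq}$.
* **FCI-structured** (`rdm2_from_fci()`): visits only pairs linked by the
  precomputed string excitation tables — $O(N_{SD} M^2)$ pairs for fixed
  electron counts, with the $N_\alpha(M-N_\alpha)N_\beta(M-N_\beta)$
  mixed doubles dominating. Accumulation is serial and deterministic
  (ascending table order with flat-index aggregation), so results are
  bit-reproducible; a `pair_visits` attribute exposes the visit count
  for the scaling test.
* **Search-based** (`rdm2_from_sd_list()`): for a general selected-CI
  expansion sorted by canonical determinant key, each determinant's
  generated substitutions are located by binary search; only
  substitutions present in the expansion contribute.

All routes agree elementwise to ≤ 1e-10 on every test wavefunction, and
to the brute-force oracle at machine precision on small spaces. Wall
clock is deliberately *not* asserted anywhere: relative timings of the
strategies are hardware- and runtime-dependent; the package asserts
output equivalence only.

## Truncated CI and MCCI

CI($n$) spaces are enumerated per channel by (excitation level × irrep)
and solved with the stored subspace Hamiltonian (dense eigensolver below
65 determinants, warm-started Davidson above). MCCI follows the classic
loop: randomly augment with symmetry/Ms-allowed single/double
substitutions of randomly chosen current configurations; diagonalize,
warm-starting from the previous coefficients; prune newly added
configurations with $\max_\mathrm{roots}|c| < c_\mathrm{min}$; every
10th iteration consider *all* configurations for deletion (the reference
determinant is never deletable — it anchors the space). The subspace
Hamiltonian is updated incrementally, touching only added/removed
rows/columns; a property test drives random edit sequences against a
from-scratch rebuild.

Parameters the literature leaves open are package choices, exposed as
options and reported in logs: `n_add = max(50, |configs|)` candidates
per iteration; convergence when the energy at consecutive full-prune
checkpoints changes by less than `5e-4` hartree twice in a row. The RNG
is re-keyed from `(seed, iteration)` each augmentation, so runs are
bit-reproducible and insensitive to how many draws an iteration
consumed.

## Spin projection

$S^2$ is applied as $S^-S^+ + M_s(M_s+1)$ with ladder operators acting
orbital-by-orbital through explicit fermionic phases in the canonical
operator order. The Löwdin projector onto spin quantum number $k$,
$$P_k = \prod_{r \ne k} \frac{S^2 - r(r+1)}{k(k+1) - r(r+1)},$$
runs $r$ ascending from the minimum compatible with the open-shell count
(0 or ½) up to half the number of unpaired electrons; the result is
independent of factor order. Duplicates are merged after each factor
(coefficient tolerance 1e-12) and normalization is deferred to the end;
expanding several CSF seeds dedups once more globally. A seed with no
spin-$k$ component yields an empty expansion, reported as such. Note the
sign structure is a property of the *determinant* representation: the
$M_s{=}0$ triplet from one open-shell pair has opposite-sign determinant
coefficients, the singlet equal signs.

## Metrics

Multireference character is computed on the determinant coefficients as
stored: $\varsigma_\mathrm{MR} = \sum_i c_i^2(1 - c_i^2) = 1 - \sum_i
c_i^4$ after normalization — 0 for a single configuration, $1 - 1/n$ for
$n$ equal weights, invariant under permutation and global phase. (The
displayed formula in our source was an image; this is the definition in
the works it cites, and the package asserts the limiting behavior rather
than any transcription.) The error measure is the *unnormalized*
root-sum-of-squares over all elements of the compared quantity, with the
global sign of a wavefunction chosen to minimize the error;
wavefunctions are embedded in the union determinant set with missing
coefficients zero. Because the measure is unnormalized, errors of
different quantities are not mutually comparable — only trends across
methods are.

## Counting determinant spaces without an SCF

The acceptance-grade space sizes are exact combinatorial counts: the
number of determinants of overall irrep $g$ is
$\sum_h n_\alpha(h)\, n_\beta(h \oplus g)$ over per-irrep string
histograms, and CI($n$) counts use joint (level × irrep) histograms —
never a pair enumeration. The histograms need only the *multiset* of
active-orbital irreps, and since a symmetry-adapted SCF cannot mix basis
functions of different irreps, orbitals-per-irrep equals basis
functions-per-irrep, which follows from the shell composition of the
basis (s, p, Cartesian d on atoms and diatomics). `molecule_setup()`
encodes these multisets for Ne/6-31G*, CO/6-31G, CO/cc-pVDZ and
O2/6-31G; the bundled setups use 6-component Cartesian d functions,
which is what reproduces the published orbital counts (15 orbitals for
Ne/6-31G*, 30 for CO/cc-pVDZ). The CO reference determinant used for
CI($n$) counting occupies the $3\sigma\,4\sigma\,1\pi_x\,1\pi_y\,5\sigma$
irrep pattern (a1, a1, b1, b2, a1) in the active space. Counts are
returned as doubles because the CO/cc-pVDZ space (≈ 2.4 × 10⁹) exceeds
32-bit integers; they are exact well below 2⁵³.

## What the synthetic fixtures do and do not establish

`make_fixture()` generates deterministic toy Hamiltonians: random
symmetric $h$ with random 8-fold-symmetric two-electron tables (the
generic case — no structure to hide sign errors), a two-orbital pairing
model with a closed-form 2×2 secular equation, and a Hubbard-like chain
whose $U = 0$ limit is exactly the filled non-interacting orbitals.
These exercise every code path (including $M_s \ne 0$ and
symmetry-restricted solves with synthetically symmetrized integrals) and
are cross-checked against an independent established FCI program on two
bundled FCIDUMP fixtures. What they do not emulate: realistic integral
magnitudes and sparsity of molecular systems, near-degenerate spectra of
stretched bonds at scale, or spaces beyond ~10⁴ determinants — so green
tests establish algorithmic correctness and exact self-consistency, not
large-scale performance. The named-molecule fixture kind documents the
external integral-provider boundary and fails with an explicit message
offline; consequently the published multireference-character values for
the named molecules are represented by a deliberately failing acceptance
test rather than a skipped or fabricated one.

## Known limitations

* Pure R: toy-scale FCI (≤ a few thousand determinants) runs in seconds,
  but the multi-million-determinant molecular spaces are *counted*, not
  solved, here.
* $M \le 31$ spatial orbitals per spin string (32-bit masks); no
  multiword fallback.
* Abelian point groups only (XOR-multiplicative irrep codes, D2h and
  subgroups); real orbitals assumed throughout.
* No transition 2-RDMs between different states, no spin-resolved 2-RDM
  blocks, no perturbative selection (CIPSI/heat-bath) — all outside the
  intended scope.
* Davidson keeps all vectors in memory; no disk-backed mode.
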