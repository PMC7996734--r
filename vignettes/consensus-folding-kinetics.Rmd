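---
title: "Consensus folding kinetics of aligned RNAs: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus folding kinetics of aligned RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnalikin)
```

## The problem and the model

Folding kinetics of an RNA — which metastable structures form and how fast
populations move between them — often matter more than the thermodynamic
ground state. A full simulation at single base-pair resolution is limited to
very short sequences, so `rnalikin` coarse-grains twice: structures of a
*multiple alignment* of homologous RNAs are scored together, and the folding
space is partitioned into position-aware abstraction classes before any
kinetics are computed.

### Pseudo free energy

A consensus structure $s$ (a non-crossing set of paired alignment columns)
is scored as

$$\Delta G^{\#}(s) \;=\; \overline{\Delta G}(s) \;+\; \lambda \sum_{(i,j) \in s} C_{ij},
\qquad C_{ij} = V_{ij} - \varphi\, Q_{ij},$$

where $\overline{\Delta G}$ is the arithmetic mean of the nearest-neighbour
free energy of $s$ over the alignment rows. Before a row is evaluated, $s$
is *projected* onto it: pairs with a gap in that row and pairs the row
cannot form (outside $BP = \{AU, UA, GC, CG, GU, UG\}$) are removed, and the
remaining pairs are re-indexed to ungapped sequence positions. The
projection keeps every row's energy well defined under any backend; a row's
inability to pair is not double-counted in the energy because it is already
penalized through $Q$.

The conservation score $V_{ij}$ sums, over all row pairs $(k, l)$ in which
*both* rows can form the pair, the Hamming distance between the two rows'
pairing bases, $h(s_{ik}, s_{il}) + h(s_{jk}, s_{jl})$: a compensatory
double change (G–C in one row, A–U in another) scores 2, a consistent single
change (G–C vs G–U) scores 1, identical pairs score 0. $Q_{ij}$ is the
fraction of rows that neither form the pair nor have gaps at both columns.

Two genuinely open choices are exposed as parameters:

* **Sign and size of $\lambda$** (default $-1.0$ kcal/mol per score unit).
  $V$ is a conservation *bonus*, so a positive weight added to the energy
  would penalize covariation; the default makes covariation lower the pseudo
  free energy, the convention of consensus-folding methods generally. Any
  sign is accepted, so the opposite reading remains available.
* **Normalization** of $V$: `per_M` divides the sum over the
  $M(M-1)/2$ row pairs by $M$ (the literal prefactor of the score as usually
  printed); `per_pairs` divides by the number of row pairs, which makes $V$
  values comparable across alignment depths. Default `per_M`.

$\varphi \ge 0$ (default 1.0) scales the penalty.

### Energy backends

Row energies come from a pluggable nearest-neighbour backend built on the
unique loop decomposition of the structure (hairpin, stack, bulge, internal,
multiloop; the external loop contributes zero).

* `toy_backend()`: stack $-2.0$, hairpin closure $+3.0$, bulge/internal
  $+2.0$, multiloop $+4.0$ kcal/mol. Every energy in the documentation and
  in the tests is hand-computable with these five constants.
* `turner_backend()`: a Turner-style table bundled as a plain-text file
  (6×6 stacking matrix over $BP$, loop-length initiation energies with
  Jacobson–Stockmayer $1.75\,RT\ln(n/n_{\max})$ extrapolation, affine
  multiloop score). Dangling ends, coaxial stacking, terminal-AU penalties
  and sequence-specific loop bonuses are deliberately excluded: they would
  make the loop decomposition ambiguous, and none of the package's claims
  depend on absolute single-sequence energies. The table is a simplified
  parameter set, not a replica of any published one; users can point
  `turner_backend(path =)` at their own file.

### Hishape abstraction

A helix is a maximal run of directly stacked pairs; its index is
$(i+j)/2$ of the innermost pair, a half-integer when $i+j$ is odd, marked
`m`/`b`/`i` when the helix closes a multiloop, bulge or internal loop. The
hishape of a structure is its 5'→3' ordered list of retained helix indices;
the open chain is the distinguished `[_]`. Levels retain: `h` hairpin
helices only; `m` hairpin + multiloop helices; `a` all helices; `h+`
hairpin + multiloop helices whose loop has at least `hplus_min_branches`
direct branches. Since every multiloop has at least two branches, `h+`
coincides with `m` at the default threshold — the exact membership of the
intermediate level is historically underspecified, so the threshold is kept
as an explicit, documented toggle rather than a hidden convention. Markers
participate in hishape equality at all levels that retain them.

Helix indices live on alignment columns; `project_hishape()` recomputes them
per row through the row's gap-aware coordinate map, which is how consensus
trajectories are compared with single-sequence ones (an index shifts left by
the number of gaps the alignment inserted before the helix).

## Folding space enumeration and the k best classes

Candidate structures are *canonical*: no lonely pairs
(`min_helix_length = 2`), hairpin loops of at least 3 unpaired columns, and
every pair must pass the base-pairing filter `pair_fraction >= bp_threshold`
(default 0.5 — at least half the rows can form the pair; a boundary value
passes). `enumerate_structures()` generates each such structure exactly once
by a memoized grammar-style recursion over maximal helices;
`kbest_hishapes()` classifies the stream and returns the `k` classes with
the lowest class-minimum pseudo energy, each with its hishrep.

Exhaustive enumeration is the default strategy because the package targets
desk-scale alignments (tens of columns) where exactness is affordable and
verifiable — the brute-force oracle `brute_force_hishapes()` re-derives the
same classification by a plain, unmemoized interval backtracking, and the
test suite requires exact agreement on dozens of synthetic alignments. An
optional `energy_band` restricts enumeration to structures within a band
above the minimum. Determinism is guaranteed by explicit tie-breaking:
classes with equal energies order by hishape text, structures within a class
by dot-bracket string.

The external-loop filter (`x_filter`, off by default) removes structures
containing an external-loop component with pseudo energy strictly greater
than a threshold `e`; components *at* the threshold survive. With `e = 0`
this encodes the intuition that a substructure with non-negative pseudo free
energy is unlikely to form; strictness at the boundary is chosen so that
`e = 0` keeps exactly the components that are at worst neutral.

## Refolding pathways and barriers

`direct_path()` estimates the saddle energy between two structures with a
width-limited breadth-first search over the *direct move set*: only base
pairs unique to start or target may be added or removed, each move reduces
the base-pair distance by one, so a path has distance + 1 states. The
frontier keeps at most `width` partial paths (default 16), ranked by the
lowest saddle seen so far, then current energy, then dot-bracket — ranking
by saddle-so-far rather than current energy is the one substantive choice
here, made because the quantity being minimized is the barrier itself.
Paths meeting at the same structure are merged keeping the better saddle.
Intermediates may contain lonely pairs (single-pair moves cannot preserve
canonicity), but moves creating hairpins shorter than 3 are never generated,
since every pair of either endpoint spans at least 4 positions.

`indirect_barrier()` additionally tries each supplied intermediate $m$
(typically the other hishreps) as a stop-over, taking the best of the direct
path and $\max$ of the two legs $a \to m \to b$. A single stop-over (rather
than nested recursion) keeps the cost quadratic in the number of classes;
the scaffold fixture in the tests shows a case where an intermediate hairpin
lowers the saddle below the direct move-set optimum.

`minimax_barrier_oracle()` computes the exact minimax saddle over the full
toggle graph of the direct move set (best-first search, guarded); the tests
require the beam to match it at saturating width and to be monotone in
width on every fixture.

## Kinetics

Rates between classes follow the Arrhenius form
$r(a \to b) = A \exp(-(B_{ab} - E_a)/RT)$ with $RT = 0.0019872\,T$ kcal/mol.
Neither the prefactor, the temperature, the time unit, nor which state pairs
get rates are fixed by the coarse-grained model itself, so the defaults are
recorded choices: $A = 1$ (time in arbitrary units on a log axis),
$T = 310.15$ K, rates between *all* pairs of selected classes, barriers
symmetrized to the best value found in either direction (which guarantees
detailed balance with respect to the Boltzmann weights of the class
energies), and pairs without a found path disconnected with rate 0 (reported
via a message, never a silent zero).

`simulate_kinetics()` propagates $p(t) = p_0 e^{Rt}$ through the
symmetrized eigendecomposition $S = D^{1/2} R D^{-1/2}$ ($D$ the Boltzmann
weights), which is stiff-safe over arbitrarily long horizons. Eigenvalues
above $-10^{-12}\,\|\Lambda\|$ are clamped to zero: the generator's
equilibrium mode is analytically zero, and its numerical residue would be
amplified by $e^{\lambda t}$ at $t \sim 10^{10}$. The default grid is 60
log-spaced times on $[10^{-2}, 10^{10}]$. `equilibrium()` solves
$\pi R = 0$ directly (per connected component, with a warning when the
matrix is reducible) and the tests require the $t \to \infty$ populations to
match it to $10^{-6}$, and the two-state closed form to $10^{-8}$.
`group_populations()` sums curves over disjoint groups of states, the
device used to compare homologs whose equivalent hishapes have shifted
indices.

The pipeline preset `neg_only = TRUE, start_open = TRUE` simulates all
strictly negative level-`h` classes plus the open chain, starting from the
open chain — the protocol for switch-like RNAs where the unfolded state is
the biologically meaningful origin.

## The synthetic generator: what it emulates, what it does not

`generate_alignment()` evolves `n_rows` sequences from an ungapped reference
around a planted structure: each planted pair is, with probability
`comp_rate`, jointly replaced by a different member of $BP$ (the covariation
signal $V$ rewards), unpaired positions mutate independently at `mut_rate`,
and gaps follow one of two policies — `terminal` (gaps only in the flanks
outside the planted pairs, keeping truth bookkeeping exact; the default) or
`interior` (random inserted columns, each row drawing a base or a gap, for
coordinate-projection tests). Defaults (`n_rows = 8`, `comp_rate = 0.5`,
`mut_rate = 0.05`, `gap_rate = 0`) are the conditions under which the
recovery property is stated: the planted hishape should be recovered as the
rank-1 consensus class in at least 9 of 10 seeded replicates.

One fixture-design lesson is recorded here because it is easy to trip over:
the recovery property is only meaningful if the planted pairs are *visible*
to the abstraction level being checked. A planted structure whose main helix
closes an internal loop contributes nothing to its level-`h` hishape, so a
recovery check at level `h` would measure mutation noise on the small inner
hairpin instead of covariation recovery. The bundled recovery fixtures
therefore plant hairpin helices.

What the generator does **not** emulate: phylogenetic correlation between
rows (rows mutate independently — real alignments have tree structure, so
the effective number of independent row pairs is smaller than $M(M-1)/2$),
indel evolution (gaps are placed by policy, not by an evolutionary model),
and alignment error (columns are true homologies by construction). Passing
recovery tests therefore show that the scoring extracts a planted
covariation signal at realistic rates, not that the method is robust to
misalignment or phylogenetic bias.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed intervals everywhere; helix indices are
  exact half-integers (printed with one decimal only when fractional).
* IUPAC ambiguity codes are rejected at parse time: the covariance score is
  defined on concrete bases.
* A single-row alignment is the degenerate single-sequence mode: the row
  pair sum in $V$ is empty, so $C = -\varphi Q$, and with $\lambda = 0$ the
  pseudo energy equals the single-sequence energy exactly.
* An alignment with no admissible pairs yields exactly one class, the open
  chain, with pseudo energy 0.
* Energy ties: class order by hishape text, in-class representative by
  dot-bracket; repeated runs are byte-identical.
* Guards: enumeration aborts beyond `max_structures` (default $2 \times
  10^5$) and the minimax oracle beyond `max_states` ($10^6$) rather than
  degrade silently.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic,
code-generated fixtures: alignments of 20–30 columns with 1–8 rows for
enumeration and recovery, refolding fixtures of 10–30 nucleotides, and rate
matrices of 2–4 states. These sizes keep every heuristic checkable against
an exact oracle (exhaustive classification, minimax saddle, closed-form
kinetics) — the package's claims are exactness claims at desk scale, and the
heuristics (beam width, indirect stop-overs, energy bands) are the knobs
that scale the same machinery to longer RNAs.

## Known limitations

* No partition-function / ensemble pseudo energies: a class is represented
  by one structure, so class size does not influence the kinetics.
* No co-transcriptional folding; full-length sequences only.
* No pseudoknots, no Stockholm input, no alignment construction — alignments
  are taken as given.
* The bundled Turner-style table is simplified (no dangles, coaxial
  stacking, or special loops); for publication-grade single-sequence
  energies substitute a full parameter file.
* Barrier estimates are upper bounds from a heuristic; width monotonicity
  and oracle agreement are verified on small fixtures, not guaranteed
  globally.
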