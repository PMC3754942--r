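---
title: "Designing biased repeat-protein libraries and modelling binder characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing biased repeat-protein libraries and modelling binder characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphareplib)
library(dplyr)
```

## The problem

Artificial helicoidal repeat proteins (αRep) are built from stacked 31-residue
HEAT-like modules flanked by N- and C-terminal caps. Six surface positions per
module — 18, 19, 22, 23, 26 and 30 — form the binding surface and are
randomised when a selection library is built. Two design questions follow:

1. **Which codons, in which proportions?** Full randomisation (NNK everywhere)
   wastes library diversity on side chains that are rare at a given position
   in the natural repeat family and admits chemically undesirable residues
   (cysteine everywhere; proline at helical positions 22, 23, 26). Instead,
   each variable position is encoded by a *mixture of partially degenerate
   codon cassettes* whose pooled translation mimics the natural
   position-specific residue distribution. For the adjacent pairs 18–19 and
   22–23, both codons must sit on the same synthetic oligonucleotide, so the
   unit of design is a *codon-pair cassette* and the design target is a
   *dipeptide* distribution.
2. **How good is the resulting library?** This splits into combinatorial
   accounting (how many repeat sequences are encoded, how completely a library
   of a given size samples them) and a stochastic model of the construction
   process itself — micro-gene circle polymerisation introduces frame-shifted
   modules, which an in-frame "filtration" step (phage display of an
   N-terminal tag) removes before the validated modules are shuffled into the
   final library.

The package implements both, plus the biophysical models used to characterise
selected binders: one-site and competitive-displacement isothermal titration
calorimetry (ITC), two-state differential scanning calorimetry (DSC), and 1:1
surface plasmon resonance (SPR) kinetics.

## Degenerate codon algebra

A degenerate codon is three IUPAC ambiguity symbols standing for an equimolar
pool of concrete codons. `expand_degenerate_codon()` enumerates the pool;
`translate_degenerate_codon()` turns it into a residue distribution under a
stop-codon policy. The default policy, `drop-renormalize`, removes stop
codons and renormalises — the appropriate model when stop-bearing sequences
are removed downstream. `amber-as-Gln` instead reads TAG as glutamine,
modelling supE amber-suppressor hosts; TAA and TGA are never read through.

```{r}
translate_degenerate_codon("vnk")   # N-cap 18/19: 16 residues, no C/W/Y/F
```

One deliberate surface: the N-cap positions 22/23/26 codon is recorded as
`dht` in the published materials, whose literal expansion encodes only 9
residues (N, T, I, D, A, V, Y, S, F), while the 13-residue set printed
alongside it (A, D, E, F, I, K, L, M, N, S, T, V, Y) is exactly what `dhk`
encodes once the amber codon is dropped. The package implements both codons
faithfully and leaves the choice to the caller rather than guessing which of
the two the authors meant:

```{r}
nrow(translate_degenerate_codon("dht"))
sort(translate_degenerate_codon("dhk")$residue)
```

Within a cassette, bases mix equimolarly (the standard assumption for
degenerate-oligo synthesis); design weights act only *between* cassettes,
via `mixture_distribution()` and `optimize_weights()`.

## The design target: position profiles from a repeat collection

`position_frequencies()` and `dipeptide_frequencies()` compute per-position
marginals and adjacent-pair joint frequencies from an aligned module
collection, after `curate_collection()` removes modules with more than three
indels (gap characters). Gap handling is the simplest auditable rule: a
module's indel count is its number of gap characters, and gap-bearing rows
are excluded per-position from frequency denominators.

The natural collection behind the published design (1719 curated repeats
mined from a sequence database) is not itself published, so the package
ships `generate_synthetic_collection()`: it draws aligned modules whose
variable-position marginals follow a configurable profile
(`default_position_profiles()` encodes the documented qualitative trends —
proline commonest at 18 and absent from 22–30, small residues at 23, large
polar residues at 30 — as a stylized, explicitly synthetic stand-in), with
optional coupling of the 18–19 and 22–23 pairs to a specified joint table.
Tests verify that marginals are recovered within total-variation 0.06 at the
collection size of 1719, and that uncoupled positions pass a chi-square
independence test. What passing these tests shows is that the *estimators*
are correct; it says nothing about how closely the stylized profiles track
the real repeat family, which is exactly why the profile is an input, not a
constant.

Aromatic enrichment — the published design raises Tyr/Trp above their
natural frequency by an unstated factor — is exposed as an explicit
per-residue multiplier (`boost_residues()`) rather than a guessed value.

## Cassette selection and weight fitting

The published scheme encodes the 18–19 dipeptides with 26 cassettes and the
22–23 dipeptides with 24, chosen so that most encoded dipeptides are among
the most frequent natural ones (87 and 60 distinct dipeptides encoded; 65/87
and 54/60 among the natural top-100). The cassette identities are not
published, and no selection algorithm is named, so the package states its
own and makes it reproducible:

* `enumerate_cassettes()` forms all ordered codon pairs from the printed
  per-position codon lists (110 candidates for 18–19, 150 for 22–23),
  annotating each with its encoded dipeptide set and flagging
  constraint violations (no Cys anywhere; no Pro at 22/23/26).
* `select_cassettes()` runs greedy (optionally frequency-weighted)
  maximum-coverage selection followed by single-swap local refinement until
  no swap improves coverage. Ties break lexicographically on the codon
  strings, so the design is deterministic. Greedy max-coverage carries the
  classical (1 − 1/e) guarantee, and the swap step only improves on it;
  on toy instances the tests compare against exhaustive search.
* `optimize_weights()` fits cassette proportions to a target distribution by
  least squares constrained to the probability simplex, via projected
  gradient descent with backtracking line search. The iteration is monotone
  in the objective and stops when the objective decrease falls below 1e-9.
  Projected gradient was chosen over a QP formulation because the problem is
  small, the simplex projection is exact, and monotone descent is an
  invariant worth asserting. Target mass outside the encodable support is
  reported as irreducible, never silently dropped.

Because the published counts (87, 60) describe the authors' unpublished
cassette choice, the package treats them as lower bounds for its own
selector — which, at the published budgets, covers 110 and 128 dipeptides
respectively — and does not claim to reproduce the original sets.

```{r}
cs <- codon_sets()
lib <- select_cassettes(enumerate_cassettes(cs$pos18, cs$pos19), budget = 26)
length(encoded_dipeptides(lib))
```

## Diversity accounting

`repeat_space()` multiplies per-site alternative counts exactly
(87 × 60 × 16 × 3 = 250,560 repeat sequences, ≈ 2.5 × 10⁵);
`protein_space()` raises that to the number of repeats in exact
big-integer arithmetic, since 250,560⁷ ≈ 6 × 10³⁷ overflows double
precision. `expected_distinct()` quantifies sampling coverage under the
uniform-sampling assumption (the construction process gives no
clone-frequency model): a library of size L drawn from S equiprobable
variants contains S(1 − (1 − 1/S)^L) distinct ones in expectation — so a
single repeat's space is sampled exhaustively by a 1.7 × 10⁹-clone library
while two-repeat space already is not.

```{r}
diversity_report(c(87, 60, 16, 3), n_repeats = 0:4, library_size = 1.7e9)
```

## The assembly, filtration and shuffling model

The construction simulator uses the minimal model sufficient for the
published library-characterisation columns: each clone draws a repeat number
n from a configurable distribution; each inserted module is independently
frame-shifted with probability ε_mod; caps fail with ε_cap; a clone is
coding iff nothing is defective. The closed form

> in-frame fraction = (1 − ε_cap)² · Σₙ p(n) (1 − ε_mod)ⁿ

is implemented in `analytic_inframe()` and the simulator is tested against
it within 3σ binomial error at 10⁵ clones. The repeat-number family defaults
to a truncated geometric on 0..10 with mean 2, matching the reported mean
size of coding clones in the primary library; the true distribution of the
rolling-circle assembly is uncharacterised, which is why the family is a
config parameter. Defaults ε_mod = 0.2 (the primary library's 20% defective
motifs) and ε_lig = 0.03 (the shuffled library's 97% correct motifs) are the
documented study conditions, and ε_cap defaults to 0 because the published
table does not separate cap from module errors.

`filter_inframe()` models the anti-tag phage capture (idempotent, keeps
exactly the coding clones), `shuffle_modules()` reassembles clones from the
validated module pool with fresh ligation errors, and `library_stats()`
reports the five characterisation columns on a seeded clone sample. The
simulated pipeline reproduces the published trend: filtration + shuffling
raises both the in-frame fraction and the mean motif number among coding
clones. The companion shorthand `inframe_from_motif_rate()` (q^n̄) evaluated
at q = 0.97, n̄ = 2.3 gives 93%, the in-frame percentage reported for the
optimized library.

## Clone annotation

`annotate_protein()` segments a clone against a `scaffold_spec()` by exact
length arithmetic — caps anchored at the ends, |sequence| = |N-cap| + 31k +
|C-cap| — rather than profile HMMs, which fixed 31-residue modules make
unnecessary. Segments are verified against consensus at the non-variable
positions (default mismatch tolerance 20% per segment; the worst offending
segment is named on rejection), and the six variable-position residues per
motif are tabulated with one row for the N-cap and one per module, the
layout used in the published binder table. The real scaffold consensus is
published elsewhere, so the shipped `default_scaffold()` is explicitly
synthetic; it places a BsmBI-like CGTCTC site at fixed module codons so that
`check_reading_frame()` can verify restriction-site integrity alongside
length-mod-3 and internal-stop checks. `generate_fixture_clone()` is the
exact inverse of annotation (property-tested for k = 0..8 modules), using a
fixed back-translation table so DNA fixtures are deterministic. A truncated
C-cap — proteolytic clipping of the last helices is a known behaviour of
these scaffolds — can be modelled by configuring a shorter C-cap consensus.

## Binding models

All simulators are deterministic at zero noise and seeded otherwise, and
every fitter is tested to invert its simulator exactly on noise-free data.

**One-site ITC.** The cell/syringe bookkeeping uses the perfusion (overflow)
convention: an injection of dV mixes into the V₀ cell and expels dV of mixed
solution, so cell species dilute by V₀/(V₀+dV) per injection and the
expelled complex is subtracted from the measured heat. Each injection's heat
is the change in V₀·ΔH·[complex], with [complex] from the exact quadratic
solution of the 1:1 equilibrium. The fit (`fit_one_site()`) runs
Levenberg–Marquardt on (log K_d, n, ΔH), initialised from curve heuristics.
Defaults mirror the published instrument setup: 200 µL cell (the printed
"0.24 µL" is treated as a typographical artifact and the volume is a
parameter), 2 µL injections, titrant 200–350 µM into 20–35 µM target — a
Wiseman c of ~190 for the 141 nM interaction, which is why the recovery
tests average over replicate titrations: near the steep-curve regime single
noisy titrations determine K_d only to ~±15%.

**Competitive displacement.** A tight binder titrated into receptor
pre-bound to a weaker one sees the apparent affinity
K_app = K_a^strong / (1 + K_a^weak·[weak]) (`apparent_ka()`), bringing
single-digit-nM binding into the fittable range. The simulator and fitter
solve the ternary equilibrium exactly — bracketed root finding on the
monotone mass balance in free receptor, Newton-polished, tested to 1e-9
against the closed-form cubic — and the initial cell heat content accounts
for the pre-equilibrated weak complex. The weak ligand's (K_d, ΔH) are held
fixed during fitting, as in the published analysis.

**DSC.** The two-state excess heat capacity
ΔCp(T) = K(T)·ΔH_cal·ΔH_vH / [(1+K(T))²RT²] is parameterised with the van't
Hoff constant K(T) = exp[(ΔH_vH/R)(1/T_m − 1/T)] — the anchoring K(T_m) = 1
is the only choice that makes the printed equation peak at T_m, with height
ΔH_cal·ΔH_vH/(4RT_m²) and area ΔH_cal (both property-tested).

**SPR.** 1:1 Langmuir association/dissociation, with k_off fitted first on
pooled dissociation phases and k_on second with k_off fixed (separate-rate
fitting, as in the published analysis); K_d = k_off/k_on. The published
rates give K_d = 5.7 nM, i.e. 6 nM at one significant figure.

**Thermodynamics.** `gibbs()` applies ΔG° = −RT ln K_a = ΔH° − TΔS° with
R = 1.9872 cal mol⁻¹ K⁻¹.

```{r, fig.width = 5, fig.height = 3.5}
p <- one_site_params(kd = 141e-9, n = 0.9, dh = -12)
e <- itc_experiment(cell_conc = 30e-6, syringe_conc = 350e-6)
fit <- fit_one_site(itc_heats(p, e, noise = 0.02, seed = 1), e)
tidy(fit)
autoplot(fit)
```

## Numerical choices and problem sizes

* Simplex-projected least squares: objective tolerance 1e-9, so fitted
  weights are accurate to ~3 × 10⁻⁵; iteration is monotone by construction.
* Ternary equilibrium: uniroot bracket [0, M_tot] (the mass balance is
  monotone), tolerance 1e-12 relative, plus Newton polish.
* Nonlinear fits parameterise rate/affinity constants on the log scale to
  keep them positive; non-convergence raises, never returns silently.
* Stochastic test sizes were chosen as the smallest that make the assertions
  sharp: 10⁵ clones for binomial 3σ agreement with the assembly closed form,
  collections of 1719–5000 modules for profile recovery, 5–10 seeded
  replicates for fit-recovery averages.
* Zero-mass and degenerate inputs (all-gap columns, empty module pools,
  budget 0, only-stop codons) are rejected with diagnostics rather than
  propagating NaN.

## Known limitations

* The synthetic collection and scaffold are stylized stand-ins; analyses of
  real repeat families should load their own aligned FASTA and consensus.
* The assembly model is binary per module (correct/frame-shifted) and knows
  nothing of nucleotide-level error mechanisms or phage growth competition.
* Coverage accounting assumes uniform clone sampling.
* The ITC models are strictly 1:1; several published binders are homodimers
  whose measured K_d is a composite of dimer dissociation and binding — the
  package reports what the one-site fit reports, as the instrument software
  would, and leaves coupled-equilibrium models out of scope.
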