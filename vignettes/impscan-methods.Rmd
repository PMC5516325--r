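---
title: "Methods: motif-based HolPase discrimination, profile HMMs and assay kinetics"
author: "impscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based HolPase discrimination, profile HMMs and assay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impscan)
```

This vignette records the scientific model behind each module, the
tunable parameters, the numerical choices, and the design decisions
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The classification problem

Bacterial genomes carry several paralogous IMPase-like proteins of the
FIG superfamily. In *C. glutamicum* these are HisN (the
histidinol-phosphate phosphatase of l-histidine biosynthesis), Cg0911
(weak HolPase side activity), SuhB, ImpA and CysQ (no detectable
HolPase activity). Mutual sequence identities are only 20–30%, and
within that band overall similarity does not predict function: some
proteins annotated as HolPases are SuhB-like, and some true HolPases
score below the similarity cut-offs normally used for ortholog calls.
Function tracks a small number of conserved residues instead, grouped
into six motifs along the sequence.

## Motif model

A motif is a set of reference-anchored positions, each carrying an
allowed residue class and a level:

* **required** positions drive presence (examples for HisN motif 5:
  Asp191 with Glu tolerated; aromatic 193; aromatic-or-His 195; exactly
  one aromatic at 188/189 with the counterpart small).
* **preferred** positions express the weaker "highly/moderately
  conserved" statements (e.g. Arg187 with Val/Leu tolerated, Gly190,
  aromatic 192). A motif needs a fraction of its preferred outcomes
  satisfied; the threshold defaults to 0.7 (`preferred_fraction_threshold`,
  exposed in the rule schema) — lenient enough that a single deviant
  weakly-specified residue does not flip a motif that keeps all its key
  residues.
* **forbidden** patterns veto a motif. HisN motif 5 forbids the
  Asp-then-Leu pair characteristic of Cg0911/SuhB/ImpA at the positions
  homologous to SuhB 203/204. We place this pair at HisN reference
  positions 195/196 using the arginine anchor correspondence (SuhB
  Arg195 aligns with HisN Arg187, a +8 offset).

Motif 1 has alternative variants (OR semantics) covering the
proteobacterial N-terminus with Lys at 34 *or* 35, an aromatic at 40
and Asp41; the two placements of the lysine are encoded as two
alternative position lists.

Positions are 1-based in each family's reference protein. Queries are
anchored to the reference by an optimal global alignment
(`anchor_map()`), so motif evaluation is independent of query
numbering, terminal extensions and moderate indels.

Qualitative conservation wording maps to rule levels as: "strictly
conserved" → required with a singleton class; "highly conserved" →
required where an explicit tolerance is named (D/E at 191, R/V/L at
187), otherwise preferred; "moderately conserved" → preferred. For the
non-HisN families only the textually specified discriminating residues
are encoded (SuhB: Arg195+Arg196 then GSAAL, Asp203/Leu204; ImpA: the
Arg179/Arg181 pair; CysQ: the Ser64 motif-2 variant in its own
coordinates, Pro219, and the absence of aromatics at 192–195 and of
Asp/Glu at 191); their remaining motifs carry the residues shared by
all IMPase-like proteins (Asp46, Glu69/Glu70, the Asp85/Ile87/Asp88/
Thr90 active-site block, Asp215) plus a schematic Gly96 anchor for
motif 4, whose full composition is only available graphically in the
original analysis. CysQ ships five motifs: its highly conserved motif 4
has no positional definition available, so none is invented.

## Reference scaffolds

The real *C. glutamicum* proteins are not bundled (they are two small
GenBank downloads; see `inst/extdata/README.md`). For simulation and
testing the package generates *synthetic reference scaffolds*
(`make_family_reference()`): 260-residue sequences with the canonical
residue of every rule position implanted and all other positions drawn
from background frequencies. They satisfy the family's rules by
construction and share nothing else with the database proteins — so
passing tests demonstrate the machinery (anchoring, rule evaluation,
classification logic), not recovery of the real proteins' measured
identities.

## Classification and triage

`classify_sequence()` aligns a query to all five references
(Needle-default scoring), picks the best family by score (canonical
tie-break HisN > Cg0911 > ImpA > SuhB > CysQ, with a warning), scans
the best family's motifs, and assigns the family only when all its
motifs are present. Triage mirrors the misannotation survey: class 1 =
best family HisN, motifs present, overall score below the
identification threshold (still called a HolPase — motif evidence
overrides moderate similarity); class 2 = best family HisN but motif 5
absent (not a HolPase); class 3 = annotation claims HolPase but the
protein is most similar to a non-HisN family whose motifs are present
(reassigned).

The ortholog-identification cut-off "BlastP score ≥ 125 bits with ≥80%
coverage" is approximated by thresholds on the package's own alignment
score and on the aligned fraction of the query (default 0.80). The
default score threshold of 300 was calibrated once on the synthetic
scaffolds: cross-family scaffold alignments score ≤ ~40 while
within-family alignments of simulated orthologs score in the hundreds
to ~1400, so 300 separates the five paralogs cleanly while leaving
deliberately distant simulated orthologs below it (the class-1 regime).
This mapping is an approximation, not a reproduction of BlastP bit
scores, which the package does not compute.

## Taxonomy roll-up

Presence is rolled bottom-up: a genus is positive with ≥1 positive
species; every higher rank is positive with ≥3 positive children or
with positive children ≥ half of the non-unknown children. Species of
unknown presence (no sequence data) leave the denominator. The rule is
monotone: adding a positive species can never turn an ancestor
negative.

## Profile HMM engine

`build_hmm()` constructs a Plan7-like model without the flanking
N/C/J loop states: match columns are alignment columns with gap
fraction < 0.5; match emissions are column counts plus a
background-weighted pseudocount (total mass 0.1 by default, BLOSUM62
marginal background); insert emissions equal the background;
transitions come from the observed per-row state paths with Laplace
(+1) smoothing (observed I↔D adjacencies, which the architecture lacks,
are skipped). The model is matched globally; leading/trailing sequence
is absorbed by the terminal insert states I0/IM at zero emission
log-odds, so flanks cost only transition probability ("glocal"
alignment — a documented divergence from HMMER's multi-hit local
architecture).

Scoring runs the forward or Viterbi recursion in log space (Rcpp);
the bit score is log2 P(seq | model) − log2 P(seq | background i.i.d.
null, no length term). Residue X emits with zero log-odds. E-values
come from a Gumbel tail fitted by maximum likelihood to the forward bit
scores of ≥ 1000 background sequences of matched length
(`calibrate_evalues()`); E = database size × P(S ≥ s). Iterative search
rebuilds the model from the Viterbi realignment of the included hits
(insert-state residues are dropped from the rebuilt alignment) until
the included id set repeats. The sequence-level inclusion threshold
defaults to the UniProt-scale 1e-65; desk-scale databases need a laxer
value (tests use 1e-5 on 16–40 sequence databases). jackhmmer's
distinct sequence- and domain-level cutoffs are deliberately collapsed
into the single sequence-level threshold.

## Kinetics

The malachite-green assay chain is: calibration line (absorbance vs
known phosphate, OLS, linear range 0.07–0.85 AU enforced with
warnings), initial rates as OLS slopes of released Pi vs time (negative
slopes floored at 0), then the Hill equation in the half-saturation
parameterization

v = Vmax · Sʰ / (S₀.₅ʰ + Sʰ),

fitted by Levenberg–Marquardt least squares with ≥16 multi-starts over
a log-spaced S₀.₅ grid × h ∈ {0.7, 1, 2, 4}; kcat = Vmax / [E] and
kcat/Km = kcat / (S₀.₅·10⁻⁶) in s⁻¹ M⁻¹. Concentrations are µM
internally; only the efficiency converts to molar at the boundary. The
"Km" reported by saturation assays of cooperative enzymes is read as
S₀.₅, the half-saturation concentration.

Product activation (the l-histidinol stimulation of Cg0911) uses a
hyperbolic Michaelian activation term
v(x) = v0 (1 + (fold−1)·x/(k_act+x)); the experiments report only the
plateau fold-change and the half-maximal concentration, not a
functional form, so the hyperbola is a documented assumption (the
identity v(k_act) = v0(1+fold)/2 holds exactly). A fit whose fold 95%
CI includes 1 is flagged "no activation". Replicates are pooled as
individual points rather than averaged first; with multiplicative
noise of constant CV the two choices give nearly identical estimates
and pooling keeps the residual degrees of freedom honest.

## Synthetic generators

`simulate_family()` mutates a reference scaffold with per-column
substitution rates by conservation category (strict 0, high 0.05,
moderate 0.3, variable 0.7), drawing replacements from
BLOSUM62-conditional exchange distributions (likelier exchanges more
probable) and placing indels only in variable columns (geometric
lengths, p = 0.5, capped at 5; rate 0.01/column). Motif positions —
required *and*, by default, preferred — are held fixed
(`protect_preferred = TRUE`): real ortholog families keep all six
motifs detectable in essentially every member (the original database
scan found them in 1687 of 1695 HMM hits), and a generator that
mutates single preferred positions of one-position motifs at 5% would
contradict that regime. Sensitivity of motif presence to individual
positions is therefore probed with explicit ablations
(`ablations = list(list(motif, position, replacement))`), which bypass
protection. What the simulations consequently do *not* exercise is
borderline preferred-fraction arithmetic on naturally drifted
sequences; the threshold logic is covered by constructed cases instead.

`simulate_kinetics()` applies multiplicative Gaussian noise
(1 + CV·z), CV 0.05 by default, to the model rates on the stated
concentration series, optionally expanding each rate into a 3-point
time course. All generators are pure functions of (spec, seed); the
package-wide default seed is 1069.

## Problem sizes and determinism

The shipped tests run entirely desk-scale: families of 20–50 sequences
for search and classification (the confusion matrix uses 50 per family
across all five families), 40-sequence labeled databases for iterative
search, Gumbel calibrations of 150–400 background sequences at model
length ≤ 260, exhaustive-enumeration oracles at sequence length ≤ 8
(alignment) and path enumeration on models with M ≤ 4 (forward), and
200 repeated Hill-fit simulations for the recovery/coverage property.
Every stochastic routine takes an explicit seed; re-running any
generator or fit with the same configuration is bit-reproducible.

## Known limitations

* Non-HisN motif content beyond the textually specified residues is
  schematic; users can supply complete rule sets via the YAML schema
  (`read_motif_rules()`).
* BlastP bit scores are not reproduced; the score threshold is a
  calibrated stand-in and should be recalibrated if real reference
  proteins replace the synthetic scaffolds.
* The HMM engine is single-hit glocal without domain envelopes or
  posterior decoding; E-value calibration is per-model and per-length.
* Lineage-specific motif variants (alphaproteobacterial R187→V/L,
  actinobacterial aromatic 192) are encoded as global tolerances or
  preferences rather than lineage-switched rule sets.
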