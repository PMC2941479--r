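---
title: "Phyletic profiling of 8-oxo-G repair families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyletic profiling of 8-oxo-G repair families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxogrepair)
library(dplyr)
```

## The problem

7,8-dihydro-8-oxoguanine (8-oxo-G) is among the most common oxidative DNA
lesions; it mispairs with adenine and is handled by a dedicated trio of base
excision repair enzymes. MutT is a nudix-family 8-oxo-dGTPase that keeps
8-oxo-G out of the nucleotide pool; MutM excises 8-oxo-G paired with C; MutY
is an adenine-DNA glycosylase that excises the A misincorporated opposite
8-oxo-G. MutY and MutM belong to the helix-hairpin-helix (HhH) glycosylase
superfamily, which also contains close relatives such as the Nth/endonuclease
III family, and both carry a two-domain architecture — an HhH-GPD catalytic
core plus a family-specific second domain (the MutY C-terminal 8-oxo-G
recognition domain; the MutM/OGG N-terminal domain).

Deciding, for a panel of proteomes, which species retain which of the three
families is harder than it sounds: single-domain relatives (Nth) produce
strong partial hits, gene predictions are frequently truncated at exon
boundaries, and family assignment by raw similarity alone confuses the
HhH-superfamily members. This package implements that calling procedure as a
reusable, testable pipeline, maps the resulting absences onto a species tree
as gene-loss events under Dollo parsimony, and screens protein alignments for
clade-specific sequence insertions near catalytic motifs — the kind found in
several ascomycete subgroups (a ~15-residue MutM insert just downstream of
the HhH-GPD element in one subgroup, a ~20-residue MutY insert inside the
adenine recognition site in another).

Because the original survey depended on live 2009-era sequence databases, the
package is exercised end-to-end against a bundled synthetic-evolution
simulator that plants losses, decoy paralogues, truncations and insertions
along a simulated species tree and emits complete truth tables. Every claim
the test suite makes is a recovery statement about planted truth, not about
real genomes.

## Calling rules

A species scores *present* for a family iff a candidate protein passes all
three checks:

1. **Homology.** A local-alignment hit against a family query sequence with
   E-value strictly below `1e-20`.
2. **Domain validation.** Every required domain is found as a *specific* hit
   with E-value strictly below `1e-5`: Endo3c and DNAglycosylase_C for MutY,
   OGG_N and Endo3c for MutM, MTH1 for MutT. A hit is specific when its model
   outscores every superfamily relative (Endo3c vs Nth) on the same region;
   a candidate whose HhH region is explained at least as well by the Nth
   model is rejected outright (`similar-domain-best-hit`).
3. **Reciprocity.** Searched back against the family query database (all
   three families plus Nth), the candidate's best hit must belong to the
   claimed family.

Both E-value thresholds are strict inequalities, and relaxing either can only
add presences (a monotonicity property the tests assert). When two candidates
pass in one cell, the lower homology E-value wins and the conflict count is
recorded. Absence is a default, not a proof: cells with no qualifying
candidate are recorded as absent with the full evidence trail retained, since
incomplete proteomes are indistinguishable from true loss at this level.

Candidates whose required domains are incomplete and whose species has
genomic sequence available are passed through terminal extension
(`extend_truncated()`): the full-length family query is aligned against all
six reading frames of the genome, the frame segment overlapping the
candidate's locus is located, and missing terminal residues are appended
verbatim from the genome translation. The extension span is padded by the
reference's unaligned overhang, because a local alignment can stop a residue
or two short of the true terminus while the homologous segment clearly
continues; padding is clipped at stop codons. One round of query augmentation
(orthologues found in the first pass re-used as queries for cells still
empty) is on by default and capped at two extra queries per family.

## The alignment engine and E-values

Searches use exact affine-gap Smith-Waterman (Rcpp), not a heuristic seeded
search: at the package's scale exact dynamic programming is affordable and
removes seeding artefacts as a variable. The default scoring scheme is
BLOSUM62 with gap open −11 and extend −1 (a length-k gap costs
`gap_open + k * gap_extend`); the original survey does not record its search
parameters, so these are explicit, configurable defaults. Ties between
equal-scoring local alignments are broken toward the lexicographically
smallest start coordinates, which the engine resolves exactly by propagating
start coordinates through the DP.

E-values come from an empirical extreme-value calibration
(`calibrate_evalue()`): optimal local scores of random background-composition
sequence pairs (default 200 pairs of length 300) are fitted to a Gumbel law
by the method of moments, giving `E(S; m, n) = K·m·n·exp(−λS)`. This avoids
hard-coding published λ/K values that would be wrong for any non-default
matrix. The fit is validated two ways in the tests: the engine against a
brute-force oracle, and the calibration against its own definition — a search
of a shuffled database should yield on average about one hit with E ≤ 1
(observed ≈ 1 over 20 seeded repetitions). E-values are floored at 1e-300 so
they remain positive for arbitrarily strong self-hits.

Domain models are position-specific scoring matrices built from seed
alignments with Dirichlet pseudocounts
(`log((count + pc·bg)/(n + pc)/bg)`, default total pseudocount 5), scanned
ungapped over every window, with a per-model Gumbel null calibrated on 1,000
seeded shuffles of a length-matched background sequence. Ungapped scanning is
a deliberate simplification: the synthetic domains are contiguous blocks, and
gapped profile alignment (profile HMMs) is out of scope. The
specific-vs-similar margin defaults to 0 bits — strictly greater score wins —
since the original procedure states that only specific hits count without
quantifying a margin; the margin is exposed as a parameter.

## Dollo loss mapping

Losses are reconstructed per family under Dollo parsimony: one origin at the
root, irreversible losses. Under this model the minimal placement is the set
of stems of maximal all-absent clades, which is *unique* — so "report all
co-optimal placements" degenerates to this single root-most solution, and
ties never arise. An all-absent profile is explained more parsimoniously by
absence at the root than by losses on every root child; `dollo_map()` returns
zero events with the flag `family-absent-from-root` in that case, and the
brute-force oracle used in the tests enumerates the root-absence option
alongside every branch subset so the two agree on all 2^n profiles.
Polytomies are handled naturally (each child branch independently). Dollo
rather than general gain/loss parsimony matches the premise that the system
is ancient and widely conserved, making convergent re-invention implausible.

## Insertion detection

Present homologues of a family are aligned progressively (profile-profile
Needleman-Wunsch along a UPGMA guide tree built from pairwise identity, or a
supplied guide), with the family query included as an insert-free reference
row. `call_insertions()` then finds maximal column runs where clade occupancy
is at least `min_purity = 0.9`, outgroup occupancy at most
`max_outgroup_occupancy = 0.1`, and run length at least `min_len = 8`
columns. The defaults reflect the reported insert sizes (~10–20 residues):
`min_len = 8` sits safely below the smallest insert of interest while
excluding alignment jitter; the occupancy bounds tolerate one aberrant row in
clades of ten or more. No formal caller existed for the original analysis, so
all three are exposed as parameters. Positions are reported relative to
annotated motifs (HhH-GPD, adenine recognition site, nudix) in *ungapped
reference residues* — matching how such positions are described in practice
("about 10 residues downstream of the HhH element"). The HhH-GPD motif is
occasionally written HhH-PVD; the package treats these as one annotation.

Scanning every tree clade (`detect_clade_insertions()`) is self-limiting:
for a sub-clade of the true insertion clade the outgroup contains
insert-bearing rows and fails the occupancy bound; for a super-clade the
purity drops. Only the true clade (plus occasional single-row misalignment
artefacts) qualifies.

## The simulator and what it does (not) emulate

`simulate_oxog_dataset()` draws a random rooted binary topology with
exponential branch lengths rescaled so the deepest root-to-leaf path is
`depth = 0.25` expected substitutions/site (keeping every orthologue pair
within the divergence regime the thresholds are designed for, ≤ ~0.5
substitutions/site on any leaf-to-leaf path). Sequences evolve by i.i.d.
per-site replacement with probability `1 − exp(−t)` per branch, replacements
drawn from Robinson-Robinson background frequencies; there are no indels
outside planted insertions, so insertion calls have unambiguous truth.

Family architectures share a common ancestral Endo3c core duplicated into
family-private copies (MutY and MutM copies at 0.2 substitutions/site from
the ancestor; the Nth decoy copy at 0.3), plus family-specific domains and
linkers. Domain seed alignments are eight sequences at 0.15 divergence around
each consensus. These divergences are free parameters of the simulator — the
original study reports no orthologue divergence levels — chosen once as
realistic for intra-superfamily distances and documented here, not tuned.
Decoys evolve from the Nth root along the same tree (two per species by
default), so they share the HhH core but are closer to the Nth model than to
Endo3c — exactly the specific-vs-similar margin the classifier must resolve.

Planted scenarios are sampled to be *Dollo-identifiable*: per family, no two
loss branches nested or siblings (a sibling pair would be indistinguishable
from a single parental loss), and the family always survives somewhere.
Default conditions: 16 species, 5 losses, a 15-residue MutM insertion placed
10 residues downstream of the HhH-GPD motif and a 20-residue MutY insertion
inside the adenine recognition site, 2 decoys per species, 20% of true genes
truncated by 10–40 residues at one terminus (each truncated gene accompanied
by a genome record holding the full unspliced ORF plus 60-nt flanks).

Deliberately not emulated: intron/exon structure (genomes are unspliced ORFs,
so extension needs no splice model), codon-level substitution models,
realistic indel processes, EST evidence, and composition biases. Passing
tests therefore demonstrate that the *procedure* recovers planted signal
under controlled conditions; they do not certify performance on real
proteomes, where fragmented assemblies, splice-variant predictions and
compositionally biased lineages add failure modes the simulator does not
model.

## Numerical choices and degenerate inputs

- Scores are doubles throughout; the engine's tie-breaks (lowest start pair,
  then lowest end) and the hit sort (E-value, then subject id) make every
  output order deterministic.
- E-value and PSSM calibrations are seeded and reproducible; each pipeline
  run calibrates from its `calibration_seed`.
- Empty proteomes yield empty hit lists (not errors); proteins shorter than
  every model yield no domain hits; single sequences align to trivial MSAs.
- All-gap seed-alignment columns are dropped with a warning; partially
  gapped columns keep residue-only counts.
- Degenerate backgrounds (any frequency 0 or 1) and non-negative expected
  substitution scores are rejected at construction.
- Unknown residues are rejected by default; a wildcard mode (score 0) exists
  and is used internally for six-frame translations containing stops.

## Problem sizes

The test suite and the acceptance script run at the sizes the package treats
as its reference conditions: 16-species end-to-end recovery; a catalogue of
more than 20 rooted topologies with 4–6 leaves swept over all 2^n presence
profiles against a brute-force Dollo oracle; 100 decoys audited across
seeded simulations; 50 insertion-recovery replicates; 200 random pairs
against the alignment oracle. On one CPU the whole acceptance script takes
about four minutes.

## Interface note

The package exposes its pipeline as composable functions over tibbles
(`simulate_oxog_dataset() |> run_oxog_pipeline()`, or the individual stages
`search_proteome()`, `scan_domains()`, `classify_candidate()`,
`build_matrix()`, `map_losses()`, `progressive_align()`,
`call_insertions()`, `locate_insertion()`), with `tidy()`/`glance()`
methods and plot functions for each result type. A shell-level interface
would add nothing here — the natural unit of work is an R session or script,
as the README's worked example shows.

## Known limitations

- Ungapped domain scanning cannot recognise a domain whose terminal residues
  are missing; the extension step exists precisely to restore such termini,
  and the overhang padding makes restoration exact in the unspliced setting.
- Progressive alignment can split an insertion block for very small clades
  (two rows) at higher divergence, costing an occasional recovery (observed
  ~1 in 50 replicates at default conditions).
- The Gumbel moment fit is a bulk fit; its far tail (E ≪ 1e-20) is an
  extrapolation. The pipeline only ever compares E-values to thresholds well
  inside the calibrated regime's monotone range, and threshold decisions near
  the boundary are exercised by constructed cases, not by trusting the tail.
- Dollo parsimony cannot see a loss nested under another loss, and treats
  every absence as loss rather than assembly gap; both caveats are inherent
  to the model, not the implementation.
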