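---
title: "Mining and classifying Pseudomonas lipopeptide NRPS systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and classifying Pseudomonas lipopeptide NRPS systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipomine)
```

## The biological model

Nonpathogenic *Pseudomonas* lipopeptides (LPs) are assembled by type I
nonribosomal peptide synthetases (NRPSs) under the collinearity rule: the
peptide sequence follows the order of C-A-T modules across two or three
consecutively acting enzymes. The first module carries a starter
condensation domain (Cs) that acylates residue 1 with a fatty acid;
extension condensations are either plain (LCL) or dual-function C/E
(condensation plus epimerization of the preceding residue); termination is
by a **tandem of two thioesterase domains**, which separates these systems
from the single-TE siderophore and Mycin-type synthetases. Standalone
epimerization (E) domains never occur in LP systems but do occur in
pyoverdine NRPSs, so an E domain is treated as disqualifying evidence. A
family is a chemical equivalence class summarized by its `[l:m]` signature
— peptide length and macrocycle size — refined by the module distribution
across genes and the genomic organization (contiguous operon vs a
*bifurcate* cluster whose initiator gene sits far from the operon).

The package expresses each analysis stage as a module with an explicit
contract: knowledge base, synthetic data, NRPS parsing, BGC mining,
A-domain specificity, peptide/family assignment, phylogenetics, module
evolution, and HSQC fingerprints. Central containers are S4 classes
(`LpKnowledgeBase`, `LpFamily`, `SimConfig`, `SyntheticBgc`, `LpGenome`,
`NrpsSystem`, `BgcRecord`) with validity methods; per-row results are
plain data frames.

## The knowledge base

`inst/extdata/lp_families.json` encodes the 13 families. Two content
decisions deserve explanation:

* **Variant sequences are reconstructions.** The primary literature
  describes most variants by their *differences* (Viscosin types vary at
  positions 2/4/9, Amphisin at 8/9/11, Bananamide at 2/6/8, entolysin vs
  xantholysin by Q-S switches at 10/13, the Factin members at position 5,
  nepenthesin by a Gln6/Ser8 position swap). The shipped sequences are
  reconstructed from the published structures of the named compounds under
  those constraints, and the `provenance` column marks every row as such.
  All inter-variant difference patterns used anywhere in the package are
  therefore exact even where an absolute residue assignment at an
  unconstrained position is conventional.
* **The `[l:m]` collision rule is scoped to cyclic families.** Orfamide
  and Poaeamide intentionally share 10:8 — the one signature collision
  among the cyclic families, and the reason family assignment uses module
  distribution, organization and homology as tie-breakers. The two linear
  families (Factin and thanafactin, macrocycle 0) both have 8 residues:
  the thanafactin length is forced to 8 by the lipotetrapeptide LP4
  arithmetic (LP4 = ThfA module 1 + the last three ThfB modules after
  excision of four internal residues), and syringafactin-type Factins are
  octapeptides. The uniqueness test therefore asserts exactly one
  collision *among cyclic families* plus the shared 8:0 of the linear
  pair.

Predicted LPs whose lengths match no family template (LP4, LP7, LP9,
LP10a/b, LP12) live in a separate table with a `derivedFrom` column;
LP13a–d fit the Asplenin template and are stored as its `predicted`
variants. Predicted entries are excluded from classification references by
default to avoid circular assignment.

## Synthetic data: what it emulates, and what it does not

All generators are driven by a `SimConfig` whose defaults are the study
conditions: intergenic spacers uniform in **150–300 bp** (the conserved
untranslated region of trigenic operons), domain lengths of 450/440/80/230
aa for A/C/T/TE, per-site substitution `mutationRate` (0.05 in recovery
experiments — comfortably inside the divergence real A-domain clades
tolerate), 2–5 decoy genes, and HSQC jitter SDs of (0.01, 0.1) ppm.
Every generator call draws from a private RNG stream keyed by
`(seed, call-tag)`, so adding generators never shifts existing outputs and
the same configuration is byte-identical, file output included.

The reference universe is anchored by a fixed internal library seed,
independent of user seeds: per-kind domain anchors, one specificity anchor
per residue of the 14-letter LP alphabet (mutually < 40% identical by
construction), and per-(family, position, residue) A-domain *lineages*
diverged 25% from their anchor. Lineages play the role of the curated
database of A domains with experimentally determined specificity: two
same-substrate modules from different systems are ~55–60% identical
(matching the moderate within-clade homology of real A domains), while a
mined module stays within a few percent of its own lineage. Genomes are
emitted as GenBank flat file + GFF3 + protein FASTA + a machine-readable
truth JSON; GenBank is 1-based inclusive, internal coordinates 0-based
half-open.

What the generator does **not** emulate: real Pfam-like domain sequence
structure (domains are anchored random sequences — adequate because the
caller's contract is nearest-reference similarity, which is
representation-agnostic), codon-level nucleotide sequences, fatty-acid
moieties and congener mixtures, and real phylogenetic correlation between
taxonomy and NRPS divergence. Passing recovery tests therefore demonstrate
the correctness of the pipeline's logic and thresholds on data with known
truth, not its calibration on real genomes; for real data, the domain-table
TSV adapter and newick/alignment adapters let externally produced
annotations and trees enter at the module boundaries.

## Domain calling and parsing

The caller slides each reference exemplar along the protein (stride 10)
computing windowed positional identity, refines candidate peaks at stride
1, scores the refined window by global-alignment identity (BLOSUM62, gap
open 10 / extend 0.5, terminal-gap columns excluded), and keeps hits at or
above the per-kind threshold **0.5**, selected greedily with overlap
suppression (ties: higher score, longer hit, smaller start). The 0.5
threshold sits midway between the ~0.7 identity of a true domain at 5%
divergence (relative to a lineage 25% off its anchor) and the ~0.1 of
background, and is calibrated on synthetic data only — real-genome use
should go through the external-annotation adapter. Modules are delimited
at C-type domains; trailing TEs attach to the final module; assembly
promotes the unique Cs-gene to the front and the TE-TE gene to the end,
keeping middle genes in genomic order.

Equal-length sequence comparisons use exact positional identity (the
ungapped diagonal is the relevant global alignment when both sides share a
reference window length); unequal lengths fall back to full alignment. The
exported `adomainIdentity()` always aligns, and canonicalizes argument
order so the value is exactly symmetric even where co-optimal alignments
differ between orientations.

## Specificity, families, superfamilies

`classifySpecificity()` is a nearest-neighbour call over identity — the
operational reading of "nearest clade" — with four tunables: ambiguity
half-width `delta = 0.05` identity (references that close to the best hit
contribute their specificities), acidic-clade threshold `0.75` (below it,
Glu/Gln/Asp inflate each other, reproducing the intertwined acidic clade),
Ile promiscuity threshold `0.9` (below it a `{Val, Leu}` alternate set is
attached), and an `unknown` floor of `0.4`. The paper-level behaviour the
defaults must reproduce is qualitative (mixed acidic clusters, a
promiscuous Ile type); the numeric values are repo calibrations on
synthetic data and are exposed as arguments. Ties at exactly equal
identity resolve to the lexicographically smallest reference id and
inflate the ambiguity set. Thanafactin lineages are excluded from the
default reference set (they behave as a homogeneous outgroup and are
analysed separately); the end-to-end miner requests the full set because
assigning thanafactin producers is in its scope.

Family assignment proceeds from `candidatesByLength`, then (i) module
distribution vs templates, (ii) organization, (iii) mean A-domain identity
to each family's lineages — which is what separates Orfamide (contiguous)
from Poaeamide (bifurcate) at equal 10:8 signatures. Variant matching is
ambiguity-aware (an ambiguous position matches any member of its set), so
Glu/Gln uncertainty cannot manufacture spurious `new_variant` calls. The
implied macrocycle is always copied from the family definition — TE
phylogeny has poor discriminatory value for cyclization, so no code path
derives `m` from the sequence, and novel families get `m = NA`. The
`new_variant` homology threshold is 0.7 NRPS identity (the literature's
boundary between families sits below 70%). Superfamily grouping clusters
all A domains by average linkage at identity cutoff 0.6, forms per-system
profiles of cluster ids, and joins systems at multiset profile overlap
≥ 0.5 (shared ids over the shorter profile); 0.5 is a repo choice
calibrated to recover planted four-pool partitions.

## Phylogenetics and congruence

Distance = 1 − identity; trees by neighbor joining (negative branches
clamped to zero with a warning); supports by site-resampling bootstrap
over NJ. Distance/NJ replaces maximum-likelihood inference deliberately:
at desk scale the claims under test concern congruence *structure*, not
branch-length estimation, and NJ on additive matrices provably recovers
the generating topology (a property the suite fuzzes over random 6–10
leaf trees). Congruence reports the Robinson–Foulds distance normalized by
its unrooted-binary maximum `2n − 6`, the correlation of cophenetic
distance matrices, and a greedy ranking of leaves by how much their
removal improves RF — the report used to flag candidate horizontal
transfers. No hard discordance cutoff is imposed; the ranking is a top-k
report by design.

## Module evolution

Windowed identity follows the standard three-bin visual (window = 50
alignment columns, slide 1, gaps count as mismatches; bins 100 / 30–99 /
< 30). Module-level comparison aligns A-domain sequences only — C/E
domains coadapt to their neighbours and would blur event boundaries — by
global dynamic programming with match score = A-domain identity and gap
penalty 0.4 per module (set so that a genuine module loss, costing 0.4,
always beats chaining ~0.55-identity same-substrate mismatches, while
random ~0.05 pairings never out-score a gap). Unaligned runs are
deletions; aligned pairs with differing substrate but homologous flanks
(≥ 0.7 identity on both sides) are exchanges — terminal modules cannot be
exchanges and are reported as substitutions; adjacent same-gene modules at
identity ≥ 0.9 are duplications. The 0.9 duplication threshold quantifies
"near-identical adjacent A domains" and is calibrated on synthetic
duplications only; it is exposed as an argument.

## HSQC fingerprints

Dereplication compares the CHα cross-peak positions of a query against
reference compounds measured under identical conditions. Matching is an
optimal one-to-one assignment (Jonker–Volgenant, exhaustively verified for
small instances) under the normalized distance
`d = sqrt((ΔH/tolH)² + (ΔC/tolC)²)` with pairs rejected at `d > 1` via
dummy nodes of cost 1. Defaults `tolH = 0.03` ppm, `tolC = 0.4` ppm
reflect typical HSQC reproducibility; the match verdict needs coverage
≥ 0.9 and tolerance-normalized RMSD ≤ 1. The source criterion is
qualitative ("a match is obtained"), so the 0.9 coverage default is a repo
decision, exposed as an argument. Only CHα peaks are modelled; raw NMR
processing is out of scope.

## Problem sizes and determinism

The recovery experiments run at sizes a workstation handles in minutes:
50 synthetic genomes spanning all 13 families and both organizations at
5% divergence for end-to-end recovery, 14 × 10 leave-one-out for the
classifier, 50 random 6–10-leaf trees for NJ, 20 random module-block
deletions, 20 dereplication seeds. All randomness flows through tagged
seeds; reruns are bit-reproducible.

## Known limitations

* The domain caller assumes substitution-style divergence from some
  reference exemplar; strongly indel-diverged or fragmented real proteins
  should enter via the external domain-table adapter.
* Stereochemistry is stored (e.g. the Viscosin Leu5 D/L split) but never
  predicted — C/E epimerization activity is unreliable to infer.
* Initiator/operon pairing trusts module-count completion with a homology
  tie-break; genomes with several same-family split systems can be
  genuinely ambiguous and are reported as such rather than guessed.
* Superfamily structure is recovered relative to the packaged lineage
  universe; on real data the identity cutoff (0.6) would need
  re-examination against the empirical within-clade divergence floors
  (~0.65 for Ser/Thr, ~0.6 for Leu/Ile/Val, down to ~0.5 in particular
  modules).
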