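# lipomine

Charting the lipopeptide (LP) production capacity of *Pseudomonas* is an
exercise in reading nonribosomal peptide synthetases (NRPSs). The cyclic and
linear LPs of the nonpathogenic *P. fluorescens* lineage are assembled by
type I NRPS systems with a highly stereotyped build: an initiator module
whose starter condensation domain (C<sub>s</sub>) acylates the first residue
with a fatty acid, a collinear run of C-A-T extension modules (condensation,
adenylation, thiolation), and a terminal **tandem of two thioesterase (TE)
domains** that releases the linear or macrolactonized product. Standalone
epimerization domains are absent (dual C/E condensation domains do that
work), which — together with the TE tandem and a conserved flanking synteny
of LuxR-family regulator genes and the tripartite *pleABC* exporter — makes
LP clusters recognizable in genome sequence alone.

`lipomine` implements that recognition and everything a desk analysis
builds on it, for bioinformaticians studying natural-product biosynthesis:

* a versioned **knowledge base** of the 13 LP chemical families with their
  `[l:m]` signatures (peptide length *l*, macrocycle size *m*; e.g.
  viscosin 9:7, xantholysin 14:8), per-gene module-configuration templates,
  peptide variants and superfamily membership;
* a **BGC miner** that calls NRPS domains by windowed nearest-reference
  similarity, validates the diagnostic architecture, applies the exclusion
  rules (single-TE termination, standalone E domains, fragmented genes),
  scans flanking synteny and resolves contiguous vs bifurcate organization
  (pairing orphan initiator genes with their distant operons);
* **peptide prediction** under the collinearity rule: each module's
  A-domain substrate is called by nearest-reference identity, with
  clade-aware ambiguity (the intertwined Glu/Gln/Asp group, the promiscuous
  Ile type that also recruits Val/Leu);
* **family/variant assignment** and variant comparison (including the
  recurrent Gln&harr;Ser "Q-S switch"), plus A-domain homology profiles and
  superfamily grouping;
* desk-scale **phylogenetics** (identity distances, neighbor joining,
  site-resampling bootstrap) and NRPS-vs-*rpoD* congruence scoring with
  ranked discordant-strain reports;
* **module-evolution** analysis: sliding-window identity profiles
  (window = 50, BLOSUM62) and module-level alignment calling duplication,
  deletion and exchange events;
* **HSQC fingerprint dereplication**: CH&alpha; peak lists matched by optimal
  one-to-one assignment under ppm tolerances.

Because real mining runs against GenBank-scale data, the package ships a
seeded **synthetic-data generator** that emulates the relevant genomic
features (family-templated module configurations, 150–300 bp intergenic
spacers, LuxR/*pleABC* flanking synteny, bifurcate cluster placement, decoy
genes, reference-derived A-domain lineages, jittered peak lists), so the
entire pipeline is testable offline with known ground truth.

## Worked example

Generate a synthetic genome carrying one Amphisin-family cluster, mine it,
and dereplicate a simulated spectrum:

```r
library(lipomine)

cfg <- simConfig(seed = 5, mutationRate = 0.05)
g   <- makeGenome(list(list(family = "Amphisin", organization = "contiguous")),
                  cfg, "demo")
res <- mineLipopeptides(g)
predictionTable(res$hits)
#>                        systemId organization nModules
#> 1 demo_b1_amphisin_nrps1_system   contiguous       11
#>                                       peptide nAmbiguous   family       status
#> 1 Leu-Asp-Thr-Leu-Leu-Ser-Leu-Leu-Leu-Ile-Asp          0 Amphisin known_member
#>   matchedVariant
#> 1        lokisin

q <- makeHsqc("tensin", simConfig(seed = 3))
dereplicate(q, spectralLibrary(familyVariants("Amphisin")$name))[[1]]
#> MatchResult vs tensin: match (coverage 1.00, RMSD 0.461, n=11)
```

The miner found the planted trigenic cluster ([2-4-5] modules), validated
its TE tandem and flanking synteny, predicted the 11-residue peptide with
zero ambiguous positions, and matched it to the lokisin variant of the
Amphisin family ([11:9]). The jittered 11-peak CH&alpha; fingerprint
dereplicates to its own reference compound with full coverage; the RMSD is
the tolerance-normalised residual (0 = perfect overlay, 1 = at tolerance).

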