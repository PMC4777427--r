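# missedgene

Deciding whether a gene absent from a genome annotation is truly
**missing** from the organism or merely **missed** because the assembly
failed in that region — the evidence chain behind the avian *foxp3* case,
packaged as reusable, tested R functions.

Claims that a lineage has "lost" a gene often rest on its absence from
draft-genome annotations. But absence has a mundane alternative
explanation: GC-rich, repeat-dense regions assemble poorly from short
reads, and genes inside them vanish from annotations while their
neighbours survive. `missedgene` operationalises the forensic workflow for
telling the two apart:

* **Synteny** — classify a target locus from its conserved gene
  neighbourhood (`classify_locus()`): is it annotated between its flanks
  (`ANNOTATED`), spanned but unannotated (`SPANNED_UNANNOTATED`), inside a
  large assembly gap (`GAP_IN_REGION`), split across scaffolds
  (`FLANKS_SPLIT`), or is the neighbourhood itself missing
  (`FLANK_MISSING`)? Survey many genomes with
  `co_annotation_contingency()` and `quality_stratify()`.
* **Region forensics** — `gc_fraction()`, `masked_fraction()`,
  `gap_runs()`, `n50()`, `assembly_stats()`.
* **Exon recovery** — `spliced_align()`, a protein-to-genome dynamic
  program (codon-level BLOSUM62 matches, affine gaps, GT–AG introns,
  N-gaps passable only inside introns; C++ core), plus reference-guided
  `curate_boundaries()` and `exon_report()`.
* **Protein features** — FoxP-style domain architecture
  (`detect_architecture()`: proline-rich N-terminal region, zinc finger,
  leucine zipper `[VI]-x(6)-L-x(6)-L-x(6)-L`, forkhead domain) and clade
  signature residues from reference-anchored alignments
  (`anchor_align()`, `signature_residues()`).
* **Expression evidence** — exact-match transcript-read coverage per
  codon (`exact_match_coverage()`, `covered_aa()`) and in-silico PCR
  (`insilico_primer_match()`).
* **Verdict** — `integrate_evidence()`, a deterministic rule cascade
  ending in `PRESENT_ANNOTATED`, `PRESENT_UNANNOTATED`, `LIKELY_MISSED`,
  `LIKELY_ABSENT` or `INDETERMINATE`, with the fired rules recorded.

A synthetic-neighbourhood simulator (`simulate_neighborhood()`,
`fragment_assembly()`, `simulate_reads()`) generates archosaur-like
*foxp3* neighbourhoods with complete ground truth — gene order
`naa10(+), ppp1r3f(−), foxp3(+), ccdc22(−), cacna1f(+)`, a 298-aa/11-exon
target with 66% GC in its region, planted domain layout — so the whole
chain is testable offline. Results are tibbles or small S3 objects with
`tidy()`/`glance()` methods and `autoplot()`/`plot_neighborhood()`
displays.

## Worked example

Simulate a neighbourhood, classify the locus, recover the gene by spliced
alignment, and check the one primer that should match:

```r
library(missedgene)

sim   <- simulate_neighborhood(neighborhood_spec(seed = 1))
locus <- classify_locus(sim$record)
glance(locus)
#> # A tibble: 1 × 7
#>   genome_id status    intergenic_span gap_total gap_largest region_gc region_masked
#>   <chr>     <chr>               <dbl>     <int>       <dbl>     <dbl>         <dbl>
#> 1 sim_1     ANNOTATED            7527         0           0     0.671         0.113

r      <- sim$truth$region
region <- substr(sim$record$scaffolds$sequence[1], r[1] + 1, r[2])
glance(spliced_align(sim$truth$target_protein, region))
#> # A tibble: 1 × 5
#>   n_exons strand score coverage protein_length
#>     <int> <chr>  <dbl>    <dbl>          <int>
#> 1      11 +       1478        1            298

detect_architecture(sim$truth$target_protein)
#> <domain_architecture> 298 aa; ProR [0,131) proline 25.2%; ZF absent;
#>   LZ [131,153) (first I); FRK [209,298)

insilico_primer_match("TTGTGCAGGCTCAGGTTG", sim$truth$target_cds)
#>               primer best_identity orientation match_start match_end matched_peptide
#> 1 TTGTGCAGGCTCAGGTTG             1     reverse         671       689           NLSLH
```

The locus is `ANNOTATED` in the intact simulation; the aligner recovers
all 11 planted exons with full protein coverage; the protein shows the
expected architecture (25.2% proline N-terminal region, no zinc finger,
isoleucine at the first zipper position); and the primer matches in
reverse orientation, landing exactly on the `NLSLH` peptide of the
forkhead domain.

The "missed" configuration — conserved flanks around an uninterrogable
gap — is reproduced by the crow-like fixture:

```r
crow <- crow_like_record()
integrate_evidence(classify_locus(crow, upstream_flank = "naa10",
                                  fallback_upstream = "hsd17b10"))
#> <evidence_report> american_crow_like: LIKELY_MISSED
#>   locus status: GAP_IN_REGION
#>   - region gap_in_region with conserved flanks and no recoverable exons:
#>     assembly quality explains the absence
```

Here the intergenic region spans 36,546 bp, 23,713 bp of it one assembly
gap, so the absence of recoverable exons says nothing about the organism:
the verdict is `LIKELY_MISSED`, not absent.

See `vignettes/missed-not-missing.Rmd` for the models, parameter choices
and limitations.

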