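---
title: "Missed or missing? An evidence chain for genes absent from genome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missed or missing? An evidence chain for genes absent from genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missedgene)
library(dplyr)
```

## The problem

When a gene cannot be found in a genome annotation there are two very
different explanations: the gene is genuinely absent from the organism, or
the assembly and annotation simply failed in that part of the genome. The
distinction matters — absence claims ("birds have lost gene X") have been
retracted more than once after the gene turned up in a better assembly.
The avian *foxp3* locus is the motivating case for this package: the gene
sits in a GC-rich, repeat-dense region that short-read avian assemblies
handle poorly, so most bird genomes show a conserved neighbourhood
(*naa10*, *ppp1r3f*, ..., *ccdc22*, *cacna1f*) with a hole where *foxp3*
should be.

`missedgene` implements the full evidence chain for adjudicating such a
case:

1. **Synteny**: classify the target locus from the annotations of its
   conserved gene neighbourhood (`classify_locus()`), and survey
   co-annotation and assembly quality across many genomes
   (`co_annotation_contingency()`, `quality_stratify()`).
2. **Region forensics**: GC content, soft-masked repeat fraction, and
   assembly-gap runs of the intergenic region (`gc_fraction()`,
   `masked_fraction()`, `gap_runs()`, `n50()`).
3. **Exon recovery**: spliced protein-to-genome alignment of a homologous
   protein against the region (`spliced_align()`), with reference-guided
   boundary curation (`curate_boundaries()`).
4. **Protein features**: FoxP-style domain architecture — proline-rich
   N-terminal region, zinc finger, leucine zipper, forkhead domain — and
   clade signature residues (`detect_architecture()`,
   `signature_residues()`).
5. **Expression**: exact-match transcript-read coverage of a candidate
   coding sequence (`exact_match_coverage()`) and in-silico PCR
   (`insilico_primer_match()`).
6. **Verdict**: a deterministic rule cascade integrating whatever evidence
   exists (`integrate_evidence()`).

Because the real data live in sequence archives, the package ships a
synthetic-neighbourhood simulator with complete ground truth, so every
stage is testable offline and the central claim — that GC-linked assembly
failure produces "missed" loci — can be demonstrated *in silico*.

## The simulator and what it emulates

`simulate_neighborhood()` generates one contiguous scaffold carrying the
archosaur gene order `naa10(+), ppp1r3f(-), foxp3(+), ccdc22(-),
cacna1f(+)`. Its defaults are the emulated study conditions:

* a 298-residue target protein over 11 exons, with a FoxP-style layout:
  proline-rich N-terminal region (25.2% proline over 131 residues), no
  zinc finger, a leucine zipper matching `[VI]-x(6)-L-x(6)-L-x(6)-L` with
  isoleucine at the first position, and an 89-residue forkhead domain whose
  sequence carries the `NLSLH` peptide;
* 66% GC in the region between the target's neighbouring genes, against a
  42% GC background (typical of avian genomes);
* soft-masked repeat tracts at 15% of intergenic sequence;
* introns that always begin `GT`, end `AG`, and are at least 30 bases.

Coding sequence is back-translated with a fixed, GC-rich
vertebrate-preferred codon per residue (`back_translate()`). This keeps the
simulation deterministic given its seed and reproduces two properties of
the real locus at once: the elevated GC of the coding sequence, and the
exact primer-binding site — the codons for `...A-N-L-S-L-H-K...` under
this table spell out the reverse complement of the one primer that matches
the locus perfectly.

Species presets (`foxp3_presets()`) vary the N-terminal region length and
proline fraction to emulate the reported per-species values (ground tit
25.2%, American alligator 20.3%, Chinese alligator 21.9%, gharial 25.5%,
green anole 10.8%, Burmese python 8.7%), with the gharial's short
55-residue N-terminus included deliberately. The proline count is planted
exactly (`round(p * n)` prolines in an `n`-residue region), so the
measured enrichment is a genuine recomputation through domain detection,
not an assertion.

What the simulator does **not** emulate: real transposon families (repeat
tracts are plain lowercase runs), sequencing-technology error profiles,
diploidy, alternative splicing, and non-canonical `GC-AG` splice sites.
Passing tests therefore demonstrate that the machinery is correct on data
with these idealisations, not that any particular real genome is gapped.

```{r simulate}
sim <- simulate_neighborhood(neighborhood_spec(seed = 1))
sim$record
classify_locus(sim$record) |> glance()
```

## The fragmentation model

`fragment_assembly()` is a stylised stand-in for GC-linked assembly
failure; no quantitative model links GC to breakage in the source
material, so the package states its own: per 1-kb window the scaffold
breaks with probability `base_break_rate`, multiplied by
`gc_break_multiplier` where window GC exceeds 0.55 (clamped at 1). A break
becomes an internal N-gap run (500–5000 bases by default) with probability
0.5, otherwise a scaffold split — the two failure modes seen in real
assemblies (a gapped spanning scaffold versus single-gene scaffolds).

All per-window draws derive deterministically from `(seed, window)`, and a
window breaks when its fixed uniform draw falls below the window's break
probability. Breakpoint sets are therefore *nested* as the multiplier
grows: raising `gc_break_multiplier` can only add damage. This common
random numbers design makes the central monotonicity property — the
fraction of genomes whose target locus is no longer confidently annotated
rises with GC-linked fragility — hold per seed rather than merely in
expectation, which keeps the property test sharp without enormous
replication.

```{r sweep}
missed_rate <- function(mult, seeds = 1:20) {
  mean(vapply(seeds, function(s) {
    fr <- fragment_assembly(simulate_neighborhood(neighborhood_spec(seed = s))$record,
                            fragmentation_model(base_break_rate = 0.03,
                                                gc_break_multiplier = mult,
                                                seed = s))
    classify_locus(fr)$status != "ANNOTATED"
  }, logical(1)))
}
sapply(c(1, 4, 16), missed_rate)
```

## The spliced aligner

`spliced_align()` finds the optimal chain of exons aligning a protein to
genomic DNA, local in both sequences: codon-level matches under BLOSUM62,
affine gaps (first unit −12, extension −2), a flat −20 intron penalty, and
introns only at `GT...AG` with a 30-base minimum. Both strands are tried.
The dynamic program keeps one running maximum over donor sites per protein
row, so splice transitions cost O(1) and the whole alignment is O(mn); it
is implemented in C++ and handles a 300-residue protein against a 15-kb
region in well under a second.

Numerical and grammatical choices, stated explicitly because they define
the search space:

* **Introns fall on codon boundaries** (phase 0 only) and frameshifts are
  not modelled. The simulator plants phase-0 introns to match. This is the
  main simplification relative to a full protein-to-genome model with
  split codons; it is what makes an exact exhaustive oracle tractable, and
  exon phases are reported as 0 throughout.
* **Gap runs never span an intron**: crossing a junction re-opens a gap,
  and unaligned protein segments (insertions) attach to the exon on their
  left, never to a splice site.
* **N runs are impassable inside exons but free inside introns** — the
  property that lets a partially gapped region still yield a partial exon
  chain, as recovered for the falcon loci.
* **Ties** prefer, in order: continuing a match, closing a protein gap,
  closing a DNA gap, starting fresh, splicing — so fewer introns win at
  equal score, deterministically.
* Scores accumulate in single-precision floats; with integer BLOSUM62
  entries and penalties, all attainable scores are integers well inside
  float precision.

The test suite checks the aligner against an independent oracle that
exhaustively enumerates every legal exon chain on small instances and
scores each with a plain Needleman–Wunsch, against
`Biostrings::pairwiseAlignment()` three-frame local alignment in the
infinite-intron-penalty limit, and against the simulator's ground truth
(exact boundary recovery for ≥95% of planted exons across 50 seeds).

```{r align}
r <- sim$truth$region
region <- substr(sim$record$scaffolds$sequence[1], r[1] + 1, r[2])
al <- spliced_align(sim$truth$target_protein, region)
glance(al)
```

`curate_boundaries()` mirrors the manual curation step of anchoring exon
boundaries on a trusted homolog: a junction within two residues of a
reference breakpoint is snapped to it when a valid `GT`/`AG` pair exists
there; otherwise it is left alone and flagged.

## Domain architecture and signatures

Domain detection is template-anchored: the forkhead (FRK) and zinc-finger
(ZF) consensus templates are located by global–local alignment, with a
0.35 identity floor over the template span deciding presence. The floor
reflects the family structure — the forkhead domain is alignable across
the whole FoxP family, while the zinc finger is not detectable in the
relevant reptilian and avian sequences; a sequence with no locatable
forkhead is not classifiable as FoxP and raises an error. The leucine
zipper is found by its consensus motif (`lz_pattern()`), taking the match
nearest the forkhead. The N-terminal (ProR) region runs to the ZF, or to
the LZ when no ZF is detectable, and carries its proline fraction
(denominator excludes alignment gaps, includes X).

The templates shipped in `foxp_templates()` are synthetic consensus
sequences constructed for this package, not database extracts; the
forkhead block deliberately contains no V or I so the zipper anchor cannot
fire inside it.

Signature discovery (`signature_residues()`) operates on a
reference-anchored alignment (`anchor_align()`: every sequence aligned
globally to a baseline, columns indexed by baseline position, `X` runs
masked as missing data). A signature column is one where all ingroup
members with data agree and the residue is absent from every exclusion-set
sequence. Whether a clade signature must be absent only from the
paralogues (FoxP1/2/4) or also from other FoxP3s is genuinely ambiguous in
comparative practice; both readings are supported by composing
`exclusion_sets`, and the panel demonstration uses both: against the
paralogues alone the bird rows show eleven conserved-and-absent columns,
five of which overlap the twelve-residue mammalian signature; adding the
mammalian FoxP3 to the exclusion leaves the six strictly avian columns. A
`max_ingroup_mismatch` option relaxes strict identity for larger panels.

```{r signature}
panel <- simulate_foxp_panel()
aln <- anchor_align(panel[, c("id", "sequence")], "mouse_foxp3")
birds <- panel$id[panel$clade == "bird"]
paralogues <- panel$id[panel$clade == "paralogue"]
signature_residues(aln, birds, list(paralogues = paralogues),
                   reference_signature = mammalian_signature_reference())
signature_residues(aln, birds, list(paralogues = paralogues,
                                    mammal = "mouse_foxp3"))
```

## Expression evidence and the verdict

`exact_match_coverage()` counts, per codon, the reads whose full sequence
matches the coding sequence exactly (either orientation); a codon counts
only when fully contained in the match, which keeps counts unambiguous at
match edges. Exact substring matching — not heuristic mapping — is the
point: perfect-identity reads are the strong form of expression evidence,
and the operation needs no external aligner. The demonstration read set
tiles the 152-codon window from the middle of the leucine zipper to four
residues short of the forkhead end, leaving an eight-codon block uncovered,
and `covered_aa()` recomputes 144 covered codons from it.

`integrate_evidence()` is a pure rule cascade over whatever evidence is
supplied: annotated between flanks → `PRESENT_ANNOTATED`; recovered exons
covering ≥15 forkhead residues in a spanned or gapped region →
`PRESENT_UNANNOTATED`; a gapped or split region with conserved flanks and
no exon evidence → `LIKELY_MISSED`; a cleanly spanned region with no exon
or read evidence → `LIKELY_ABSENT`; anything else → `INDETERMINATE`.
Every verdict records the rules that fired.

```{r verdict}
crow <- crow_like_record()
integrate_evidence(classify_locus(crow, upstream_flank = "naa10",
                                  fallback_upstream = "hsd17b10"))
```

## Synteny classification details

A few decisions in `classify_locus()` were genuinely open and are worth
recording:

* **Gap threshold.** A spanning region counts as `GAP_IN_REGION` when its
  largest N run reaches 20% of the intergenic span (configurable). The
  motivating gapped region is 65% gap, far above any sensible threshold;
  20% marks the point where an absence of recovered exons stops being
  informative.
* **Fallback flanks.** When the primary upstream flank is unannotated, the
  nearest related gene stands in for it (as `hsd17b10` does in the
  crow-like fixture), via an ordered fallback list.
* **Orientation.** Flank order on the scaffold decides consistency;
  single-gene strand inversions are tolerated, since an inverted
  opposite-strand flank does not alter the conserved location.
* **Multiple flank copies** resolve to the pair closest to each other on
  one scaffold.
* **Quality groups.** A genome falls in the multi-gene group when any
  scaffold carries two or more distinct neighbourhood genes, in the
  single-gene group when neighbourhood genes occur only alone, and in the
  zero group otherwise — one consistent reading of a counting rule that is
  underspecified for partial annotations.

## Problem sizes and determinism

The shipped tests run the aligner-versus-oracle comparison on 200 random
instances (5–8 residue proteins against roughly 36–50 bases, half with
planted introns), planted-truth recovery on 50 simulated neighbourhoods, and the
fragmentation sweep at five multipliers × 100 seeds; the whole suite
completes in under two minutes on one CPU. These sizes were chosen so the
exhaustive oracle stays exact (two-intron chains are still enumerable) and
the Monte-Carlo properties are stable; all randomness is seeded, and every
simulator output records the seed that produced it.

## Known limitations

* The splice model is canonical `GT–AG`, phase-0 only, with no frameshift
  state; genes with split codons across introns are recovered with
  boundaries up to one codon off, which the curation step can repair given
  a reference structure.
* Repeat masking is treated as given (lowercase); the package neither
  masks nor models repeat families, and hard-masked bases are
  indistinguishable from assembly gaps by design.
* The synthetic survey fixtures reproduce published marginal structures so
  the counting machinery can be exercised offline; they are stand-ins, and
  conclusions about any real genome require running the same functions on
  real annotations.
* `integrate_evidence()` weighs evidence by fixed rules, not
  probabilistically; the rationale list exists so a user can audit which
  rules drove a verdict.
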