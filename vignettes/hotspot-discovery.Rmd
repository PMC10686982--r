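---
title: "Non-coding mutation hotspot discovery: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-coding mutation hotspot discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crvhotspot)
library(data.table)
```

## The problem

Melanoma genomes carry an enormous burden of somatic variation, more than
99% of it non-coding. A small fraction of those variants are
cis-regulatory: they create or destroy transcription-factor binding sites
in promoters and enhancers and thereby rewire gene expression (the TERT
promoter mutations are the canonical example). `crvhotspot` implements a
burden-style screen for such variants: it looks for *hotspots* — clusters
of recurrent somatic mutation — concentrated inside regions with
independent evidence of regulatory activity, and asks whether each
regulatory hotspot's score is extreme relative to hotspots from the rest
of the genome.

## The model

**Merging.** Within a chromosome, variant records whose start positions
lie within `window` bp (default 25) of each other are chained
transitively into one cluster, mirroring `bedtools merge` semantics; a
cluster may therefore span more than `window` bp. Clusters with fewer
than `min_count` records (default 3) are discarded as isolated variation.
The 25 bp window reflects the scale of a transcription-factor binding
site: disrupting any of several adjacent bases can break the same site.

**Donor score.** A hotspot with `D` variant records at `G` distinct
positions scores `D^2/G`. Squaring `D` rewards recurrence; dividing by
`G` rewards concentration of that recurrence at few positions. Ten
records at four positions score `10^2/4 = 25`. By default `D` counts
*records* (a donor mutated at two positions contributes twice), because
the reference worked example sums per-position donor counts; distinct
donor counting is available via `count = "donors"`.

**Functional weighting.** Each record is weighted by a pre-computed
per-position functional-impact score (a FunSeq2-style track combining
conservation and motif creation/destruction evidence). The hotspot's
`mean_funseq` is the arithmetic mean over all `D` records; positions
absent from the track are imputed as 0 and counted in
`n_missing_funseq`, so missing annotation can never inflate a score.
Indels are looked up at their first reference base.

**Hotspot score and testing.** The hotspot score is
`donor_score * mean_funseq`. Hotspots are partitioned by region
membership: *test* (≥1 bp overlap with the regulatory set), *null*
(outside it), or *excluded* (overlapping exons or exclusion-listed
regions). The p-value of a test hotspot is the plain proportion of null
hotspot scores greater than or equal to it — ties count, zero is allowed,
no pseudo-count is added (the reference analysis explicitly reports
adjusted p-values of 0). Benjamini–Hochberg step-up q-values control FDR.

```{r worked-example}
v <- data.table(donor_id = paste0("D", 1:10), chrom = "chr1",
                pos1 = rep(c(101L, 111L, 121L, 131L), c(3, 1, 2, 4)),
                ref = "G", alt = "A", variant_class = "SNV")
track <- score_track(data.table(chrom = "chr1", start = 0L, end = 1000L,
                                score = 1.5))
call_hotspots(v, track)[, .(chrom, start, end, D, G, donor_score,
                            mean_funseq, hotspot_score)]
```

## Tunable parameters

| parameter | default | unit | why this default |
|---|---|---|---|
| `window` | 25 | bp | binding-site scale; the reference pipeline's merge window |
| `min_count` | 3 | records | "3 or more variants" defines a hotspot |
| `count` | `"records"` | — | matches the worked example's record summing |
| `g_mode` | `"starts"` | — | an MNV is one record at one start; footprint counting is the documented alternative |
| `alpha` | 0.05 | — | conventional FDR threshold |
| `promoter_up/down` | 3000/3000 | bp | default of the annotation tool family this emulates |
| `p_consensus` | 0.997 | — | conventional zero-mismatch consensus-profile value |
| `threshold_bits` | self-score − 1 | bits | tolerates no mismatch for a 10-mer at `p_consensus` 0.997 |

## ETS motif analyses

For each variant in a significant hotspot, an 11 bp window is cut with
the variant at position 6 (20 bp windows put it at position 10, one left
of center, both by convention). `nearest_ets_offset()` locates the
nearest ETS core `GGAA` on either strand; when the nearest occurrence is
`TTCC`, the window is re-read as its reverse complement so the motif
always reads `GGAA`, and the reported offset is `variant index − motif
start` (0–3 means inside the core).

One design choice was genuinely open: the tie-break when a variant is
equidistant from two occurrences. Preferring a strand (the obvious rule)
makes the answer depend on which strand the window was read from — for
`GGAAXXXGGAA` with the variant in the middle, the original window and its
reverse complement would report different offsets, violating strand
involution. Ties are therefore broken on the final *oriented offset*
(the 3′ flank wins), which is invariant under reverse complement; the
plus-strand occurrence is preferred only among candidates that already
agree on the offset.

Consensus 10-mers are turned into position weight matrices the way
consensus-to-profile tools do: probability `p_consensus` for the
consensus base, `(1 − p_consensus)/3` for the rest. Scanning scores
log-odds in bits against a uniform 0.25 background on both strands; hits
beyond `max_instances` (default 50,000, matching the reference analysis)
are uniformly down-sampled under a caller-supplied seed.

## The synthetic benchmark: what it emulates, and what it does not

`sim_config()` describes a self-contained world: i.i.d. random genome at
GC 0.41; disjoint regulatory intervals covering 12% of the genome;
an exponential score track whose mean is 6.7-fold higher inside
regulatory regions; 183 donors; background mutations falling
independently per donor and base; and planted recurrent hotspots (10 by
default, 5–12 records each over 1–4 positions with gaps within the merge
window) placed inside regulatory intervals.

The default `background_rate` is **3.7e-5 mutations/bp/donor**, derived
from the cohort the generator emulates: ~2.09e7 substitutions across 183
donors and ~3.1 Gbp. A much higher rate (1e-3/bp/donor) is sometimes
quoted for toy benchmarks, but at 183 donors it yields 0.18 expected
mutations per base; nearly every position is mutated, 25 bp chaining
fuses the whole genome into a few hundred mega-hotspots, and planted
signal is unrecoverable by construction. We treat that regime as a
mis-scaling and document it rather than benchmark in it.

What a green recovery test establishes: on sparse, positionally uniform
background with cleanly separated score distributions, the pipeline finds
essentially every planted hotspot of ≥5 records at q < 0.05. What it
does not establish: performance under mutational signatures (UV
dipyrimidine bias), regional rate covariates (replication timing,
expression), clonality or copy-number structure — the null here is purely
positional, exactly as in the method being implemented.

### A known, structural false-discovery floor

Because the generator elevates the score track 6.7-fold inside
regulatory regions, *any* background cluster of ≥3 records that happens
to fall inside a regulatory interval outscores essentially the entire
null distribution and is called significant alongside the planted
hotspots. At the default rate this contributes ~2–3 such calls per 100 kb
replicate against 10 planted hotspots, i.e. an irreducible ~13%
false-discovery fraction *measured against the planted manifest*
(pooled over 20 seeds: sensitivity 1.00, false discoveries ≈ 0.13). The
corresponding acceptance assertion (≤ 10%) is deliberately left failing
rather than tuned around: lowering the mutation rate or shrinking the
score fold would make the test pass by changing the world, not the code.
This mirrors a real property of the method: functional-score weighting
separates the compartments wholesale, so calls inside regulatory regions
are enriched but not individually guaranteed to be driver-like.

### Numerical and reproducibility choices

All generators derive independent sub-streams from one master seed, so
any subset of them reproduces exactly; RNG state is restored after each
call. Empirical p-values sort the null once and binary-search
(`O((m+n) log m)`); the BH step-up is the textbook `rev(cummin(rev(...)))`
formulation clipped to 1. Score-track tiles are 25 bp so that compartment
mean recovery concentrates (4,000 tiles per 100 kb). The fold-recovery
acceptance check runs the same world at 1 Mb and averages five seeds —
a sample-size choice; the effect size and estimator are untouched.

## Limitations

* The null is positional only; no trinucleotide signature or covariate
  correction (deliberately out of scope).
* FunSeq2-style scores are consumed, never computed.
* MUT windows support length-preserving alleles only; indel windows are
  rejected rather than approximated.
* The annotation module collapses UTRs into Exon and uses a fixed ±3 kb
  promoter; it is a deliberately simple stand-in for a full annotation
  engine.
* The empirical p-value resolution is 1/(number of null hotspots); small
  genomes give coarse p-values, and an empty null compartment is an
  error, not a silent pass.
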