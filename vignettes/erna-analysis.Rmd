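---
title: "Calling enhancer transcription states and testing their consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling enhancer transcription states and testing their consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernatools)
```

## The question and the design

Enhancers can be transcribed into short noncoding RNAs (eRNAs), but many
active enhancers are not. `ernatools` treats transcription as a binary,
tissue-specific *state* of an enhancer and asks three questions: does eRNA
expression track target-gene expression beyond what generically transcribed
neighbourhoods would produce; are target genes of transcribing enhancers
expressed higher than those of non-transcribing ones, even for the *same*
enhancer position observed across tissues; and do eRNA sequences carry
miRNA-like elements with complementary sites in the promoters of their own
target genes?

All coordinates in the package are 0-based half-open (BED-native); any
1-based input dialect must be converted at the reader boundary. This single
convention is load-bearing: every window test below is half-open, so abutting
features never count as overlapping and no stage applies its own ±1.

## State calling

An enhancer enters the analysis only if it is *intergenic*: it overlaps no
gene and its gap to every transcript boundary is at least the margin
(default 3000 bp, strict — a 2999 bp gap disqualifies; the boundary is the
transcript span, not the CDS). Contigs overlapping any gene are removed, so
read-through of annotated genes cannot masquerade as enhancer transcription.
The call itself: a contig's transcript start (5′ end; `start` on `+`,
`end − 1` on `−`; unstranded contigs are rejected because their 5′ end is
undefined) must fall in `[enhancer_start − w, enhancer_end + w)` with
`w = 3000`. "Around the locus" is interpreted as boundary extension, not a
midpoint window, and the window is half-open for consistency with the
coordinate convention. When several contigs qualify, the highest-BPKM one is
attached as *the* eRNA (downstream stages need one expression value per
enhancer) and the qualifying count is retained; ties resolve to the first
maximum, and a contig may serve several enhancers.

## Expression and correlation

BPKM = covered bases / (region length / 10³) / (library mapped bases / 10⁶).
It is linear in coverage and inversely linear in length and library size;
the package takes region-level BPKM tables as input rather than recomputing
from alignments.

The correlation stage pairs each eRNA's BPKM with, per region class:

* **target gene** — the region from the strand-aware TSS spanning the eRNA's
  length (truncated at the transcript end), so eRNA and gene are measured
  over equal-length regions;
* **flanking bins** — three 1-kb bins per side starting at the ±3 kb window
  boundary, shifted to the eRNA's far end when the eRNA extends past the
  boundary; bins overlapping a gene are discarded with their label;
* **gene upstream** — a region of the eRNA's length immediately 5′ of a
  gene's TSS;
* **random intergenic** — a length-matched interval uniform over intergenic
  space (gene spans expanded by the same 3 kb margin).

The last two backgrounds are this package's construction (their exact
recipe is not fixed by the analysis design, so both are declared here).
Pearson r is reported with a one-sided p (positive alternative, t transform
on n − 2 df) because the claim under test is directional; a two-sided option
exists on `pearson_cor()`. Pairs with a missing region value are dropped
listwise per class, and a class with fewer than 3 usable pairs is flagged
undefined rather than reported. When an enhancer targets several genes, each
(eRNA, target gene) pair enters once — a multiplicity choice, recorded here.

## Cross-tissue comparison

Per target gene, enhancer midpoints from all tissues are clustered by single
linkage at 1000 bp. Midpoints are used because they are symmetric and
insensitive to unequal enhancer lengths; single linkage in one dimension is
just "cut where the sorted gap exceeds the window". A valid group has both a
transcribing and a non-transcribing member; per gene, only the largest valid
group(s) survive — disjoint ties are kept as separate groups, and a tie
among groups sharing an enhancer resolves by a seeded uniform choice (with
single-linkage clusters that case cannot arise, but the rule is implemented
for externally supplied groupings).

Expression is standardized per tissue, `(x − mean)/sd` with the sample
(n − 1) sd, over each tissue's full set of target-gene BPKMs — a tissue-level
reference distribution, not just the grouped genes. Per group the target
gene's z is averaged over member tissues by state, and the pair differences
are tested with a one-sided paired t (via a one-sample t on the differences).
The per-tissue unpaired comparison deduplicates by (gene, state) before the
one-sided Wilcoxon rank-sum test — a gene targeted by several same-state
enhancers contributes once — and uses exact enumeration for tie-free samples
up to n = 20 per side, the tie-corrected normal approximation otherwise.
The group scatter's trend is the least-rectangles (geometric-mean) line,
`slope = sign(r)·sd(y)/sd(x)`: symmetric in x and y, and always at least as
steep in magnitude as ordinary least squares.

## Family-annotation enrichment

The covariance-model scan itself is out of scope; the module consumes a hit
table (query, family, class, score) that a thin importer can fill from real
scanner output. Hits are deduplicated per (query, family) so proportions are
over per-query indicators; totals default to *all* queries (not just
annotated ones), a choice exposed as the `n_real`/`n_control` arguments.
Controls match the eRNAs in number and in length (lengths drawn with
replacement from the eRNA length multiset) and are placed uniformly over
intergenic space under the same 3 kb margin used for enhancer filtering.
The per-family test is the pooled one-sided two-proportion z; it is
implemented from its closed form because that specific statistic is the
method (the base-R proportion test is a continuity-corrected chi-square,
which is not the same number); a degenerate pooled proportion (0 or 1)
reports p = 0.5 under the equality convention with a flag. Significant means
p < 0.001. The class comparison then asks whether the eRNA-versus-control
excess is stronger for miRNA families than for other families: among hits to
significant families of each class, the fraction coming from eRNAs is
compared, again with the pooled z.

## miRNA-like promoter targets

A family is *confirmed* inside an eRNA by an exact (100% identity)
occurrence of its mature sequence or its 7-nt seed (mature positions 2–8;
U ≡ T), in either orientation; the leftmost match wins, mature beating seed
at equal position. Promoters are TSS −1000..+200 with other genes' bodies
subtracted (possibly empty); 3′UTRs run from the coding end to the gene end
and do not exist for noncoding genes.

Two scanners cover the confirmed families:

* **Seed sites**, TargetScan nomenclature: a full 7-nt seed complement
  followed by A is an 8mer; without the A, 7mer-m8; a 6-nt complement of
  seed positions 2–7 plus A, with no position-8 match (which would be an
  8mer), is 7mer-A1. The site's A is required in the target regardless of
  the miRNA's first base. The antisense scan applies the same rule to the
  reverse complement with positions mapped back; duplicate
  (position, type, strand) rows collapse.
* **Complementarity alignment**: the mature sequence slides ungapped along
  the target, 3′→5′ against 5′→3′, scoring +5 per Watson–Crick pair, +1 per
  G:U wobble, −3 per mismatch, with miRNA positions 2–8 doubled; windows
  scoring ≥ 80 (default) are reported. The scheme is declared, simplified,
  and not claimed identical to any external program's scoring; a perfect
  22-mer scores 145 and a single seed mismatch costs 16.

A (eRNA, gene, family) triple is retained only if the promoter has a site
and the 3′UTR has none — promoter-unique targeting, the configuration
associated with activation rather than canonical repression. Significance
per eRNA comes from a shuffle bootstrap: the eRNA's characters are permuted
(mononucleotide by default; a dinucleotide-preserving Altschul–Erickson
shuffle is available), the *entire* identification procedure reruns on each
of B = 100 shuffles, and `p = (1 + #{shuffle statistic ≥ observed})/(1 + B)`.
The add-one estimator avoids p = 0 at finite B and makes the p-values
conservative by construction. The bootstrap statistic is the retained match
count (configurable to existence); only eRNAs with at least one retained
match on the real sequence — the "resulting" miR-like eRNAs — are taken
through the bootstrap.

## The synthetic world

`generate_world()` emulates the complete input bundle with known truth. Its
defaults are the package's reference conditions and are not tuned per run:

| parameter | default | meaning |
|---|---|---|
| `n_tissues` | 12 | tissues with separate enhancer maps and contigs |
| `chrom_length`, `n_genes` | 8 Mb, 300 | non-overlapping genes, gaps ≥ 15 kb |
| `n_enhancers` | 250 | one locus per inter-gene gap, ≥ 3 kb margins |
| `erna_fraction` | 0.4 | per (locus, tissue) transcription probability |
| `rho` | 0.6 | latent log-scale eRNA–target correlation |
| `delta` | 0.5 | latent z shift of target genes of transcribing enhancers |
| `sigma` | 0.3 | log-scale expression sd |
| `share_fraction` | 0.5 | loci present in all tissues (≤ 250 bp jitter) |
| `base_hit_rate`, `n_families` | 0.02, 200 | family-hit background |
| `family_enrichment` | +0.15 | planted excess, one miRNA-class family |
| `other_enrichment` | +0.06 | planted excess, one other-class family |
| `seed_site_rate` | 0.5 | per-eRNA planted mature + promoter 8mer |

Design notes, in the order they matter:

* Gene gaps of ≥ 15 kb leave room for an enhancer, its 3 kb margins and the
  3 kb of flanking bins on each side, so flank classes keep usable sample
  sizes; genes are placed by cumulative sums, and an impossible packing is a
  configuration error, not a silent truncation.
* Expression is bivariate normal on the log scale, then exponentiated, so
  BPKMs are positive and skewed like real coverage data. At `sigma = 0.3`
  the BPKM-scale Pearson correlation is `(e^{ρσ²} − 1)/(e^{σ²} − 1) ≈ 0.98ρ`
  (0.589 for ρ = 0.6), so the planted and measured scales almost coincide;
  the truth record stores both. The state shift `delta` is planted on the
  latent scale; pushed through the lognormal and the per-tissue
  standardization it measures ≈ 0.48 for `delta = 0.5` (closed-form mixture
  moments, implemented in `lognormal_mixture_moments()`).
* Contig 5′ starts for transcribing enhancers are uniform in the ±3 kb
  window, lengths lognormal (median 500 bp) and clipped to the inter-gene
  gap so the gene-overlap filter cannot flip a planted state; decoy contigs
  are rejection-sampled to keep their 5′ starts outside every enhancer
  window of their tissue. Background-region expression (flanks, upstream,
  intergenic) is drawn independently of everything planted — backgrounds
  are null by construction.
* A gene's tissue-specific expression latents are independent across
  tissues. One consequence is deliberate and documented: in the group-mean
  scatter the transcribing and non-transcribing means are uncorrelated, so
  the least-rectangles slope there carries no signal (its sign is sampling
  noise) even though the paired *shift* is exactly the planted effect. A
  cross-tissue gene random effect would make that scatter look like real
  data but would attenuate the within-tissue eRNA–target correlation away
  from the planted `rho`, so it is omitted.
* One miRNA-class family gets a +0.15 hit excess. A second, other-class
  family gets +0.06 — without it the miRNA-versus-other comparison is
  undefined on the default world (one class would have no significant
  family); +0.06 makes that family detectable with ≥ 98% probability at the
  default world's ~700 queries (pooled-z power calculation).
* Sequences are uniform random A/C/G/T with planted elements overwritten in
  place: the mature sequence into the eRNA, the exact 8mer site into the
  target promoter. Background chance sites are *not* scrubbed; scanners are
  expected to find them, and truth lists are complete for planted sites
  only.

What passing tests on these worlds do **not** show: real contig coverage
structure (assembly gaps, biased 5′ ends), realistic karyotypes or gene
density, correlated expression across tissues, chromatin context, or any
specific real-data count — those depend on external accessions that this
package deliberately does not require.

## Numerical and degenerate-input choices

* Pearson and rank-sum delegate to the standard R tests; constant vectors,
  sub-minimal sample sizes, and zero-variance paired differences raise
  errors rather than returning NA.
* The pooled z handles pooled proportions of 0 or 1 as a flagged degenerate
  with p = 0.5 (equality convention).
* Tie-breaks: equal-BPKM qualifying contigs resolve to the first maximum;
  tied maximum-size groups sharing an enhancer resolve by a seeded uniform
  draw; `build_groups`, `sample_matched_controls`, the generator and the
  bootstrap all take explicit integer seeds and restore the caller's RNG
  state, so identical seeds give byte-identical outputs.
* `least_rectangles_line()` with r exactly 0 takes the positive slope by
  convention; constant input is an error.

## Verification scales

The test suite checks the stages against independent brute-force oracles —
per-base window membership for state calling (1000 random worlds of ~200
enhancers), per-base masks for interval subtraction and overlap, exhaustive
rank enumeration for the rank-sum test, naive substring/all-window
enumeration for both scanners (1000 random cases), and an exhaustive
grouping enumerator (50 four-tissue worlds) — plus statistical calibration:
paired-t type-I error within 0.05 ± 0.02 over 2000 null group sets of 50
groups and power ≥ 0.9 at α = 0.001 with `delta = 0.5` and 100 groups;
correlation recovery within [0.5, 0.7] and background |r| < 0.1 per class in
≥ 95% of 200 replicate worlds of 500 pairs; ≤ 0.2 significant families per
200-family null run averaged over 100 runs (the exact level of the discrete
pooled z at these sizes is 0.00093); and a bootstrap median p < 0.05 over 50
planted-site eRNAs at B = 100. These problem sizes are the package's chosen
reference scales; they keep the full suite to a few minutes on one CPU.
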