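---
title: "Bulked-segregant delta-index screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant delta-index screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascreen)
```

## The problem and the statistic

Bulked-segregant analysis (BSA) localises trait-associated loci by pooling
individuals with extreme opposite phenotypes — here a sensitive bulk S and a
tolerant bulk T of 20 diploid individuals each, as in a salt-alkali tolerance
screen of the swimming crab — and contrasting pooled allele frequencies from
whole-genome sequencing of the two pools.

At a biallelic site, each pool's **SNP/InDel index** is the fraction of its
reads carrying the alternate allele,

$$\mathrm{index} = \frac{d_{alt}}{d_{ref} + d_{alt}},$$

computed strictly from the VCF `AD` field so that reads excluded by the
caller cannot skew the denominator. The **delta index** is the difference
between the pools,

$$\Delta = \mathrm{index}_T - \mathrm{index}_S,$$

near 0 for sites segregating independently of the phenotype and near
$\pm 1$ for sites co-segregating with it. The sign convention is tolerant
minus sensitive; it only flips labels, all screening uses $|\Delta|$.

## Filter cascade

Raw pooled calls contain sites where the index is uninformative. A site is
removed when

* its index is below `low_index` (default 0.3) **in both pools** — a
  shared low-frequency alternate allele carries no contrast; or
* a pool's total depth is below `min_depth` (default 7). The depth wording
  in the source protocol is ambiguous between "either pool" and "both
  pools"; the default removes a site when *either* pool is shallow, the
  conservative reading (an index estimated from fewer than 7 reads is
  unreliable wherever it occurs), and `depth_rule = "both"` selects the
  permissive reading.

Sites with zero depth in a pool have an undefined index and always fail;
they are excluded rather than imputed.

## The null confidence envelope

The screening thresholds alone do not calibrate chance: at finite depth a
null site can reach a large $|\Delta|$ by sampling error. The envelope
models the two stages of sampling that generate a pooled read count under
no association:

1. **Bulk composition.** Each bulk of $n$ diploids carries $2n$
   chromosomes; the bulk's realised allele frequency is
   $\mathrm{Binomial}(2n, 0.5)/2n$. The 0.5 reflects a segregating allele
   with no phenotype linkage; with $n = 20$ this finite-bulk stage
   contributes variance that read depth cannot remove.
2. **Read sampling.** Given the realised frequency $f$ and the observed
   pool depth $d$, the alternate read count is $\mathrm{Binomial}(d, f)$.

`null_delta_envelope()` simulates `n_sims` (default 10,000) such sites at
the observed per-pool depths and returns the empirical
$(1-\mathrm{level})/2$ and $1-(1-\mathrm{level})/2$ quantiles of the
simulated $\Delta$ (inverse-ECDF quantiles, `type = 1`, so that tiny-depth
envelopes match exact enumeration of the discrete outcome space — a
property the test suite checks). Because $\Delta$ is discrete, realised
coverage sits slightly above the nominal level (about 95.0–95.8% at depth
45), which the package's acceptance tolerance of one percentage point
absorbs.

A **candidate marker** must jointly (i) pass the filter cascade, (ii) fall
outside its own null envelope at the configured level (default 95%), and
(iii) satisfy $0.69 \le |\Delta| \le 1$. Whether the confidence screen was
meant in addition to or as the definition of the 0.69 cutoff is not
derivable from the protocol wording; both are applied conjunctively, and
`use_envelope = FALSE` or `delta_lo = 0` disable either part. At the
default design (depth $\approx 45$, bulks of 20) the absolute window is
the binding constraint and the null false-positive rate of the full screen
is far below 0.1%.

`bsa_scan()` wraps the cascade into one fit and memoises envelopes on the
(depth S, depth T) pair, so screening $10^5$ Poisson-depth sites costs only
a few thousand envelope simulations.

## The pool-seq simulator

The synthetic-data generator defines the conditions under which the
pipeline is exercised:

* two bulks of **20** diploids, mean pool depth **45** (the study design
  this package mirrors reported 44.65× and 48.31×; one shared Poisson mean
  is used for both pools);
* depth is Poisson rather than fixed so the `min_depth` filter branch is
  exercised naturally;
* null sites share an alternate-allele frequency drawn from
  $U(0.2, 0.8)$ — wide enough that the 0.3 both-pool index filter removes
  some genuinely polymorphic sites, exercising that branch;
* one causal locus whose bulk-frequency divergence is `causal_delta`
  (default 0.9) at the locus and decays **linearly** to zero over
  `linkage_window` bp (default 50 kb) — the simplest decay shape; both knobs
  are configuration, and a single-locus architecture is the default with
  multi-locus scenarios left to configuration;
* sampling is **two-stage** (chromosomes into the bulk, then reads from
  the bulk), which is what makes the envelope's null model correct for the
  simulated data;
* SNPs and InDels (left-anchored, 1–10 bp) in equal proportion by default.

The simulator emulates allele-depth data, not reads: no sequencing-error
model, no alignment artifacts, no reference bias, and contigs are i.i.d.
uniform DNA. Passing tests therefore demonstrate the statistical machinery
under the stated sampling model, not robustness to upstream calling noise
in real data.

Reference simulation places 1–4-exon genes with CDS spanning the exons
(total length a multiple of 3, GFF phase accumulated along the
transcription direction), non-overlapping by construction. All artifacts
round-trip through standard formats: FASTA, GFF3, VCF v4.2 with `AD`, TSV.

## Annotation

Variants are classified against the gene models with precedence
exonic > splicing > intronic > upstream/downstream > intergenic. The
windows are not part of the source protocol and use common annotator
defaults: 1 kb for upstream/downstream (a site inside the upstream window
of one gene and the downstream window of another gets the combined
"Upstream/Downstream" class) and 2 bp of intron for splice sites. Coding
effects of SNPs rebuild the affected codon from CDS segments, phase and
strand and translate with the standard genetic code (no initiator-codon
special-casing); InDels in CDS are tagged frameshift/in-frame and stay in
a plain "Exonic" class rather than the SNP effect classes. When a site
hits several transcripts the most severe effect wins (stop gain > stop
loss > non-synonymous > synonymous). Candidates — including intergenic
ones — are anchored to the containing gene or the nearest gene span on
the contig, ties broken toward the smaller gene id for determinism.

## Marker validation and enrichment

Validation panels (marker × genotype counts for the two phenotype groups)
are tested with Pearson chi-square without continuity correction, after
dropping genotype categories empty in both groups. This choice is
empirical: it reproduces the printed p-values of the motivating study's
validation table exactly at three decimals (0.007, 0.001, 0.007), which
the one-way ANOVA its text names does not under any standard dosage
coding; the chi-square is therefore the primary test, with an exact
conditional enumeration test (`fisher_exact_reference`, total ≤ 60)
reported alongside as a small-sample reference. No multiple-testing
correction is applied to the panel, matching the uncorrected p < 0.05
rule; Benjamini–Hochberg is available where rates matter. Allele
frequencies are counted from two-letter genotype labels; for In/Del/Indel
panels the genotype-to-allele mapping is not derivable from the labels and
must be supplied explicitly.

Candidate-gene enrichment is a one-sided hypergeometric
over-representation test — the universal default for GO/KEGG-style ORA —
against a background of all genes anchored from pre-screen markers, with
BH-adjusted q-values reported next to raw p-values (selection uses raw
p < 0.05, the adjusted column is informational).

## Numerical choices and problem sizes

* Envelope quantiles: inverse ECDF (`type = 1`); envelopes memoised per
  depth pair; all simulation seeded, and library code restores the
  caller's RNG state.
* Undefined indices (`NA`) propagate and fail filters; depth-0 sites are
  legal in every format.
* Multiallelic VCF sites keep the first ALT with a warning (the index is
  defined for a biallelic contrast).
* The total-yield helper truncates Gbp to two decimals by default
  (`mode = "round"` for half-up), matching the yield-reporting convention
  of the motivating study.
* Default test/vignette problem sizes — 10,000 envelope simulations,
  10,000 coverage test sites, 100,000 null sites for the false-positive
  property, 25 recovery replicates — were chosen as the smallest sizes at
  which the Monte-Carlo standard errors are comfortably inside the asserted
  tolerances.

## Worked example

```{r example, fig.width = 7, fig.height = 4, eval = FALSE}
sc <- sim_scenario(seed = 42)           # 3 contigs, causal locus on contig_1
ref <- simulate_reference(sc)
sites <- simulate_pool_depths(plant_sites(sc, ref$genome), sc)
fit <- bsa_scan(sites, bulk_size = sc$bulk_size, seed = 42)
summary(fit)
plot(fit, contigs = "contig_1")
```

## Known limitations

* Per-site screening only; no sliding-window smoothing of $\Delta$ along
  chromosomes and no G′-style alternative statistics.
* The envelope's null assumes a segregation frequency of 0.5 per bulk
  (F-population-style); `seg_freq` is exposed because extreme-tail bulks
  from one outbred population need not satisfy it.
* Annotation covers the region classes above; UTR/ncRNA classes,
  isoform-level reporting and homology-based functional annotation are out
  of scope.
* The exact panel test enumerates tables up to 60 observations and refuses
  beyond.
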