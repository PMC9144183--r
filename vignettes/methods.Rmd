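---
title: "Methods: promoter CGI filtering and expression–methylation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter CGI filtering and expression–methylation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its model, the choices that were
genuinely open, and what the synthetic tests do and do not demonstrate.

## The filtration model

The pipeline operationalizes one idea: a gene whose tumor expression change
is *concordant* with its promoter methylation change is a plausible subject
of epigenetic regulation, hence a candidate for epigenetic therapy.
Concordance means the directions agree under the standard repressive model
of promoter methylation: upregulated + hypomethylated (oncogene-like
activation) or downregulated + hypermethylated (tumor-suppressor-like
silencing). The pipeline is a pure filtration — no effect is estimated
jointly; each stage makes an independent, auditable call:

```
DEG list  →  promoter has CGI?  →  expression direction ⊗ methylation direction  →  class
```

Every input gene is carried to the final report (non-island and discordant
genes as `unclassified`), so the count at each stage is recoverable from the
output alone.

## Promoter extraction

All internal coordinates are 0-based half-open on the forward strand;
conversions happen only when reading BED (already 0-based) or GFF3
(1-based inclusive). The TSS is the feature start on `+` and the rightmost
feature base on `-`; promoters are reported in transcription orientation so
"upstream" has a strand-independent meaning. The default window is
**2000 bp upstream, 0 downstream**: the island-position rule below needs
only the first 200 bp excluded, and 2 kb is a conservative superset of the
proximal promoter as commonly delimited; both lengths are arguments.
Windows running off a contig are clipped and flagged rather than dropped.
`N` bases are retained — the scanner, not the extractor, decides how to
count them. For multi-isoform annotations the caller must pre-select one
TSS per gene; the package takes annotation rows at face value.

## CpG-island detection

The criteria — GC content > 50 %, observed/expected CpG ratio > 0.6, length
> 200 bp, with `O/E = N_CpG · L / (N_C · N_G)` — are classical
(Gardiner-Garden-type), but they define a predicate, not an algorithm. We
adopt the de-facto-standard sliding realization (as in Takai–Jones-style
scanners) and specify it completely so it is testable:

* slide a 200 bp window in 1 bp steps; a window qualifies iff **both**
  ratio thresholds hold strictly;
* merge overlapping or adjacent qualifying windows;
* trim each merged region one base at a time until the *whole region*
  satisfies both thresholds; regions falling below the minimum length are
  dropped; survivors must be strictly longer than 200 bp.

Numerical details that required a decision:

* **N handling.** `N` is excluded from `L`, `N_C`, `N_G` and the GC
  denominator, and a window more than half `N` never qualifies — assembly
  gaps must not fabricate islands. An all-`N` window has GC 0 by convention
  (with a warning at the user-facing level).
* **Trim side.** When a region fails, one base is removed from the end
  whose removal most increases the failing statistic. When both statistics
  fail, GC% is the deciding one (O/E decides only once GC passes) — one
  statistic must be named for the rule to be deterministic, and GC is the
  cheaper, more stable quantity. Ties trim the 3′ end. The brute-force test
  oracle enumerates windows and merges independently and shares only this
  trim contract, which is part of the algorithm's definition.
* **Strand.** Reverse complement maps CG→CG and preserves GC, so window
  qualification and merging are exactly mirror-symmetric; the 3′ tie-break
  is the only orientation-dependent step, and a seeded property test
  confirms mirror-image islands on the tested cases.

The island-position rule — a gene counts as CGI-bearing when an island
**starts** at least 200 bp upstream of the TSS — is one reading of "island
at least 200 bp upstream"; alternatives (island *ends* ≥ 200 bp upstream,
or restricting the scan to `[-200, 0)`) would make the 200 bp exclusion
zone either stricter or vacuous. Requiring the start upstream of −200
keeps islands that extend toward the TSS, which is the common biological
situation, while excluding islands confined to the immediate TSS vicinity.

## Direction calls

Beta values (`β = M/(M+U+offset)`, default offset 0 per the plain ratio
definition; an Illumina-style offset of 100 is an argument) are bounded and
typically bimodal, and TPM is heavy-tailed, so both modalities use the same
machinery: a two-sided **Wilcoxon rank-sum** test per gene (normal
approximation; constant genes get p = 1 rather than an error) with
**Benjamini–Hochberg** adjustment across genes. Significance alone is not a
direction: micro-differences become significant at large n, so a direction
additionally requires a minimal effect — `|Δβ| ≥ 0.1` (a conventional
smallest biologically interesting methylation difference) and
`|log₂FC| ≥ 1` (two-fold), both configurable, at q < 0.05. Expression tests
rank `log2(TPM+1)`; ranks are invariant to the transform, which is kept
for interpretability of intermediate output. The fold change uses
pseudocount 1, so it is shrunk toward 0 near the detection floor —
deliberate, as "directions" of ~1 TPM genes are noise. Probe-level beta
input is collapsed to genes by the per-sample mean (median available)
before testing.

## Enrichment

"Gene set enrichment" over an unranked list is read as over-representation
analysis: upper-tail hypergeometric `P(X ≥ k)` per set, BH across reported
sets, universe defaulting to the union of set members so the null is
explicit and reproducible. Sets with zero overlap are omitted (their p is
1 by construction); ties sort by set name for determinism.

## The synthetic-data generator

The generator exists so the full pipeline can be exercised against known
truth without external downloads. Its defaults are the study conditions
used throughout the tests:

| parameter | default | why |
|---|---|---|
| genes / CGI-bearing | 51 / 24 | the flow shape being emulated |
| planted concordant genes | 5 + 2 | ditto |
| DEG split | 25 up / 26 down | input-list shape |
| samples | 20 tumor / 20 normal | small TCGA-like arm |
| Δβ | ±0.3 | clear biological shift, sub-saturating |
| β noise | Beta, concentration 20 | sd ≈ 0.11 at β = 0.5 |
| log₂FC | ±2 | four-fold, typical strong DE |
| TPM noise | log-normal, σ = 0.5 (log₂) | realistic biological CV |
| island | 500 bp, GC 65 %, CG-token rate 0.25 | comfortably above all three thresholds |
| background | GC 35 %, CpG depleted ×10 | vertebrate-like CpG-poor bulk |

Promoter islands are literal `CG` tokens diluted with random bases (the
single-base GC rate is solved so the overall island GC hits its target);
backgrounds break 90 % of chance `CG` dinucleotides, mimicking the CpG
depletion of bulk vertebrate DNA. Islands are planted with their start
100–1300 bp from the upstream edge of the 2 kb window, i.e. always ≥ 500 bp
upstream of the TSS — margins, not boundary cases. Genes carrying a planted
fold change draw their normal-group mean from 10–1000 TPM (null genes from
1–1000): a planted "direction" on a ~1 TPM gene is erased by pseudocount
shrinkage in *any* estimator, so planting effects there would encode an
unrecoverable truth rather than test the caller. Each generator restores
the caller's RNG state; a master seed derives per-stage seeds, and equal
seeds give byte-identical output files.

What passing synthetic tests **does not** show: performance under probe-
level artifacts, normalization and batch effects, realistic genome-wide CpG
landscapes (only one island per promoter is planted), correlated
methylation–expression noise, or multi-isoform TSS ambiguity. The planted
effects are homogeneous and well-separated; real tumor cohorts are neither.

## Problem sizes in the tests

The checked-in tests run the scanner-vs-oracle comparison on 100 random
sequences of 300–3000 bp, recovery and specificity on 100 + 100 simulated
promoters, sensitivity on 200 planted genes per modality with 20/20
samples, null FDR on 1000 genes, exhaustive hypergeometric enumeration for
universes up to N = 12, and the full study-shaped run (51 genes). These
sizes give stable Monte-Carlo estimates at interactive runtimes.

## Known limitations

* One TSS per gene; no isoform logic.
* No IDAT/array preprocessing, no count-based DE models; inputs are
  assumed normalized (beta, TPM) or precomputed.
* The CGI scanner is the deterministic sliding-criteria family, not an HMM
  or methylome-informed caller; results near the thresholds are sensitive
  to the trim contract by construction.
* The concordance classifier is deliberately binary per modality; genes
  with partial evidence (one modality significant) are reported but not
  ranked.
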