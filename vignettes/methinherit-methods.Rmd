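---
title: "methinherit: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methinherit: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methinherit)
```

## The model

### Per-cytosine methylation

A bisulphite experiment reports, for each reference cytosine, a
methylated read count $m$ and an unmethylated count $u$. The site's
methylation level is the mC/C ratio $m/(m+u)$. Sites are stratified by
sequence context — CpG, CHG, CHH ($H \in \{A, C, T\}$) — read from the
strand-oriented reference triplet: the base at the site and the two
following bases, reverse-complemented on the minus strand. Counts are
kept **per reference cytosine**; complementary CpG strand counts are not
merged by default (merging is available via `merge_cpg_strands()`, which
conserves totals).

Genome-wide summaries are reported both as pooled levels
($\sum m / \sum (m+u)$, invariant under splitting or merging counts
across sites) and as mean-of-site levels; whether published global
figures are pooled or averaged is often unstated, so both are emitted.

The bisulphite conversion rate is estimated as
$1 - \sum m / \sum(m+u)$ over all sites of designated control sequences
known to be unmethylated (spike-in or control contig); every methylated
call there is a conversion failure.

### DMR calling

For each context the genome is tiled into windows
$[k \cdot \text{step},\, k \cdot \text{step} + \text{size})$, clipped at
chromosome ends. A window is **tested** when each of the two samples has
at least `min_sites` covered context sites inside it (the five-site rule
applied per sample — the stricter of the two possible readings, and
configurable). Counts are pooled per group into the 2×2 table
$[[m_A, u_A], [m_B, u_B]]$ and assessed with a two-sided Fisher exact
test; the fold change is computed on the pooled window levels with a
pseudo-level $\varepsilon = 10^{-6}$,
$\text{fc} = (\ell_B + \varepsilon) / (\ell_A + \varepsilon)$, so a
window going from level 0 to a positive level is hyper-eligible rather
than undefined. A tested window is a DMR when $P < \alpha$ **and**
$\text{fc} \ge t$ (hyper) or $\text{fc} \le 1/t$ (hypo), with $t = 2$ by
default. "Hyper" always means higher methylation in group B, the
treated/stored sample.

Statistical assumptions worth naming: pooling treats reads within a
window and group as exchangeable Bernoulli draws (a binomial model); the
raw-$P$ criterion performs no multiple-testing correction (Benjamini–
Hochberg within context is available via `padjust = "bh"` but is off by
default, because the defining criterion is the raw $P$); and replicates
are pooled before testing rather than modelled, matching a design with
one pooled methylome per condition.

### Fisher exact test

`fisher_exact_two_sided()` sums hypergeometric point probabilities (all
tables with the observed margins) whose probability does not exceed that
of the observed table, with a relative tie tolerance of $10^{-7}$ —
the same tie rule used by `stats::fisher.test` — and evaluates
probabilities in log space so large pooled counts cannot underflow.
Degenerate margins (an all-zero row or column, leaving a one-dimensional
table) return $P = 1$. The implementation is checked in the test suite
against an independent enumeration oracle for every 2×2 table with total
$\le 30$ (about 46,000 tables, $|\Delta p| \le 10^{-9}$) and
spot-checked against `stats::fisher.test` on random larger tables.

### Annotation

Gene bodies are the full transcript span $[tx_{start}, tx_{end})$;
promoters default to the 1-kb window immediately upstream of the TSS
("within 1 kb of the TSS" is ambiguous between upstream-only and ±1 kb;
upstream-only is the conservative regulatory reading, and
`mode = "both"` provides the alternative). Overlap is ≥ 1 bp on
half-open intervals, so abutting intervals do not overlap. A gene may
accumulate records for both region classes and both directions through
distinct DMRs; records are de-duplicated on (gene, region class,
direction) with supporting DMR identifiers retained, so every assignment
is re-verifiable — the test suite re-checks each claimed overlap.

### Integration

Expression and protein tables are *inputs* (differential testing itself
is routine and out of scope); only the threshold filters and direction
logic live here. DEGs pass with fold change ≥ 2 in either direction
(reciprocal rule for down-regulation) and Q ≤ 0.001. Proteins pass with
|fold change| ≥ 1.3 and FDR-adjusted P ≤ 0.05 — the source material
states both a 1.3-fold (figure) and 1.5-fold (methods) threshold, so 1.3
is the default and 1.5 a documented variant. Proteins map to genes via
an explicit map; unmapped significant proteins are reported, never
silently dropped.

The concordance table takes one gene per row from the strict triple
intersection sperm-DMGs ∩ embryo-DMGs ∩ DEGs (`loose = TRUE` relaxes to
any two layers). The methylation direction of a gene in one generation
uses gene-body records when present, falling back to promoter records
with a region note; a gene whose supporting region class carries both
directions is annotated "mixed" and listed separately rather than forced
into a single direction.

## The synthetic world

The generator's defaults state the world the package is tested in:

| parameter | default | why |
|---|---|---|
| context baselines | CpG 0.93, CHG 0.014, CHH 0.04 | the global levels a hypermethylated vertebrate sperm methylome shows |
| coverage | Poisson, mean 30 | typical WGBS depth; only total volume is usually published |
| overdispersion ρ | 0.05 (beta-binomial) | site-to-site biological variability; no noise model is published, so a mild standard choice |
| conversion failure | 0.005 | matches a reported conversion rate just above 99.45 % |
| planted DMRs | 100 × 1 kb, CpG, levels 0.40 ↔ 0.93, half hyper | the level pair exceeds the two-fold rule in both directions with \|Δ\| ≥ 0.4; width = one caller window |
| inheritance fraction | 0.6 | a majority-but-partial retention, the regime worth testing |
| genome | 2 × 500 kb + 20 kb control contig, GC 0.4 | desk-scale genome; fish-like GC |
| genes | 200, 1–4 kb, non-overlapping | dense enough that roughly half of planted DMRs hit genes |
| DEG coupling | 20 DEGs, half coupled to inherited-DMR genes, fc ∈ [2, 6] | makes the three-way join non-trivial in both directions |

Placement details: planted DMRs are aligned to caller windows and
rejection-sampled to contain at least 10 CpG sites, guaranteeing the
five-site rule per strand-site; distinct windows make planted regions
non-overlapping by construction. The inherited subset is an exact
without-replacement sample of $\lfloor f \cdot n \rfloor$ DMRs. In the
embryo generation the fresh embryo carries the fresh-condition (A)
levels at all planted regions and the stored embryo the stored (B)
levels only at inherited regions — non-inherited regions *revert to the
fresh state*, not to the context baseline, because planted fresh levels
differ from baseline and a literal baseline revert would create spurious
fresh-vs-stored embryo differences at non-inherited regions, making the
emitted truth unusable for scoring. With this choice the embryo truth is
exactly the inherited set.

Coupled DEGs are drawn from genes carrying a direction-consistent
inherited DMR; the direction rule is: gene-body methylation direction
carries over to expression, promoter methylation acts repressively
(promoter hyper → down). Uncoupled DEGs are drawn from DMR-free genes.
Planted DEGs/DEPs receive fold changes and significance values that pass
the stated filters; all other genes fail at least one threshold, so
filter output equals planted truth by construction.

What the generator does **not** emulate — and what a green test
therefore does not establish: read-level artefacts (mapping bias,
duplicates, M-bias), CpG-island structure and distance-dependent
co-methylation, copy-number or SNP-induced count distortions,
replicate-to-replicate biological variance (one methylome per
condition), and any realistic effect-size distribution for DMRs (none is
published; the planted 0.40 ↔ 0.93 switch is deliberately strong).

## Numerical choices

* All internal coordinates are 0-based half-open; conversion to 1-based
  (cytosine reports, GFF3) or 0-based (BED) happens only in readers and
  writers, verified by round-trip tests.
* Fold-change pseudo-level ε = 10⁻⁶; Fisher tie tolerance 10⁻⁷
  (relative), log-space evaluation.
* BED scores are −log₁₀(P) capped at 1000 (P = 0 underflow maps to the
  cap).
* Windows with fewer than `min_sites` covered sites in either sample are
  skipped, not reported; a window with zero pooled reads in both groups
  is skipped (no table can be formed).
* Promoters are clipped to [0, chromosome length); a promoter fully off
  the chromosome end is dropped.
* Context classification within 2 bp of the oriented sequence end is an
  error by default (`end_policy = "truncate_as_CHH"` coerces); N in the
  lookahead excludes the site.
* All stage seeds derive from a single configuration seed by fixed
  offsets; identical seeds give byte-identical outputs (tested).

## Acceptance-test interpretations

Two acceptance properties required an interpretation, made once and
recorded here:

* **Global-level recovery** runs the generator with ρ = 0, zero
  conversion failure and no planted DMRs: the property is about pooled
  levels matching planted baselines under exact binomial counts within
  3 binomial standard errors; planted DMRs shift the pooled CpG level
  away from baseline by construction, and a 0.5 % conversion failure
  biases CHG/CHH by far more than 3 s.e.
* **Planted-DMR recovery** scans the context in which DMRs are planted
  (CpG) at the caller's default thresholds, with the generator at its
  full defaults (including ρ = 0.05). Scanning CHG/CHH in that benchmark
  would only re-measure the null behaviour of the raw-P rule (see
  limitations), which the type-I property covers separately.

## Known limitations

* **The raw-P two-fold rule is fold-change-fragile at near-zero
  baselines.** In CHG (baseline 1.4 %), a 1-kb window pools only a few
  dozen methylated reads, and occasional windows double their level by
  chance while reaching P < 0.05; with overdispersion this is more
  frequent still. The worked example in the README shows such CHG calls
  alongside a perfect CpG recovery. This mirrors the behaviour of the
  criterion on real data (DMR counts in the tens of thousands) and is a
  property of the published rule, not a defect of the implementation;
  use `padjust = "bh"`, larger `min_sites`, or restrict `contexts` when
  it matters.
* Fisher's exact test assumes binomial sampling within windows; with
  beta-binomial overdispersion it is anti-conservative. The type-I
  guarantee (≤ 0.06 at α = 0.05) holds for binomial counts.
* Pooling replicates discards between-replicate variance; the package
  deliberately implements the published pooled design rather than a
  beta-binomial regression caller.
* Adjacent significant windows are separate DMRs by default (window-level
  reporting); `merge_adjacent_dmrs()` is a post-process whose merged P is
  a summary (the minimum), not a re-test.
* The window geometry of the original analysis is unpublished; 1-kb
  non-overlapping tiles are a common default, and both size and step are
  configurable.
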