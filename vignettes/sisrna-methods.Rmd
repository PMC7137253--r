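---
title: "Methods: classifying and characterizing stable intronic sequence RNAs"
author: "sisprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and characterizing stable intronic sequence RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spliced introns are mostly degraded within minutes, but in some systems —
most prominently the *Xenopus tropicalis* oocyte nucleus (germinal vesicle,
GV) — intron fragments persist for days as **stable intronic sequence RNAs
(sisRNAs)**. Operationally, a sisRNA here is an RNA-seq peak that lies
entirely inside an intron, overlaps no exon of any annotated gene, and is at
least 150 bp long (the length floor excludes miRNA/siRNA/piRNA-sized
contaminants). `sisprofiler` implements that classification and the
downstream genome-wide characterization: distribution over genes and
introns, sequence composition, positional density along transcripts, motif
enrichment, and conservation metaprofiles. A seeded synthetic-genome
generator with planted ground truth makes every stage testable.

# Classification model

A peak is accepted per (host gene, intron) pair when

1. the peak interval is fully contained in the intron,
2. the peak overlaps no exon of **any** gene in the reference set, and
3. peak length ≥ `min_length` (default 150 bp, inclusive).

Two points were genuinely open and are decided as follows. First, the exon
veto uses exons of all genes, not only the host: overlapping genes exist and
an unqualified "does not overlap an exon" is only safe genome-wide. Second,
a peak contained in introns of two overlapping genes is counted once per
host gene (`multi_gene_policy = "per_gene"`); this matches published totals
in which per-gene sisRNA counts exceed unique peak counts. A
`"unique_only"` policy is available. The 150 bp threshold is inclusive: the
rule is a cut-off *at* 150, and the minimum observed length in real data is
a property of the data, not of the rule.

Gene models are reduced to one exon chain per `gene_id`: exons of all
isoforms are unioned and introns are the gaps of the union. A gene then has
a single intron set, matching how published per-gene intron counts are
tabulated. Genes without introns are kept in gene lists but excluded from
every ratio denominator. Internally all coordinates are 1-based closed
(`GRanges` convention — the one-convention-everywhere rule that avoids ±1
drift in R); genePred, BED and bedGraph inputs are shifted on read and back
on write.

# Distribution statistics

`group_by_intron_count()` groups intron-containing genes into intron-count
classes 1–9 and a pooled "≥10" class. Within each row,
`pct = 100 · n_genes_with_sisrna / n_genes`,
`sisrnas_per_gene = n_sisrnas / n_genes` (all genes of the group, not only
sisRNA-positive ones — verified against published ratios), and
`sisrnas_per_intron = n_sisrnas / n_total_introns`. The Total row prints
the full gene count but divides by intron-containing genes only.

All correlations are Pearson product-moment coefficients; the precision of
published values (e.g. R = −0.1724 for peak signal versus host-gene FPKM)
indicates a product-moment statistic, and `correlate()` refuses degenerate
input (< 3 pairs or zero variance). The signal column of the peak file is
used as provided; whether it is a summit height or an area is metadata of
the upstream peak caller, not of this package.

The package ships the raw printed cells of the published GV summary tables
(`published_gv_summaries()`). Only raw counts are stored; every derived
cell is recomputed, which turns the published tables into a desk-scale
oracle for the summary arithmetic.

# Composition statistics

GC fraction, CpG density and CA|TG density are computed pooled over a
region set (`composition_profile()`) or per region
(`per_region_composition()`, the distribution behind boxplot-style
comparisons). Dinucleotide occurrences are counted at every offset within a
region (overlapping counts; windows spanning region boundaries are not
counted), on the + strand only — every reported metric is
reverse-complement symmetric after class collapsing, which the test suite
asserts. Densities are per 100 bases; N bases are excluded from all
denominators, and any k-mer window containing N is skipped in both
numerator and offset denominator.

k-mer observed/expected ratios collapse each word with its reverse
complement (10 dinucleotide classes, 32 trinucleotide classes). The
expectation is genuinely underdetermined by the source material, so both
candidates are implemented: the default background is the genome-wide class
frequency (O/E = relative prevalence versus the genome, consistent with the
motif-enrichment expectation below; the whole genome then has O/E ≡ 1,
asserted exactly in tests), and a mononucleotide-product
("CpG-island-style") expectation is available via
`background = "mononucleotide"`. Outputs record which was used.

# Density along joined intron transcripts

For each gene the introns are concatenated 5'→3' in transcription order
(for minus-strand genes joined position 1 is the rightmost intron base).
The joined axis of length $L$ is split into 100 bins by integer partition —
bin $b$ covers joined positions $\lfloor (b-1)L/100 \rfloor + 1$ to
$\lfloor bL/100 \rfloor$, so bins tile exactly and differ by at most one
base. Per bin, the density is the fraction of its positions covered by at
least one sisRNA of that gene:
$\mathrm{Den}_b = \sum_i x_i / L_b$ with $x_i$ the 0/1 coverage indicator.
The aggregate profile is the **unweighted** mean of per-gene profiles (each
gene counts equally regardless of intron content). Genes whose joined
transcript is shorter than the bin count are excluded (their bins would be
empty) and their number is reported. An exact conservation identity —
$\sum_b \mathrm{Den}_b \cdot L_b$ equals the number of covered joined
positions — is asserted for every profile the tests build.

# Motif enrichment

Enrichment of a motif in a region set is
$E = \mathrm{OCC}_{obs} / \mathrm{OCC}_{exp}$ with
$\mathrm{OCC}_{exp} = N \cdot L_r / L_g$: $N$ genome-wide occurrences,
region size $L_r$ (after merging overlaps), genome size $L_g$. An
occurrence counts as observed if it intersects the region set by ≥ 1 bp,
and at most once however many regions it touches. Setting the region set to
the whole genome forces $E = 1$ exactly, a test identity.

Occurrences come from a direct log-odds PWM scan rather than from MAST.
This is the package's one deliberate methodological substitution: the
enrichment formula consumes occurrence positions, and a transparent scanner
with an explicit per-window p-value is both sufficient and reproducible.
TRANSFAC-format count matrices are normalized with a pseudocount of 1% of
the column total (no −∞ log-odds); the background is the genome
mononucleotide frequency. Log-odds scores are discretized to a 0.01-bit
per-column grid; the exact distribution of the gridded window score under
the background is obtained by convolution across motif positions, and the
reported threshold is the smallest achievable score whose tail probability
is ≤ `p_site` (default 1e-4). Scanning scores windows on the same grid, so
the p-value bound is exact rather than approximate. Both strands are
scanned; windows containing N are skipped; palindromic double-hits at one
interval are deduplicated to a single occurrence, while overlapping
same-strand hits at different offsets are kept — the occurrence list is
positional.

One practical consequence, visible in the tests: at `p_site = 1e-4` the
scanner tolerates of order one false hit per 10⁴ windows by construction,
so "recover exactly the planted sites" demonstrations use backgrounds small
enough that windows × p_site ≪ 1; and a 6-mer consensus cannot pass a 1e-4
bound against a uniform background at all (its exact-match probability is
4⁻⁶ ≈ 2.4·10⁻⁴), which is why the planted-recovery fixtures use a 10-mer
or a GC-rich 6-mer against an AT-rich background.

# Conservation metaprofiles

`anchor_profile()` averages per-base conservation scores (phastCons-style,
in [0, 1]) in ±150 bp windows anchored at the 5' end, midpoint, or 3' end
of each interval. Anchors are strand-aware and offsets run 5'→3', so
reversing every interval's strand exactly reverses the profile. Windows
deliberately extend beyond interval boundaries — the exon–intron boundary
signal lives there. Missing track values and positions beyond scaffold ends
reduce the per-offset count but never enter the mean (zero is a valid
conservation score, so missing ≠ 0). The midpoint of an even-length
interval is the left-of-center base, a deterministic tie-break.
`boundary_contrast()` summarizes an intron-anchored profile as mean
exon-side score minus mean intron-side score, excluding the boundary base
itself. Scores outside [0, 1] in dirty input tracks are clamped with a
warning.

# The synthetic-data generator

`simulate_bundle(sim_config(seed))` emits a complete, seeded bundle —
FASTA genome, genePred gene models, BED peaks, fixedStep wiggle
conservation, TRANSFAC PWMs, FPKM table, and the planted truth. The
defaults are the study conditions the pipeline targets, fixed once:

* **Genome**: 4 × 700 kb scaffolds (2.8 Mb), i.i.d. bases at the published
  whole-genome composition (A 29.97%, C 20.04%, G 20.04%, T 29.96%).
* **Genes**: 200, packed left-to-right with 0.5–2.5 kb gaps and random
  strands; intron count geometric with mean 7.8 (the published average;
  zero-intron genes occur naturally); exon lengths log-normal
  (median 250 bp, floor 160 bp so every ±150 bp boundary window has clean
  exon context); intron lengths log-normal (median 700 bp, floor 180 bp so
  a minimum-length sisRNA fits with 1 bp clearance).
* **sisRNAs**: 0.36 per intron on average (the published per-intron rate),
  with per-intron rates proportional to intron length (longer introns host
  more sisRNAs, reproducing the published length correlation) and
  multiplied by 2 for first and 3 for last introns (both-ends enrichment
  with 3' preference). Lengths are log-normal with median 330 bp
  (realized mean ≈ 360 bp), floored at 150 bp, truncated to the intron, and
  placed uniformly without overlap.
* **Composition bias**: planted regions are resampled from a GC-shifted
  base model and then a fraction (default 0.5) of their CG dinucleotides is
  rewritten to TG or CA — the deamination path that makes real sisRNAs CpG
  poor and TG/CA rich. The pre-rewrite GC level solves
  $x - r(x/2)^2 = \mathrm{GC}_{bg} + \Delta$ so the configured ΔGC
  (default +1.85 percentage points, the published sisRNA−genome gap)
  survives the rewrite. Realized deltas are recorded in the truth object.
* **Motif**: a sharp 8-mer PWM; sites planted at 1.5·10⁻⁴ per bp outside
  sisRNAs and `motif_fold` (default 2) times that inside, plus a control
  PWM never planted. Measured E is diluted toward 1 by chance scanner hits,
  which the recovery band (±50%) accommodates.
* **Decoys**: exon-crossing peaks (40% of the planted count), fully
  intronic sub-150 bp peaks (15%), and intergenic peaks (60%) — each
  violating exactly one classification rule, so the true-peak fraction
  (~47%) resembles the published ratio of accepted sisRNAs to raw peaks.
* **Conservation**: exons at 0.8, introns and intergenic at 0.25, a 10 bp
  linear ramp inside each intron end, Gaussian noise (SD 0.05) clamped to
  [0, 1], rounded to 3 decimals.
* **Expression coupling**: gene FPKM log-normal; planted peak signal
  ∝ FPKM^(−0.3) with log-normal noise, giving the negative signal–FPKM
  correlation reported for real data.

What the generator does **not** emulate: splice-site and branch-point
sequence, isoform structure (one transcript per gene), overlapping genes,
GC isochores or any large-scale composition heterogeneity, read-level noise
(peaks are intervals, not pileups), and alignment-derived conservation
(the track is a geometric caricature with the right anchored structure).
Passing tests therefore demonstrate that the *operations* are correct and
that planted effects of realistic size are recovered — not that the
biological conclusions would survive real-data artifacts such as mappability
gaps or annotation errors.

# Problem sizes and numerical choices

The test suite runs classification oracles on 20 random 10-gene/300-peak
instances, recovery checks on 20–120-gene genomes (0.4–1.6 Mb), and the
full pipeline plus the acceptance script on the default 200-gene / 2.8 Mb
configuration — sizes chosen so the whole suite completes in a few minutes
on a single core while keeping ≥ 100 kb of planted sequence (composition
deltas to ±0.01) and ≥ 200 planted motif sites (enrichment to ±50%).
Score-grid granularity is 0.01 bits; conservation scores are compared
exactly where the construction is exact (constant tracks, coverage
identities) and to 10% where sampling noise enters. Ties: even-length
medians average the two central values; even-length midpoints take the
left-of-center base; bin boundaries use floor partition.

# Known limitations

* The MAST→direct-scan substitution means motif occurrence lists are not
  bit-compatible with the original tool chain; enrichment values are
  validated against planted truth only.
* `per_gene` multi-host counting can double-count a peak's bases in pooled
  composition when genes overlap; `unique_sisrnas()` collapses to unique
  intervals before any length or composition pooling.
* The O/E background choice changes absolute ratios (not orderings); both
  definitions are exposed and labelled.
* Conservation profiles average whatever intervals they are given; the
  choice of "all introns" versus "sisRNA-free introns" is the caller's.
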