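---
title: "Methods: binwise DMR calling, heterochromatin occupancy, and ITC isotherm fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binwise DMR calling, heterochromatin occupancy, and ITC isotherm fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetkit)
```

# Scope

`hetkit` implements the downstream computational analyses used in studies of
plant heterochromatin readers: calling differentially methylated regions
(DMRs) from whole-genome bisulfite counts, relating region sets (DMRs, ChIP
peaks, transposable elements) to each other and to chromosome geography,
profiling coverage tracks over scaled features, and fitting isothermal
titration calorimetry (ITC) binding isotherms. Read alignment, peak calling
and differential expression are upstream of this package: its inputs are
per-cytosine count tables, BED intervals and bedGraph tracks.

# The DMR model

The genome is tiled into 100-bp bins. For one cytosine context
(CG, CHG or CHH) and one bin, all read observations are pooled into a
2x2 table of methylated versus unmethylated read counts for the two
samples, and a two-sided Fisher exact test is applied. Writing $m_A, t_A$
for the methylated and total read counts of the reference sample in the
bin (and $m_B, t_B$ for the mutant), the bin's methylation difference is
$\Delta = m_B/t_B - m_A/t_A$. Across all *tested* bins of a context the
Fisher p-values receive a Benjamini–Hochberg adjustment
($q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$), and a bin is a DMR when

* $q \le 0.01$, and
* $|\Delta| \ge 0.4$ (CG), $0.2$ (CHG) or $0.1$ (CHH).

A bin is *tested* only if both samples have at least 4 cytosines of the
context covered by at least 4 reads in the bin. Three deliberate reading
choices, each exposed in the audit table so they can be revisited:

* **Coverage filter filters bins, not reads.** An under-covered cytosine
  still contributes its reads to the pooled counts; it only fails to count
  toward the 4-cytosine eligibility tally. The filter exists to remove
  bins with too few informative cytosines, not to censor observations.
* **Pooled read counts, not binary cytosine calls.** The 2x2 table uses
  read counts summed over the bin's cytosines (the weighted bin level
  $m/t$), which keeps low-coverage cytosines from dominating.
* **Two-sided test, direction post hoc.** Hypo- and hyper-DMRs are both
  reported, so the test is two-sided (point-probability rule, identical to
  `stats::fisher.test`) and the direction is the sign of $\Delta$.
  BH is applied per context over all tested bins genome-wide.

Bins where either sample has zero pooled reads have an undefined level and
are excluded before testing. DMR counts are reported at bin level;
`merge_adjacent()` provides merged regions as a secondary output with the
delta recomputed from pooled counts.

# Region and profile analyses

**Overlap statistics** count elements of one set sharing at least 1 bp
with the other (on a common 100-bp grid this equals bin identity).
Percentages are reported at full precision alongside two integer displays:
nearest integer and truncated. The truncated form matches the field's
"91% (11 of 12)" reporting style (11/12 = 91.7%).

**Bound TEs** are those with *strictly more than* 80% of their length
covered by the union of peaks; a TE at exactly 80% is not bound.

**Shuffled nulls** reproduce `bedtools shuffle` semantics: each control
set carries the identical multiset of region lengths; a chromosome is
chosen proportional to its length and a start uniformly among positions
that keep the region inside it. Control regions may overlap one another
(the shuffle semantics without an exclusion file); a no-self-overlap mode
and exclusion zones are available via rejection sampling. Mark association
at peaks is `log2(mean over peaks / mean over controls)` with the control
mean averaged over (by default three) sets; the ratio cancels per-million
scaling.

**Metaplots** use scale-regions semantics: fixed 2-kb flanks split into
fixed-width bins, bodies rescaled to a fixed bin count by exact
fractional-overlap weighting. Features shorter than the body bin count are
stretched, not dropped, so short TEs stay in their length class.
Minus-strand features are reversed before binning. Positions not covered
by any track interval are missing, and missing values are excluded from
the mean's denominator. Methylation metaplots pool reads per positional
bin across features (weighted); an unweighted per-feature average is
available with `weighted = FALSE`. Genomic-context composition assigns a
region to TE / gene / intergenic by majority bp with ties broken toward
TE, a deterministic rule consistent with TE-centric reporting; bp inside
both a TE and a gene count as TE.

**TE-family enrichment** is a reconstruction (the choice of statistic is
not standard across studies): fold = family bp share among DMR-overlapped
TE bp over family bp share among all TE bp, with a hypergeometric count
test as a screening p-value.

# The ITC model

The single-site-class (n identical independent sites) isotherm: after
injection $i$ the perfusion-diluted cell concentrations are
$[M]_i = M_0 \frac{1 - d_i/2V_0}{1 + d_i/2V_0}$ and
$[X]_i = X_0 \frac{d_i/V_0}{1 + d_i/2V_0}$ with $d_i$ the cumulative
injected volume. Bound-site concentration solves the binding quadratic
with site concentration $S = N[M]$, the cell heat content is
$Q_i = [MX]_i V_0 \Delta H$, and the measured injection heat corrects for
the displaced half-injection:
$\delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$.

Defaults (cell 100 uM, syringe 1200 uM, $V_0$ = 0.2 mL, 19 x 2 uL
injections) reflect the quoted experimental concentrations and standard
instrument geometry; they are configuration, not ground truth. The fit
minimizes squared residuals in heat-per-mole-of-injectant units
(kcal/mol, the convention of instrument software) over
$(\log K_d, \Delta H, \log N)$ from a deterministic multi-start grid with
BFGS/Nelder-Mead polishing; all-zero heats are rejected explicitly ("no
binding detected") and a Wiseman c-value ($N M_0 / K_d$) outside
[1, 1000] is flagged rather than silently fitted.

Two numerical facts worth knowing:

* A protein with $n$ identical independent cassettes is algebraically
  identical to a one-site system at $n$-fold site concentration; the test
  suite uses this as the oracle for the multivalent scenario, and it is
  why a single-site-class fit to a trivalent reader recovers $N \approx 3$.
* Under the perfusion convention, expelled unbound macromolecule makes the
  literal sum of heats fall short of $N M_0 V_0 \Delta H$ when the
  injected volume is a sizeable fraction of $V_0$ (about 4% short at
  80 uL into 200 uL). Heat conservation is therefore verified on a
  saturating low-overflow schedule (concentrated syringe, 10 uL total),
  where it holds to about 0.1%.

# What the synthetic data emulates — and what it does not

The generator states one world and the tests live in it; its defaults are
not tuned to outcomes.

* **Genome**: two 1-Mb chromosomes (desk-scale; correctness of the
  statistics does not depend on genome size), each with a pericentromeric
  zone defined as the central third. TEs are placed without overlap;
  long TEs (> 4 kb, drawn 4.5–12 kb) go pericentromeric with probability
  0.85, short TEs (log-normal around 800 bp) with 0.4, and genes sit
  mostly on the arms. Gypsy/Copia/En-Spm labels dominate the long class.
* **Methylome**: cytosine positions are uniform at configured densities
  (CG/CHG/CHH = 6/6/10 per 100 bp) rather than sequence-derived — the DMR
  caller consumes counts, not sequence. Heterochromatin baselines
  CG/CHG/CHH = 0.85/0.70/0.20, arms 0.10/0.05/0.03, chosen as typical
  plant pericentromere versus euchromatin levels. Coverage is
  Poisson(20), methylated counts Binomial. The mutant loses CHG 0.5 and
  CHH 0.15 inside planted regions (long TEs by default) with CG
  untouched, emulating a non-CG-specific silencing defect. One methylome
  per genotype (single-replicate design). CG strands are simulated
  independently (per-cytosine report convention; no symmetric-pair
  coupling).
* **ChIP**: per-window expected rates (heterochromatin 8, arms 1)
  with log-normal multiplicative noise standing in for read-count
  overdispersion; the reader track is a scalar multiple of the H3K9me2
  track times noise, so the noiseless limit has correlation exactly 1;
  H3 gets a mild (+30%) elevation over the target. Peaks are merged
  windows at least half-covered by the target mask.
* **Isotherms**: forward-model heats plus Gaussian noise scaled to the
  largest heat; ground-truth parameters ride along as an attribute.

Not emulated: sequence composition, bisulfite conversion error, read-level
simulation, replicate structure, truncated-vs-intact TE classification.
A green test therefore establishes that the statistics recover a planted
signal of the stated size under idealized noise — not that the pipeline is
robust to alignment artifacts or conversion bias.

All randomness flows from one integer seed through fixed named
sub-streams (genome layout, cytosine map, per-genotype counts, ChIP,
isotherm, shuffling), so wild-type and mutant share a cytosine map while
their read draws stay independent, and identical seeds give byte-identical
output files.

# Numerical choices and degenerate inputs

* Fisher p-values follow the point-probability two-sided rule with the
  same $1 + 10^{-7}$ inclusion tolerance as `stats::fisher.test`; the
  test suite verifies exact agreement with direct hypergeometric
  enumeration for all tables with margins up to 30.
* A cytosine at 1-based position $p$ belongs to the bin containing
  0-based $p-1$: position 100 falls in bin [0,100), 101 in [100,200).
* Empty bins, bins with zero totals, regions without covered cytosines
  and windows without track coverage are missing, never zero.
* `shuffle_regions` rejects a region longer than every chromosome;
  placement failure after the retry cap is an error, not a silent drop.
* The fitter's multi-start grid is fixed (Kd in 0.1–100 uM, N in 0.5–5,
  dH from the observed total heat), making fits reproducible without a
  random seed.

# Worked example

```{r example, eval = FALSE}
g   <- generate_genome(genome_spec(seed = 101))
m   <- methylome_model()
wt  <- simulate_methylome(g, m, "wildtype", seed = 101)
mut <- simulate_methylome(g, m, "mutant",   seed = 101)
bins <- make_bins(g$chrom_sizes)
res <- call_dmrs(aggregate_bins(wt, bins, "CHG"),
                 aggregate_bins(mut, bins, "CHG"), "CHG")
table(res$dmrs$direction)
```

The README shows this example with the numbers it prints; the acceptance
script (`scripts/acceptance.R`) recomputes the two headline quantities
(stoichiometry recovery and the Kd round trip) from scratch at run time.

# Known limitations

* The DMR caller is the binwise Fisher recipe only: no smoothing, no HMM
  segmentation, no replicate-aware dispersion model.
* Bound-TE classification and family enrichment are sensitive to the peak
  caller upstream; this package treats peaks as given.
* The ITC module fits the single-site-class model only; cooperative or
  sequential multi-site models, and baseline integration from raw power
  traces, are out of scope.
* The fit's standard errors are asymptotic (numerical Hessian); for
  noiseless round trips they are effectively zero and for c > 1000 the
  Kd is weakly identified, which the c-value flag reports.
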