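---
title: "Methods: comparative phosphosite density and mammalian lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative phosphosite density and mammalian lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosevol)
```

## The question and the model

Long-lived mammals appear to carry more predicted phosphorylation sites in
the intrinsically disordered C-terminal tail of SIRT6 than short-lived ones.
`phosevol` implements the comparative machinery needed to test that kind of
claim for any protein family: predicted-site counting, cross-species
coordinate mapping, and regression of species maximum lifespan on sequence
features under phylogenetic correction.

Phosphosites are predicted by the minimal proline-directed motif: a serine
or threonine immediately followed by proline (`[ST]P`), the core recognition
pattern of CMGC-family kinases. This is deliberately the crudest defensible
predictor — no machine-learned scoring, no kinase-specific position weight
matrices — because the comparative signal of interest is a count, and a
transparent counting rule keeps it interpretable. A `-1`-proline variant
(`scan_phosphosites(..., minus1_proline = TRUE)`) exists for sensitivity
analysis but is off by default: counting uses strictly `[ST]P`.

Species trait values are not independent draws: close relatives resemble
each other. The central model is therefore phylogenetic generalized least
squares (PGLS). For log10 maximum lifespan $y$ and a feature vector $x$,

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}(0, \sigma^2 C), $$

where $C_{ij}$ is the shared root-to-MRCA path length of species $i$ and
$j$ — the expected trait covariance under Brownian motion on the phylogeny.
The estimator is closed-form GLS,
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$, with
$\hat\sigma^2 = (y-X\hat\beta)^\top C^{-1}(y-X\hat\beta)/(n-p)$, standard
errors from $\hat\sigma^2\,\mathrm{diag}[(X^\top C^{-1}X)^{-1}]$, and
two-sided p-values from the $t_{n-p}$ distribution. `pgls()` implements this
by whitening through the Cholesky factor of $C$ (no explicit inverse);
`ols()` is the identical machinery with $C = I$, the uncorrected baseline.
The covariance is the plain Brownian one: no Pagel's $\lambda$ or
Ornstein–Uhlenbeck parameter is estimated, matching the "default Brownian
model" convention of comparative analyses, and inference is the standard
closed-form t test rather than likelihood-ratio machinery.

Each sequence feature is screened **separately** against lifespan
(`lifespan_screen()`), not in a joint model; a joint fit is available via
`joint = TRUE` but is not the default, because the features are strongly
inter-correlated (site density, proline fraction and charge all describe the
same tail) and the scientific claim is per-feature. Boolean features (the
acceptor-presence flag) are encoded 0/1 and fitted with the same PGLS — a
pragmatic choice over phylogenetic logistic regression that mirrors how such
binary comparisons are usually reported.

## Coordinates, the C-terminal boundary, and conservation

All residue positions are 1-based. Cross-species positions are compared
through an alignment: `build_column_map()` maps reference residue $k$ to the
column holding the reference's $k$-th non-gap character, and
`project_cterm_boundary()` places the domain boundary in every species as
1 + (number of its residues strictly before the boundary column). A species
aligned entirely with gaps beyond the boundary gets a zero-length domain; it
is flagged and excluded from regression rather than given an undefined
density.

The boundary itself is a required, always-logged parameter with default
reference residue **290** of the human sequence. The conserved region of the
protein extends to roughly position 298, and the one C-terminal
phosphoacceptor inside that conserved region sits at 294; a 290 boundary
keeps that acceptor inside the scored C-terminal domain while starting the
domain where conservation is still unambiguous. Because the sources report
the region, not a number, the boundary is surfaced in every manifest so no
run can silently depend on it.

Conservation (`conservation_profile()`) is strict identity: per column, the
count of the modal non-gap residue divided by the number of rows. Gaps are
never the modal residue but do count in the denominator, so ragged
C-terminal columns score low — the strictest reading of "absolute
conservation, no credit for chemical similarity". Whether gap-heavy columns
should instead be trimmed before scoring is genuinely open; profiles over a
trimmed block can be had by subsetting the alignment first.

The acceptor flag (`has_phosphoacceptor_at_ref()`) accepts S or T at the
mapped column by default — the counted motif is `[ST]P`, so a serine
substitution preserves the phosphoacceptor property — with `accept = "T"`
available for the strict threonine-only reading. Net charge uses the
simplest convention: K, R = +1; D, E = −1; histidine and termini ignored.
`X` residues count toward lengths, never toward tallies. Charge and
composition fractions are computed over the C-terminal domain by default
(the region of interest), with `region = "full"` available.

## MS relative phosphopeptide abundance

`read_quant_table()` ingests modified-peptide quantification tables (a
generic canonical dialect, or the documented subset of FragPipe-style
`combined_modified_peptide.tsv` columns). Two filters precede any ratio:
protein probability strictly above 0.95 ("above" is read as exclusive), and
site-localization probability at least 0.80 for modified records ("at
least" is read as inclusive). The filters are idempotent and their removal
counts are reported.

The relative abundance of a site is the summed MS1 intensity of its
phosphopeptide divided by the summed intensity of the *same* peptide without
the phosphorylation — same sequence and same fixed modifications (e.g.
cysteine alkylation), summed over charge states. When the unmodified peptide
was undetected the ratio is flagged `UNDEF` rather than infinite, preserving
the distinction between "site fully occupied" and "ratio undefined".
Peptides carrying two phosphosites are excluded from single-site ratios by
default (`include_multi = TRUE` assigns them to each constituent site); the
right treatment is genuinely ambiguous and the default is the conservative
one.

## What the synthetic generator emulates

Real inputs for the lifespan analysis are a downloaded ortholog set, a
lifespan database and a published phylogeny. So that every stage can run and
be tested offline, `simulate_study()` generates inputs with the statistical
structure the analysis assumes:

* **Tree** — a pure-birth (Yule) tree, `birth_rate = 1`: with $k$ lineages
  the next split waits $\mathrm{Exp}(\lambda k)$; after the $n$-th lineage
  one final $\mathrm{Exp}(\lambda n)$ interval elapses, giving expected
  depth $\sum_{k=2}^{n} 1/(\lambda k)$ — the closed form the tests check.
  Yule rather than birth–death because it is the simplest process with a
  testable depth expectation.
* **Lifespans** — Brownian motion of log10 lifespan along the tree
  (simulated directly on the log10 scale, the analysis scale; years are
  back-transformed only for the output table), root 1.2 log10 years
  (a 16-year ancestor), rate `sigma2 = 0.12`.
* **Sequences** — a conserved core of 298 residues shared by all species,
  containing no `[ST]P` except an optional acceptor analog at position 294
  (always followed by proline, so presence = motif) whose probability is
  logistic in log10 lifespan; then a 120-residue C-terminal segment with
  $K \sim \mathrm{Poisson}(\texttt{baseline} + \texttt{effect}\cdot
  \log_{10}\text{lifespan})$ planted `SP`/`TP` dimers. Dimers occupy
  non-overlapping slots and the filler alphabet contains no P, S or T, so
  the planted count is *exactly* what a scan recovers — the bookkeeping
  identity the tests assert. Per-species expectations saturate at the
  segment's dimer capacity (`cterm_length/2`); a configuration infeasible
  on average is an error.
* **MS tables** — per site, a log-normal unmodified intensity, modified =
  true ratio × unmodified × mean-1 log-normal noise (`ms_noise_cv = 0.2`),
  each intensity independently zeroed with `ms_missing_rate = 0.1`, plus
  optional planted low-confidence decoy rows to exercise the filters.

Everything is reproducible: a fixed seed yields byte-identical output files.

**Choice of the default effect size.** The defaults are the conditions under
which the pipeline's operating characteristics are stated: type-I error of
PGLS at $\alpha = 0.05$ within $0.05 \pm 0.015$, and power $\ge 0.90$ for a
positive site-density slope at $n = 128$ species. `site_effect = 12`
additional expected sites per log10 year over a 120-residue segment is a
site-density slope of 0.1 per log10 year — the upper end of what the
observed short- versus long-lived contrast (roughly 0.04 to 0.09 density
over one log10 year of lifespan) would suggest. It sits there deliberately:
integer site counts carry Poisson noise that is independent across species,
and after phylogenetic whitening that noise is up-weighted for species on
short terminal branches, so smaller (entirely realistic) effects are simply
not detectable at this panel size with 90% power. Likewise `sigma2 = 0.12`
spreads tip lifespans (SD ≈ 0.7 log10 years) somewhat more broadly than a
real mammal panel. Passing the power criterion under these conditions shows
the pipeline finds a planted signal of the stated size; it does *not* show
that a real panel of 128 species would yield significance for a weaker true
effect.

What the generator does **not** emulate: substitution/indel evolution of the
sequences (cores are identical, tails are noise around planted dimers, the
true alignment is gap-free), correlated evolution of charge or composition
with lifespan, chromatographic or spectral structure in the MS tables, and
name mismatches between sources (exercised instead by dedicated fixtures).
Passing tests on synthetic data therefore validate the statistical and
bookkeeping machinery, not the biology of any particular protein.

## The packaged ortholog panel

`inst/extdata/synthetic_sirt6_orthologs*.fasta` is a constructed stand-in
panel, not downloaded sequences (the `synthetic_` prefix marks this). Its
analogs carry the documented site architecture of the SIRT6 comparison: the
human analog has the near-invariant N-terminal site, the acceptor at 294,
and C-terminal motifs such that the default boundary yields **6** predicted
C-terminal sites; the guinea-pig analog yields **2**, the bowhead-whale
analog **6**; the acceptor analog is present in the primate and cetacean
analogs and absent in rodents. One reported subtlety is encoded on purpose:
seven C-terminal phosphosites are observed for human by MS, yet the strict
`[ST]P` scan counts six. Two of the observed sites are adjacent residues,
and adjacent acceptors cannot both be followed by proline — so the analog
places a threonine at 337 followed by the serine-proline at 338, an
MS-observable acceptor that the strict motif scan rightly does not count.
The accompanying tree is ultrametric with roughly divergence-time-scaled
branch lengths, and the lifespan table carries database-style maximum
lifespans for the eight species.

## Numerical choices and degenerate inputs

* $C$ is factored by Cholesky; if factorization fails, a ridge of
  $10^{-8}\times\overline{\mathrm{diag}(C)}$ is added once, with a message.
  A rank-deficient design fails loudly, naming the aliased predictors.
* Pruning a tree to the species intersection preserves root-to-MRCA path
  lengths exactly: the path collapsed at the root is retained as a root
  edge and added to every covariance entry (shared ancestry of all
  retained taxa).
* Species names are matched after case-folding and space/underscore
  normalization; everything dropped is logged and recorded in the manifest.
* Zero-length branches are allowed with a warning; negative or missing
  branch lengths are errors.
* An empty C-terminal domain yields zero counts and undefined density; the
  species is flagged and excluded from regression.
* p-values use $t_{n-p}$; with $n \le p$ the fit refuses rather than
  returning pseudo-inference.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to keep the whole suite in
minutes while leaving Monte-Carlo error well below the asserted margins:
2000 Brownian-null replicates on a fixed 64-leaf Yule tree for type-I
calibration (MC SE ≈ 0.005 against a ±0.015 band), 500 replicates for slope
recovery, 200 end-to-end replicates at 128 species for power and for null
calibration, and single 150-species panels for the headline two-predictor
screen. The motif-scan and column-map oracles run over ~1000 random
sequences/alignments each.

## Known limitations

* PGLS here is fixed-covariance Brownian GLS: no $\lambda$/OU estimation,
  no measurement-error model for the predictor. Poisson noise in site
  counts attenuates slopes; the power statement above quantifies the
  consequence.
* The binary acceptor flag is fitted by PGLS, not phylogenetic logistic
  regression; p-values for very unbalanced flags should be read with care.
* Conservation scoring is strict identity over all rows, including
  gap-heavy columns.
* The FragPipe dialect covers the documented column subset, not every
  FragPipe export variant; the generic dialect is the stable interface.
* Real-data reproduction (NCBI orthologs, lifespan databases, a published
  mammal tree) is supported by the same functions but is not packaged:
  those inputs require downloads, and no fetched copy ships here.
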