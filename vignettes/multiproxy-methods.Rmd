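---
title: "Multi-proxy authentication of ancient skeletal remains: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-proxy authentication of ancient skeletal remains: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoproof)
library(dplyr)
```

Museum collections contain skeletal material whose taxonomic and
chronological attribution rests on decades-old excavation records and
morphology alone. `paleoproof` implements the molecular toolkit used to
re-evaluate such material with several independent lines of evidence:
ancient-DNA authentication by cytosine-deamination profiling, mitochondrial
lineage assignment from branch-diagnostic positions, collagen preservation
screening, radiocarbon calibration, and collagen peptide mass
fingerprinting (ZooMS). Each proxy is usable on its own; a pipeline merges
their verdicts per specimen and flags disagreements rather than reconciling
them.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The synthetic study system

Real re-analyses of this kind start from deep-sequenced single-stranded
libraries; at package scale we work instead on a fully synthetic study
system with known ground truth.

`generate_panel()` builds an aligned set of mitochondrial genomes for four
lineages — modern human, Neanderthal, the Denisovan/Sima de los Huesos
clade, and a chimpanzee-like outgroup — on a circular reference of
configurable length (default 1,000 bp; real mtDNA is ~16.6 kb, but nothing
in the methods depends on the scale). A requested number of columns per
branch is made diagnostic: the branch carries a derived allele, all other
genomes and the outgroup share the ancestral one. Optionally, extra
columns differ between Neanderthal and modern human only; at those columns
the other groups are given a third allele so that the pairwise set never
overlaps the branch-diagnostic set and so that the outgroup cannot polarise
them (exercising the unpolarised-site code path; the modern-human allele
then occupies the `derived` slot by convention). Everything else is
identical across genomes, so the planted sites are the complete truth for
the site caller.

`simulate_fragments()` draws fragments from a source genome with:

* **Length**: truncated normal, mean 45 bp, sd 10, bounds 30–80 bp — a
  typical ancient-DNA insert distribution. Fragments may span the circular
  origin.
* **Damage**: the C→T probability at distance $i$ from a fragment end is
  $p(i) = p_\mathrm{base} + (p_\mathrm{max} - p_\mathrm{base})e^{-\lambda i}$,
  a standard exponential overhang approximation with few parameters
  (defaults $p_\mathrm{max} = 0.3$, $p_\mathrm{base} = 0.01$,
  $\lambda = 0.3$). In single-stranded-library mode (`both_ends = TRUE`,
  the default) C→T applies at both ends in the molecule's own orientation;
  for a position in the middle of a fragment, $i$ is the distance to the
  *nearer* end (the model defines a per-end profile; min-distance is the
  simplest single-valued combination and is exact wherever fragments are at
  least twice the profile depth, which the 30 bp minimum guarantees for the
  default depth). A double-stranded mode (5′ C→T, 3′ G→A) is provided for
  generality.
* **Contamination**: each fragment is, with the stated probability, drawn
  from a modern-human genome with the flat baseline rate — present-day DNA
  carries no terminal damage.
* **Sequencing error**: none beyond deamination. This keeps the worked
  examples analytic: with damage switched off, every emitted base equals
  the source genome base, which is what makes exact 100%/0% support
  statements testable.

What the generator does **not** emulate: indels, heteroplasmy, coverage
bias, adapter read-through, quality-score variation (all bases are Phred
37), or empirically calibrated damage parameters. Passing tests therefore
demonstrate the correctness of the statistical machinery on an idealised
library, not performance on any particular sequencing run.

## Molecule preparation

Reads are emitted as fully overlapping pairs (read length equals fragment
length), so `merge_read_pair()` reconstructs full-length molecules: among
suffix/prefix overlaps of at least `min_overlap` (default 11 bp) with
mismatch fraction at most 0.1, the overlap with fewest mismatches wins,
ties to the longer; the consensus takes the higher-quality base.
Non-overlapping pairs are discarded — only complete molecules enter the
damage and allele counts, since terminal positions are meaningful only on
complete molecules.

`align_to_circular_reference()` places each molecule by a gap-free
semi-global scan of both orientations over the doubled reference, reporting
the fewest-substitutions placement in original-circle coordinates (ties:
smallest start, then forward strand). At mtDNA scale this is exact and
deterministic, with no external aligner; gapped alignment is deliberately
out of scope, and a minimal SAM text path (`read_sam()`) lets any external
aligner be substituted. `deduplicate()` collapses fragments sharing
`(start, end, strand)` — amplification copies of one template — keeping the
copy with the highest summed base quality. Keying on placement rather than
sequence is an interpretive choice: it collapses duplicates that differ
only by deamination, which sequence-keying would keep apart.

Bases below Phred 20 are treated as uncalled and excluded from damage and
allele counts throughout.

## Damage authentication

`damage_profile()` estimates, at each distance 0–14 from either end, the
frequency with which a reference C is read as T; the denominator counts
confidently called bases over a reference C, and positions with no
observations are reported as `NA`, never as zero (zero would fabricate
evidence of absence). An interior baseline uses positions more than 15 bp
from both ends. Confidence intervals are exact binomial.

The conditional (opposite-end) filter retains molecules with a terminal
C→T at the end opposite the one being measured. Because contaminants
essentially never carry terminal damage, the filtered subset is enriched
for endogenous molecules; on a mixture the conditional terminal frequency
therefore exceeds the unconditional one, while on a pure ancient sample the
two agree (damage events at opposite ends are independent). The filter
window defaults to exactly the terminal base.

`authenticate()` calls a specimen ancient when the terminal frequency at
either end reaches `min_terminal_freq` (default 0.10 — a conventional
screening value for single-stranded libraries; "substantial" damage has no
canonical definition, so the threshold is exposed) **and** a one-sided
exact binomial test of the terminal counts against the interior baseline
rejects at `alpha = 0.01`. Undefined terminal frequencies give an
"insufficient data" verdict with the flag down.

## Lineage assignment

`branch_support()` counts, over each branch's diagnostic positions, the
observations equal to the derived or the ancestral allele (anything else is
excluded from the total), yielding the percentage of sequences supporting
the derived state — once over all molecules and once restricted to
putatively deaminated ones. Each overlapping (fragment, site) pair counts
one observation by default; a per-fragment majority mode is available for
strict sequence counting, and the two differ only when single fragments
span several sites of one branch.

One interaction deserves emphasis: at diagnostic positions whose two
alleles differ by C↔T or G↔A, deamination itself can convert a derived
base into the ancestral one (or vice versa). This bias is strongest in
exactly the subset the conditional filter selects. `branch_support()`
therefore has an `exclude_damage_prone_sites` switch that drops such
transition sites from the deamination-filtered counts. It defaults to off,
so the raw Figure-style percentages are reproducible; the end-to-end
pipeline (`run_pipeline()`) switches it on for classification, because a
handful of damage-induced miscalls can otherwise pull a true specimen below
any high support threshold.

`classify_mtdna()` labels a specimen "Modern Human" when damage evidence is
present, filtered modern-human support is ≥ 95% over at least 3 informative
observations, and Neanderthal support is ≤ 5% (symmetrically for
"Neanderthal"). When branch-specific filtered coverage is too sparse the
expanded pairwise Neanderthal-versus-modern-human site set is consulted
instead — mirroring the practice of widening the site set when the
deamination filter leaves very few informative molecules. The 95/5/3
thresholds are package choices (published analyses report raw percentages
without a formal rule) and are exposed as arguments.

```{r lineage-demo}
panel <- generate_panel(seed = 7, genome_length = 1000,
                        n_sites_per_branch = 10, n_pairwise_sites = 10)
sites <- find_diagnostic_sites(panel, "both")
frags <- simulate_fragments(panel, "modern_human", 2000,
                            damage = damage_model(0.3, 0.01),
                            contamination_fraction = 0.3, seed = 8)
support <- branch_support(frags, sites, exclude_damage_prone_sites = TRUE)
support
verdict <- authenticate_fragments(frags, specimen_id = "demo")$verdict
classify_mtdna(support, verdict)
```

## Collagen quality control and isotopes

The atomic C:N ratio is `(pC/12.011)/(pN/14.007)`; rounding happens only at
presentation. The default acceptance window is yield strictly above 1% and
C:N within 2.9–3.6 (the classic DeNiro window); a stricter 3.1–3.5 van
Klinken preset is included, and passing it implies passing the default.
Recomputing the ratio from published elemental percentages reproduces most
printed ratios exactly at one decimal; where a printed ratio was evidently
computed from unrounded measurements the recomputation can differ by up to
0.1 at the displayed precision — the residual is documented, not
"corrected". Isotope screening is configuration, not hard-coded science:
d15N ranges for dietary populations ship as an editable table
(`default_isotope_ranges()`), records below every configured human range
are flagged as more plausible for a herbivorous or omnivorous animal, and
records with identical d13C and d15N are flagged as possibly deriving from
a single individual.

## Radiocarbon calibration

`calibrate_date()` evaluates, on a calendar grid (linear interpolation of
the curve at 5-year steps), the likelihood
$\exp\!\left(-\frac{(y - \mu(t))^2}{2(\sigma^2 + \sigma_c(t)^2)}\right)$
for a determination $y \pm \sigma$ against curve mean $\mu$ and error
$\sigma_c$, normalises it, and extracts highest-posterior-density intervals
by descending-density accumulation. HPD (not central) intervals are used,
so multimodal posteriors — routine on wiggly stretches of a real curve —
return multiple ranges per level. Bounds are rounded outward to 10 years
(calendar ranges are conventionally printed in multiples of 10; outward
rounding never shrinks an interval). Single-date calibration only: no
reservoir corrections, no sequence modelling, no marine or southern
hemisphere curves.

`read_curve()` parses the standard IntCal text dialect. The package ships
no copy of any published curve; `identity_curve()` provides a synthetic
linear curve under which calibration has a closed form — the posterior is
the normal likelihood itself, so HPD endpoints must match normal quantiles
to within one grid step. That closed-form agreement, posterior
normalisation to 1e-9, and the density-optimality of the HPD set are the
verification surface for this module.

```{r cal-demo}
res <- calibrate_date(5580, 26, identity_curve(0, 10000), lab_code = "demo")
tidy(res)
```

## ZooMS classification

`match_markers()` compares a peak list against a marker panel: a marker
matches when any peak lies within ±0.2 m/z (tolerance configurable; no
published value exists for the workflow being reproduced, so a typical
external-calibration figure is used). Intensities are ignored beyond an
optional floor — identification is presence/absence. `classify_zooms()`
requires at least 2 matched markers for a candidate (configurable),
discards candidates contradicted by a discriminating marker present at
another taxon's mass, and reports a single survivor as the taxon with a
"complete" or "partial" series annotation. Several equally supported
candidates whose matched peaks coincide are reported as their ambiguity
group — e.g. a carnivore series lacking the discriminating marker A cannot
be narrowed below "Mustelidae/Pantherinae/Hyaenidae". An empty spectrum is
"No Collagen"; matched-nothing is "unidentified".

The shipped panel contains the five published hominin marker masses
(1235.6, 1477.8, 2115.1, 2832.4, 2957.5 m/z) plus *synthetic* demonstration
taxa whose masses are invented so the grouping logic can be exercised;
real analyses should supply the published marker compendium as their own
panel table.

## The specimen report

`merge_reports()` joins the per-proxy outputs on canonical specimen ids
(an alias map handles known alternate spellings of museum numbers, e.g.
"IGVR 20334" for "IGVR 203334"), renders analyses a specimen never
underwent as "Not analysed", and flags hominin-mtDNA-versus-non-hominin-
ZooMS conflicts instead of reconciling them. Duplicate conflicting rows for
an id are an error. `run_pipeline()` drives whichever stages a declarative
config requests and echoes every threshold used, so each report is
auditable and each number is reproducible by invoking the owning module
alone.

## Numerical choices and degenerate inputs

* Undefined frequencies (no observations) are `NA` end to end — plots drop
  them, tests assert them, nothing imputes 0.
* Alignment ties break deterministically (smallest start, then + strand);
  dedup ties break by id after quality.
* The posterior grid is linear at 5-year steps; HPD extraction accumulates
  whole grid points, so interval endpoints are grid points before rounding.
* Fragment simulation resamples lengths until the truncated-normal bounds
  are met, falling back to the bounds' midpoint for degenerate parameters.
* Problem sizes in the shipped tests — 1 kb references, 300–10,000
  fragments, cohorts of 9 specimens over 10 seeds — were chosen as the
  smallest scales at which the binomial tolerances (3 SE) are sharp enough
  to catch real defects.

## Known limitations

The damage model is a two-parameter exponential, not a full
overhang-length likelihood; contamination is estimated only via the
conditional-filter contrast, not as a point estimate; consensus genome
reconstruction, haplogroup calling and phylogenetic inference are out of
scope; the ZooMS module performs no raw-spectrum processing (peak picking,
deisotoping); and the calibration module is single-date only. The spelled
reference accession for the human mtDNA coordinate system is sometimes
miscited in the literature as "NC_0120920" — the canonical rCRS accession
is NC_012920; nothing here depends on the real rCRS, but users aligning to
it should use the canonical record.
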