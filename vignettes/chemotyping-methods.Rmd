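---
title: "Methods: cannabinoid chemotyping from SIM peak areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cannabinoid chemotyping from SIM peak areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemovar)
```

## The problem

*Cannabis* plants produce their cannabinoids as carboxylic acids (THCA,
CBDA, and their propyl homologs THCVA, CBDVA) which decarboxylate to the
neutral forms (THC, CBD, THCV, CBDV). Two axes of chemical variation define
a plant's chemotype: the ring system (dicyclic CBD-type vs tricyclic
THC-type, governed by the codominant B locus carrying CBDA-synthase and
THCA-synthase alleles) and the alkyl side chain (pentyl C5 vs propyl C3).
`chemovar` turns integrated LC-MS selected-ion-monitoring (SIM) peak areas
into chemotype fraction statistics, asks whether chemotype measured early in
development predicts chemotype at maturation, and categorizes plants into
chemotype classes.

The package operates downstream of peak integration: its inputs are a
calibration-standards table (analyte, nominal concentration, peak area) and
a long-format sample table of peak areas; chromatogram processing, retention
alignment and vendor formats are out of scope.

## Quantification

Each analyte's detector response is fit as a quadratic
$A = a c^2 + b c + c_0$ by least squares over six standard levels
(0.032, 0.16, 0.8, 4, 20, 100 μg/mL). A companion straight-line fit
provides the linearity diagnostic `r2_linear`; quantification itself uses
the quadratic, with the linear R² reported as QC only. The fitted response
must be strictly increasing on the calibration range (the derivative of a
quadratic is linear, so endpoint checks suffice); a non-monotone fit is
rejected rather than inverted, because inversion would be ill-posed.

Inversion solves the quadratic for the unique admissible root in
$[0, 1.1 \times c_\max]$ on the increasing branch of the parabola. The 10%
headroom tolerates areas marginally above the top standard; anything larger
raises a saturation error. Numerical edge policies:

* when $|a|$ is negligible relative to $|b|$ (below $10^{-12}$ in scaled
  units) the inversion falls back to the linear solution;
* areas at or below the fitted blank response map to concentration 0;
* concentrations below the lowest standard (the working LOQ,
  0.032 μg/mL) are retained but flagged `below_loq`, since fraction
  statistics legitimately use sub-range values (pure chemotypes can carry
  fractions well below 1%).

Concentrations in the injected (1:5 diluted) extract are multiplied by the
dilution factor; with tissue mass and solvent volume supplied (250 mg in
25 mL for dried floral tissue), weight-per-weight values in mg/g are also
reported. Duplicate extraction replicates are averaged per analyte, and
replicate repeatability is summarized per fraction statistic as the squared
Pearson correlation of the paired values — chosen over a regression R²
because it is symmetric in the two replicates, which carry no order.

## Fraction statistics

Neutral cannabinoids are expressed as acid equivalents via the
molecular-weight ratio of the acid to its neutral (the acid carries the
CO2 lost on decarboxylation):

* C3 factor: MW(C20H26O4)/MW(C19H26O2) ≈ 1.15365 (prints as 1.1536 after
  4-decimal truncation),
* C5 factor: MW(C22H30O4)/MW(C21H30O2) ≈ 1.13995 (prints as 1.1399).

Masses use the IUPAC conventional atomic weights (C 12.011, H 1.008,
O 15.999); the weight table is injectable for sensitivity checks. Internal
computation uses the full-precision ratios; the truncated constants are
available behind `printed_constants = TRUE` solely for bit-compatible
regression against published arithmetic. `truncate_decimal()` exists to
validate the truncation, which is deliberately not rounding.

With the eight fraction analytes on the acid-equivalent scale, the four
fraction statistics are percentages of their common total, e.g.

$$F_{C3} = 100\,\frac{\mathrm{THCVA}+\mathrm{CBDVA}+1.1536\,(\mathrm{THCV}+\mathrm{CBDV})}{\mathrm{total}}$$

and analogously for $F_{C5}$ (C5 analytes), $F_{dicyclic}$ (CBD-type) and
$F_{tricyclic}$ (THC-type). Because each pair partitions the same total,
$F_{C3}+F_{C5} = F_{dicyclic}+F_{tricyclic} = 100$ holds exactly by
construction, and all fractions are invariant under rescaling of the
profile. CBGA, CBG, CBN and CBC are quantified but excluded from the total,
which is defined over the eight fraction analytes only.

Log10 ratios of the fraction pairs are used for distributional displays.
Zero fractions of near-pure homozygotes would make these infinite, so
numerator and denominator are clamped to a visible floor, default 0.01%
(so a pure dicyclic plant maps to $\log_{10}(100/0.01)=4$). The floor is a
reporting device only; it never feeds back into concentrations.

B-locus zygosity is read off $F_{dicyclic}$ with the 90%/10% convention:
values ≥ 90% are dicyclic homozygotes, ≤ 10% tricyclic homozygotes, and
the interior heterozygotes; the boundary itself counts as homozygous. For
heterozygotes, the within-alkyl-class comparison divides the
dicyclic:tricyclic acid-equivalent odds inside the C5 pool by the same odds
inside the C3 pool; a zero denominator marks the plant undefined and it is
excluded from cohort means rather than floored, since this ratio is an
inferential quantity, not a display.

## Developmental stability

Stability is assessed by regressing maturation-stage fractions on
vegetative- and flowering-stage fractions with the intercept omitted. For
an origin-constrained fit the conventional statistics use the uncentered
total sum of squares:

$$\hat\beta = \frac{\sum x_i y_i}{\sum x_i^2},\qquad
R^2 = 1-\frac{SS_{res}}{\sum y_i^2},\qquad
F = \frac{(n-1)(\sum y_i^2 - SS_{res})}{SS_{res}}\ \text{on}\ (1,\,n-1)\ \text{df}.$$

This is the standard no-intercept convention (it is exactly what
`summary(lm(y ~ x + 0))` reports, and `lm` backs the implementation); note
that uncentered R² is not comparable to the centered R² of an
intercept-bearing fit and is generically large whenever x and y are both
positive. The through-origin constraint encodes the biological null that a
plant with a zero fraction early in development stays at zero.

For the outlier analysis the panel is first truncated to non-extreme
chemotypes (maturation fraction within [10, 90]%, boundaries retained;
removal uses the strict inequalities), then points are deleted stepwise:
at each step the through-origin fit is recomputed, residuals are
standardized internally ($r_i = e_i / \sqrt{SS_{res}/(n-1)}$), and the
point with the largest $|r_i|$ is removed, ties broken by plant id so
traces are reproducible. Internal standardization is the plainest reading
of "standardized residuals"; leave-one-out studentized residuals are
available behind `type = "studentized"`. Because published "explained
variance reduced by X%" figures are ambiguous between accountings, the
trace reports both the relative reduction in residual SS between baseline
and final fits and the plain change in R², and treats any comparison with
published percentages as qualitative.

## Chemometric categorization

Plants are clustered on their raw three-stage fraction vectors
(vegetative, flowering, maturation, in %). No standardization is applied:
all three axes share units and scale, and scaling would distort the
premise that genotype is constant while stages add noise. Euclidean
k-means is delegated to `stats::kmeans()` with 50 random restarts under a
fixed seed (restart-based seeding with this many starts is the established
equivalent of more elaborate seeding schemes at these problem sizes, and
the tiny-instance tests verify global optimality against exhaustive
partition enumeration). The criterion curve records the best total
within-cluster sum of squares (WSS) for k = 1..k_max and is made monotone
by carrying solutions forward.

The elbow is formalized as the k maximizing the second difference of
log WSS — equivalently, the k whose preceding WSS drop is largest relative
to the following one. The log scale makes the rule scale-free: on the
curve (1000, 400, 100, 90, 85) it selects k = 3, where a raw second
difference would select k = 2 purely because the first drop is numerically
huge. A curve with no pronounced bend (maximum log-curvature below 0.05)
is flagged low-confidence, and the degenerate linear curve falls to k = 2.
The rule is a formalization of a visual judgement and is deliberately kept
configurable in spirit: `select_k()` returns the full diagnostic vector so
a user can apply a different functional.

With k = 3 the clusters are ordered by centroid mean and labelled low /
intermediate / high; other k fall back to ordinal labels. Reported
per-class ranges are of the maturation-stage fraction and may overlap
between adjacent classes, because cluster boundaries live in the
three-stage space, not on the maturation axis alone.

## The synthetic panel generator

No raw plant panel is distributed with the analysis this package
implements, so the generator is a first-class module that emulates the
study design end to end — 20 accessions, 99 plants (three to seven per
accession), three developmental stages, duplicate extraction replicates,
twelve analytes — down to calibration standards and peak areas, with truth
tables retained so every pipeline stage can be tested against known
answers.

Genotypes: the B locus is drawn with weights 0.40/0.20/0.40 for tricyclic
homozygote / heterozygote / dicyclic homozygote (about 20 heterozygotes
per panel, matching the heterozygote cohort size the analysis regime
assumes), and a latent three-class C3 trait with weights 0.50/0.30/0.20
reflecting the predominance of low-propyl germplasm. Latent fractions are
drawn as truncated normals centred at the midpoint of their class range
with SD = width/6 (the usual "range ≈ ±3σ" convention): F_dicyclic on
[0.5, 7], [25, 75] and [93, 99.5] for the three genotypes, F_C3 on
[0.4, 20], [18, 65] and [60, 92] for the three classes. The unimodal
within-class shape matters: it is what makes the dicyclic:tricyclic
distribution genuinely trimodal (three discrete modes) and leaves the
three C3 classes overlapping into a continuum, and it is what renders
k = 3 identifiable to the elbow rule — under, say, uniform draws over the
same supports, the heterozygous band is so dispersed that splitting it
keeps paying and no elbow criterion settles at 3.

Stages: each stage realizes the latent value plus Normal(0, 1.5 percentage
points) biological noise, clipped to [0, 100]. Three designated
heterozygote outliers drift toward parity in F_dicyclic — no drift at
vegetative, half at flowering, and at maturation the full 25 pp drift,
which spans the heterozygous band, so their maturation value sits at
parity up to noise. These give the stepwise-deletion analysis a known
answer set.

Concentrations: each plant × stage draws a total acid-equivalent abundance
uniform on 20–150 μg/mL of extract. The target (F_C3, F_dicyclic) pair is
decomposed into the 2×2 pool allocation over {C3, C5} × {dicyclic,
tricyclic} under the constraint that the C5 dicyclic:tricyclic odds equal
`het_skew` (default 1.44) times the C3 odds; this reduces to a quadratic
with a unique feasible root (closed form in `decompose_fractions()`), so
the within-class heterozygote analysis has exact truth. Pools split 90:10
acid:neutral on the acid-equivalent scale — fresh and carefully dried
tissue is acid-dominant; the proportion is configurable because true
neutral shares are rarely reported. Small amounts of CBGA, CBG, CBN, CBC
(2% of total) exercise the full 12-analyte panel without entering the
fractions.

Detector layer: per-analyte quadratic response truths (mild positive
curvature, sensitivity spread across analytes), standards at 1%
multiplicative noise, duplicate sample replicates at 2% — the precision
regime of a well-behaved single-quadrupole SIM assay, and the level at
which replicate fraction R² > 0.99 emerges rather than being imposed. All
randomness flows from one seed; a given seed reproduces the tables
byte-for-byte.

What the generator does not emulate: chromatographic artifacts
(co-elution, carryover, drift), inter-day calibration drift, censoring at
the detection limit, accession-level genetic structure beyond the shared
plan, any region-to-chemotype association (provenance labels are pure
metadata), and G×E responses. Passing tests therefore demonstrate the
pipeline's correctness under the stated statistical model of the assay,
not robustness to instrument pathology.

## Problem sizes and runtime choices

The test suite and acceptance script run at the study's own scale: full
99-plant panels for end-to-end checks, 20 seeded panels for the replicate
repeatability summary, 100 seeded panels for elbow stability, 1000
Monte-Carlo repeats for calibration linearity, and exhaustive k-means
enumeration only for n ≤ 8. These sizes keep the whole suite in the
one-minute range on a single core while leaving every stochastic bound a
comfortable margin.

## Input conventions and degenerate cases

CSV inputs are comma-separated UTF-8 with "." decimals and a header; `#`
lines are metadata comments. Developmental stages are the names
vegetative / flowering / maturation; the decimal growth-stage code 1008 is
accepted as an alias for vegetative, but 2202 is rejected as ambiguous
because the code has been used in print for both flowering and maturation.
Duplicate (plant, stage, replicate, analyte) rows and unknown analyte
codes are errors with row numbers. Plants missing a stage are excluded
from the stage regressions and clustering with a message, but keep their
per-stage fraction rows.

Other degenerate-input policies: a profile with no quantifiable fraction
analyte is an error (fractions of an empty total are meaningless); an
all-zero early-stage vector cannot be regressed through the origin;
constant fraction vectors make replicate R² undefined and error rather
than returning NA silently.

## Known limitations

* Published regression and cluster statistics from the original panel
  (R² values, F statistics, cluster ranges) are not reproducible without
  the raw data; the package validates its conventions by properties and
  synthetic truth recovery instead.
* The uncentered R² convention, internal standardization of residuals and
  the WSS elbow criterion are each one of several defensible readings of
  under-specified methods text; all three are documented above and the
  alternatives are either available behind flags or exposed through
  diagnostics.
* Quantification assumes the integrated areas are blank-corrected and
  interference-free; the package does not model matrix effects.
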