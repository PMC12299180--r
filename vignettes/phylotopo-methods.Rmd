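---
title: "Methods: phylogenetic structure, microtopography and competition in mapped forest plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic structure, microtopography and competition in mapped forest plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotopo)
```

## The question the package addresses

In a fully mapped forest plot, the species found together in a small quadrat
are a sample from the local species pool filtered by the environment and by
interactions among neighbours. Two classic processes leave opposite
phylogenetic fingerprints. Environmental filtering admits only species whose
(phylogenetically conserved) tolerances match the local conditions, so
co-occurring species tend to be close relatives — phylogenetic *clustering*.
Limiting similarity, the competitive exclusion of ecologically similar close
relatives, spreads local communities across the phylogeny — *overdispersion*.
Which fingerprint dominates can change with the spatial grain of the quadrat
and with the life-history stage of the stems examined, because filtering acts
strongly on establishing saplings while accumulated neighbourhood competition
shapes the survivors.

`phylotopo` implements the full analysis chain for such plots: quadrat
tiling, per-quadrat phylogenetic structure under a randomization null,
terrain covariates from an elevation model, a distance-weighted neighbourhood
competition index, and mixed-effects models linking them — plus a
synthetic-forest generator that injects each assembly process at known
strength so the whole chain can be validated end to end.

## Quadrat system and life stages

The plot is a square of side $L$ metres with coordinates measured from the
south-west corner. A grain $s \in \{2.5, 5, 10\}$ m tiles it into $(L/s)^2$
quadrats; cells are half-open $[is, (i+1)s)$ so each stem falls in exactly
one quadrat, with the far boundary ($x$ or $y = L$) folded into the last
cell. The grains nest exactly (four 2.5 m quadrats per 5 m quadrat, four
5 m per 10 m), and the community matrices are required to respect that
nesting: child counts sum to the parent's. A 340 m plot therefore has 289
20 m blocks and 4624 5 m working quadrats.

Stems carry DBH in cm with a census floor of 1 cm (smaller stems are not
recorded; a table containing one is rejected as a data defect). Life stages
are DBH bins: sapling (< 5 cm), juvenile (5–15 cm), adult (≥ 15 cm), with
the boundary values 5 and 15 going to the older bin. Every analysis runs for
the community as a whole and for each stage separately.

## Phylogenetic structure metrics

Given a rooted ultrametric phylogeny with branch lengths (tips = species
codes; the tree is pruned to the census checklist, preserving all retained
path lengths), the per-quadrat metrics are:

* **SR** — species richness.
* **PD** — Faith's phylogenetic diversity: total branch length of the
  minimal subtree spanning the quadrat's species *and the root*. The
  root-inclusive convention means a single-species quadrat has PD equal to
  that tip's depth and the full pool recovers the total tree length; PD is
  monotone under adding species.
* **MPD / MNTD** — mean pairwise and mean nearest-taxon cophenetic distance
  among the species present (presence-based; abundance weighting is not
  used, matching the common default).
* **NRI / NTI** — negated standardized effect sizes,

  $$\mathrm{NRI} = -\frac{\mathrm{MPD}_{\mathrm{obs}} -
  \overline{\mathrm{MPD}}_{\mathrm{null}}}{\mathrm{sd}(\mathrm{MPD}_{\mathrm{null}})},$$

  and NTI likewise from MNTD, so positive values indicate clustering and
  negative values overdispersion.

**Null model.** The null shuffles the tip labels of the cophenetic distance
matrix (999 draws by default), holding each quadrat's composition, richness
and occupancy fixed while randomizing species identities across the pool.
The pool is the set of species present in the community matrix being
analysed — saplings are judged against the sapling pool, and each grain
against its own matrix. Tip shuffling is the field-standard default when the
randomization scheme is otherwise unspecified; it is the only null
implemented. Alongside the SES, each quadrat gets a two-sided rank p-value
of the observed MPD/MNTD within its null distribution (the observation is
ranked among the 999 draws plus itself).

Quadrats with SR < 2 have no pairwise structure and are flagged invalid
(they keep SR and PD and still enter the SR/PD models). A null standard
deviation at floating-point zero — e.g. a quadrat containing the entire
pool, where every shuffle returns the same value — makes the SES undefined;
such quadrats are flagged and excluded downstream. The sd cutoff is a
relative $10^{-6}$: genuine null sds on these trees are many orders of
magnitude larger, while pure round-off after the sum-of-squares update and
square root sits near $10^{-8}$.

Stage-level inference mirrors a violin plot against the zero line: per
(grain, stage), the mean NRI and NTI over valid quadrats with a two-sided
one-sample t-test against 0 (groups with fewer than 3 valid quadrats are
flagged NA).

## Terrain covariates

The elevation model is a regular square-celled raster (ESRI ASCII grid on
disk; 5 m cells by default, aligned to the census grid). Derivatives use a
3 × 3 window:

* **slope, aspect** — Horn's 8-neighbour weighted finite differences;
  slope in degrees. Aspect (downslope compass bearing) is folded to a
  single bounded "southness" score $-\cos(\mathrm{aspect})$: +1 due south,
  −1 due north, 0 flat. A continuous score avoids the 0/360° wrap fallacy
  of raw degrees while keeping the stated ordering (south-exposed high,
  north-exposed low).
* **TPI** — focal elevation minus the mean of the available neighbours
  (ridges positive, depressions negative).
* **TRI** — the *standard deviation* of the 8 neighbouring elevations.
  This follows the defining wording adopted here; note it differs from
  Riley's original TRI (root-mean-square of focal-to-neighbour
  differences).
* **roughness** — elevation range (max − min) over the full 3 × 3 window,
  the standard definition in the GDAL/terra toolchain.
* **D8 flow** — each cell drains to its steepest-descent neighbour
  (ESRI codes E=1 … NE=128, drop divided by centre distance; ties take the
  lowest code; pits and flats take code 0 and stop the flow). Flow
  accumulation counts the cells draining through each cell, itself
  included, by accumulating in order of decreasing elevation. Because the
  D8 *code* is categorical, the regression covariate is
  $\log_{10}(1 + \mathrm{accumulation})$ — a monotone wetness proxy that
  carries the intended "capacity for water convergence" meaning. Both
  layers are emitted.

Edge policy: TPI/TRI/roughness use the neighbours that exist (no padding);
the Horn gradient replicates the nearest edge cell. All windowed metrics are
checked against brute-force per-cell loops, and all are invariant to adding
a constant elevation.

Quadrat covariates are means of the cell values whose centres fall in the
quadrat. At the 2.5 m grain on a 5 m raster a quadrat may contain no cell
centre; it then takes the value of the cell containing its own centre.
Covariates are z-scored (mean 0, sd 1) before modelling; a zero-variance
covariate is an error rather than a silent constant column.

## Neighbourhood competition

Hegyi's competition index for focal stem $i$ is

$$CI_i = \sum_{j} \frac{d_j / d_i}{\mathrm{dist}_{ij}},$$

summing over neighbours $j$ of any species and stage. "Neighbourhood" is
read as a circular radius equal to the analysis grain (2.5/5/10 m) centred
on the focal stem — a radius avoids the edge artifacts a same-quadrat rule
creates for stems near quadrat boundaries; a same-quadrat mode is available
(`hegyi_ci(mode = "quadrat")`) for comparison. No edge correction is applied
at the plot boundary, so stems within one radius of an edge see truncated
neighbourhoods and slightly low CI; the models inherit that conservative
bias. Coincident stems (distance exactly 0) are a hard error naming the
pair — clamping the distance would inflate CI without bound. A uniform-grid
spatial index keeps the search near-linear; results equal the $O(n^2)$
double loop exactly.

Quadrat-level CI is the mean over focal stems of the requested stage in the
quadrat (competitors are never stage-filtered), missing where the quadrat
has no such stem.

## Stage models

Per response, grain and stage grouping, the model is a linear mixed-effects
fit (REML, `lme4`):

$$\mathrm{SR/PD} = \beta_0 + \beta_1 CI + \beta_2 \mathrm{Elev} +
\beta_3 \mathrm{Aspect} + \beta_4 \mathrm{Slope} + \beta_5 \mathrm{TPI} +
\beta_6 \mathrm{TRI} + \beta_7 \mathrm{Flow} + u_{g} + \varepsilon,$$

with NRI/NTI models adding $\beta_8 SR$ — SES values are mechanically
related to richness, so richness is partialled out. Roughness is computed
and can be appended (`build_design(extra_predictors = "roughness")`) but is
not in the default set, which follows the seven-predictor form above. All
predictors are z-scored within each design so the $\beta$s are comparable
effect sizes; responses are left on their natural scales.

**Random intercept.** The stated intent of a species-level random effect
does not transfer directly to quadrat-level responses, where no single
species applies. The default grouping is the quadrat's *dominant species*
(highest summed basal area, $\propto \sum d^2$) — the quadrat-granular
reading of "species effects" — with the parent 20 m census block available
as an alternative (`group = "block"`) to absorb spatial pseudo-replication
instead. Random intercepts only: slopes for 8 predictors over ~10² groups
are unidentifiable at these sizes.

Inference is a Wald t-test per coefficient with residual degrees of freedom
($n - p$), reported with significance tiers a/b/c for $p <$ 0.05/0.01/0.001
and no multiple-testing correction (raw p-values are reported; readers can
apply their own). When the random-intercept variance converges to the
boundary (singular fit) the model falls back to OLS with a warning — the
grouping then carries no information, and the fixed effects agree with OLS
to numerical precision by construction. Designs with fewer than 10 rows per
predictor are refused outright rather than fitted badly; collinear
predictors are an error naming the aliased columns.

## The synthetic forest

The generator emulates the study conditions a mapped-plot analysis
presumes: a square plot (examples use 100–150 m; the full 340 m design is
exercised where cheap), ~50–104 species on a depth-1 ultrametric Yule tree
(pure birth, rate 1, depth rescaled), $10^3$–$10^4$+ stems with continuous
(not cell-snapped) coordinates, a geometric rank-abundance distribution
(ratio 0.94 — a few dominant species, a long rare tail), and a right-skewed
DBH distribution, $1 + \mathrm{lognormal}(1.3, 1)$ cm, putting roughly
52/38/10% of stems in the three stages so no stage is degenerate. The DEM
is a planar trend plus Gaussian noise smoothed with a Gaussian kernel and
rescaled to a chosen relief amplitude.

Abundance ranks are assigned to tips in *randomized* order: tip numbering
follows topology, so assigning ranks by label would make the dominant
species close relatives and bias NRI positive even under neutrality (an
effect we measured at ≈ +0.2 mean NRI before randomizing).

Three assembly scenarios share one code path, so `intensity = 0` reproduces
the neutral forest bit for bit regardless of mode:

* **neutral** — species drawn from the abundance distribution, placed
  uniformly.
* **filtering** — a species' placement probability over DEM cells is
  $\propto \exp(\mathrm{intensity} \times a_{sp} \times E_c)$, where $E_c$
  is the z-scored environmental field (elevation by default; TPI or log
  flow accumulation selectable) and $a_{sp}$ is a conserved affinity. The
  affinity is an *early-burst* Gaussian trait: variance rate decaying as
  $e^{-6\,\mathrm{depth}}$, total tip variance 1. Plain Brownian motion was
  tried first and rejected: a single Brownian trait is only weakly coupled
  to cophenetic distance (cor ≈ 0.25 between squared trait differences and
  distances), and at ~50 species the realized trait can by chance make
  trait-similar species phylogenetically *distant*, flipping the recovered
  sign on some seeds. Concentrating variance on deep branches gives each
  major clade a coherent affinity, so sorting along the gradient assembles
  close relatives — the construction the scenario is meant to guarantee.
* **repulsion** — stems are placed sequentially; a proposal is accepted
  with probability $\exp(-\mathrm{intensity} \times \bar w)$, where
  $\bar w$ is the mean over established stems within 10 m of the kernel
  weight $1 - d_{\mathrm{coph}}/\mathrm{diameter}$ (1 for itself, 0 for the
  most distant tip). The *mean* (not sum) keeps the penalty in [0, 1], so
  acceptance does not collapse as density grows; after 100 rejected tries a
  proposal is accepted unconditionally, bounding runtime. The 10 m radius
  covers the largest analysis grain.

Intensities are dimensionless. The calibrated "strong signal" settings used
in examples and checks are 3 for filtering and 12 for repulsion: swept
across independent seeds, these recover the injected sign with |t| > 6 on
every seed tried, whereas weaker settings (e.g. repulsion at 4) are
tree-dependent — the kernel contrast between a typical pair (weight
≈ 0.1–0.25) and close relatives varies with tree shape.

A separate regression fixture (`simulate_regression_dataset()`) draws the
eight standardized predictors i.i.d. N(0, 1) with a group random intercept
and Gaussian noise — the exact generative model the stage models assume —
for coefficient-recovery and coverage checks with known $\beta$.

**What the generator does not emulate** — and hence what passing checks do
*not* establish about real data: demographic dynamics (growth, mortality,
recruitment — stages are drawn independently of position), dispersal
limitation and conspecific aggregation beyond the injected scenarios,
multi-stemmed individuals, spatially autocorrelated model residuals,
measured-covariate error, and real topography (the smooth DEM has no
drainage network, cliffs or terracing). Calibration and recovery results
certify the *machinery* under the stated generative model, not the
ecological conclusions one would draw from any particular forest.

## Determinism and numerical choices

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; the same arguments always reproduce the same output, to the byte
for the pipeline's CSV/Newick/ASCII-grid artifacts (the run manifest
contains no timestamps for this reason). Scenario equivalence at
`intensity = 0` is structural: all modes draw the same random numbers in
the same order. Cell weights are normalized with a max-shift before
exponentiation, so large intensities do not overflow.

Problem sizes in the test suite and acceptance checks are chosen to keep
the full run in minutes while leaving the statistics well-powered: null
calibration pools two 150 m neutral forests (2 × 900 five-metre quadrats,
999 randomizations each — per-quadrat rejection at nominal 5% is then
estimated from ~1800 quadrats); scenario recovery uses 100 m forests with
4000 stems; coefficient recovery uses n = 2000 with 50 replicates for
coverage. Pooling across forests matters because quadrats within one forest
share the realized abundance-to-tip assignment: per-forest mean NRI under
neutrality fluctuates by ~±0.2 between forests even though the per-quadrat
rank test stays calibrated, so neutrality checks use between-forest
variability, not the (too small) within-forest standard error.

## Known limitations

* The taxa-shuffle null is the only null model; richness-conserving swap
  algorithms for abundance-weighted metrics are out of scope.
* No spatial autocorrelation structure in the mixed models; the block
  grouping absorbs coarse spatial variance but residuals within blocks are
  treated as independent.
* No edge correction for the competition index at the plot boundary.
* PD, MPD and MNTD are presence-based; abundance-weighted variants are not
  implemented.
* The D8 flow routing does no pit filling; closed depressions in a rough
  DEM terminate flow paths (on the smooth synthetic DEMs this is rare).
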