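---
title: "Methods: longitudinal cortical-thickness analysis with longicort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal cortical-thickness analysis with longicort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

longicort implements a complete longitudinal surface-based morphometry
pipeline: per-vertex symmetrized percent change of cortical thickness (CT),
surface smoothing, mass-univariate general linear models with nested
step-up model selection, random-field-theory (RFT) cluster inference for
nonisotropic fields with a permutation oracle, cluster-wise brain–behavior
correlation under false-discovery-rate control, and gene-expression
decoding of statistical maps with hypergeometric gene-set enrichment. A
synthetic-cohort generator reproduces the statistical structure such data
have — two-timepoint thickness maps with age-related thinning, spatially
clustered group differences in thinning rate, skewed behavioral item
responses, spatial expression matrices — so every stage can be exercised
and calibrated without subject data. This vignette records the model, the
parameters that matter, and the design and numerical choices.

## The outcome measure: symmetrized percent change

For thickness maps $CT_{T1}, CT_{T2}$ (mm) acquired an interscan interval
$ISI$ (years) apart,

$$\mathrm{rate} = \frac{CT_{T2}-CT_{T1}}{ISI}, \qquad
  \mathrm{avg} = \tfrac12 (CT_{T1}+CT_{T2}), \qquad
  CT_{spc} = 100\,\frac{\mathrm{rate}}{\mathrm{avg}} \;[\%/\mathrm{yr}].$$

This is the standard longitudinal two-stage definition: an annualized
change normalized by the within-subject average thickness, exactly
antisymmetric under exchanging the timepoints. Vertices whose average
thickness falls below a guard of $10^{-6}$ mm are masked invalid rather
than divided — a pathological zero-thickness vertex must not poison the
downstream GLM. `vertex_map` objects carry mandatory unit tags
(`mm`, `percent-per-year`, `t`, ...) and addition/subtraction across
mismatched units is an error; mixing raw thickness with annualized change
is the classic silent failure this prevents.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` define the study conditions. For
subject $i$ at vertex $v$,

$$CT_i(T1, v) = b + u_i + \alpha\,(a_i - \bar a) + \varepsilon_{i1v}, \qquad
  CT_i(T2, v) = b + u_i + \alpha\,(a_i - \bar a)
     + ISI_i\, r_i(v) + \varepsilon_{i2v},$$

with baseline $b = 2.7$ mm, between-subject spread
$u_i \sim N(0, 0.1^2)$ mm, cross-sectional age slope
$\alpha = -0.03$ mm/yr over ages 11–18, measurement noise
$\varepsilon \sim N(0, 0.05^2)$ mm independent per timepoint, and thinning
rate $r_i(v) = r_{TD} + \delta\,[i \in \mathrm{ASD}]\,[v \in \mathrm{patch}]$,
$r_{TD} = -0.03$ mm/yr. Group sizes default to 33 + 37 and the interscan
interval to $N(2.06, 0.24^2)$ years — the scale of a two-year adolescent
follow-up cohort. Planted patches are geodesic disks computed by Dijkstra
over edge lengths, so planted effects are connected in exactly the
adjacency the cluster-finding stage uses.

Behavioral item responses (43 items, 0–3 each) are truncated
negative-binomial counts with group- and subscale-specific means, a
per-subject gamma severity factor shared across timepoints (inducing
within-person correlation and the heavy-tailed, zero-inflated totals that
such instruments show), and completely-at-random missingness capped at 3
items per timepoint. Item means are calibrated only to group-level
subscale summaries (about 25 ± 19 for the clinical arm vs 2 ± 3.7 for
controls at T1), which under-determines per-item parameters; the
truncation at the 0–3 scale is compensated by a fixed mean-inflation
factor so realized subscale means land on the targets. Per-item
distributions beyond that are not modeled.

One master seed feeds a named sub-stream per component (demographics,
thickness, behavior, expression, permutation), so changing one component's
draws never perturbs another's, and identical configurations are
bit-identical. The planted truth (cluster labels, true rate delta, planted
gene identities) is returned in a separate `truth` element that no
analysis function accepts.

**Template scale.** The template is an icosphere; subdivision level 4
(2562 vertices) with radius 40 mm is the default. The radius is chosen so
that the 10-mm smoothing kernel spans about 3.3 vertex spacings: continuum
random-field theory requires the field to be smooth at the mesh scale. At
a life-size 100-mm radius this vertex count would put the spacing at the
kernel width itself, where the t-field is effectively discrete and cluster
inference degenerates to isolated vertices. The default is therefore a
*scaled-down search region* (about 1/6 of a cortex-scale area), not a
life-size cortex; all quantities remain in physical mm units.

## Smoothing

Surface smoothing is iterated area-weighted neighbor diffusion,
$x \leftarrow x + \tau D_a^{-1} (W - D)\,x$, with the unweighted edge
Laplacian and vertex-area mass matrix. Because the Laplacian is symmetric
with zero row sums, the area-weighted integral of the map is conserved
exactly at every step, the operation is linear, and for $\tau$ below the
stability bound it is a contraction — variance can only decrease. The
iteration count and step size are calibrated once per (mesh, FWHM) pair by
an impulse-response experiment: an impulse is diffused, a Gaussian is
fitted to log-response against squared geodesic distance, and the total
diffusion is rescaled by the diffusion law (squared width grows linearly
in the number of steps), splitting it over at least 8 sub-stability steps
so the effective kernel is continuously tunable. On the default template
the achieved kernel is within a few percent of the requested 10 mm.
Smoothing is applied to the per-subject $CT_{spc}$ maps, not to the raw
thickness maps.

## The vertex-wise GLM

`build_design()` constructs the shared design: intercept, group
(TD = 0, ASD = 1), sex (male = 0, female = 1), and mean-centered
continuous covariates (age, age², FSIQ, ISI; optionally the behavioral
change score and its group interaction). With 0/1 coding and centered
covariates, the group coefficient is directly the adjusted ASD−TD
difference in $CT_{spc}$. The quadratic age term is built from centered
age and then centered again; over an 11–18 age range the raw square is
nearly collinear with age and would ill-condition the fit. Centering can
be performed over all subjects or over the ASD arm only (for within-group
subanalyses). `fit_vertex_glm()` fits ordinary least squares independently
at every vertex and forms $t = c^\top\hat\beta / \sqrt{\hat\sigma^2
c^\top (X^\top X)^{-1} c}$ with $dof = n - \mathrm{rank}(X)$; residuals
are retained for smoothness estimation.

**Step-up model selection.** Candidate terms are admitted by an
extra-sum-of-squares test of the enriched against the current model. How
the per-vertex tests aggregate into one decision is genuinely open; the
default pools residual sums of squares over vertices and performs a single
nested F with vertex-scaled degrees of freedom. This is exact when vertex
noise is independent and homoscedastic; under spatial smoothing vertices
are positively correlated and the effective vertex count is smaller, so
the pooled test is then optimistic about its degrees of freedom — the
alternative `mean_p` summary (cortex-average per-vertex p against its null
expectation of 1/2) is kept as an option. On unsmoothed null cohorts the
pooled test's type-I rate is nominal (checked by simulation in the test
suite).

## RFT cluster inference

Clusters are formed at the Student-t quantile
$u = t_{1-p/\mathrm{tails}}(dof)$ (the study default is $p = 0.05$,
two-tailed) as connected components of supra-threshold vertices over
shared-edge adjacency, positive and negative tails labeled separately.

Local smoothness is estimated from unit-normalized GLM residuals: for each
edge, the mean squared difference of normalized residuals approximates
twice one minus the spatial correlation, giving the squared derivative per
mm and hence a local FWHM under a Gaussian autocorrelation model,
$\mathrm{FWHM} = \sqrt{4\log 2\,\ell^2/\mathrm{ssq}}$. Each vertex's resel
density is its area divided by its squared FWHM; nonisotropy enters by
measuring every cluster's extent as the sum of its members' local resel
densities rather than in mm².

The corrected p of a cluster of extent $s$ resels combines the expected
cluster count with an extent tail in a Poisson clumping bound:

$$E[m] = R_0\,\rho_0(u) + R_2\,\rho_2(u), \qquad
  P(S \ge s) = \Big(1 + \frac{2\beta s}{\nu}\Big)^{-\nu/2}, \quad
  \beta = \rho_2(u)/\rho_0(u),$$
$$p_{\mathrm{cluster}} = 1 - \exp\big(-\mathrm{tails}\cdot E[m]\cdot
   P(S \ge s)\big),$$

with $\rho_d$ the Euler-characteristic densities of a t-field,
$R_2$ the total search-region resels, and $R_0 = 2$ for a closed
sphere-topology surface (no boundary term). The extent tail is the
standard exponential approximation (rate matched to the expected extent
per cluster, $\rho_0/\rho_2$) integrated over the chi-squared distribution
of the local variance scaling of a t-field — heavier in the far tail at
finite $dof$ and reducing to $\exp(-\beta s)$ as $dof \to \infty$. A
two-tailed search doubles the expected cluster count inside the
exponential rather than doubling and capping the p afterwards: the two
forms agree wherever p is small, but the capped form collapses all small
clusters onto exactly $p = 1$, which destroys rank comparisons against the
permutation oracle.

**Calibration and its limits.** On null synthetic cohorts the expected
cluster count matches the observed count closely, and the permutation
oracle below achieves a family-wise error of 0.05 exactly. The analytic
cluster p remains mildly anticonservative at the liberal cluster-forming
threshold of $p = 0.05$: across 800 null replicates the measured
family-wise error was about 0.08 at nominal 0.05. This is the documented
behavior of extent-based RFT at low forming thresholds — the
approximations are asymptotic in $u$ — and is precisely why the
permutation test ships alongside: where the corrected p matters near the
decision boundary, the permutation p is the authoritative number.

**Permutation oracle.** `permutation_cluster_test()` implements
Freedman–Lane residual permutation: the nuisance-only model is fitted, its
residuals are permuted over subjects and added back to the nuisance
fitted values, the full model is refitted, and the maximum cluster resel
extent is recorded per permutation; each observed cluster's p is
$(1 + \#\{\max S^* \ge s\})/(1 + n_{\mathrm{perm}})$. Observed and
permutation p-values agree in rank (Spearman $\rho > 0.98$ in the test
suite) over clusters large enough for the permutation null to resolve;
clusters smaller than every permutation maximum all receive the same
permutation p of 1, so rank agreement is evaluated on the resolvable
ones.

## Brain–behavior correlations

Subject-level mean $CT_{spc}$ is extracted per significant cluster
(unweighted vertex mean by default; the area-weighted option is recorded
in the output attributes) and correlated with behavioral measures by
two-sided Pearson tests. Benjamini–Hochberg adjustment runs across the
full cluster × measure family computed in one call — the widest in-run
family, the conservative reading when the family is otherwise
unspecified — and the family definition is recorded on the result.

## Behavioral scoring and imputation

The 43-item instrument is scored as a total plus four factors
(persistent, stereotyped, self-injurious, compulsive). No canonical
item-to-factor assignment ships as "the" mapping: the default map uses
the instrument's subscale structure (6 stereotyped, 8 self-injurious,
8 compulsive, 21 persistent items) and any user-supplied partition of the
43 items is accepted.

Missing items (at most 3 of 43 per person per timepoint) are completed by
single predictive-mean-matching imputation: per item, a linear prediction
is fitted on complete cases (predictors: the other items; a recipient's
own missing predictors are filled by complete-case column means for
prediction only), the donor pool is the `k_donors = 5` complete cases with
nearest predictions, and the imputed value is drawn uniformly from the
donors' observed values — it therefore always lies in the item's observed
support. Randomness enters only at imputed cells, under a named seed
sub-stream. Single rather than multiple imputation is deliberate: the
downstream analysis consumes one completed dataset.

## Transcriptomic decoding and enrichment

`decode()` ranks genes by the Pearson correlation between their expression
across spatial samples and the t-map sampled at those locations (vertex
value, or unweighted parcel mean). Candidates are genes with a *similar*
pattern — positive correlation at two-sided $p < 0.05$; the threshold is a
selection step, not a hypothesis test, hence deliberately liberal. A
signed mode also returning the anticorrelated list exists but is off by
default. `enrich()` tests candidate lists against gene sets by the
hypergeometric upper tail over a declared universe, with the odds ratio
from the 2×2 table; a zero overlap reports OR 0, and when any other cell
is zero the Haldane–Anscombe 0.5 correction keeps the *reported* OR finite
while the p-value is never corrected. The default universe is the number
of genes in the supplied expression matrix — the universe must match the
population actually tested — with the genome-scale value (e.g. 20,787
protein-coding genes) available as explicit configuration.

## Numerical and representational choices

- Vertex indexing is 1-based throughout, the R convention shared by every
  mesh and graph package this package builds on; the on-disk formats carry
  no indices, and an explicit index column in a CSV map is validated
  0-based (the convention of the originating tools) and converted at the
  boundary.
- Binary morphometry ("curv") I/O is new-style only (magic `0xFF 0xFF
  0xFF`, big-endian float32); GIFTI shape files use ASCII encoding; CSV
  maps carry 9 significant digits. Every writer emits a JSON sidecar with
  unit tag, mesh id and provenance (stage, parameters, seed).
- Item missingness on disk is the empty field or `NA`; numeric sentinels
  are rejected because items live on the 0–3 scale.
- Degenerate inputs error early and specifically: zero-variance residual
  columns, empty clusters, rank-deficient designs (naming the collinear
  columns), universes smaller than the tested union, non-positive
  interscan intervals (naming the subjects).

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the full pipeline at desk
scale: 2562-vertex templates for cluster-level calibration (200 null
replicates for family-wise error; 50 replicates for planted-effect
detection and recovery; 199-permutation oracles on 10 cohorts), 162-vertex
templates for oracle-equivalence and decoding experiments (50 replicate
expression matrices of 400 genes × 100 samples). These sizes were chosen
so the distributional claims are testable with meaningful Monte-Carlo
precision while the whole suite stays interactive.

## What passing tests do and do not show

The generator emulates the *statistical* structure of registered
longitudinal thickness data: spatially smooth noise after kernel
smoothing, age-related thinning, group-clustered rate differences,
skewed zero-heavy behavioral totals, expression profiles tracking an
effect map. It does not emulate cortical folding geometry, registration
error, scanner artifacts, spatially autocorrelated gene expression, or
donor structure of a real expression atlas. Calibration results
(family-wise error, power, decoding recovery) therefore validate the
statistical machinery under the generative model, not performance on any
particular real dataset; in particular, spatial autocorrelation in real
expression data makes the parametric decoding p optimistic, which is why
the decoding threshold is treated as a selection device and enrichment
conclusions rest on the downstream hypergeometric test.
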