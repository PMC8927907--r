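---
title: "Models and methods behind glycomirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycomirnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomirnet)
```

# The problem

Pancreatic islets adapt their microRNA complement to chronic glycemic
stress, and some of those miRNAs in turn repress genes required for insulin
and glucagon secretion. Cohorts of islet donors are small (organ donation),
so the analysis has to wring signal out of ~18 donors spanning normal
glucose tolerance (NGT, HbA1c < 6%), impaired glucose tolerance (IGT,
6.0--6.4%) and diagnosed type 2 diabetes (T2D, >= 6.2% with a diagnosis).
`glycomirnet` implements the complete chain from expression matrices to
disease-variant overlap:

1. **Differential expression** of miRNAs between IGT/T2D and NGT donors
   with the SAM statistic and a permutation-estimated FDR.
2. **HbA1c association**: a covariate-adjusted linear-model scan of log2
   miRNA expression on HbA1c.
3. **Intersection** of the two scans into the concordant *Up-Pos*
   (upregulated, positively HbA1c-associated) and *Down-Neg* sets.
4. **Validated-target mapping** with an islet-expression filter,
   Jaccard-distance clustering of miRNAs by shared targets, and a
   random-miRNA-set null for targeting density.
5. **Signed weighted co-expression network** over the target genes:
   soft-thresholded adjacency, topological overlap, deterministic tree-cut
   modules, eigengenes, eigengene merging, and module--trait correlation.
6. **Over-representation analysis** of module genes against gene-set
   collections.
7. **cis-eQTL mapping** of miRNA expression with SNP quality control and
   per-miRNA multiplicity correction, and **overlap** of nominal eQTLs
   with a catalogue of T2D / insulin-secretion risk variants.

Every stage is validated against a synthetic-data generator that plants
each effect the stage is supposed to recover.

# Differential expression: SAM

For feature $i$ with case/control means $\bar x_{1i}, \bar x_{2i}$ the
statistic is

$$ d_i = \frac{\bar x_{1i} - \bar x_{2i}}{s_i + s_0}, \qquad
   s_i = \sqrt{\tfrac{1/n_1 + 1/n_2}{n_1 + n_2 - 2}
   \left(\textstyle\sum_1 (x - \bar x_1)^2 + \sum_2 (x - \bar x_2)^2\right)} $$

with the exchangeability constant $s_0$ chosen on a percentile grid of
$s$ to minimise the coefficient of variation of window-wise
median-absolute-deviations of $d$ -- the original tuning that removes the
dependence of $|d|$ on $s$. The choice is deterministic; ties resolve to
the smallest percentile.

FDR estimation permutes the group labels. All distinct relabelings are
enumerated when there are at most `n_perm` of them (e.g. 20 for a 3v3
design); otherwise `n_perm` **balanced** shuffles are drawn -- each
pseudo-case group receives its proportional share of true cases, so real
effects cancel inside permuted groups instead of inflating the null.
Balanced draws come from rejection sampling of plain label shuffles under a
swap-symmetric criterion, which makes the antisymmetry property exact:
swapping the case/control labels negates every $d_i$ and swaps the up/down
sets, including their $q$ values. For each threshold $\Delta$, features are
called where the ordered $d_{(i)}$ departs from the permutation-mean order
statistics by more than $\Delta$ (scanning up and down from the origin);
$\mathrm{FDR}(\Delta) = \pi_0 \cdot \mathrm{median\ false\ calls} /
\mathrm{called}$, with $\pi_0$ estimated from the share of observed $d$
inside the central permutation quartiles. A feature's $q$ is the smallest
$\mathrm{FDR}(\Delta)$ at which it is called, so called-set size is
monotone in $\Delta$ and $q$ is well defined.

The default contrast is **unpaired**; donors in these designs are matched
on age, sex and BMI at the cohort level rather than as explicit pairs, and
unpaired two-class SAM is the conventional default in the array tools this
follows. A paired variant (one-sample SAM on per-pair differences with
sign-flip permutations) is available through the `pairs` argument for
designs with explicit donor pairing.

# HbA1c association scan

Per miRNA, ordinary least squares of log2 expression on HbA1c adjusted for
age, BMI, sex (0/1), glycemic status, and days of islet culture. Glycemic
status enters **ordinally** (NGT/IGT/T2D as 0/1/2) by default -- the
progression is naturally ordered and a single degree of freedom preserves
residual degrees of freedom at $n = 18$ -- with two-indicator coding
available (`status_coding = "dummy"`). p values are two-sided from the $t$
distribution on $n - k$ degrees of freedom; Benjamini--Hochberg adjustment
runs across all tested miRNAs, and the positive/negative sets take
$q < 0.1$ with the corresponding coefficient sign. The whole panel shares
one design matrix, so the scan is a single QR decomposition; tests assert
equality with feature-wise `ols_fit()` calls at $10^{-10}$.

A structural caveat this package makes explicit: glycemic status is itself
a threshold function of HbA1c, so adjusting for status leaves only the
within-stratum HbA1c variation (residual SD around 0.3%) to identify the
slope. Power at $n = 18$ therefore depends steeply on the realised HbA1c
spread of the cohort, and occasional cohorts with compressed within-stratum
spread recover little -- visible as seed-to-seed variance in the planted
recovery studies.

# Target maps and set similarity

The islet-expression filter keeps a gene when at least `min_count`
normalized counts (default 3) appear in at least `min_frac` of samples
(default 80%). Both "at least 3" and "more than 3" phrasings circulate for
this filter; `>= 3` is the default and `strict_greater = TRUE` selects the
other reading. Target sets are deduplicated per (miRNA, gene) and
optionally intersected with the expressed set; filtering before mapping
and mapping before filtering commute (tested).

miRNA similarity uses the Jaccard distance
$1 - |A \cap B| / |A \cup B|$ -- a metric on nonempty sets (axioms tested
exhaustively over a 5-element universe) -- with average-linkage
hierarchical clustering over a lexicographically ordered miRNA list so leaf
order is deterministic. The targeting-density null redraws $k$ miRNAs
uniformly without replacement from the profiled universe (the natural
sampling frame: any profiled miRNA could have been selected) and records
unique-target and interaction counts.

# Signed co-expression network

Adjacency $a_{ij} = \left((1 + \mathrm{cor}(g_i, g_j))/2\right)^\beta$
with Pearson correlation over samples and $\beta = 12$ by default: a
signed network, so anticorrelated genes are unconnected rather than
connected. Topological overlap

$$ \mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{j \ne i} a_{ij} $$

is computed by matrix algebra and tested against a literal triple loop at
$10^{-12}$. `pick_soft_threshold()` reports, per power, the $R^2$ of the
log-frequency vs log-connectivity regression signed by the negative slope,
recommending the smallest power reaching 0.8 or else the argmax. Planted
equal-size modules produce a bimodal degree distribution that is *not*
scale-free, so on such data the fallback triggers by construction; what
the tests assert is full module recovery at both the recommended and the
default power.

Module detection clusters $1 - \mathrm{TOM}$ with average linkage and cuts
the tree deterministically in two stages: a constant-height cut at 0.99 of
the tallest merge, then recursive splitting of every branch whose merge
height exceeds the **core height** -- the 0.9-quantile of merge heights --
of both children by more than `split_gap` (default 0.03) of the tallest
merge. Measuring the gap against core heights rather than child root
heights is what makes the cut robust to single stray genes chaining onto a
tight branch, the classic failure mode that dynamic tree cutting exists to
solve; unlike the dynamic-hybrid algorithm the procedure here is a few
lines, fully deterministic, and its two parameters are exposed in
configuration. Branches below `min_module_size` (default 10) stay
unassigned (label 0); labels are 1..M by decreasing size with ties broken
by first gene.

Eigengenes are first principal components of the gene-standardized module
submatrix (unit norm over samples, validated against an independent PCA),
signed so that the mean correlation with member genes is non-negative --
without a sign convention, module--trait correlation signs would be
arbitrary. Modules whose eigengenes cluster below `mergeCutHeight = 0.25`
on $1 - \mathrm{cor}$ are merged and eigengenes recomputed, iterating to a
fixpoint (idempotence is tested). `reassignThreshold = 0` is interpreted
as "no post-hoc reassignment of genes between modules", so no such stage
exists. Outlying samples (late joiners of a Euclidean sample dendrogram)
are flagged, never dropped automatically -- dropping a donor is a decision
the analyst must own.

Module--trait correlation uses Pearson for traits treated as normally
distributed (HbA1c, log2 insulin/glucagon expression) and Spearman for
ordinal or skewed ones (diabetic status, islet purity), following the
conventional mapping for these phenotypes; the mapping is a configurable
argument, not hard-coded. p values are BH-adjusted across modules within
each trait, which answers the question actually asked ("which modules
track this trait?").

# Over-representation analysis

Upper-tail hypergeometric $P(X \ge k)$ for overlap $k$ of an $n$-gene
query with a $K$-gene set in an $N$-gene universe, computed via the stable
distribution-function routine and tested against exact combinatorial
enumeration for $N \le 12$. The universe defaults to the islet-expressed
gene set from the expression filter -- enrichment against all annotated
genes would confound "expressed in islets" with "in this module". Every
set with a nonempty universe intersection is reported (overlap 0 gives
$p = 1$; no hidden minimum-overlap filters), and BH runs across tested
sets. Because the hypergeometric is discrete, $P(p < \alpha)$ under a
random query is strictly below $\alpha$; the calibration tests assert the
one-sided property (no anti-conservatism) rather than a symmetric band
around $\alpha$.

# cis-eQTL mapping

SNP QC fails a variant for call rate below 95%, minor allele frequency
below 1%, or Hardy--Weinberg equilibrium $\chi^2$ p below 0.05, listing
every violated criterion. The conventional 5% missingness cut is used; a
printed threshold of "0.05%" for missingness in this literature is a
recurring typo for the 0.05 fraction. The cis window is $\pm 1$ Mb around
the miRNA start, bounds inclusive -- "within 1 Mb" is read as a symmetric
window, the universal convention in eQTL tools. Per (SNP, miRNA) pair, OLS
of log2 expression on allele dosage (additive 0/1/2) plus age, sex, BMI,
HbA1c and culture days; missing dosages are mean-imputed per SNP for the
regression only, while QC sees them as missing. BH is applied within each
miRNA's cis-SNP set (per-phenotype correction in the FastQTL style);
nominal eQTLs are flagged at $p < 0.05$ because at $n = 18$ nothing
survives correction and multiple nominal signals at a locus remain
informative. Risk-catalogue overlap joins by rsid first, falling back to
exact (chrom, 1-based pos) equality; a SNP under two trait classes yields
one row per class.

# The synthetic-data generator

The generator emulates the emulated study's design, not merely "some
data": 18 donors in a 7/6/5 NGT/IGT/T2D split with HbA1c drawn within the
stratum ranges 4.6--5.95 / 6.0--6.4 / 6.2--7.0%, 470 profiled miRNAs of
which 9 are planted Up-Pos and 22 Down-Neg, five co-expression modules
coupled to islet purity, round-robin miRNA-to-module targeting with decoy
interactions, Binomial(2, MAF) genotypes with planted cis-eQTLs inside
$\pm 1$ Mb windows, and a risk catalogue containing a configurable
fraction of the planted eQTL SNPs. All randomness flows from one root seed
through named streams (`sim_seed(seed, "cohort")`, ...), so any one table
is reproducible in isolation and the full dataset is byte-identical under
a fixed seed. Donor covariates use plausible ranges (age U(30, 75), BMI
truncated N(26, 4), sex Bernoulli(0.5), culture days U{1..9}) -- stand-ins,
not estimates, since no donor-level distributions are published.

**Effect sizes.** Planted group shifts default to 1.5 feature-SDs. The
planted HbA1c slope defaults to 1.0 log2 units per % with a residual SD of
0.25 log2 units, i.e. 4 feature-SDs per %. That magnitude is not
arbitrary: with glycemic status adjusted for, the identifying HbA1c
variation has SD ~0.3%, so a slope of $b$ feature-SDs per % yields
$t \approx 0.3 b \sqrt{18}$ -- reaching BH significance at $q < 0.1$ over
~500 features requires $b \approx 4$. A real study that detects ~90
associated miRNAs at this design necessarily detected effects of roughly
this size, so the generator plants effects at the detectability edge of
the design it emulates. A design-time power simulation (before any test
was written) put recovery at ~78% under these defaults; slopes below ~2
SD/% are essentially undetectable under this design and would make every
recovery test vacuous.

**What the generator does not emulate** -- and therefore what passing
tests do not show about real data: probe- or sequencing-level noise
(expression is Gaussian on the log2 scale; counts are a deterministic
`round(2^log2)` transform, with none of the overdispersion of real RNA-seq),
batch or array effects, correlated covariates (age/BMI/sex are independent
of HbA1c by construction), linkage disequilibrium between SNPs, a
realistic MAF spectrum, population structure, or biologically structured
target databases (decoys are uniform). Recovery rates here are upper
bounds on what the same pipeline achieves on real cohorts.

# Numerical choices and degenerate inputs

* OLS uses QR; rank deficiency is an error naming the collinear columns;
  a zero-residual fit reports $p = 0$ with a `degenerate` flag instead of
  NaNs. Oracle agreement at $10^{-10}$ (normal equations), TOM and SAM
  formula oracles at $10^{-12}$.
* Correlation-based steps refuse zero-variance inputs explicitly
  (undefined-correlation flags in hormone correlations, errors in
  adjacency construction, warnings + exclusion for constant traits).
* Monomorphic SNPs reaching the eQTL scan raise an internal error: QC is a
  contract, and silently skipping would hide its violation.
* Empty intersections, empty overlap tables and empty enrichment
  collections return typed empty tables, not errors.
* Tie-breaks are deterministic everywhere: lexicographic miRNA order
  before clustering, first-gene tie-breaks in module numbering, smallest
  percentile in the $s_0$ grid.

# Problem sizes in the test suite

The suite exercises the study conditions at sizes chosen to keep each
Monte-Carlo block in seconds: 20 seeds at 500 miRNAs x 18 donors for SAM
and scan calibration/recovery (300 permutations per run), three seeds of
the 600-gene / 180-sample / 5-module network fixture, 20 seeds of the
100-donor eQTL fixture, and 2000 set-level draws for ORA calibration.
These are the package's validation scales; the functions themselves hold
no size assumptions beyond memory.

# Known limitations

* The tree cut is a deliberate simplification of dynamic hybrid cutting;
  on real data with nested or unbalanced modules the two can differ, and
  no attempt is made to reproduce any particular published module count.
* SAM power at small $n$ is what a calibrated estimator allows (~75%
  sensitivity at 1.5-SD shifts, 9v9); estimators that report higher
  sensitivity at the same nominal FDR are typically anti-conservative.
* The HbA1c scan's status adjustment absorbs most between-group signal by
  construction; interpreting its coefficient requires the caveat above.
* eQTL overlap is set-based (shared variants), not colocalization; no LD
  is modelled, so an overlap is suggestive, not causal.
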