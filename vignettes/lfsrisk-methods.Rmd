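---
title: "Models and methods behind lfsrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lfsrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfsrisk)
library(dplyr)
```

# Scope

`lfsrisk` provides Mendelian risk prediction for families segregating a rare,
dominant, deleterious germline TP53 variant (Li-Fraumeni syndrome, LFS), and
the machinery needed to validate such predictions on family data of uneven
quality. Four model components interlock:

1. a **cause-specific (CS) competing-risk model** for the first event
   (sarcoma, breast cancer, other cancers, death),
2. a **multiple-primary-cancer (MPC) recurrent-event model** for cancer
   onsets over the life course,
3. a **Mendelian carrier-inference engine** (exact pedigree peeling) that
   converts family history into a carrier probability, and
4. a **validation pipeline** (ROC/AUC, observed/expected calibration, family
   bootstrap, Kaplan-Meier comparator, Classic/Chompret criteria, cohort
   summary tables).

Because clinical family data of this kind cannot be redistributed, the
package also ships a **synthetic cohort generator** that emulates the two
data-collection regimes seen in practice: research-protocol-based (RPB)
families with complete ages, and clinical-counseling-based (CCB) families in
which ages are frequently missing.

# The CS model

For outcome $k \in \{\text{sarcoma}, \text{breast}, \text{other},
\text{death}\}$ the cause-specific hazard is Weibull proportional hazards
with a multiplicative frailty $Z$,

$$\lambda_k(t \mid X, Z) = Z\,\frac{\kappa_k}{\rho_k}
  \Big(\frac{t}{\rho_k}\Big)^{\kappa_k - 1}
  \exp\{\beta_{kG} G + \beta_{kS} S + \beta_{kGS} G S\},$$

where $G \in \{0,1\}$ is carrier status, $S \in \{0,1\}$ is sex (1 =
female), and the breast hazard is structurally zero for males. $Z$ is gamma
with mean 1 and variance $\theta$ — the only frailty family with closed-form
marginals, which is why we use it. Marginalising $Z$ gives the crude
incidence ("CS penetrance")

$$q_k(t \mid X) = \int_0^t \lambda_k^{(1)}(u \mid X)\,
  \bigl(1 + \theta \Lambda_\cdot(u \mid X)\bigr)^{-(1/\theta + 1)}\, du,$$

with $\Lambda_\cdot$ the total conditional cumulative hazard, and marginal
survival $(1 + \theta\Lambda_\cdot(t))^{-1/\theta}$, so that
$\sum_k q_k(t) + S(t) = 1$ identically. The integral is evaluated by
adaptive quadrature (absolute tolerance $10^{-11}$ per segment); the test
suite verifies conservation to well below $10^{-8}$ across the integer age
grid 0–100 and agreement with $10^6$-draw frailty Monte Carlo within
sampling error.

**Frailty sharing.** We treat the frailty as *individual-level* throughout,
for both CS and MPC components. A family-shared CS frailty is a defensible
alternative, but it breaks the conditional independence of phenotypes given
genotypes that exact peeling requires, and it would decouple the generator
from the penetrance formulas the package predicts with. Individual frailty
keeps generator, penetrance, likelihood and peeling mutually consistent, so
the package's strongest tests — generator-vs-model identities — are exact.

# The MPC model

Primary-cancer onsets follow a nonhomogeneous Poisson process with Weibull
baseline intensity, individual gamma frailty (variance $\theta$), and
covariates $X(t) = \{G, S, G{\times}S, D(t), G{\times}D(t)\}$, where $D(t)$
indicates a prior primary before $t$, letting the second primary depend on
the first. The gamma frailty is conjugate to the Poisson process: after
observing $n$ events by $t_0$ the frailty posterior is
$\mathrm{Gamma}(1/\theta + n,\; 1/\theta + \Lambda(0, t_0))$, so the
next-primary penetrance has the closed form

$$q(t \mid t_0, n) = 1 - \left(\frac{1/\theta + \Lambda(0, t_0)}
  {1/\theta + \Lambda(0, t)}\right)^{1/\theta + n},$$

with $D$ switching on at the first onset inside $\Lambda$. At $\theta \to 0$
this reduces to $1 - e^{-\Lambda(t_0, t)}$. Penetrance is supported up to
the second primary; third and later primaries are deliberately out of scope
(occurrences are too sparse to support them).

# Carrier inference

Most relatives are untested, so $G$ is latent. The per-individual phenotype
likelihood $P(\text{history} \mid G, S)$ is evaluated in closed form under
either model (events contribute marginal densities; the gap to censoring
contributes the marginal no-further-event probability; components missing
their ages contribute 1, so an undated history is structure-only
information). Family likelihoods then follow the Mendelian factorisation —
Hardy–Weinberg founder priors at allele frequency $f$ (default
$6 \times 10^{-4}$), autosomal transmission, dominance in the phenotype —
and are computed by Elston–Stewart peeling, implemented as exact sum-product
variable elimination over the 3-state genotype factor graph. On loop-free
pedigrees the elimination cliques are exactly the nuclear families (linear
cost); marriage loops merely enlarge local cliques and remain exact, so no
loop-breaking approximation is needed. Intermediate factors are
max-rescaled with an accumulated log scale to avoid underflow in large
families.

The carrier posterior for a counselee is the target's genotype marginal;
test results enter as genotype clamps under three scenarios: ignore all
tests (pre-test counseling), clamp only the proband, or use every result.
The MPC model is the default phenotype model for inference; the CS model is
available via an argument. A brute-force configuration enumerator (refused
above 12 members) serves as the oracle: peeling is required to match it to
$10^{-10}$ on 200 random pedigrees, and posteriors must be calibrated
against simulated truth (the calibration check generates founders from
Hardy–Weinberg at an enriched frequency with no seeded lineage, so the
inference prior equals the generative law exactly).

Patient-facing predictions are genotype-weighted mixtures: e.g. the
first-primary risk is $p\,q_k(t \mid G{=}1) + (1-p)\,q_k(t \mid G{=}0)$ with
$p$ the carrier posterior, conditioning on being event-free at the current
age per genotype *before* weighting.

# Default parameters

The shipped CS/MPC coefficients are plausible placeholders chosen once for
testing and simulation — carrier log hazard ratios near 3, Weibull scales
placing wildtype lifetime cancer risk near population levels and carrier
lifetime risk near the very high levels characteristic of LFS (roughly 0.9
by late life for female carriers under the MPC defaults). They are **not**
fitted estimates, and no acceptance check compares against published
parameter values; all verification is invariance- and recovery-based. Users
with fitted parameters supply them via `cs_params()` / `mpc_params()` or the
flat key-value config read by `read_model_params()`.

# The synthetic cohort generator

`simulate_structure()` builds three-generation families (configurable): a
founding couple, offspring counts from a Poisson(2.5) truncated to 1–8,
partners marrying in with probability 0.7, and Mendelian transmission. One
founding-couple member is seeded as a heterozygous carrier so that
ascertainment through a carrier proband is feasible at a realistic allele
frequency ($6\times10^{-4}$); `seed_carrier = FALSE` disables this when an
exactly Hardy–Weinberg cohort is wanted.

`simulate_phenotypes()` draws, per individual, a current age (uniform within
generation-specific bounds: 55–90, 30–65, 5–40 years by default — founders
are the oldest generation), a gamma frailty, and a first event by inverse
transform on the total CS hazard, typed by the hazard ratios at the event
time; a death first-event truncates follow-up. Given a first cancer at
$t_1$, the second primary is drawn from the *MPC conditional law* given one
event at $t_1$ (the history-updated frailty posterior), which makes the
generator and `mpc_penetrance()` agree by construction — this identity is
one of the package's core oracles. The second primary is recorded without a
specific type.

`ascertain()` tests the proband always and each relative independently with
probability 0.15 (motivated by clinical cohorts in which only a few percent
of relatives have known genotype), then retains families with at least one
affected, tested carrier, one of whom (chosen at random) becomes the
proband. `apply_missingness()` assigns each nonproband one of four
categories — complete, missing age at last contact only, missing diagnosis
age only, missing both — at the CCB rates (53/41/4/2 percent); probands stay
complete, and the assigned category is retained so frequencies are
recoverable.

What the generator does *not* emulate: population demography, assortative
mating, screening-driven earlier diagnoses, secular trends, misreported
(rather than missing) ages, and post-cancer mortality beyond censoring.
Passing tests therefore certify internal consistency and the machinery's
correctness, not clinical transportability.

# Validation pipeline

Exclusions mirror clinical validation practice: members with unknown first-
or second-primary diagnosis ages, or unknown age at last contact while
cancer-free, are excluded from the *subject set* but remain in the pedigree,
where they still carry structural information for peeling. Cancer-risk tasks
additionally drop probands (ascertainment bias). Subjects split into group 1
(no cancer), group 2 (single primary), group 3 (multiple primaries), with
task-1 evaluation at the age at last contact (group 1) or first diagnosis
(groups 2–3), and task-2 evaluation at the age at last contact (group 2) or
second diagnosis (group 3). Group-2 members lacking an age at last contact
cannot be scored for task 2 and are dropped from that task only.

AUC uses the midrank (Mann–Whitney) formula with ties counting one half —
algebraically identical to pair counting, and the tests require *exact*
equality with an $O(n^2)$ pair-count oracle. Calibration is the
observed/expected ratio $\sum y_i / \sum \hat q_i$. Confidence intervals are
percentile bootstrap (simplest reproducible choice) resampling *families* by
default, preserving within-family correlation; degenerate resamples (e.g.
one-class AUC) are redrawn and counted. The secondary "inferred" filter
keeps tested subjects plus untested ones with carrier posterior $> 0.1$ or
$< 0.001$, strict inequalities. A Kaplan–Meier comparator stratifies
penetrance by sex and carrier status and mixes strata by the carrier
posterior. The Classic and Chompret criteria are provided as rule-based
comparator classifiers; unknown ages never satisfy an age-bounded clause,
"premenopausal" is operationalised as breast cancer before 50, "same
lineage" via parental-side sets, and the Chompret revision is selectable
(2009/2015, default 2015, which adds the breast-before-31 clause and the
choroid-plexus and anaplastic-rhabdomyosarcoma tags).

**A calibration subtlety.** Evaluating each case *at their own event age*
(the validation-task design above) makes O/E exceed 1 even when scores come
from the exact generating model: cases contribute $F(T)$ at their event time
$T$ rather than $F(c)$ at end of follow-up, and $E[F(T) 1\{T \le c\}] <
F(c) P(T \le c)$. Observed O/E ratios above 1 in such designs are therefore
expected, not necessarily evidence of underprediction. For this reason the
package's *self-consistency* calibration check uses a fixed prediction
horizon with follow-up beyond it (label = event by age 40, score = model
probability by 40), under which O/E is exactly calibrated; the bootstrap CI
must cover 1 in at least 90% of 50 seeded replicates. Those replicates use
40-family cohorts: with many fewer clusters the percentile bootstrap is
known to undercover, and the realistic clinical scale is above 100 families.

Cohort summaries reproduce the standard clinical reporting shape: counts by
sex × (healthy/SPC/MPC) × (wildtype/mutation/unknown) with subtotals;
missingness-category tables at family, individual, and
first-degree-relatives-and-spouse levels (percentages to the nearest
integer, one decimal below 1%); and family-size percentiles.
`synthetic_clinical_fixture()` deterministically constructs a
124-family/3,297-individual cohort hitting a published-style clinical
margin profile, used to verify the tables end to end.

# Estimation

`fit_mle()` maximises the summed family log-likelihoods (peeling with all
test results clamped) by L-BFGS-B with box constraints ($\theta \ge 0$,
shapes/scales positive), with observed-information standard errors from the
numerical Hessian. The optional ascertainment correction conditions on the
proband's data (carrier genotype plus observed phenotype) — a simplified
proband-conditioning scheme rather than a full ascertainment-event model.
Likelihood concavity is not assumed; a multi-start option must agree on the
recovery fixtures. For fully-genotyped cohorts under the CS model the
Mendelian prior factorises out of the hazard likelihood, so the objective
uses a vectorised closed-form kernel (verified against summed peels).

Parameter recovery is the module's acceptance surface: at 200
fully-genotyped families per replicate (the documented minimal identifiable
design: seeded carrier lineages, complete ages, no correction — the genotype
prior is constant in the hazard parameters, so non-random genotypes cause no
bias), the three carrier log-hazard-ratios must fall within ±2 SE of truth
in at least 90% of replicate-coefficient pairs across 20 seeded replicates,
and the pooled bias t-statistics must be unremarkable at $\alpha = 0.01$.

# Numerical and design choices

- Ages are continuous 0-based years; intervals half-open $[0, t)$; the risk
  grid is integer ages 0–100.
- Genotypes have 3 states (0/1/2 copies) with exact Hardy–Weinberg founders;
  dominance collapses the phenotype likelihood to carrier = (copies ≥ 1).
  The de novo rate defaults to 0 and is configurable.
- Missing data sentinels: empty CSV fields; `0` (parents) and `-9` (ages) in
  the PED dialect.
- The reader refuses single-parent references (clinical files must be
  explicit); only the simulator may auto-complete parents.
- Ties in ROC cutoffs contribute half-concordance; operating points use
  score ≥ cutoff.
- Problem sizes in the verification suites (200 random pedigrees for the
  peeling oracle; $10^6$ Monte-Carlo draws for penetrance; $10^4$
  individuals for generator consistency; 50 × 40-family replicates for O/E
  coverage; 20 × 200-family replicates for recovery) were chosen once as the
  smallest sizes at which the corresponding asymptotics are comfortably in
  regime.

# Known limitations

- The CS and MPC components are linked heuristically in the generator (first
  event from CS, subsequent from MPC): there is no single joint model of
  cancer types *and* recurrence, mirroring the two-model structure of the
  underlying methodology.
- Carrier inference under the MPC default is mildly misspecified for
  cohorts generated with CS first events; the calibration test therefore
  scores with the generating model. Real-data carrier inference inherits
  whatever misspecification the chosen penetrance parameters carry.
- Variant-specific penetrance, polygenic modifiers, X-linkage,
  multi-allele models, and third-or-later primaries are out of scope.
- The proband-conditioning ascertainment correction is a simplification; it
  is exercised by tests but recovery fixtures fit unascertained cohorts.
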