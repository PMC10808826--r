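---
title: "Reduced-order portal venous hemodynamics and the ALWSS risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order portal venous hemodynamics and the ALWSS risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalwss)
```

## Motivation and scope

After splenectomy for portal hypertension with splenomegaly, the residual
splenic vein (SV) is ligated near the splenic hilum. The resulting
dead-end stump stagnates, and stagnation — quantified as wall area exposed
to low wall shear stress (WSS) — predisposes to portal venous system
thrombosis. The package's score is the **area of low wall shear stress
(ALWSS)**: the wall area of the whole postoperative portal venous surface
(stump included) whose WSS is *strictly below* a patient-specific
threshold set at 20% of the area-weighted space-averaged WSS of that same
surface. Areas are reported in cm² and stresses in Pa.

The package deliberately replaces two stages that normally require
clinical data: the 3D image-based CFD solve is replaced by a reduced-order
generalized-Newtonian tube-flow model on a parametric vessel network, and
the patient cohort is replaced by a synthetic one with a known logistic
risk model. Everything downstream of those substitutions — the score
definition, the thresholding, the evaluation statistics — is implemented
exactly as it would be applied to real data.

## Geometry model

The portal venous tree is a centerline network of five segments — portal
vein (PV), superior mesenteric vein (SMV), splenic vein (SV), left gastric
vein (LGV), inferior mesenteric vein (IMV) — each with a length, a
piecewise-linear radius profile on normalized arclength (0 = proximal
inflow end, 1 = distal end), and a tortuosity (centerline length over
endpoint chord). Junctions are point nodes; junction wall patches are
attributed to the parent segment. The three anatomical types encode where
the minor tributaries drain: Type 1 LGV→SV and IMV→SV, Type 2 LGV→PV and
IMV→SV, Type 3 LGV→SV and IMV→SMV.

**Attachment positions.** Tributaries that drain "to the SV" are attached
at the SV's distal end — the splenoportal confluence — while attachments
to the PV or SMV are interior (mid-length). This choice reflects the
anatomy (the LGV joins near the confluence) and has a structural
consequence the rest of the model relies on: after ligation the SV carries
no throughflow anywhere along its wall, so the whole stump is a genuine
dead end, while in Type 3 the distal half of the SMV carries the IMV flow
in addition to its own and its WSS rises accordingly.

**Virtual splenectomy** (`apply_splenectomy`) closes the SV into a stump
and changes nothing else, on the assumption that the operation does not
appreciably alter the morphology of the remaining veins. The
transformation is a pure state change; a property test asserts the
geometric fields are identical before and after.

**Descriptors.** The `distance_metric` of a segment is its endpoint
straight-line distance, `length / tortuosity`. This is the package's
convention for the scalar "distance" descriptor of a tortuous vessel,
chosen so that length and distance are independent descriptors related
through the tortuosity.

**Discretization.** The lateral surface is cut into axial strips of width
at most `dx` (default 1 mm); each strip's area is `2πR(x) · h` with `R`
evaluated at the strip center. The midpoint rule is exact for constant and
linearly tapered radius profiles, and the default `dx` keeps the area
error below 0.1% for any plausible vessel. Inlet/outlet caps and the
closed stump tip carry no lateral area and are not represented.

## Rheology and the tube-flow inversion

Blood is a Carreau shear-thinning fluid,
$$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
  \bigl[1+(\lambda\dot\gamma)^2\bigr]^{(n-1)/2},$$
with defaults $\mu_0 = 0.056$ Pa·s, $\mu_\infty = 0.00345$ Pa·s,
$\lambda = 3.313$ s, $n = 0.3568$ — a widely used four-parameter fit for
human blood, all configuration-overridable. Shear-thinning matters here
precisely because the post-splenectomy portal system flows slowly.

For steady fully developed flow in a circular tube the
Weissenberg–Rabinowitsch–Mooney (WRM) relation gives
$$Q(\tau_w) = \frac{\pi R^3}{\tau_w^3}
  \int_0^{\tau_w} \tau^2\,\dot\gamma(\tau)\,d\tau ,$$
with $\dot\gamma(\tau)$ the inverse of the constitutive law
$\tau = \mu(\dot\gamma)\dot\gamma$. Because a parabolic (or any fully
developed) inlet profile determines $\tau_w$ through the mean velocity
alone, the reduced model needs only the cross-sectional mean flow.

Numerically, the integral is transformed to shear-rate variables
($\tau = \tau(\dot\gamma)$, $d\tau = \tau'(\dot\gamma)d\dot\gamma$) so no
root find is nested inside the quadrature; `stats::integrate` is run at
relative tolerance $10^{-12}$. $Q(\tau_w)$ is strictly increasing, and the
root in $\tau_w$ is bracketed a priori by the two Newtonian envelopes
$4\mu_\infty Q/\pi R^3 \le \tau_w \le 4\mu_0 Q/\pi R^3$, so
`stats::uniroot` converges globally; the constitutive inversion is
finished with a few Newton steps to push the residual to machine
precision. Validation is against two closed forms: Poiseuille
($n = 1$, matched to $10^{-6}$ relative over a $10\times10$ $(Q,R)$ grid)
and the power-law tube solution
$\tau_w = K\bigl(Q(3n+1)/(n\pi R^3)\bigr)^n$ (matched to < 0.5% with the
Carreau law driven deep into its power-law regime).

## Boundary conditions and flow propagation

The total portal flow is computed from the ultrasound-measured PV velocity
and the PV diameter read from the geometry at PV mid-length,
$Q_{PV} = V_{PV}\,\pi (D_{PV}/2)^2$, and divided among the tributaries by
population-averaged proportions. The default split — SMV 0.40, SV 0.45,
LGV 0.05, IMV 0.10 — is an explicit, auditable stand-in for
population-averaged values in portal-hypertensive patients (the
splenomegalic spleen dominates); every cohort report records the split
used. The outlet pressure defaults to 3332.9 Pa (25 mmHg), typical of
portal hypertension.

**Postoperative inflow** is genuinely ambiguous: is the preoperative PV
velocity maintained after ligation, or does the splenic contribution
simply disappear? The package defaults to removing the SV share (the PV
then carries $Q_{SMV}+Q_{LGV}+Q_{IMV}$), since the ligated SV cannot
contribute inflow, and provides a `renormalize` mode that preserves the
preoperative total for sensitivity analysis. The two modes bracket the
physiological truth.

Flows propagate by summation: a segment's flow is its own inlet flow plus
every tributary attached strictly upstream, stepping up at each
attachment. Mass is conserved exactly at every junction by construction,
and a property test verifies balance to $10^{-12}$ relative on random
trees. Pressures integrate the fully developed momentum balance upstream
from the outlet, $\Delta P = 2\tau_w\,h/R$ per strip; the stump carries no
flow, so its tip node sits at the junction pressure.

**Stump WSS.** The default stump model is pure stasis: $\tau_w = 0$ on
every stump strip, consistent with low-WSS regions concentrating on the
ligated SV. An optional `decay` mode lets the parent vessel's junction WSS
penetrate the stump as $\tau_w(s) = \tau_{junction}\,e^{-s/D_{SV}}$ with
$s$ the distance from the junction, mimicking the finite penetration depth
of 3D recirculation; the decay length (one stump diameter) is a modeling
knob, not a measured value. Under the stasis default every positive
threshold captures the whole stump, so ALWSS is bounded below by the stump
lateral area $\pi D_{SV} L_{SV}$ — a per-patient hand-computable bound the
acceptance tests assert for every synthetic patient.

## The score

```{r score, eval = FALSE}
mean_wss <- space_averaged_wss(field)        # area-weighted, Pa
thr      <- low_wss_threshold(mean_wss)      # 0.2 * mean by default
alwss(field, thr)                            # cm^2, strict inequality
```

Ties at the threshold are excluded ("lower than" is strict), which also
fixes the degenerate case: with a zero threshold even fully stagnant
strips contribute nothing. The averaging surface is the whole
postoperative tree including the stump; the stump's zero-WSS area thus
pulls the mean (and the threshold) down as well as contributing low-WSS
area. ALWSS equality with an independent brute-force strip scan is
asserted exactly on randomized fields.

## Synthetic cohorts and the label model

Per-patient clinical data in this setting are not publicly deposited, so
cohorts are generated. Covariates are truncated normals chosen as
plausible for adult splenomegalic portal hypertension (not read from any
published figure): PV velocity 15 ± 4 cm/s on [6, 30]; PV diameter
13 ± 2 mm on [9, 18]; SV diameter 12 ± 3 mm on [7, 20]; SV length
100 ± 25 mm on [50, 180]; SV tortuosity 1.3 ± 0.2 on [1, 2]; spleen
maximum diameter 16 ± 3 cm on [11, 25] (descriptive only); anatomy type
probabilities (0.5, 0.3, 0.2). All are configuration-exposed. Veins not
sampled per patient (SMV, LGV, IMV dimensions, PV/SMV lengths) use fixed
defaults from `default_vessel_params()`.

Thrombosis labels are drawn from a logistic model on the *computed* ALWSS:
$P(\text{thrombosis}) = \text{logit}^{-1}(\beta_0 + \beta_1\,
\text{ALWSS})$. The default slope $\beta_1 = \ln 3 / 30 \approx 0.0366$
per cm² triples the odds per 30 cm² of low-WSS area; the intercept
$\beta_0 = -1.848$ was calibrated once, against the ALWSS distribution of
an $n = 4000$ default cohort (mean 38.95 cm²), to give ≈ 40% prevalence —
the prevalence of the published 15-patient cohort whose summary record
`fixture_cohort()` packages. Under these defaults the synthetic ALWSS
range (roughly 13–99 cm² at $n = 500$) brackets the clinically reported
range.

What the generator does *not* emulate is as important as what it does:
there is no junction recirculation beyond the optional decay model, no
pulsatility, no vessel compliance, no measurement error on the Doppler
velocity, and — most fundamentally — the labels are generated *from* the
score rather than observed independently of it. Passing tests therefore
demonstrate internal consistency of the pipeline and correctness of the
statistics, not clinical validity of ALWSS; the attainable AUC is a
property of the chosen $\beta_1$, not a clinical estimate.

## Statistical conventions

Published analyses rarely state their ROC conventions, and with small
cohorts the conventions matter, so the package fixes them explicitly:

* **AUC** is the trapezoidal integral of the empirical ROC over unique
  score thresholds. The accumulation is done in integer pair counts, so
  the result is *exactly* the Mann–Whitney statistic $U/(n_1 n_0)$ with
  ties weighted 0.5 — asserted as identity, not approximation, in the
  tests, and cross-checked against an independent ROC implementation.
* **Decision threshold**: candidates are midpoints between consecutive
  sorted unique scores plus $\pm\infty$; classification is positive when
  the score is *higher than* the threshold; the accuracy maximizer is
  returned with ties broken toward the smallest threshold.
* **Pearson correlation** uses the t-distribution p-value on $n-2$
  degrees of freedom (`stats::cor.test`), verified against a permutation
  test on small samples.
* **Mood's median test** splits each group at the pooled grand median
  into "above" versus "at or below" (ties go below) and applies the
  Pearson chi-square without continuity correction — the classical
  definition; implementations differ, so this is documented.

## Problem sizes and determinism

Validation uses cohorts of 200 (stump-bound property, per-patient) and
500 (AUC recovery against a $10^5$-draw Monte-Carlo oracle over the
cohort's score distribution), a 13-point SV-diameter sweep (8–20 mm), and
100-replicate property loops elsewhere; these sizes give stable statistics
at interactive runtimes. Every random draw flows from a single integer
seed — cohort covariates and label noise use separate derived streams —
so any result in the package, including every output file byte, is
reproducible from configuration plus seed. Output files embed the package
version and an MD5 hash of the configuration.

## Known limitations

Segment-wise fully developed flow ignores entrance lengths, junction
secondary flows, and wall compliance; the stump models bracket, but do not
resolve, the 3D recirculation physics; the flow split and Carreau
constants are population defaults, not patient-specific; and the
15-patient summary fixture carries only marginal counts, so no per-patient
comparison against published geometry is possible. The package is a
laboratory for the scoring-and-evaluation methodology, not a clinical
prediction tool.
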