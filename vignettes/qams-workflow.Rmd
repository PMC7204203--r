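---
title: "Single-marker quantification of five longan-leaf markers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification of five longan-leaf markers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
```

## The problem

Quality control of herbal material usually means quantifying several
marker compounds, each against its own reference standard. Standards are
expensive and some are hard to source, so the QAMS strategy
(*quantitative analysis of multi-components by a single marker*) runs a
standard for only one component — the internal reference — and quantifies
the rest through pre-established **relative correction factors** (RCFs)
that relate each analyte's detector response per unit mass to the
reference's. qamskit implements this workflow for the five flavonoid and
phenolic markers of longan (*Dimocarpus longan*) leaves — ethyl gallate
(C1), astragalin (C2), quercetin (C3, the internal reference), luteolin
(C4) and kaempferol (C5) — on narrow-bore (UPLC) and conventional (HPLC)
reversed-phase systems.

## The model

**Calibration.** Within each component's linear range the detector
response is affine in injected mass, $A = k\,m + b$ ($A$ area counts, $m$
µg). Curves are fitted by ordinary least squares *with* a free
intercept, because the reference curves all carry intercepts;
forcing the origin would fold the intercept into the slope and bias
small-mass inversions. Linearity is accepted at Pearson $r \ge 0.9996$,
the weakest value among the reference curves.

**RCFs, two routes.** With subscript $s$ the internal reference and $i$
an analyte,

* multipoint: $f_{s/i} = \dfrac{m_s A_i}{m_i A_s}$, evaluated at each
  injection level of a common working solution and summarized by mean
  and RSD;
* slope: $f_{s/i} = k_i / k_s$, the ratio of calibration slopes.

Because $A \approx k m$, the two coincide exactly when intercepts and
noise vanish — a property the test suite asserts at $10^{-12}$. With real
intercepts the multipoint values drift systematically with injection
level (the intercept's relative weight shrinks as mass grows), which is
exactly the level-dependence visible in per-volume RCF tables; the drift
direction and magnitude reproduced by the noiseless generator match the
reference means to the third decimal.

**Quantification.** Three routes are carried side by side:

* ESM: invert the analyte's own curve, $m_i = (A_i - b_i)/k_i$;
* QAMS1: take the reference mass from the reference's curve and apply
  the multipoint-mean factor, $m_i = m_s A_i / (f_{s/i} A_s)$;
* QAMS2: $m_i = A_i / (k_s f_{s/i})$, which algebraically equals
  $A_i / k_i$ — ESM with the intercept dropped. Hence QAMS2 − ESM is the
  constant $b_i/k_i$ per injection for every component, a diagnostic the
  tests assert and the agreement analysis makes visible as a constant
  offset at correlation 1.

Contents convert as
$c\,[\mathrm{mg/g}] = m_{inj}\,V_{extract} / (V_{inj}\, M_{powder})$
with $m_{inj}$ in µg, volumes in mL and µL, mass in g (the unit factors
cancel since µg/µL = mg/mL). Replicate injections (3 by default) are
averaged after conversion.

**Peak location.** Unknown peaks are identified by relative retention
time (RRT), $R_t = t_i / t_s$, which is invariant under any uniform
rescaling of run time and therefore transfers across systems. Expected
RRTs default to per-instrument-class means because the first-eluting
marker's RRT shifts by several percent between UPLC and HPLC while the
others move by ~1 %. The matching tolerance is ±2 %: comfortably above
the observed cross-system spread of the well-behaved markers, far below
the smallest inter-component gap (~9 %). When no retention-time hint is
given, the reference peak is chosen as the peak whose adoption minimizes
the total relative deviation of the best analyte matches; two candidate
peaks inside one tolerance window raise an ambiguity error rather than a
silent choice.

**Method transfer.** Moving a method between columns uses the standard
geometric rules: flow scales with bore cross-section
($\nu_t = \nu_o d_t^2/d_o^2$), injection volume with column volume
($V^{inj}_t = V^{inj}_o V^{col}_t/V^{col}_o$), and gradient breakpoints
by $(V^{col}_t/V^{col}_o)(\nu_o/\nu_t)$ so each segment delivers the
same number of column volumes. Column volume is taken proportional to
$d^2 L$; porosity cancels in every ratio. Transfers compose and
round-trip exactly. Published bench conditions are typically fine-tuned
after such scaling, so transferred times are a starting point, not a
reproduction claim; indeed no single printed column geometry reconciles
the reference assay's 5× flow and 10× injection factors, which is why
geometry is user input here (the bundled conventional-bore default is
4.6 × 150 mm).

## What the generator emulates — and what it does not

The synthetic module stands in for the instrument. It emulates:

* affine response with the reference slope/intercept per (component,
  system) — so noiseless series reproduce those constants to machine
  precision when re-fitted;
* the working-solution design: one mixed standard (245.2, 108.0, 416.0,
  46.0, 72.2 µg/mL for C1–C5) injected at 0.2–1.0 µL (UPLC) or 2–10 µL
  (HPLC), spanning each stated linear range;
* multiplicative area noise, normal with sd = RSD·mean truncated at 0,
  defaulting to 0.3 % (UPLC) and 1.0 % (HPLC) — the instruments'
  repeated-injection precision scales; heavier tails are never
  characterized in the source data, so none are modelled;
* retention as internal-reference time × RRT plus independent normal
  jitter (defaults 0.02 / 0.08 min). Absolute reference times (11 min
  UPLC, 26 min HPLC) are free parameters chosen to put all peaks inside
  the printed gradient windows with the detection-wavelength switch
  between the first and second peak; no retention physics is modelled
  because none is recoverable from the source;
* true contents per region defaulting to the ten-region reference
  determinations (0.1–3.5 mg/g), extracted at 4.0 g per 20 mL;
* rendered chromatograms as Gaussians whose integrals equal the peak
  areas, over a drifting baseline — no exponentially-modified tailing,
  co-elution or detector saturation.

Passing tests therefore demonstrate *internal* consistency — that the
estimators recover what the generative model encodes, at the noise the
instruments report — not robustness to matrix effects, drifting response
factors or asymmetric peaks, which real assays must re-validate.

One caveat on retention jitter: the generator draws it independently per
peak. Real run-to-run retention drift is strongly correlated across
peaks (flow and temperature move everything together), and RRT cancels
correlated drift exactly — that is its whole point. With *independent*
jitter at 1 % of the run, an RRT deviation has sd ≈ 1.4 %, so a ±2 %
window cannot give error-free matching; perfect assignment under the
independent-jitter model is only guaranteed at jitter a few tenths of a
percent, which is where the assignment property is tested (0.3 %, the
scale of routine retention precision). Under correlated drift the
assignment would tolerate far larger excursions.

## Numerical choices

* RSD uses the sample (n−1) standard deviation throughout; recomputed
  cross-condition dispersions match reported ones only under this
  convention (2.27 % vs a stated 2.28 % bound, the residue being the
  rounding of the printed inputs).
* Report rounding is half-away-from-zero to 3 decimals
  (`round_half_up()`), the convention of analytical reporting; base R's
  round-half-even would turn 0.8125 into 0.812.
* Pearson significance uses the exact $t$ transform
  ($t = r\sqrt{(n-2)/(1-r^2)}$, two-tailed), the conventional reading of
  a two-tailed 0.01 level at $n = 10$ regions.
* ESM inversion never rejects: masses outside the linear range
  (including negatives when $A < b$) are returned with an
  `out_of_range` flag, because transparency beats silent clipping near
  the detection limit and the reference workflow quantifies real
  samples without stating range enforcement.
* The stated linear ranges are printed rounded, so the generator's
  range check uses a 0.5 % relative tolerance (the top UPLC level,
  0.2452 µg, must not trip a warning against a range printed as
  0.245 µg).
* Integration sets peak boundaries at flanking valleys (or signal
  edges) and subtracts the straight line joining them; quadrature is
  trapezoidal. At ≥10 samples per peak sd (enforced) this recovers
  isolated Gaussian areas within 0.5 %.
* The working-solution concentrations are taken as authoritative where
  the stock-dilution arithmetic cannot reproduce them; the dilution
  narrative is not reconciled.

## Problem sizes

The shipped analyses and tests run: 6-level × 5-component series per
instrument; ten regions × 3 replicate injections per instrument; 400
seeded replicates for the assignment-accuracy property; 30 seeded
9-portion spike-recovery experiments; 200 draws for the noise-RSD
calibration check. These sizes give Monte-Carlo standard errors well
inside the asserted bands while keeping the default suite in the
tens-of-seconds range.

## Known limitations

* RCF durability across *real* instruments is supported here by the
  published nine-condition dispersion table, not by simulating new
  hardware; the generator has no mechanism for condition-dependent
  response.
* Absolute contents of real leaf samples are not reproducible from the
  published record (no raw chromatograms are deposited); they enter
  only as generator defaults and correlation inputs.
* Detection-wavelength switching is carried as metadata, not physics —
  per-component response slopes absorb the wavelength choice.
* Peak areas are arbitrary detector counts; nothing maps them to
  mAU·s.
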