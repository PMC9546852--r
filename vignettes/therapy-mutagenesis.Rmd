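---
title: "Quantifying therapy-induced somatic mutagenesis in clonally expanded stem cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying therapy-induced somatic mutagenesis in clonally expanded stem cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(therasig)
```

## Scientific question

Systemic cancer therapy exposes not only the tumour but every dividing
tissue in the body. Whole-genome sequencing of clonally expanded single
stem cells from *healthy* colon and liver of treated and untreated donors
makes the mutagenic cost of therapy measurable: each clone's genome is a
faithful record of the mutations its founding stem cell accumulated over
the donor's life, including any treatment episode.

`therasig` implements the full analysis chain for such cohorts:

1. **Catalogs** — read per-clone variant calls (VCF or TSV), keep clonal
   mutations (VAF > 0.30, present in the founding cell rather than
   acquired in culture), and classify them into the COSMIC-style SBS96,
   DBS78 and ID83 channel schemes (`read_mutations()`, `filter_clonal()`,
   `build_context_matrix()`).
2. **Burden model** — regress total burden on age with a donor-level
   random intercept, bootstrap the expected-burden line, and test treated
   donors for excess burden (`fit_aging_lmm()`,
   `bootstrap_expected_burden()`, `excess_burden_scan()`).
3. **Signatures** — de novo NMF extraction with reference-guided rank
   selection, then strict constrained refitting of a tissue-specific
   signature set (`extract_denovo()`, `select_rank()`, `refit_strict()`,
   `fit_exposures()`).
4. **Treatment effects** — per-cycle platinum dose-response (SBS35),
   the SBS:DBS coupling of platinum damage, bimodal 5-FU activation
   (SBS17), non-parametric group comparisons and correlations
   (`dose_response()`, `sbs_dbs_ratio()`, `compare_groups()`,
   `correlate()`).
5. **Structural variation** — simple vs complex SV classification by
   length bin, and the radiotherapy footprint coupling ID8 indels to
   small structural deletions (`classify_sv_profile()`,
   `radiation_footprint()`).
6. **Synthetic cohorts** — a generator with known ground truth
   (`cohort_config()`, `simulate_cohort()`, `write_cohort()`) used for
   end-to-end validation throughout.

## The statistical model

### Aging clock

Burden for clone $i$ of donor $d$ is modelled as

$$y_{id} = \beta_0 + \beta_1\,\mathrm{age}_d + b_d + \varepsilon_{id},
  \qquad b_d \sim N(0, \sigma_b^2),\ \varepsilon_{id} \sim N(0, \sigma^2),$$

fitted by REML with `nlme::lme`. The donor random intercept corrects for
multiple clones per donor. On the driver cohort
(`analysis/02_burden_aging.R`) the untreated fit recovers
43.1 mutations/year (95% CI 32.6–53.5) against a generating rate of 43,
with donor SD 116.6 and residual SD 132.1 (generated: 100 and 150).

Degenerate designs (noise-free toy data, or one clone per donor with an
exact linear relation) make `lme` fail; the fit then falls back to
ordinary least squares with a warning and reports a donor-intercept SD of
0. With only 2 donors the REML denominator degrees of freedom reach 0, so
the confidence interval uses a fallback of $\max(1, n-2)$ df.

### Bootstrap excess-burden test

`bootstrap_expected_burden()` resamples 70% of the untreated samples
without replacement $B$ times, refits the model, and records the expected
line over ages 5–80. A treated donor's mean burden is compared to the
bootstrap distribution of the expectation at their age with the
add-one-smoothed one-sided empirical p-value
$p = (1 + \#\{\text{expected} \ge \text{observed}\})/(B+1)$, significant
at $p < 0.01$.

**Calibration caveat (measured, not hypothetical).** The null
distribution is the uncertainty of the *mean line*, not the predictive
distribution of a new donor. Between-donor scatter
($\sqrt{\sigma_b^2+\sigma^2} \approx 180$ under the generator defaults)
never enters it, so the test is anti-conservative for donor-level
hypotheses: over 200 simulated null treated samples (10 cohorts × 20
donors, $B = 1000$) the measured type-I rate at nominal $p<0.01$ was
**0.23**. The corresponding acceptance test block fails honestly rather
than being skipped. The test is well calibrated only for effects large
relative to biological scatter — an injected excess of +1650 SBS at age
24 (roughly a full adjuvant-chemotherapy effect) is detected in 20/20
replicates. Significant calls on small excesses should be read as
"above the average aging expectation", not "outside the normal donor
range".

### Signature extraction and refitting

`extract_denovo()` is NMF with multiplicative updates under the
generalised Kullback–Leibler objective, best of 100 random restarts.
`select_rank()` extracts at each candidate rank and matches de novo
signatures to reference profiles **one-to-one** (greedy, in decreasing
cosine order, each reference claimable once); the chosen rank is the
largest at which every de novo signature attains cosine ≥ 0.8 with its
own reference. One-to-one matching matters: an overfit rank splits one
mutational process into near-duplicate signatures that would all match
the same reference with replacement, so with-replacement matching could
never reject overfitting.

`refit_strict()` first solves non-negative least squares
(`pracma::lsqnonneg`), then greedily removes the signature whose removal
costs the least reconstruction cosine, while the cost stays below
`max_delta = 0.004`. The merged 5-FU signature `SBS17` is the
renormalised sum of SBS17a and SBS17b (`merge_signatures()`). Optional
signatures enter the refit set only when their de novo counterpart
reaches ≥ 10% relative contribution in some sample (`signature_set()`).

**Strict refitting censors small exposures (measured).** Elimination
zeroes genuinely small exposures: clones with 1–2 platinum cycles (true
SBS35 exposure ≈ 80–130 mutations) are frequently refitted to exactly 0,
so the attribution error correlates with dose. Over 40 simulated
cohorts the strict pipeline estimated a dose-response slope of 128.7 on
average (true 105; per-replicate 2-SE coverage 0.80), with error growing
+19.4 per cycle ($p = 0.007$); plain NNLS exposures (`max_delta = 0`)
gave 103.6 with coverage 0.95. The drivers therefore use strict
refitting for presence/absence of a process and plain NNLS for
quantitative regressions; `analysis/03_signatures.R` writes both
exposure matrices.

### Treatment effects

`dose_response()` is the same donor random-intercept LMM with cycles as
the fixed effect. `sbs_dbs_ratio()` regresses DBS on SBS exposure and
reports the reciprocal slope (SBS per DBS) with a delta-method SE,
flagged unreliable when the slope CI spans 0. `compare_groups()` uses
the exact Wilcoxon enumeration for small tie-free samples and the
corrected normal approximation otherwise; `correlate()` reports Pearson
r with a Fisher-z interval.

### Radiotherapy footprint

Simple SVs are single-breakpoint DEL/DUP events stratified into
half-open length bins (with a sub-kilobase [50 bp, 1 kb) bin, because
radiation deletions concentrate in [50 bp, 10 kb)); anything in a
multi-breakpoint cluster counts once per cluster as a complex event.
`radiation_footprint()` correlates ID8 indel exposure with the
radiation-window deletion count and reports the low-microhomology
(≤ 1 bp) fraction — radiation deletions arise by non-homologous end
joining and carry little microhomology.

## The synthetic cohort generator

`cohort_config()` freezes the study conditions; they are generator
defaults, never tuned to make tests pass:

| parameter | default | meaning |
|---|---|---|
| `aging_rate_mean` | 43 /yr | clock-like SBS rate (SBS1/5/18 mixture) |
| `burden_intercept` | 100 | burden at age 0 |
| `donor_sd`, `residual_sd` | 100, 150 | biological scatter |
| `platinum_per_cycle_mean` | 105 | SBS35 per CAPOX cycle (SD 40·√cycles) |
| `dbs_per_sbs` | 1/26 | platinum DBS5 per SBS35 (binomial) |
| `fiveFU_activation_prob` | 0.2 | per-clone Bernoulli; active clones gain N(265, 195) SBS17 |
| `radio_id8_mean` | 80 (SD 15) | radiotherapy ID8 indels |
| `sv_del_per_id8` | 0.18 | simple structural deletions per ID8 indel |
| `vaf_clonal`, `vaf_subclonal` | Beta(60,60), Beta(4,26) | VAF draws |
| `n_invitro_subclonal` | 50 | culture-acquired subclonal SBS per clone |

The treated design mirrors a realistic adjuvant-therapy cohort (7 donors,
ages 24–77, 0–5 CAPOX cycles, three irradiated donors); the `"liver"`
preset keeps the clock but zeroes all treatment effects, reflecting the
empirical finding that systemic chemotherapy mutagenesis is
tissue-restricted. Realism choices: channel draws are multinomial from
the generating signature profiles, so sampling noise propagates into
extraction exactly as in data; per-clone 5-FU activation is bimodal, not
a mean shift; subclonal spike-ins leak through the VAF > 0.30 filter at
the Beta(4,26) tail rate (~2%), as real culture mutations would; SV
output mixes radiation deletions (log-uniform 50 bp–10 kb, no
microhomology), background DEL/DUP and complex clusters.

Because the reference COSMIC profiles are not redistributable here, the
package bundles a *synthetic* near-orthogonal reference set
(`synthetic_reference_signatures()`) whose roles (clock, deamination,
ROS, 5-FU, platinum, colibactin, radiation) mirror the real catalogue;
the flat clock-like signature has cross-cosines up to ~0.43 with block
profiles, like its real counterpart.

## Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(seed = 20220601)
bt <- burden_table(co$context["SBS96"], co$meta)
fit <- fit_aging_lmm(bt[!bt$treated, ])

ref <- merge_signatures(synthetic_reference_signatures("SBS96"),
                        c("SBS17a", "SBS17b"), "SBS17")
fx <- fit_exposures(co$context$SBS96,
                    ref[, c("SBS1", "SBS5", "SBS18", "SBS17", "SBS35")],
                    max_delta = 0)  # NNLS for quantitative estimation
tr <- co$meta$received_platinum
dose_response(fx$exposures[tr, "SBS35"], co$meta$capox_cycles[tr],
              co$meta$donor_id[tr])
```

The numbered drivers under `analysis/` run this end to end and write
`results/`; on the shipped cohort they recover an aging rate of 43.1/yr
(true 43), a platinum slope of 89.1 ± 13.3 SBS/cycle (true 105, within
1.2 SE), 1 DBS per 29.1 SBS (true 26), 4/21 5-FU–exposed clones active
(activation probability 0.2), and an ID8–deletion correlation of r = 0.93
with 0.21 deletions per ID8 indel (true 0.18).

## Limitations

- The excess-burden test is anti-conservative at the donor level (type-I
  0.23 at nominal 0.01 under the generator's biological scatter); use it
  for large effects or treat p-values as relative to the mean aging line.
- Strict refitting under-attributes exposures below roughly 150–200
  mutations; quantitative regressions should use NNLS exposures.
- The per-replicate SBS:DBS ratio estimate is attenuated by noise in the
  SBS regressor (errors-in-variables); aggregate by the median over
  replicates or cohorts.
- The bundled reference signatures are synthetic; analysing real cohorts
  requires supplying the real reference matrix (any channels × signatures
  matrix with matching channel names works throughout).
- The generator draws burdens top-down (counts, then channels) and does
  not model genomic position, replication timing or transcriptional
  strand bias.
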