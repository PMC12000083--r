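---
title: "Aligning tibio-femoral reference frames across marker sets with reframekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning tibio-femoral reference frames across marker sets with reframekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reframekin)
```

## The problem

Optical gait analysis estimates knee kinematics from retroreflective
markers, and every laboratory's marker set (Plug-in-Gait and its wand or
KAD variants, medial-marker sets, cylinder-fit sets, ...) implies its own
femoral and tibial segment frames.  Two labs recording the *same* knee
motion therefore report visibly different ab/adduction and
internal/external rotation curves: a misalignment of only a few degrees
between the assumed and functional flexion axes leaks the large flexion
signal into the small out-of-sagittal channels (kinematic crosstalk).
`reframekin` implements the reference frame alignment method (REFRAME) for
the rotational tibio-femoral case: it finds *constant* re-orientations of
the femoral and tibial frames that minimise a weighted crosstalk cost, so
that kinematic signals from differently defined frame conventions become
directly comparable.

## Conventions

Segment frames are right-handed with x pointing laterally, y anteriorly
and z proximally.  The joint rotation is the tibia relative to the femur,
\(T = R_{fem}^T R_{tib}\), decomposed as an intrinsic XYZ Cardan sequence:
\(\alpha_x\) (extension positive, so flexion is negative), \(\beta_y\)
(adduction positive) and \(\gamma_z\) (internal tibial rotation positive).
For display, flexion is sign-flipped to positive
(`to_clinical_display()`); stored data keep the rotation convention.  Left
knees are mirrored into the right-knee convention by inverting the
mediolateral coordinate; on orientations this is the conjugation
\(R \mapsto M R M\) with \(M = \mathrm{diag}(-1,1,1)\), which preserves
flexion and negates the other two angles.  All interfaces use degrees;
trigonometry is done in radians internally.

Orientations whose \(\beta_y\) comes within the gimbal tolerance of 90°
(\(|\cos\beta_y| < 10^{-7}\)) raise a structured degenerate-orientation
condition carrying the conventional resolution (\(\gamma_z = 0\), the free
rotation folded into \(\alpha_x\)).  Knee data never approach 90°
ab/adduction, so any hit indicates corrupt input rather than a case to
silently resolve.

## The REFRAME cost and optimizer

The corrections post-multiply each segment's orientation — they re-orient
the frame relative to the segment it represents — giving the corrected
joint rotation \(T'_t = R_{femcorr}^T\, T_t\, R_{tibcorr}\) with the same
constant corrections over the whole series.  The cost is the weighted sum

\[
J = w_{add}\,\mathrm{RMS}(\beta_y) + w_{introt}\,\mathrm{RMS}(\gamma_z)
  + w_{flex}\,\mathrm{RMSE}(\alpha_x,\ \alpha_x^{ref}),
\]

with defaults \(w_{add} = w_{introt} = 1\) and \(w_{flex} = 0.2\); the
reference flexion is the reference marker set's raw flexion (default label
`"PiG"`; the reference set is optimized against its own raw flexion, so
its column of results stays meaningful).  A weighted *sum* of per-channel
terms is used (not the RMS of pooled residuals) because the weights are
stated per criterion; the weights are configurable for sensitivity checks.

The corrections are parameterised as two Cardan triplets (six angles) and
minimised with a deterministic derivative-free simplex search
(Nelder–Mead via `stats::optim`), started from identity plus the best
points of a fixed coarse lattice (±12° in steps of 6°) over the femoral
and tibial y/z angles to escape local minima under large offsets, and
finished by a restarted simplex at the target tolerance (`tol = 1e-8`
relative cost change, at most 10,000 evaluations per search).  The search
is fully deterministic; `cost_final <= cost_initial` always holds because
identity is among the starts.  Restricted problems (any subset of the six
angles) are supported via the `free` argument, which is also how the
exhaustive grid-search oracle in the tests cross-checks the optimizer.

### The femoral flexion-axis restriction

Transformations of the femoral frame about the flexion (x) axis must be
restricted, and implementing the optimizer shows exactly why: conjugating
both frames by a common x-rotation, \(R_{femcorr} \to R_{femcorr}R_x(\varphi)\),
\(R_{tibcorr} \to R_{tibcorr}R_x(\varphi)\), maps \(T'_t \to
R_x(-\varphi) T'_t R_x(\varphi)\), which leaves a crosstalk-free (pure
flexion) series — and hence every term of \(J\) — unchanged.  The
corrections are therefore only identified up to this one-parameter family,
and an unregularised simplex drifts tens of degrees along the flat valley
without converging.  `femoral_x_mode` offers three semantics:

* `"penalized"` (default): the femoral x angle stays free but a weak
  explicit quadratic penalty \(10^{-4}\,\mathrm{fem}_x^2\) (degrees) pins
  the gauge deterministically at the minimal-\(|\mathrm{fem}_x|\) member of
  the family.  The penalty adds at most a few hundredths of a degree for
  realistic corrections and still allows genuinely non-zero femoral x
  corrections when the data demand them.
* `"locked"`: femoral x held at exactly zero (five free angles).
* `"bounded"`: \(|\mathrm{fem}_x|\) constrained to a limit.

Because of the same gauge freedom, parameter recovery on crosstalk-free
data is assessed on the *net* residual
\((R_{mf} R_{femcorr})^T (R_{mt} R_{tibcorr})\) against identity, which is
gauge-invariant; the individual corrections may legitimately differ from
the inverses of the imposed misalignments by a common x-rotation.

## Comparison metrics and aggregation

`rmse()`/`rms()` operate on 101-point cycle-normalized waveforms per trial
(RMS is the RMSE against constant zero).  `pairwise_rmse_table()` computes
per-trial RMSE for every marker-set pair and channel and aggregates at two
levels: per knee across its trials, and overall across all trials and
knees, with the sample SD (n − 1); overall aggregation pools trial-level
values rather than averaging knee means first.  RMSE is symmetric, so the
table stores one row per unordered pair with a stage tag; the triangular
grid layout of printed tables is presentation, handled by
`format.comparison_table()`.  Corrections are fitted once per knee and
marker set on all of that knee's trials concatenated after normalization
(per-trial fits remain available by passing a single trial to
`reframe()`).

## What the synthetic study emulates — and what it does not

`build_study()` generates the study shape: 15 subjects × 2 knees × 9
steps at 200 Hz (cycle duration 1.1 s), observed through five marker sets
that differ by constant frame misorientations.  The ground-truth flexion
curve is a closed-form 8-harmonic trig polynomial (an early-stance bump
peaking ~18° at 20% of the cycle and a swing bump peaking ~60° at 77%),
exactly zero at 0% of the cycle; ab/adduction is a small double-bump
(second-harmonic) excursion of 1.5° amplitude and int/external rotation a
2.5° first-harmonic-dominated excursion, both zero at 0%.  The two
out-of-sagittal shapes are deliberately decorrelated: if they shared a
waveform shape, a constant frame rotation about the flexion axis could
collapse one true channel into the other, and the fitted corrections
would reflect that collapse instead of the imposed frame misalignments.  Per-trial variability rescales channel amplitudes (5% SD by
default).  The preset misalignments carry longitudinal offsets from −2°
to +14° and x/y offsets of at most 2.5°, patterned on the magnitudes
reported for real marker sets; they are configuration, not claims about
any real system.  Keeping x/y offsets to a few degrees keeps the
second-order Cardan cross terms (≈ \(\tfrac12 x y\)) below 0.1°, so the
int/external rotation offset read at the neutral 0%-cycle sample matches
the imposed net z-misalignment difference to well within 0.2°.

Soft-tissue artifact is modelled as a zero-mean time-varying rotation of
each frame whose amplitude couples to instantaneous flexion (plus a small
smooth random component), emulating swing-phase crosstalk; it is
deliberately simple, switchable off, and per-set scalable (the
cylinder-fit style set gets 0.2× by default).  Left knees are generated in
left-side coordinates and must pass through `mirror_left_to_right()`,
exercising the side convention end to end.

Passing tests on this generator demonstrates correctness of the frame
algebra, the optimizer and the aggregation — it does **not** demonstrate
that constant corrections fully reconcile real marker sets, because real
soft-tissue artifact makes the inter-frame misorientation time-varying,
marker sets disagree in ways beyond frame orientation, and event detection
and translational effects are outside this package's scope.

## Numerical choices

* Gimbal tolerance \(10^{-7}\) on \(|\cos\beta_y|\); resolution
  \(\gamma_z = 0\).
* Per-channel unwrapping of \(\alpha_x\) and \(\gamma_z\) with a 180°
  jump threshold (gait signals are smooth; this prevents spurious RMSE
  from branch flips).  \(\beta_y\) lives on [−90°, 90°] by construction.
* 101 samples per normalized cycle (0–100% inclusive), linear
  interpolation.
* Optimizer: identity + up to 3 lattice starts, stage-one simplex at
  relative tolerance \(10^{-7}\) (capped at 2,000 evaluations), polish at
  \(10^{-8}\); multistart lattice ±12° in 6° steps.
* Problem sizes in the shipped tests and acceptance script: the full
  default study (5 × 30 × 9, 150 fits), 50 random-misalignment recovery
  knees, a 61 × 61 grid oracle and 1,000-case rotation property sweeps —
  sizes chosen so the whole suite completes in minutes on one core while
  still exercising the complete design.

## Known limitations

Only rotational kinematics are treated (no frame-origin optimization);
corrections are constant per fit, so time-varying soft-tissue effects are
reduced but not removed; marker-to-frame construction for specific marker
sets is out of scope (the package starts from segment poses or joint
angles); and inferential statistics beyond mean ± SD are not provided.
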