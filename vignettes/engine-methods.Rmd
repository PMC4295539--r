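---
title: "The aqueduct engine: design, model, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The aqueduct engine: design, model, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqueduct)
```

## The problem

Neuroimaging analyses are long chains of stages — import, motion
correction, quality control, smoothing, within-subject model fitting,
group statistics — applied to data organized hierarchically (a study of
subjects, each with sessions). Hand-managed chains are error-prone: a
changed parameter or an added subject silently leaves stale intermediate
results behind, and parallelism has to be bolted on per analysis.

`aqueduct` separates three concerns:

* **what** to do — module interfaces and tasklists, declarative documents;
* **which data** to do it on — a study description;
* **how and when** to run — the engine: dependency wiring, incremental
  scheduling, parallel dispatch, provenance.

## Modules, streams, domains

A *module interface* declares a stage's domain, settings with defaults,
and named input/output *streams* (`epi`, `structural`,
`realignment_parameter`, ...). Stream names are deliberately unspecific
about processing state: the `epi` stream may be motion-corrected or
smoothed; downstream modules do not need to care. The *domain* states the
granularity of instantiation: `study` (once), `subject` (per subject),
`session` (per subject–session). The domain hierarchy is a tree rooted at
`study`; further session-like leaves (e.g. `diffusion_session`) can be
registered, and a study description then supplies their per-subject
enumerators.

Pipelines are wired automatically: each consumed stream comes from the
*nearest preceding* stage that declares it as an output, so a QC stage in
the middle of an EPI chain is transparently skipped by the search. A
fully qualified reference `module.stream` on an invocation overrides this
default when an earlier stage's output is wanted. Unconnected streams are
reported when the plan is built, before anything runs.

At the instance level, edges respect the hierarchy: equal domains connect
matching coordinates; an ancestor-domain source (subject-level structural
into session-level work) feeds each of its descendants; a
descendant-domain source *fans in* (per-subject contrast maps into a
study-level test). Sideways links (between sessions, or between
session-like sibling domains) never exist; they are rejected when the map
is built. The test suite checks the whole map against a brute-force
oracle that scans all stage pairs × instance pairs with independently
coded rules.

## Incremental execution

Each completed instance leaves a flag file `done_<module>_<index>` in its
directory. The flag is not empty: it records a snapshot of the input
digests (MD5 of every placed input file, per stream) the instance ran
with, which turns "have my inputs changed?" into a local, testable
predicate. An instance is *done* iff its flag exists and the current
upstream digests equal the snapshot. Flags are written atomically
(write-temp-then-rename), so a crash mid-write cannot fake completion.

Invalidation is eager: when the plan is built, every stale instance's
flag is deleted together with the flags of its entire
downstream-reachable set (deciding staleness lazily at dispatch would
give the same executions but would leave misleading flags on disk in the
interim). Garbage-collected payloads are a separate case: their
instances stay *done* (the digests survive in the manifests) until a
pending dependent actually needs the deleted files, at which point
exactly the producers required are re-run.

Two backends share all of this logic. `localsingle` steps through
instances in topological order; `parallel` dispatches every instance
whose dependencies are complete to an in-process fork pool, so one
subject's smoothing starts the moment that subject's normalization
finished, regardless of other subjects. Cluster submission is an
extension point that would honor the interfaces' resource estimates; it
is not implemented here. For deterministic modules the two backends
produce identical output trees, which the suite checks by digest
comparison.

A failed instance blocks its dependents; independent subtrees keep
running (most useful work per debugging round). A `fail_fast` switch
stops at the first failure instead.

## Data placement

The engine, not the module, moves data. Inputs are materialized (hard
link with copy fallback; copying is configurable) inside the instance's
own directory — a module that did not request a stream simply does not
have it, so it cannot accidentally be used. Fan-in inputs are placed in
per-source subdirectories (`src_S1_sess2/...`) because several sources
may carry identically named files; the single-directory layout of the
equal/ancestor cases would collide. Outputs must be declared: files a
module writes but does not register under a stream are never passed on,
and writing outside the instance directory is an error. Because placed
inputs may be hard links, module outputs replace files by
write-temp-then-rename — truncating a linked file in place would reach
through the inode and corrupt the upstream instance's registered output
(the suite asserts every registered digest still matches the bytes on
disk after a full run).

## Branches

A tasklist may fork into alternatives that share the upstream trunk
(e.g. smoothing at 8 vs 12 mm). Expansion flattens alternatives in
declaration order; a module appearing in both alternatives gets
occurrence indices `_00001`, `_00002`, so the directories never collide
even without suffixes, and each alternative's `analysisid_suffix`
relocates its stages into a sibling analysis directory. During stream
resolution a branch stage sees its own alternative's earlier stages and
the trunk before the branch point — never a sibling branch. Trunk
instances execute once and are shared. One open syntactic point: the
branch element names (`<branch>`, `<alternative analysisid_suffix=...>`)
are this package's own, chosen to carry exactly the information the
semantics need (a suffix per alternative over a shared trunk).
Initialisation modules are assumed not to declare streams; they run
unconditionally on every invocation.

Stages placed on the trunk *after* a branch resolve their streams against
the trunk only; a stage that needs branch outputs belongs inside the
alternatives.

## Parameters

Merged settings come from three sources with increasing precedence:
interface defaults, per-invocation tasklist settings, user overrides
(`set_parameter()` for general namespaces such as
`acq_details.numdummies`, `set_tasksetting()` per stage). Defaults
documents may include a base document (W3C XInclude) and redefine a few
elements in a `<local>` section — a site file states only what differs.
Repeated modules are addressed as `name` (first occurrence) and
`name_0000k` (later ones); the printed convention only ever shows unique
modules, so a deterministic disambiguation was needed. The merged set is
stored whole in the provenance record, and merging an already-merged set
with no overrides is the identity. XML carries text, so decimal-looking
strings become numbers and `true`/`false` become booleans on parse.

## The first-level model

Events are specified in *scans* (`add_event`: onsets need not be sorted;
a scalar duration broadcasts; converting from seconds is the caller's
job). Each event yields a boxcar regressor on the scan grid with
fractional onsets/durations accumulating proportionally into overlapped
scans; optionally the boxcar is convolved with a canonical double-gamma
response (positive lobe gamma(6, 1), undershoot gamma(16, 1) scaled by
1/6, sampled at the nominal TR, unit peak — a conventional shape, stated
here because no part of the printed interface fixes it). Parametric
modulators enter as mean-centered occurrence weights, separating
modulation from the main effect. Nuisance columns are the motion
parameters plus one constant per session; motion columns with zero
variance (the toy realigner's rotation columns are identically zero) are
dropped rather than fed to the fit as exact collinearities.

Contrasts (`add_contrast`, default type `"T"`) come in three formats:
`sameforallsessions` tiles a per-session vector over every session
block; `singlesession:<name>` fills one block, zeros elsewhere;
`uniquebysession` consumes one long vector across all sessions' task
columns. With `auto_movesandmeans` the nuisance columns get zeros
automatically; otherwise the vector must already cover the full design
width. Sessions are addressed through the format tokens only — the
specification interface has no per-session wildcard.

Voxelwise OLS gives `t = c b / sqrt(s2 c (X'X)^-1 c')` with `n - rank(X)`
degrees of freedom (pseudoinverse with a warning if rank-deficient); the
second level is a voxelwise one-sample t across subjects with `n - 1`
degrees of freedom, with zero-variance/nonzero-mean voxels flagged
degenerate.

## The synthetic study generator

`generate_synthetic_study()` stands in for the output of DICOM
conversion. Defaults — chosen once as a small but recognizably fMRI-like
regime — are 2 subjects × 1 session, 12 × 12 × 10 voxels at 3 mm, 27
scans of which 3 are dummies (written with 15% elevated intensity to
mimic pre-steady-state saturation), a block design of 6 scans on / 6 off
at amplitude 8 on a baseline of ~100, Gaussian noise sd 1, and per-scan
integer head movements within ±2 voxels. Activation is injected as a
pure sustained block (integer timing): the first-level boxcar regressor
then matches the injected time course exactly, which is what makes
zero-noise amplitude recovery a machine-precision check rather than an
approximate one. The canonical-response mode exists and is tested on its
impulse-response shape, but the bundled pipeline fits boxcars.

What the generator does *not* emulate: rotations and sub-voxel motion,
slice timing, susceptibility distortion, physiological noise and drift,
anatomical variability between subjects. Tests passing on this material
demonstrate the engine's bookkeeping and the estimators' algebra — not
that the toy modules would cope with real scanner data.

## Toy module numerics

* **Realignment** estimates integer translations only, by exhaustive
  search over ±3 voxels maximizing correlation with the first volume.
  The correlation is evaluated on the overlap window of each candidate
  shift — including border voxels would let zero-filled edges swamp the
  signal of a smooth image. Vacated voxels of the corrected volume are
  imputed from the reference volume, so static background is restored
  instead of leaving design-correlated zeros at the edges. Integer-only
  motion is what makes exact recovery a meaningful test; rotations are
  reported as zero columns.
* **Smoothing** is a separable Gaussian, `sigma = FWHM / sqrt(8 ln 2)`
  per axis in voxel units, zero-padded at the boundary; the
  impulse-response test therefore targets interior voxels.
* **Time-series diagnostics** report, per adjacent volume pair, the mean
  squared intensity difference scaled by the squared global mean of the
  series. The scaling constant is one of several conventions in use; this
  one is chosen for invariance to global intensity scaling. Outliers are
  flagged above a configurable multiple (default 10×) of the median
  metric. Assets are linked into a central report browsable within and
  between subjects; with ≥ 2 subjects a between-subject motion summary
  (max |translation| per subject) is added.
* **Garbage collection** deletes stream payloads of stages whose
  `permanenceofoutput` rank is below the threshold, per stream rather
  than per directory (flags, manifests, logs and provenance always
  survive), so archived analyses keep their terminal results *done*
  while intermediates are regenerable on demand.

## Problem sizes and determinism

The test suite and the acceptance script run on 8 × 8 × 6 × 15-scan
studies (the full default 12 × 12 × 10 × 27 study appears once, in the
end-to-end activation-geography check); randomized map-equivalence
checks use 200 pipelines of ≤ 6 stages on ≤ 3 × 3 studies; the
second-level null calibration uses 2000 simulated 8-subject studies.
These sizes were picked so the whole suite re-runs in well under a
minute while every check still exercises the full code path. The engine
itself is seed-free; all randomness lives in the generator and the
simulations, which take explicit seeds, and NIfTI output is
byte-deterministic, which is what makes the serial/parallel and
repeated-run digest comparisons exact.

## Known limitations

* Stream identity is the bare name; there are no typed stream variants,
  so a tasklist author must know what state the last producer leaves the
  data in.
* A target cannot consume two same-named streams from different
  qualified sources.
* The parallel backend is an in-process fork pool; cluster and cloud
  submission are out of scope.
* Remote connection re-reads and re-digests the remote manifests on
  every run; for very large remote trees an mtime-based fast path would
  be the next step.
* The toy modules are exercisers, not neuroimaging tools: no slice
  timing, no normalization, no sub-voxel registration, no prewhitening
  or high-pass filtering in the GLM.
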