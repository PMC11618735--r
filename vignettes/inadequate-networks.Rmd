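---
title: "Annotating carbon backbones from INADEQUATE and JRES spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating carbon backbones from INADEQUATE and JRES spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inadnet)
library(dplyr)
```

## The measurement and the model

The 2D INADEQUATE experiment detects pairs of directly bonded carbons. A
bonded pair (a, b) with chemical shifts $\delta_a$ and $\delta_b$ produces
two peaks: each carbon resonates at its own shift along the direct
(acquisition) dimension, and both peaks share the double-quantum (DQ)
coordinate $\delta_a + \delta_b$ along the indirect dimension. The two
peaks of a bond therefore sit on one horizontal DQ row, symmetric about
the $Y = 2X$ diagonal (a peak on the diagonal would be a carbon bonded to
an identical shift). When a carbon participates in two bonds, its two
peaks sit at (nearly) the same direct shift on two different DQ rows —
a vertical alignment. Chaining horizontal pairs through vertical
alignments reconstructs the molecule's carbon backbone as a connected
network, without assuming the compound is in any database.

`inadnet` turns this geometry into an annotation pipeline with five
stages: peak picking, horizontal pairing, vertical linking, database
matching, and transfer of the annotations to a 1D projection of a
J-resolved (JRES) spectrum for fast per-sample profiling.

## Multi-threshold peak picking

A single low intensity threshold cannot separate close peaks: the
connected region above the threshold swallows both. The picker therefore
iterates a ladder of thresholds from `PPmax` down to `PPmin` (`steps`
rungs). At each rung, the grid points at or above the threshold are
grouped into 4-connected regions and each region is reduced to its
intensity-weighted center of mass. Detections from all rungs are then
merged: two detections belong to the same peak when they agree within
`PPCS` ppm (direct) **and** `PPDQ` ppm (DQ); the merged peak takes the
position of its highest-threshold (sharpest) detection and the maximum
intensity of the group.

Numerical choices worth knowing:

* **Spacing.** The ladder is geometric (log-uniform) by default because
  peak intensities in these spectra span orders of magnitude; `spacing =
  "linear"` is available. With `pp_max = 100, pp_min = 1, steps = 3` the
  geometric rungs are 100, 10, 1.
* **Merging is a transitive closure.** If the lowest rungs drop below the
  saddle between two overlapping peaks, the fused bridging region is
  within tolerance of both apexes and the closure will merge them into
  one peak. `PPmin` should therefore sit above the noise floor *and*
  above overlap saddles; this is the knob the picker exposes, and the
  tests exercise both regimes. For well-separated peaks, lowering
  `PPmin` only ever adds peaks.
* **Ties.** When two detections of a peak come from the same rung, the
  more intense one provides the position. Peak ids are assigned in
  descending intensity order, so outputs are reproducible.
* Only positive intensities are picked by default (processing is assumed
  to have resolved the antiphase structure upstream); `magnitude_mode`
  picks on absolute values.

## Network construction

All peak pairs are screened with three inclusive (`<=`) rules, each with
its own ppm tolerance:

1. **DQ alignment** (`DQT`): $|\delta^{DQ}_L - \delta^{DQ}_R|$;
2. **Sum rule** (`SumXY`): the sum of the two direct shifts must equal
   the pair's mean DQ shift;
3. **Diagonal symmetry** (`SDT`): the two peaks' absolute distances from
   $Y = 2X$ must agree.

The tolerances are inclusive because equality at the boundary is exactly
the noiseless ideal; excluding it would make the zero-noise case
tie-broken by floating-point rounding. A peak may participate in several
pairs — chain carbons must. Vertical links join any two peaks from
different pairs whose direct shifts agree within `CST`; networks are the
connected components of the pair + link graph, with ids assigned by
ascending minimum direct shift so runs are comparable. Missing vertical
links (e.g., when the shared carbon's two detections drift apart by more
than `CST`) split a backbone into two smaller networks; that is visible
in the Networks report and can be repaired by relaxing `CST`.

## The simulated compound database

A database entry needs only assigned ¹³C shifts and the carbon bond
list. From these, the simulated INADEQUATE peak list is generated: for
every bond, two peaks with the DQ coordinate equal to the shift sum —
exactly, to machine precision. Source archives sometimes assign more
than one shift to a carbon (e.g., anomeric mixtures); each carbon's
alternatives are kept, and the compound's **ambiguity score** is CA/CT:
the fraction of carbons with more than one assigned shift. A fully
unique assignment scores 0, a fully ambiguous one scores 1, and
compounds above the `Ambiguity` threshold are excluded from matching.
Assignment alternatives are enumerated as the cartesian product of the
per-carbon shift lists, capped at 1024 combinations (beyond the cap the
surplus carbons keep their first shift and a warning is raised; such
entries are in practice excluded by the ambiguity filter anyway).

Matching a network against a compound proceeds in three stages:

1. sample peaks match database peaks when their **direct** shifts agree
   within `CSMT` — injectively, preferring candidates already consistent
   in DQ (within `DQMT`), then nearest distance, then lower database peak
   index. The DQ preference matters because a shared chain carbon puts
   two database peaks at the same direct shift on different DQ rows; a
   distance-only assignment would cross them at random.
2. the candidate is kept when at least `NCMT` sample peaks matched
   (`>=`, so `NCMT = 2` means "at least one confirmed bond");
3. every matched pair must also agree in DQ within `DQMT`, otherwise the
   candidate is rejected.

For ambiguous compounds, the alternative maximizing the hit score is
used. Two scores describe each retained match: the **hit score** (matched
fraction of the network's peaks) and the **coverage score** (matched
fraction of the compound's simulated peaks, within one alternative set);
both reach 1 on a noiseless self-match. A network may match several
similar compounds and one compound may span several networks; both are
reported as-is. Networks with no match are reported with their backbone
signature — the ascending list of distinct carbon shifts, e.g.
`C(28.0)-C(60.9)-C(182.2)` — so unknown compounds stay trackable across
samples and can later be added to the database.

## JRES integration

The 2D JRES spectrum separates shifts from couplings; its 1D skyline
projection (maximum over the J dimension, the default; a sum projection
is available) is multiplet-free, one apex per carbon. Projection peaks
are local maxima at or above `Intensity_threshold_1D`, integrated by the
trapezoid rule over `Peak_Width_1D` ppm on each side of the apex. Each
network peak is then assigned its nearest projection peak within a
dedicated tolerance (`jres_match_tolerance`, defaulting to `PPCS` since
both bound the same direct-dimension reproducibility); a network counts
as JRES-present when **any** of its peaks is assigned — one clean carbon
is enough to profile the compound, and overlapped carbons should not
veto it. The JRES stage is optional: the pipeline runs to the Matches
report without a JRES input.

## What the simulator does and does not emulate

`fixture_spec()` + `render_inadequate()` / `render_jres()` forward-
simulate spectra from compound definitions: Gaussian (or Lorentzian)
line shapes at the exact bond geometry, per-compound amplitudes,
additive Gaussian noise under a fixed seed (bit-for-bit reproducible),
and a ground-truth table for every peak, pair and network. Defaults are
chosen to resemble processed high-field ¹³C data: line widths of 0.12
ppm (direct) and 0.25 ppm (DQ, broader because the indirect dimension
has fewer increments), axes of 1540 points over 5–195 ppm (direct) and
10–390 ppm (DQ), amplitudes around 100 intensity units with `PPmin = 10`
in the test configuration sitting above both the noise floor and any
overlap saddle. The toy library mirrors the structural cases that matter:
a 2-carbon compound, a 3-carbon chain (vertical linking), and a branched
5-carbon compound with an ambiguous methyl pair (ambiguity 0.4).

Not simulated: antiphase doublet fine structure and phase artifacts
(peaks are rendered positive, as in magnitude-like processed data),
J-coupling fine structure in INADEQUATE, t1 noise ridges, baseline
distortions, and solvent signals. Passing round-trip tests therefore
demonstrates the pipeline's geometric and bookkeeping correctness —
peaks at the bond geometry are found, partitioned and matched exactly —
not robustness to every processing artifact of real spectra, which is
what the tolerance parameters are for.

Problem sizes used in the shipped tests: the round-trip property runs
100 randomized libraries of 1–3 compounds with 2–4 carbons each (60
noiseless, 40 with shift jitter below `CSMT`/2), on the default grids;
oracle-equivalence checks use 50 random peak sets against an exhaustive
pairer, plus brute-force union-find and BFS flood-fill references.

## Reproducibility contract

Every run writes `Summary.txt` (per-stage counts plus a verbatim echo of
every configuration value), `Peaks.tsv`, `Networks.tsv`, `Matches.tsv`
and — when the JRES stage runs — `MatchJres.tsv`, alongside
`config_used.cfg`. Reports are a pure function of inputs, configuration
and package version: timestamps go to `run.log`, never into reports, so
re-runs and checkpoint-resumed runs are byte-identical. Checkpoints are
versioned serialized containers written after every stage; `-s`-style
stage selection in `run_pipeline()` (and the `inst/cli/inadnet.R`
script) resumes from them with identical downstream results. The exact
on-disk layout of checkpoints is not part of the contract — only
resume-equivalence is.

## Worked example

```{r example}
fx <- fixture_spec(noise_sd = 0)
cfg <- new_config(pp_max = 90, pp_min = 10, steps = 6)

sim <- render_inadequate(fx)
peaks <- pick_peaks(sim$spectrum, cfg)
nrow(peaks)

pairs <- find_horizontal_pairs(peaks, cfg)
nets <- link_networks(pairs, cfg$cst, peaks = peaks)
glance(nets)

db <- build_database(fx$compounds)
res <- match_all(nets, db, cfg)
res$matches |> select(network_id, entry_id, name, hit_score,
                      coverage_score)

jr <- render_jres(fx)
jp <- pick_jres_peaks(jr$spectrum, cfg)
ta <- transfer_annotations(nets, res, jp, cfg$jres_match_tolerance)
attr(ta, "network_presence")
```

## Known limitations

* No lineshape fitting or 2D volume quantification: peak intensity is
  the region maximum, position the center of mass.
* The transitive-closure merge can fuse heavily overlapped peaks when
  `PPmin` is set below their saddle (see above).
* Matching is per (network, compound) pair; evidence is not pooled when
  one compound spans several broken networks.
* Networks broken by a missed vertical link are reported as-is; repair
  is a parameter choice (`CST`), not automatic.
* The NMR-STAR reader covers assigned chemical-shift and bond loops of
  small-molecule entries, not the full grammar of the format.
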