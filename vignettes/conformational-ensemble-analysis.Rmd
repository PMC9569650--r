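---
title: "Chemical-shift-driven conformational ensemble analysis of flexible peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-shift-driven conformational ensemble analysis of flexible peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptideCS)
```

# The problem

Flexible peptides — here the integrin-targeting RGD peptides built around a
cyclic c[Lys-Arg-Gly-Asp-DGlu] head — do not adopt a single structure in
solution. They interconvert rapidly among many conformers, so every NMR
observable is a population-weighted average over a heterogeneous ensemble.
peptideCS implements the analysis chain that turns such averaged observables
into an ensemble-level structural description:

1. **Secondary chemical shifts.** For every assigned nucleus,
   $\Delta\delta = \delta_{obs} - \delta_{rc}$, where $\delta_{rc}$ is the
   residue-type statistical-coil reference. Sustained runs of
   $\Delta\delta C\alpha - \Delta\delta C\beta$ beyond $\pm 2$ ppm call
   helix/strand; values inside the band call coil.
2. **Proline cis/trans.** $\Delta\beta\gamma = \delta C\beta - \delta C\gamma
   \approx 5$ ppm indicates a trans Xaa-Pro bond, $\approx 10$ ppm cis; peak
   intensities of the resolved forms give the cis population
   $I_{cis}/(I_{cis}+I_{trans})$.
3. **Temperature coefficients.** The OLS gradient of the amide-proton shift
   vs temperature (ppb/K); slopes less negative than $-4.6$ ppb/K indicate
   hydrogen-bond protection.
4. **$^3J_{HNH\alpha}$ couplings.** The Karplus relation
   $J(\phi) = A\cos^2(\phi - 60^\circ) + B\cos(\phi-60^\circ) + C$
   back-calculates couplings from ensemble $\phi$ dihedrals; agreement with
   measurement (Pearson r, RMS deviation) validates a selected ensemble.
5. **Ensemble selection.** Candidate conformers (e.g. cluster
   representatives of an MD ensemble) are scored by the **global CS-RMSD**:
   the per-nucleus-class (C$\alpha$, C$\beta$, HN, H$\alpha$, N, side-chain H)
   root-mean-square deviation between observed and back-calculated shifts,
   summed over classes. The N lowest-scoring conformers form the
   representative sub-ensemble; highest-N and random-N selections serve as
   controls.
6. **Validation.** The Q factor
   $Q = \mathrm{rms}(\Delta\delta_{obs}-\Delta\delta_{pred}) /
   \mathrm{rms}(\Delta\delta_{obs})$ on secondary shifts, plus the coupling
   correlation.
7. **Dynamics.** Per-residue C$\alpha$ RMSF about the superposed ensemble
   mean, shift-predicted order parameters $S^2$, and the CPMG T$_2$-filter
   intensity model $I/I_0 = e^{-R_2 T}$.

# Central objects

`ShiftTable` (observed or predicted shifts), `RandomCoilModel` (versioned
reference table + alias map), `SecondaryShiftTable`, `ConformerEnsemble`
(multi-model backbone coordinates; dihedrals derived on demand),
`ClusterResult`, `SelectionResult`. All are S4 classes with validity checks;
accessor functions (`shifts()`, `ensembleXyz()`, `selectedConformers()`, ...)
are the supported interface.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| secondary-structure band | 2 | ppm | conventional $\pm2$ ppm cutoff on $\Delta\delta C\alpha-\Delta\delta C\beta$ |
| run window | 3 | residues | "consecutive" values needed for a non-coil call; a single residue cannot be consecutive, so 2 is the minimum and 3 guards against isolated outliers |
| proline trans max / cis min | 6 / 8 | ppm | exemplar bands sit near 5 and 10 ppm; the gap yields an explicit `ambiguous` call instead of a knife-edge decision |
| temp-coefficient boundary | -4.6 | ppb/K | standard hydrogen-bond boundary; applied with $\le$ on the negative side (the boundary value itself classifies solvent-exposed) |
| Karplus preset | `bax1997` | Hz | A=7.09, B=-1.42, C=1.55; a 1993 parameterization ships as `bax1993`; the active preset id is stamped into all outputs |
| CSP weights | 1 / 0.154 / 0.25 | per ppm | standard $^1$H/$^{15}$N/$^{13}$C scaling onto the proton ppm scale |
| selection N, mode | 50, lowest | — | the ensemble-size protocol parameter; `highest` and `random` are controls |
| T$_2$ noise floor | 0.1 | of $I_0$ | detectability threshold; presence/absence is what an operator reads off a spectrum, the floor makes it quantitative |
| S$^2$ preset | `rci-lite-1` | — | see below |

# Design choices made where the design was open

**Random-coil reference.** The reference approach is sequence-dependent in
the original tools; here a residue-type statistical-coil table
(`wishart1995`, compiled from the standard literature values) ships as a
versioned CSV, swappable via `randomCoilModel(path = ...)`. Neighbor,
temperature and pH corrections are not modelled (zero by default). D-Glu is
referenced as Glu; homocitrulline as Lys (it differs from lysine only at the
side-chain terminus, far from every referenced nucleus); any other unmapped
residue type fails loudly rather than silently borrowing a reference.

**Karplus convention.** Presets assume the HN-H$\alpha$ phase
($\theta_0 = -60^\circ$ applied as $\cos(\phi + \theta_0)$, i.e. the
conventional $\phi - 60^\circ$ argument). Ensemble couplings use the
*circular* mean of $\phi$ (unit-vector average), since an arithmetic mean is
ill-defined near the $\pm180^\circ$ wrap.

**Global CS-RMSD.** The global score is the *unweighted sum* of the six
class RMSDs. The ensemble-level score back-calculates the fast-exchange
observable — the uniform average of the selected conformers' predicted
tables — and scores that against the observations; the mean of the selected
conformers' individual scores is also reported (`meanConformerScore`) so the
two averaging conventions can be compared.

**Clustering.** Average-linkage `hclust` over the pairwise
optimal-superposition RMSD matrix; the cut level minimizes the Kelley
penalty (average within-cluster spread, normalized across levels to
$[1, M-1]$, plus the cluster count). Ties resolve to fewer clusters; each
cluster is represented by its medoid.

**RMSF reference.** Two-pass superposition (fit to the first model, average,
refit to the average) onto the mean structure, CA atoms only.

**S$^2$ mapping.** The `rci-lite-1` preset maps the per-residue weighted
mean of absolute secondary shifts $s$ (weights CA 1, CB 1, N 0.4, HA 7, H 7;
floored at 0.1 ppm) through the monotone saturating map
$S^2 = 0.3 + 0.7\,(1 - e^{-(s - 0.1)/0.3})$. Only the *ordering* and bounds
of these predictions are meaningful — tests and the acceptance script assert
rigid-vs-flexible ordering, never preset-specific values.

# The synthetic-data generator

There is no deposited data to analyze, so the generator produces every
input the pipeline consumes, with the statistical structure the analysis
assumes, and stores ground truth for recovery scoring.

- **Conformers.** Per residue, a dihedral basin (helix/strand/coil) is
  sampled from a population vector; $(\phi,\psi)$ are drawn from that
  basin's wrapped normal (centers $(-63,-42)$, $(-135,135)$, $(-70,150)$;
  widths 10-15$^\circ$; versioned data file `basin_params_v1.csv`). Backbone
  coordinates follow from the dihedrals with idealized bond lengths/angles
  and planar trans peptide bonds — the pipeline tests
  geometry-to-shift-to-selection logic, not force-field realism.
- **Cyclic head.** The real macrocycle closes through side chains the toy
  backbone does not carry, so closure is a loose surrogate: the joint
  (basins, angles) of residues 1-5 is rejection-sampled until
  $d(C\alpha_1, C\alpha_5) \le 10$ Å (an $\alpha$-helical head sits near
  6 Å, a fully extended one near 12.4 Å). Head-residue basin frequencies are
  therefore conditional on closure, exactly as a real cycle conditions its
  conformational distribution.
- **Toy predictor.** Shifts are random-coil values plus fixed per-basin,
  per-nucleus offsets (`basin_offsets_v1.csv`: helix raises C$\alpha$ and
  lowers H$\alpha$; strand the reverse; coil is offset-free). Generator and
  predictor share one versioned basin definition, so they are mutually
  consistent by construction.
- **Observations.** The "measured" shift table is the uniform average of
  the toy predictions over a hidden true sub-ensemble plus i.i.d. Gaussian
  noise (default $\sigma = 0.05$ ppm); temperature series are lines with
  Gaussian noise over 298-310 K; prolines emit trans-like
  ($\Delta\beta\gamma \approx 5$) and cis-like ($\approx 10$) pairs with
  intensities proportional to the populations.

**Why the true sub-ensemble is helix-biased.** Recovery of a hidden
sub-ensemble by CS-RMSD ranking is only well-posed if the sub-ensemble
occupies a distinguishable region of conformational space — if true and
decoy conformers were drawn from the same distribution, no shift-based score
could separate them. The packaged study conditions therefore draw the 50
true conformers from helix-biased basin populations (0.80/0.05/0.15) and
the 350 decoys from coil-biased ones (0.10/0.20/0.70); that emulates the
scientifically interesting case where the experimentally populated region
differs from the bulk of the candidate pool.

**What passing tests do and do not show.** The generator's data are
idealized: uncorrelated residues, exact basin geometry, Gaussian noise, a
forward model identical to the scoring predictor. Success on this instance
shows that the *selection machinery* is correct (ranking, averaging,
controls, seeds), not that a real chemical-shift predictor would recover
real sub-ensembles at the same rate; with a real predictor the forward-model
mismatch dominates. The coil and strand basins also approach each other (as
they do on a real Ramachandran map), so individual draws near the boundary
can classify into the neighboring basin — this is deliberate, mild label
noise.

# Numerical choices

- Ranking ties break by ascending conformer id; selection is fully
  deterministic given the seed.
- The temperature-coefficient class boundary is applied with a $10^{-9}$
  ppb/K tolerance so an exactly-boundary line is not misclassified by
  floating-point noise in the regression.
- The circular mean of an empty angle set is NA; residues lacking $\phi$ in
  any model are reported missing from ensemble couplings, never imputed.
- Degenerate inputs: all-identical coordinates give a zero RMSD matrix and
  one cluster; fewer than 3 models cluster trivially with a warning;
  requesting more conformers than exist selects all with a warning; zero
  observed variance makes correlation/Q undefined (NA), not zero.
- RMSF of i.i.d. isotropic jitter with SD $\sigma$ has expectation
  $\sigma\sqrt{3 - 6/N}$ after superposition on $N$ atoms (six rigid degrees
  of freedom are removed), approaching the naive $\sigma\sqrt{3}$ from
  below; tests use the corrected form.

# Problem sizes

The test suite runs the selection protocol at the study scale it emulates
(391- and 400-conformer candidate sets, 50-conformer selections) and uses
400-model jitter ensembles for the RMSF law, chosen so sampling error is
well inside the assertion tolerances; everything else runs on small
hand-checkable fixtures.

# A worked run

```{r example, eval = FALSE}
inst <- recoveryInstance(seed = 101)        # 400 candidates, hidden 50
sel <- selectEnsemble(inst$ensemble, inst$obs, n = 50, mode = "lowest")
sel
length(intersect(selectedConformers(sel), inst$groundTruth$trueIds))
```

# Known limitations

- The toy predictor shares its forward model with the generator; plugging in
  a real back-calculation engine is an adapter behind the
  `predictShifts()` contract and is outside the tested path.
- Idealized geometry only (N, CA, C, O backbone); no side-chain coordinates,
  no omega sampling, no D-residue mirror geometry for the D-glutamate.
- The random-coil table is residue-type only; sequence-dependent neighbor
  corrections are not implemented.
- Cis prolines are simulated as shift pairs, not as a second conformer
  population in the ensemble.
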