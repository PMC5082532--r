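---
title: "Methods: mass balance, ion-binding free energy, and shift perturbation in ferromin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass balance, ion-binding free energy, and shift perturbation in ferromin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferromin)
```

ferromin packages three desk-scale analyses used to study how an acidic,
ferrous-binding protein (Mms6 of magnetotactic bacteria, and its C-terminal
peptide C20Mms6) steers room-temperature co-precipitation (RTCP) of mixed
ferrous/ferric solutions toward magnetite: (i) pH-titration equivalence-point
detection and mass-balance mineral quantification, (ii) a Metropolis Monte
Carlo toy model of single-ion binding to peptide oxygen sites with radial
distribution function (RDF) and free-energy analysis, and (iii) NMR
chemical-shift-perturbation (CSP) mapping. Each stage ships with a synthetic
data generator so the full pipeline can be exercised against known ground
truth.

## The R-versus-X mass-balance diagram

During RTCP, NaOH is added at a constant rate to a solution of total iron
concentration [Fe] with ferric fraction $X = [\mathrm{Fe^{3+}}] /
([\mathrm{Fe^{2+}}] + [\mathrm{Fe^{3+}}])$. Progress is measured by
$R$, the moles of base added per mole of iron. Each candidate mineral
consumes a fixed amount of hydroxide per iron, so it occupies a vertex
$(X_i, R_i)$ on the $R$-vs-$X$ diagram:

| species | formula (per reaction) | $X_i$ | $R_i$ |
|---|---|---|---|
| ferrous hydroxide | $\mathrm{Fe(OH)_2}$ | 0 | 2 |
| green rust (sulfate) | $\mathrm{Fe^{II}_4 Fe^{III}_2 (OH)_{12} SO_4}$ | 1/3 | 2 |
| magnetite | $\mathrm{Fe^{II} Fe^{III}_2 O_4}$ (8 OH per 3 Fe) | 2/3 | 8/3 |
| goethite | $\mathrm{FeOOH}$ | 1 | 3 |
| schwertmannite | $z = 1/8$ sulfate substitution | 1 | 2.75 |

The titration record has three plateaus separated by two steps. The first
equivalence point $E_1$ (precipitation of the ferric oxyhydroxide
schwertmannite) lies on the line $R = 2.75X$; the second, $E_2$, is the
fraction-weighted sum of the vertices of the minerals formed, so a measured
$(X, E_2)$ point decomposes by the lever rule into iron-molar fractions
$f_i$ solving

$$\sum_i f_i = 1,\qquad \sum_i f_i X_i = X,\qquad \sum_i f_i R_i = E_2 .$$

`decompose_E2()` solves this 3-by-3 system for the default candidate set
{ferrous hydroxide, green rust, magnetite}, which is the mineral regime for
$0 \le X \le 2/3$; goethite is registered for diagram completeness but
excluded from the default candidates. Fractions are reported per mole of
iron (the conservation laws above are written per Fe, which fixes the
basis). A point outside the candidate triangle yields a structured
out-of-region result naming the violated constraint rather than a clamped
answer; fractions within `tol` (default `1e-6`) of zero are clamped and the
rest renormalised. When the end point comes from a *detected* $E_2$ rather
than an exact one, the appropriate `tol` is the size of the measurement
error (the grid spacing, or a few times the logger noise): generating
mixtures with $X \ge 0.5$ sit exactly on the ferrous-hydroxide-free edge of
the triangle, so an unbiased detector lands marginally outside half the
time.

`equal_pair_solve()` answers the converse question used for ferrous-rich
protein-mediated runs: given only $X$, what mixture has equal green-rust and
magnetite iron fractions? Ferric conservation forces the shared fraction to
equal $X$ itself, so at $X = 0.2$ the solution is 60 % ferrous hydroxide,
20 % green rust, 20 % magnetite.

## Synthetic titration curves and equivalence detection

`simulate_titration()` generates a pH-logger record: $R$ grows at `rate`
(default 0.05 R/min, the rate produced by 50 uL/min of 1 M NaOH into 20 mL
at 50 mM iron) sampled every 3 s, i.e. $\Delta R = 0.0025$ per sample. pH
follows a sum of two logistic steps between three plateau levels, centred
at the theoretical $E_1 = 2.75X$ and $E_2 = \sum f_i R_i$, plus Gaussian
logger noise (default sd 0.02 pH). The two-logistic form is the simplest
curve with three plateaus and two steps; plateau defaults (2.5, 7.0, 12.5)
are qualitative read-offs of typical RTCP logs (the final plateau matching
the pH 12.5 end of titration) and are configurable — real curves do not
come with published plateau values per $X$. The default end-point mixture
is the equal green-rust/magnetite split for $X \le 0.5$, continuing
ferrous-hydroxide-free up to $X = 2/3$.

The additive ("protein") effect is modelled per the observed ferrous-rich
phenomenology: for $X \le 0.4$ the second plateau is lowered by
`dpH_plateau2` (default 0.4 pH) and the second step moved earlier by
`dR_E2` (default 0.15). Note that with all candidate vertices at $R \ge 2$,
an $E_2$ of $2.0 - 0.15$ at $X = 0.2$ lies below the mineral-regime floor,
so decomposing the shifted protein end point correctly reports
out-of-region: at default parameters the additive signal is carried by the
control-vs-additive *run deltas* (`compare_runs()`), not by decomposing the
shifted point.

`detect_equivalence()` finds steps as the two most prominent maxima of the
Savitzky-Golay smoothed derivative d(pH)/d$R$ (window 11 samples, cubic
polynomial); a maximum only counts if it exceeds 3 times the median
absolute gradient, so featureless ramps raise a "steps not found" error.
The central point $E^*$ is the midpoint of the span where the gradient
falls below 20 % of the adjacent step peaks, and its pH is read from the
smoothed curve to damp logger noise. Deltas between runs at equal $X$ are
evaluated at each run's own $E^*$ by default; a shared-$R$ evaluation is
available via `common_R`. On noiseless curves the detected steps land
within one $\Delta R$ grid step of the generating breakpoints across
$X \in [0.1, 0.9]$; with 0.02 pH noise, recovered mineral fractions stay
within 5 percentage points of truth.

## Toy Monte Carlo ion binding and the free-energy profile

The simulator stands in for molecular dynamics of one ferrous (or ferric)
ion near the acidic DEEV(E) oxygen cluster. Fixed oxygen sites in a
periodic 40 Å cubic box carry attractive Gaussian wells,

$$U(\mathbf{x}) = \sum_k -|D_k|\, e^{-d_k^2 / 2w_k^2},$$

with $d_k$ the minimum-image distance to site $k$. Gaussian wells, unlike a
force field, give closed-form ground truth: the equilibrium radial
distribution around an isolated site is $g(r) = e^{-U(r)/RT}$ after tail
normalisation, so every estimator downstream can be checked against a
numeric Boltzmann oracle. Default well width is 2.5 Å, which puts the
well-sampled plateau of the free-energy profile near $-D$ and makes the
binding shell a few Å wide, comparable to the 2.55-3.25 Å ion-oxygen
binding range seen in force-field studies; depths are free parameters
(defaults span the -4 to -11 kJ/mol range reported for weak and strong
sites). Temperature is fixed at 300 K.

Sampling is single-particle Metropolis: uniform proposals in a cube of edge
`step_size` (default 1.5 Å), periodic wrapping, R's RNG throughout so a
seed fixes the trajectory. On this smooth landscape the acceptance rate
stays near unity for any reasonable step — well depths are only a few
$RT$ and gradients are gentle — so the step size is chosen for
decorrelation, not for an acceptance-rate target; at zero depth a box-sized
step yields exactly independent uniform draws, which the uniformity tests
exploit. A single run visits a $-6.7$ kJ/mol well only a handful of times
in $2\times10^6$ sweeps, so quantitative profiles pool an ensemble of
independent starts (`batch_ensemble()` + `pool_trajectories()`), mirroring
how production studies combine one run per candidate binding site (12
sites, 24 runs over two ions). Ferric ions are modelled by scaling all
depths by `fe3_depth_scale` > 1: the extra charge binds more strongly and
indiscriminately.

Analysis follows the standard MD conventions. A frame is *bound* when the
ion is within 3.0 Å of at least one oxygen (closed interval; the boundary
convention is documented and the cutoff configurable). Site occupancy is
the fraction of bound frames within the cutoff of each site, banded
high/medium/low; co-binding is the conditional probability
$P(b \mid a)$ over bound frames, reported as undefined (never 0) when the
conditioning site is never bound. The RDF uses 0.05 Å bins (at least 14
bins across a 0.7 Å binding shell), each divided by its spherical-shell
volume, and is tail-normalised so that mean $g$ over the outer window
(default the last 3 Å below `r_max`) is 1 — matching the convention that
$g \to 1$ at large separation, where the free energy is zero. The
free-energy profile is the Boltzmann inversion $A(r) = -RT\ln g(r)$; bins
with zero counts give an absent $A$, never $\pm\infty$, and bins with
fewer than `min_count` (default 25) raw counts are masked because their
log-scale sampling error exceeds ~0.2 RT and min-picking over such bins
biases the well depth. The well is the deepest negative minimum; the
desorption barrier is $|$depth$|$ plus the highest point of the profile
beyond the well (zero if the profile rises monotonically back to the
tail). With 12-start ensembles at $2\times10^6$ sweeps per run, wells of
-4, -6.7 and -11 kJ/mol are recovered within 1 kJ/mol.

## Chemical-shift perturbation

The peptide is fixed to C20Mms6 (Ac-KSRDIESAQSDEEVELRDAL-Am, indices
1-20). `delta_shifts()` compares an apo and a holo assignment at matched
pH (tolerance 0.05; metal additions acidify the sample, and uncontrolled
pH drift would masquerade as binding, so mismatched conditions are an
error): the amide perturbation is the HN shift change and the sidechain
perturbation the mean change over sidechain protons observed in *both*
conditions — paramagnetic relaxation makes protons vanish near a bound
iron, so missing atoms are excluded and counted rather than treated as
zeros, and residues with nothing observed are flagged absent.
`rank_hotspots()` orders residues by absolute sidechain perturbation
(ties: amide, then index) and reports maximal runs of adjacent top-$k$
residues; an acidic binding cluster like DEEVE shows up as the contiguous
run 11-13 plus 15. `random_coil_deviation()` subtracts a per-residue-type
random-coil H$\alpha$ reference (a hand-entered Wishart-style compilation
shipped as editable CSV; substitute your own via `reference=`) and
summarises max/mean/sd of the absolute deviations — an unstructured
peptide deviates by only a few hundredths of a ppm. Endpoint comparison at
3 metal equivalents is the supported design; no $K_d$ is fitted.

The generator `synth_shift_tables()` scatters the apo set around the
random-coil reference (sd 0.01 ppm), then adds a specified perturbation to
every proton of chosen hotspot residues plus measurement noise. Defaults
(hotspots 11, 12, 13, 15; effect 0.05 ppm; noise 0.005 ppm) emulate a
ferrous-like titration; a fivefold smaller effect emulates the ferric
response. Under those defaults hotspot recovery places all four true
residues in the top 4 in at least 95 % of seeded runs.

## Workflows, determinism, problem sizes

`run_config()` + `run_workflow()` tie the stages into three reproducible
workflows (titration, binding, csp). Every stochastic stage requires an
explicit seed; numeric outputs are written with pinned 6-significant-digit
formatting so a rerun with the same config is byte-identical (md5-checked
manifests). A stage failure halts the run naming the stage and keeps
artifacts already written. `make_fixtures()` writes one example dataset
per workflow with a plain-text ground-truth record.

Default problem sizes are chosen so the whole test suite runs in about a
minute on one CPU: titration curves of ~1400 samples, Monte Carlo
ensembles of $10^6$-$2\times10^6$ sweeps per run, 50-seed CSP recovery
sweeps. They are package defaults, not physical claims, and scale up
linearly.

## What the generators do and do not emulate

The titration generator reproduces the *geometry* of RTCP curves (plateau
levels, step positions tied to stoichiometry, logger cadence and noise) but
none of the precipitation kinetics, speciation equilibria, oxygen-exposure
maturation, or activity corrections; passing closure tests shows the
detector and the lever-rule solver are mutually consistent, not that real
curves obey the two-logistic form. The ion simulator replaces force-field
energetics with Gaussian wells; it validates the binding/RDF/free-energy
estimators, but force-field-dependent numbers (bound percentages,
per-site occupancies, the 2.85 Å optimum distance) are outside its claims.
The CSP generator produces idealised assignment tables; real spectra add
peak overlap, titration-course drift and PRE losses that the generator
only caricatures via missing atoms.
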