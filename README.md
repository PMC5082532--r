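# ferromin

Desk-scale analyses of protein-mediated magnetite nucleation from mixed
ferrous/ferric solutions. The package is aimed at biomineralisation and
bioinorganic chemists studying how acidic, iron-binding proteins (such as
Mms6 from magnetotactic bacteria) steer room-temperature co-precipitation
(RTCP) toward magnetite, and it covers the three quantitative legs of such
a study:

1. **Titration mass balance.** RTCP progress is measured by
   *R* = mol NaOH / mol Fe at ferric fraction
   *X* = [Fe³⁺]/([Fe²⁺]+[Fe³⁺]). Each candidate mineral (ferrous hydroxide,
   green rust, magnetite, goethite, schwertmannite) consumes a fixed
   hydroxide per iron and occupies a vertex (*Xᵢ*, *Rᵢ*) of the *R*-vs-*X*
   mass-balance diagram. The first titration step obeys the schwertmannite
   line *R* = 2.75 *X*; the second step *E₂* decomposes by the lever rule
   into iron-molar mineral fractions *fᵢ* solving
   Σ*fᵢ* = 1, Σ*fᵢXᵢ* = *X*, Σ*fᵢRᵢ* = *E₂*.
   Includes a synthetic three-plateau curve generator and a
   Savitzky–Golay-based equivalence-point detector.
2. **Ion-binding free energy.** A Metropolis Monte Carlo toy model of a
   single Fe²⁺/Fe³⁺ ion among fixed peptide-oxygen sites with Gaussian
   wells, plus the standard trajectory analyses: 3 Å binding
   classification, site occupancy and co-binding statistics, shell-volume
   RDF with tail normalisation, and the Boltzmann inversion
   *A(r)* = −*RT* ln *g(r)* with well/desorption-barrier annotation.
3. **Chemical-shift perturbation.** Apo/holo Δδ tables for the C-terminal
   Mms6 peptide (Ac-KSRDIESAQSDEEVELRDAL-Am): amide and mean-sidechain
   perturbations per residue, random-coil Hα deviations, and hotspot
   ranking that surfaces the DEEVE acidic cluster.

Every stage has a seeded synthetic-data generator, so the full pipelines
are testable against known ground truth.

## Worked example

Simulate a ferrous-rich (X = 0.2) control titration, detect its
equivalence points, and decompose the end point into mineral fractions:

```r
library(ferromin)

sp   <- synth_params()                      # logger noise sd 0.02 pH
ctrl <- simulate_titration(0.2, sp, seed = 1)
pts  <- detect_equivalence(ctrl)
pts
#> <equivalence_points> E1 = 0.555, E* = 1.339 (pH 7.009), E2 = 2.14

schwertmannite_residual(pts$E1_R, X = 0.2)  # distance from R = 2.75 X
#> [1] 0.005

decompose_E2(0.2, pts$E2_R, tol = 0.01)
#> <mineral_fractions>
#>   ferrous_hydroxide   61.00 %
#>   green_rust          18.00 %
#>   magnetite           21.00 %
```

The detected first step sits on the schwertmannite line to within 0.005 R,
and the lever-rule decomposition recovers the generating mixture (60/20/20)
to within one percentage point despite the logger noise. The analytic
constrained solve used for protein-mediated ferrous-rich runs — equal
green-rust and magnetite fractions consuming the available ferric iron —
gives the exact split:

```r
equal_pair_solve(0.2)
#> <mineral_fractions>
#>   ferrous_hydroxide   60.00 %
#>   green_rust          20.00 %
#>   magnetite           20.00 %
```

Control-vs-additive deltas recover the injected protein effect (plateau-2
lowered 0.4 pH, second step 0.15 R earlier):

```r
prot <- simulate_titration(0.2, sp, seed = 2, protein = TRUE)
compare_runs(list(curve = ctrl, points = pts),
             list(curve = prot, points = detect_equivalence(prot)))
#> $dpH_at_Estar
#> [1] 0.403721
#> $dE2_R
#> [1] 0.1525
```

See `vignette("ferromin-methods")` for the models, parameter choices and
limitations, and `?simulate_ion`, `?rdf`, `?delta_shifts` for the other two
pipelines.

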