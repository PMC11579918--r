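# memthin

Local membrane thickness and related analyses for coarse-grained bilayer
ensembles.

## The problem

Signal peptidase sits in the ER membrane and must decide which substrates to
cleave: signal peptides (cleaved) and signal anchors (left intact) differ
mainly in the length of their hydrophobic stretch. One proposed selectivity
mechanism is geometric — the lipid bilayer immediately around the enzyme's
substrate-binding cleft (the "TM window") is locally *thinner* than the bulk
membrane, so only transmembrane segments short enough to fit the thinned
region present their cleavage site at the active site. Testing this idea
from molecular-dynamics simulations requires measuring membrane thickness
*locally*, in a small annulus of lipids around the protein, from noisy
phosphate-bead coordinates.

`memthin` packages that measurement, and everything needed to validate it,
for structural bioinformaticians analyzing coarse-grained (Martini-style) or
atomistic membrane simulations:

- GRO/PDB multi-frame readers and writers with role-based bead selection
  (`PO4`/`P` phosphates, `BB`/`CA` backbones, water);
- number-density profiles along the membrane normal and volumetric water
  density maps;
- dynamic TM-window selection (phosphates within a cutoff, default 6 Å, of
  any protein bead, re-evaluated per frame);
- double/triple Gaussian fits of leaflet density profiles and
  peak-separation thickness, with replicate aggregation (mean ± SEM);
- helix axes, spans and crossing angles; Kabsch superposition, RMSD and
  RMSF validation metrics;
- cleavage-efficiency statistics for gel band-intensity tables (Welch and
  pooled t tests with the conventional significance-star ladder);
- a synthetic bilayer generator with planted ground truth, so the entire
  pipeline is testable end to end without running MD.

## The measurement

The phosphate number density along the membrane normal `z` is fitted with a
sum of Gaussians

```
rho(z) = sum_k  A_k exp( -(z - mu_k)^2 / (2 sigma_k^2) ),   K = 2 or 3
```

one component per leaflet, plus (K = 3, used for the TM window) a mid-plane
component that absorbs deep-lying phosphate headgroups coordinated inside
the window. The bilayer thickness is the separation of the two *outermost*
component means, `max(mu) - min(mu)` — invariant to amplitudes and to any
rigid shift along z. Replicate simulations are aggregated as mean ± SEM, and
regions are compared as percent thinning `(bulk - window)/bulk × 100` and as
differences with quadrature-propagated errors.

## Worked example

Generate three replicate bilayers with a planted 20.1 Å window inside a
38.1 Å bulk membrane, then recover the window thickness blind:

```r
library(memthin)

spec <- bilayer_spec(bulk_thickness = 38.1, window_thickness = 20.1,
                     protein_radius = 10, n_protein_beads = 60,
                     n_frames = 100, seed = 11)
reps <- lapply(1:3, function(r) { s <- spec; s$seed <- 11L + r
                                  generate_bilayer(s)$ensemble })
res <- thickness_pipeline(reps, region = "tm_window")
res
#> <thickness_result> region=tm_window, method=triple, n=3
#>   thickness = 20.31 +/- 0.15 A (mean +/- SEM)

tidy(res)
#> # A tibble: 3 × 4
#>   replicate thickness r_squared converged
#>       <int>     <dbl>     <dbl> <lgl>
#> 1         1      20.0     0.990 TRUE
#> 2         2      20.3     0.994 TRUE
#> 3         3      20.5     0.999 TRUE

relative_thinning(38.1, res$mean)
#> [1] 46.7   # percent thinner than bulk
```

The recovered 20.31 ± 0.15 Å lands within a few tenths of an angstrom of the
planted 20.1 Å; the ~47% thinning is what distinguishes a window that admits
a 14-residue helix (`helix_span(14)` = 21 Å) from one that admits longer
anchors. `autoplot()` methods exist for profiles, fits, thickness results,
RMSF profiles, cleavage profiles and validation reports; `tidy()`/`glance()`
give tibble views of fitted objects.

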