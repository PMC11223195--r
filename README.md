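# tmtriad

Trajectory analysis for three-chain transmembrane (TM) helix assemblies of
the TREM2/DAP12 type: a receptor helix whose TM segment carries a charged
lysine (K26), bound to an adaptor homodimer whose chains carry an
aspartate/threonine DxxxT motif (D16, T20). Structural studies of this
complex ask how a *kinked* versus *straight* receptor helix changes which
adaptor chain it binds and through which residue contacts and hydrogen
bonds. `tmtriad` implements the standard trajectory observables used to
answer that, for people analysing MD trajectories (or any multi-model
coordinate series) of such bundles:

* **Kink angle** — per frame, the angle between two four-residue Cα
  displacement vectors flanking the hinge,
  θ = arccos( v₁·v₂ / |v₁||v₂| ) with
  v₁ = Cα(L24) − Cα(A20), v₂ = Cα(A36) − Cα(A32);
  summarized by mean ± SEM and the 1°-binned mode.
* **Contact maps** — residue pair (i, j) is in contact when
  min distance between atom sets ≤ cutoff (11 Å for Cα maps, 3 Å all-atom);
  *persistence* = fraction of frames in contact. Pairs with persistence
  > 0.5 survive filtering; pairs present in ≥ 3 of the six
  (system × adaptor chain) persistent maps form the consensus interface,
  classified as hydrophobic / hydrogen bond / salt bridge.
* **Hydrogen-bond occupancy** — a donor–hydrogen–acceptor triple counts on
  a frame when d(D, A) ≤ 3.0 Å and ∠(D–H···A) ≥ 150°; occupancy is the
  percentage of frames satisfied by any donor hydrogen, tabulated per
  (system, residue pair, atom label, chain) and aggregated per pair as the
  sum of its per-label occupancies. Salt bridges use a 4.0 Å
  minimum-distance criterion between charged-group heavy atoms.

Because microsecond-scale MD trajectories of this system are not
reproducible at desk scale, the package ships a synthetic generator
(`trimerAssembly()`, `generateTrajectory()`, `writeSyntheticSystems()`)
that builds ideal α-helix bundles with programmable kinks and per-frame
hydrogen-bond schedules, giving every analysis stage exact known ground
truth. See the methods vignette (`vignettes/tmtriad-methods.Rmd`) for the
model, conventions and design choices.

## Worked example

Generate the three default study systems — one kinked bundle packed
against adaptor chain A only, two straight symmetric bundles — and run the
full pipeline:

```r
library(tmtriad)
cfg <- writeSyntheticSystems(tempfile("systems"), seed = 1, nFrames = 2000)
rep <- runAll(cfg)

sapply(rep@kink, kinkMode)
#> 6z0g_TD 6z0i_TD   AF_TD
#>   101.5    25.5    26.5

rep@kink[["6z0g_TD"]]
#> KinkSeries: 2000 frames; mean 101.11 +/- 0.06 deg; mode 101.5 deg (1 deg bins)

aggregateOccupancy(rep@occupancy, "K26/D16", "A", system = "6z0i_TD")$reported
#> [1] 85.2

retainedPairs(rep@consensus)
#>   receptorResno adaptorResno count
#> 1            26           16     5

rep@classification[, c("pair", "hydrophobic", "hydrogenBond", "saltBridge")]
#>      pair hydrophobic hydrogenBond saltBridge
#> 1 K26/D16       FALSE         TRUE       TRUE
```

Reading the numbers: the kinked system's modal kink is ~101° while the
straight bundles sit at the ideal-helix four-point baseline (~25°); the
measured aggregate K26/D16 hydrogen-bond occupancy on chain A of the
unkinked system recovers its scheduled 85.2% target; and the consensus
interface across all six maps is exactly the K26/D16 pair, which is
simultaneously a salt bridge and a hydrogen bond. `runAll()` also writes
per-system kink CSVs, contact-map CSVs, the occupancy table and a
consensus JSON when `cfg@outDir` is set.

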