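# barrelgate

Trajectory metrics for membrane β-barrel proteins with a **lateral gate**
— an opening in the barrel wall through which hydrophobic cargo can exit
sideways into the membrane. The package targets the analysis questions
raised by lateral-exit candidates such as LptD and the GfcD C-terminal
13-stranded barrel, whose missing 14th strand leaves a permanent aperture
between strands β1 and β13: does the gate stay open, do membrane lipids
stay out, and do the acyl tails of a lipid anchor (lipid A) placed in the
channel exit laterally through the gate?

For an MD trajectory `{x_i(t)}` it computes:

* **Gate aperture** `d_p(t) = ‖x_Cα(a_p, t) − x_Cα(b_p, t)‖` for declared
  residue pairs `p` flanking the gate (GfcD defaults 437–668, 433–666,
  427–663), with per-pair mean/sd/min and a closure report (fraction of
  frames below a threshold, default 6 Å).
* **RMSD/RMSF** after in-package Kabsch superposition (SVD with proper
  rotation enforcement); RMSF against the mean structure after one
  alignment iteration, residue-averaged.
* **Flicker depth** `max(0, −s(x, t))` over membrane atoms near the gate,
  where `s` is the signed distance to the least-squares gate plane
  (outward normal).
* **Head tilt** `θ(t) = arccos( v·ẑ / ‖v‖ )` with `v = x_PB − x_PA`, the
  lipid head phosphorus vector, histogrammed at 2.5° resolution.
* **Insertion fraction**: the fraction of tail heavy atoms past the gate
  plane, per tail and overall, plus the order in which tails complete
  their exit.
* **Contact score**: per-residue lipid-contact frequency `f_rk` (fraction
  of frames within 4.0 Å heavy-atom cutoff) per replica `k`, combined as
  the geometric mean `(∏_k f_rk)^{1/K}` — exactly zero unless the contact
  reproduces in every replica — and written into the B-factor column for
  structure colouring.

A deterministic synthetic-trajectory generator (toy 13-strand barrel with
a vacant strand slot, scheduled tilt/egress/contact/flicker ground truth)
stands in for microsecond membrane simulations and gives every metric an
exact oracle.

## Worked example

Generate the default three-replica synthetic study bundle and run the full
pipeline:

```r
library(barrelgate)
dir <- tempfile()
cfg_path <- write_fixture_bundle(file.path(dir, "bundle"),
                                 seed = 1, n_frames = 200)
cfg <- read_run_config(cfg_path)
cfg$outdir <- file.path(dir, "out")
res <- run_pipeline(cfg)

r2 <- res$replicas[[2]]
r2$aperture
#> ApertureSeries: 200 frames, 3 pairs
#>      pair   mean_A      sd_A    min_A
#> 1 437-668 14.38403 0.3988570 13.35636
#> 2 433-666 19.49713 0.3921827 18.09064
#> 3 427-663 28.37253 0.4440822 27.02755
r2$closure$stayed_open
#> [1] TRUE
```

The three aperture pairs fluctuate by < 0.5 Å around stable means and
never approach the 6 Å closure threshold: the gate stays open. Replica 2
is the one whose lipid completes its egress — all six tails cross the
gate plane, sequentially:

```r
r2$insertion
#> InsertionSeries: 200 frames, 6 tails, final overall fraction 1.00
egress_order(r2$insertion)$table
#>   tail first_exit_frame exited
#> 1    1               21   TRUE
#> 2    2               46   TRUE
#> ...
#> 6    6              146   TRUE
```

Cross-replica contact scores single out the gate-flank residues; a
contact seen in only one replica scores exactly 0:

```r
tab <- res$aggregate$contact_table
head(tab[order(-tab$score), ], 5)
#>     resid freq_rep1 freq_rep2 freq_rep3 score
#> 10    433      1.00      1.00      1.00 1.000
#> 238   661      1.00      1.00      1.00 1.000
#> 245   668      0.93      0.95      0.97 0.950
#> 14    437      0.88      0.90      0.92 0.900
#> 240   663      0.83      0.85      0.87 0.850
```

`res$aggregate$annotated_path` points at a PDB with the scores in the
B-factor column, ready for colouring in a molecular viewer. The same
steps are available from a shell via the thin CLI
(`inst/cli/barrelgate.R synth | analyze | aggregate | config init`).

Real trajectories enter the same way: a multi-model PDB per replica (or a
DCD against a PDB topology via `read_dcd()`), plus a YAML config naming
the gate pairs, flank residues, lipid atoms and cutoffs — print a template
with `write_default_config()`.

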