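# riboqueue

Stochastic modeling of ribosome queuing and delayed reinitiation on
uORF-regulated mRNA leaders, built around the architecture of the human
ATF4 transcript leader.

## The problem

ATF4 translation is induced when cellular stress lowers ternary-complex
(TC, eIF2–GTP–Met-tRNAi) levels. The classical delayed-reinitiation
model — a REI-permissive uORF1 followed by an inhibitory, CDS-overlapping
uORF2 — does not explain why uORF2 remains well translated under stress,
why a uORF2-only reporter is still stress-inducible, or why ribosome
footprints pile up ~20 nt upstream of a stem-loop (SL3) in the
uORF2/CDS overlap. The extended model implemented here adds ribosome
queuing: SL3 stalls elongating ribosomes so that a queue of five 30-nt
80S footprints fills the 150 nt back to the uORF2 AUG, and a scanning
48S PIC stalled at SL3 sits with its P site exactly on a near-cognate
CUG 20 nt upstream, from which it can initiate.

For a scanning PIC that must reacquire TC at rate `k·tc_level` while
scanning at `v` nt/s, the probability of being initiation-competent
after `d` nt is `1 − (1 − q)^d` with `q = k·tc_level/(k·tc_level + v)`
— the discrete-race form whose continuum limit is the familiar
`1 − exp(−k·tc_level·d/v)`. Start-site selection couples to stress
through this distance race at every start codon of the leader.

The package provides:

* a **scanner** for leader features: uORFs/start-stop elements, Kozak
  context, near-cognate starts, DRACH/RRACH m6A motifs, hairpin minimum
  free energy (nearest-neighbor DP), frameshift signals, and ribosome
  queue geometry;
* a packaged **synthetic reference leader** realizing the published
  ATF4-like architecture, plus a declarative mutant construct registry
  (start-codon knockouts, SL3 unfolding, CUG and m6A substitutions,
  c-Myc insertions);
* a continuous-time **stochastic simulator** (Rcpp) of PIC loading,
  scanning, TC acquisition, initiation, elongation, stem-loop stalling,
  steric exclusion and reinitiation, with two independent verification
  oracles (an exact collision-free cascade and a brute-force
  master-equation solver);
* emulated **readouts**: reporter fold changes with bootstrap CIs,
  footprint/P-site/disome profiles, and the RNase protection assay
  (formaldehyde vs cycloheximide modes);
* **calibration** of the kinetic parameters against the published
  construct-expression ratio table.

## Worked example

```r
library(riboqueue)

ref <- build_reference_leader()
ref$manifest$uORF2_AUG_to_SL3_nt   # 150
queue_capacity(165, 315, 30)$capacity  # 5 ribosomes fit before SL3

params <- default_calibrated_params()$params
ns <- lapply(1:10, function(s)
  simulate_leader(ref, params, t_max = 2000, seed = s,
                  condition = "nonstress"))
st <- lapply(1:10, function(s)
  simulate_leader(ref, params, t_max = 2000, seed = 100 + s,
                  condition = "stress"))
fold_change(st, ns)$estimate
```

On the packaged calibration this prints a stress/non-stress fold
induction close to 5 (the run-to-run Monte Carlo spread at 10
replicates is roughly ±15%): under non-stress TC levels most scanning
ribosomes are captured by uORF2 — reinforced by the SL3 queue backing up
to its AUG — while under stress delayed TC reacquisition lets them skip
uORF2 and initiate at the main ORF. Applying a construct first, e.g.
`apply_construct(ref, "d-all")`, removes all upstream start codons and
raises non-stress output roughly twenty-fold over WT.

A queued ensemble shows the collision signatures directly:

```r
qp <- params; qp$dG_scale <- 3.0; class(qp) <- "sim_params"  # deepen stall
run <- simulate_leader(ref, qp, t_max = 2000, seed = 5, dt_snap = 8)
disome_profile(run, region = c(150, 330))$modal_spacing  # 60 nt
protection_assay(run, mode = "HCHO")
```

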