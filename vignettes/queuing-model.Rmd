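---
title: "Ribosome queuing and delayed reinitiation on the ATF4-like leader: the model behind riboqueue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosome queuing and delayed reinitiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboqueue)
```

## The biological problem

ATF4, the master transcriptional effector of the integrated stress
response, is translationally induced when global initiation drops.
Classically this is explained by delayed reinitiation: the 5' leader
carries a short REI-permissive uORF1 and a longer inhibitory uORF2 that
overlaps the main ORF out of frame. A 40S subunit that terminates uORF1
resumes scanning without a ternary complex (TC, eIF2–GTP–Met-tRNAi) and
must reacquire one before it can initiate again. At high TC levels the
rebinding happens within the short uORF1–uORF2 spacer, the 40S is
captured by uORF2 and lost; at stress-reduced TC levels rebinding is
delayed past the uORF2 AUG and the 40S initiates at the main ORF
instead. Several observations do not fit that picture alone: uORF2 stays
well translated under stress, a uORF2-only reporter is still
stress-inducible, and footprints pile up about 20 nt upstream of a
stem-loop (SL3) in the middle of the uORF2/CDS overlap. `riboqueue`
implements the extended model: SL3 acts as a physical barrier that
queues elongating 80S ribosomes (five 30-nt footprints fit exactly into
the 150 nt between the uORF2 AUG and SL3) and forces stalled scanning
PICs into productive initiation at a near-cognate CUG sitting 20 nt
upstream of SL3, precisely one PIC footprint away.

## The leader track and its annotation

All coordinates in the package are 1-based and inclusive; conversion to
0-based half-open intervals happens only when writing BED/bedGraph.
`annotate_leader()` detects, on any RNA sequence:

* uORFs and start-stop elements (`find_orfs()`); an ORF is
  REI-permissive when it has at most 30 sense codons and terminates
  upstream of the CDS — uORF1 qualifies, the CDS-overlapping uORF2 does
  not. Sense codons are counted between the AUG and the stop, so a
  start-stop element has zero.
* Kozak context (`classify_start_context()`): the package uses the
  standard two-determinant rule (purine at −3, G at +4; both = strong,
  one = medium, none = weak). The source data name the classes but not
  the rule; this convention reproduces the published medium/weak labels
  of AUG1–AUG3 and the CUG on the reference architecture.
* all nine single-mismatch near-cognate codons
  (`find_near_cognate_starts()`), a superset of the CUG/GUG named in the
  data, filterable downstream via their per-class initiation
  probabilities.
* DRACH/RRACH m6A motifs (`scan_methylation_motifs()`), reported with
  neutral effect parameters; which sites act as scanning roadblocks or
  stem destabilizers is a downstream modeling decision.
* hairpins, by a hairpin-only nearest-neighbor dynamic program
  (`predict_hairpins()`): a single stem with bulges and internal loops,
  no multiloops or pseudoknots, over a packaged stack/loop energy table
  (`default_energy_table()`). A full secondary-structure fold is out of
  scope because the object of interest is one local hairpin; absolute
  energies therefore carry a tolerance of roughly ±2 kcal/mol relative
  to full-featured folding tools, whose parameterization the source
  analysis did not pin down.
* heuristic frameshift signals (`find_frameshift_signals()`): slippery
  runs of three or more codons sharing their first two nucleotides, or
  long G/A homopolymers, and C-tracts (≥8 C within 12 nt, ≥5
  consecutive), with the 8-nt slippery-to-C-tract spacing flagged
  optimal.

## The packaged reference leader

The published analyses specify the leader's architecture (element
identities, spacings, contexts, motif positions) but not a complete
sequence, so the packaged fixture is synthetic by construction:
`build_reference_leader()` places designed element blocks at coordinates
compatible with the transcript numbering used for A235/A326, then fills
the gaps with seeded pseudo-random background and repairs violations by
rejection — stray AUGs, stop codons in the uORF2 and main frames,
accidental m6A motifs at the two control adenosines, and any competing
hairpin of stall-class stability outside the SL3 locus. The repair loop
also refolds the two stem-loop knockout mutants during assembly so that
the quadruple C→A mutation leaves no stall-class structure behind; the
GGG→AUC mutation deliberately retains a weakened stem (faster release)
rather than none, which matches its milder description. The background
is G-poor (and nearly C/G-free immediately around the SL3 locus): real
5' UTRs are more GC-rich and fold more, so passing tests on this fixture
demonstrates the machinery on a structurally quiet track, not
performance on arbitrary natural leaders.

Two recorded discrepancies in the source material are resolved as
follows: uORF1 is built with 3 sense codons (the figure-legend count;
the 4-codon phrasing presumably includes the stop), and the A326 analog
is paired inside the SL3 stem (the sequence-analysis placement) rather
than in the loop.

The realized design satisfies, by build-time assertion: start-stop
present; uORF1 = 3 codons; uORF2 = 60 codons in the −1 frame; SL3 base
exactly 150 nt downstream of the uORF2 AUG with ΔG ≈ −15 to −16.5
kcal/mol under the packaged table; the CUG 20 nt upstream of SL3 in the
main frame and weak context; AUG1/AUG2 medium, AUG3 weak and inside the
SL3 loop as the 17th codon; A235/A286/A326 analogs in motifs, A267/A311
motif-free controls; FS-A as three glycine codons with the C-tract at
the optimal 8-nt spacing. The mutant construct series is stored
declaratively in `inst/extdata/constructs.json` and applied by
`apply_construct()`, which re-annotates after editing; the c-Myc
insertions are 6 × 30 nt (after AUG1) and 10 × 30 nt (21 nt into
uORF2).

## The stochastic engine

`simulate_leader()` runs a continuous-time (Gillespie) simulation of
single ribosomes on the leader track. The species are scanning PICs
without TC, TC-bound PICs, and elongating 80S. The rules:

1. PICs load at the cap at rate `k_load` when the first footprint width
   is free, TC-less by default (`p_tc_load = 0`): all TC acquisition
   happens during scanning at rate `k_tc * tc_level`, which is what
   couples start-site selection to the stress condition for every
   construct, including leaders without uORF1. (Loading TC-bound is
   available as a configuration; with it, leaders lacking upstream
   TC-stripping elements lose all stress responsiveness, contrary to
   the uORF2-only observations.)
2. A TC-bound PIC dwelling on a start codon initiates rather than steps
   onward with probability `p_init(codon class, context)`, implemented
   as competing exponential rates (the initiation rate is
   `v_scan * p / (1 - p)`), so blocked dwells naturally raise capture.
3. Footprints exclude each other: PICs protect 12 nt upstream of the
   P site (exclusive) and 20 nt downstream (inclusive; the midpoint of
   the observed 15–25 range), 80S protect 30 nt (12 + P + 17).
4. A ribosome whose next move would push its leading edge into a folded
   stem-loop crosses at the stall-release rate
   `k_unwind = k0_unwind * exp(dG_eff / dG_scale)` composed serially
   with its free movement; a stem-loop is folded whenever no footprint
   overlaps its span, so each release flushes a short burst of the
   queue before the stem refolds.
5. A blocked or stalled TC-bound PIC may initiate at any start codon
   within ±15 nt of its P site (the back-and-forth migration window),
   at its rate multiplied by `queue_boost` and damped geometrically
   (`mig_decay` per nt) with distance — migration is diffusive, so
   displaced registers are visited less often. This one mechanism
   produces both queue-enhanced capture at the uORF2 AUG and CUG
   selection by SL3-stalled PICs.
6. Termination at a stop codon recycles the ribosome, except after
   REI-permissive uORFs (resume scanning TC-less with `p_rei_uorf`) and
   the start-stop element (`p_rei_stst`); uORF2 and the main ORF always
   recycle. Main-frame 80S that run off the modeled track end count as
   completed ATF4-like protein.
7. Modified m6A sites slow scanning (`m6a_block`) when outside a stem,
   or destabilize the stem they sit in (`m6a_stem_destab`, added to
   `dG_eff`). The A235 analog is modified under non-stress only (stress
   removes the barrier); the in-stem A326 analog is constitutive.

Every run reports exact event accounting
(`loads = scanned_off + recycled + run-off + still-elongating`), per-site
initiation counts, per-origin protein outputs, time-averaged occupancy,
and steady-state snapshots (by default the first 20% of the run is
discarded as burn-in).

## Verification: two independent oracles

`analytic_small_model()` solves the collision-free model exactly: each
dwell is a closed-form race among stepping, TC binding, and initiation
(with the stall and migration-window terms included), and REI spawns
weighted TC-less passes. `markov_oracle()` builds the full
continuous-time Markov chain over one- or two-ribosome configurations
with exclusion and solves for the stationary distribution. The two agree
to machine precision in the one-ribosome regime (they are independent
implementations), and the stochastic engine matches both within Monte
Carlo error — in no-exclusion mode against the cascade, and with
exclusion against the two-ribosome chain. TC reacquisition over a
distance d follows the discrete form `1 - (1 - q)^d` with
`q = k_tc_eff / (k_tc_eff + v_scan)`, the exact solution of the per-nt
race; the familiar `1 - exp(-k d / v)` is its continuum limit.

## Emulated readouts

* `fold_change()`: ratio of mean main-ORF outputs with a percentile
  bootstrap CI, covering all reporter comparison axes (mutant vs WT per
  condition; stress vs non-stress per construct).
* `footprint_profile()`: snapshot states to coverage and P-site
  histograms per species, using the true stored geometry.
* `disome_profile()`: stacked 80S (P-site gap exactly one footprint)
  form chains; all adjacent pairs are counted, but nuclease fragments
  are disjoint, so fragment calls pair ribosomes greedily from the
  stall-anchored 3' end of each chain. In a packed five-ribosome queue
  this yields fragment 5' ends spaced 60 nt — the disome length — with
  the 5'-most ribosome left as a monosome on the uORF2 AUG.
* `protection_assay()`: an amplicon survives a snapshot only if every
  nucleotide is covered by a protected footprint (RNase I cleaves any
  exposed region and qPCR needs an intact template). Formaldehyde mode
  counts PIC and 80S footprints; the cycloheximide control counts 80S
  footprints only, each retained with probability `chx_retention`
  (default 0.6) because non-cross-linked complexes partially dissociate
  during workup — this makes the HCHO ≥ CHX ordering structural and the
  CHX signal weak, as observed. A1 spans the queuing region (uORF2 AUG +
  132 nt), A2/A3 are equal-length controls. Enrichment ratios carry a
  half-count pseudocount; absolute enrichment values depend on nuisance
  parameters (snapshot count, amplicon margins) and are interpreted
  directionally. One directional feature is *not* stably reproduced at
  the committed calibration: the formaldehyde enrichment under stress
  exceeding the one under non-stress. Because TC rebinding is nearly
  complete by the uORF2 AUG even at the stress TC level, the two
  conditions occupy the queuing region almost equally; what does emerge
  robustly is the inference behind that ordering — a mixed queue, i.e. a
  roughly two-fold higher scanning-PIC share of queue-region occupancy
  under stress.
* `generate_synthetic_footprints()` draws multinomial P-sites at a given
  depth with configurable read lengths and jitter, to test the profile
  machinery independently of the simulator.

## Calibration

`fit_parameters()` minimizes the weighted mean squared log-ratio error
between simulated and tabulated construct/condition expression ratios
(`target_table()`), with common random numbers across evaluations and a
probe-then-Nelder-Mead search. Ratios were chosen because the targets
span 0.2–22.7; the three headline rows (WT fold induction 5.2, d-all/WT
22.7, uORF2-only induction 3.2) carry weight 3 because they are the
quantities the model exists to explain. Percent-style statements are
stored as ratios (an 80% drop is 0.2). At most a handful of parameters
are fit — the table cannot identify more; absolute flux scale
(`k_load`) cancels in every ratio and is flagged non-identifiable by
`parameter_recovery_test()`.

The committed set (`default_calibrated_params()`) pins
`v_scan = 5 nt/s`, `v_elong = 5 codons/s`, footprints at their measured
sizes, and fixes the fitted values `k_tc = 0.27/s`,
`tc_level_stress = 0.37`, `p_rei_uorf = 0.35`, `dG_scale = 4.4`,
strong-context capture 0.985, medium 0.58, weak 0.25. Three structural
conclusions from the calibration are worth stating. First, TC
reacquisition must be slow on the scanning timescale (mean rebinding
distance of tens of nt even at full TC): this is what gives the WT
leader measurable basal output via uORF1-skip under non-stress while
uORF2-only output stays several-fold lower. Second, cap-loaded PICs
must acquire TC en route: the uORF2-only construct is stress-inducible
only because a fraction of PICs reach the uORF2 AUG TC-less under
stress and are rescued downstream, partly by the SL3-stalled CUG
channel. Third, absolute loading flux cancels exactly in collision-free
expression ratios but retains weak identifiability through queue depths
once exclusion is on; the recovery harness flags the collision-free
cancellation and documents the nuance.

Simulation sizes: calibration and acceptance use runs of 2000–2500
simulated seconds (roughly 150–200 loading events each) with about 20
replicates per construct and condition, which puts the Monte Carlo
error of the headline ratios near 5–10%.

## Known limitations

* The fixture is one synthetic realization of the published
  architecture; numbers on the real transcript will differ within the
  stated tolerances, and the background is deliberately structure-poor.
* The hairpin model is local; long-range or pseudoknotted structure is
  out of scope, as are whole-cell ISR dynamics, collision surveillance,
  and codon-specific elongation.
* Several secondary targets (the m6A substitutions, the
  St-st/uORF1-only series) are reproduced directionally but sit at the
  edge of their printed "~" precision; the protection-assay enrichments
  are directional by design.
* The start-stop element inflates its own initiation via the roadblock
  slow-down over its span (a longer dwell on the AUG); its net effect
  is tuned jointly through `p_rei_stst` and `stst_block`.
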