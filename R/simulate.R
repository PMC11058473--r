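#' Simulation parameters
#'
#' All kinetic and probabilistic knobs of the scanning/initiation model.
#' Rates are per second, distances in nt, probabilities dimensionless.
#'
#' @param k_load PIC cap-loading rate (1/s); loading requires the first
#'   footprint width of the track to be unoccupied.
#' @param v_scan Scanning rate (nt/s).
#' @param v_elong Elongation rate (codons/s).
#' @param k_tc Ternary-complex (TC) binding rate at `tc_level = 1` (1/s);
#'   the realized rate is `k_tc * tc_level`.
#' @param tc_level_nonstress,tc_level_stress TC availability in the two
#'   conditions (dimensionless, in 0..1).
#' @param p_tc_load Probability a PIC carries TC already at cap loading.
#'   The default 0 makes all TC acquisition happen during scanning, which
#'   is what couples start-site selection to `tc_level`.
#' @param p_init Named list of per-dwell initiation probabilities by codon
#'   class and Kozak context: `aug_strong`, `aug_medium`, `aug_weak`,
#'   `nc_strong`, `nc_medium`, `nc_weak`, and the near-cognate CUG-in-weak-
#'   context override `cug_weak`. A TC-bound PIC dwelling over a start
#'   codon initiates rather than steps onward with this probability.
#' @param p_rei_uorf Probability that the 40S resumes scanning (TC-less)
#'   after terminating a REI-permissive uORF.
#' @param p_rei_stst Same for the start-stop element.
#' @param stst_block Scanning slow-down factor across the start-stop span
#'   (roadblock by occupying/recycling ribosomes).
#' @param k0_unwind,dG_scale Stall release at a folded stem-loop:
#'   `k_unwind = k0_unwind * exp(dG_eff / dG_scale)` with `dG_eff` the
#'   hairpin free energy (kcal/mol, negative) plus any m6A stem
#'   destabilization.
#' @param m6a_block Scanning slow-down factor over a modified (roadblock
#'   class) m6A site.
#' @param m6a_stem_destab Stem destabilization (kcal/mol, positive) by a
#'   modified in-stem m6A site.
#' @param sl_stall_cutoff Hairpins at least this stable act as stalls.
#' @param queue_boost Multiplier on the initiation rate of a blocked or
#'   stalled TC-bound PIC, for start codons within its migration window.
#' @param mig_decay Per-nt geometric decay of the migration-window
#'   initiation rate with distance from the anchored P site (migration is
#'   diffusive; displaced registers are visited less often).
#' @param pic_model PIC footprint geometry ([pic_footprint_model()]).
#' @param fp80_up,fp80_down 80S footprint: nt upstream of the P site
#'   (excluded) and downstream (excluded); total footprint is
#'   `fp80_up + 1 + fp80_down` = 30 nt by default.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(k_load = 0.12, v_scan = 5, v_elong = 3, k_tc = 2,
                       tc_level_nonstress = 1.0, tc_level_stress = 0.03,
                       p_tc_load = 0,
                       p_init = list(aug_strong = 0.85, aug_medium = 0.55,
                                     aug_weak = 0.25, nc_strong = 0.002,
                                     nc_medium = 0.0008, nc_weak = 0.0003,
                                     cug_weak = 0.0008),
                       p_rei_uorf = 0.55, p_rei_stst = 0.5, stst_block = 4,
                       k0_unwind = 2, dG_scale = 3.6, m6a_block = 25,
                       m6a_stem_destab = 3, sl_stall_cutoff = -10,
                       queue_boost = 20, mig_decay = 0.6,
                       pic_model = pic_footprint_model(),
                       fp80_up = 12L, fp80_down = 17L) {
  p <- as.list(environment())
  stopifnot(k_load >= 0, v_scan > 0, v_elong > 0, k_tc >= 0,
            tc_level_nonstress >= 0, tc_level_nonstress <= 1,
            tc_level_stress >= 0, tc_level_stress <= 1,
            p_tc_load >= 0, p_tc_load <= 1,
            all(unlist(p_init) >= 0), all(unlist(p_init) <= 1),
            p_rei_uorf >= 0, p_rei_uorf <= 1, p_rei_stst >= 0,
            p_rei_stst <= 1, stst_block >= 1, k0_unwind > 0,
            dG_scale > 0, m6a_block >= 1, queue_boost >= 0,
            fp80_up >= 0, fp80_down >= 1)
  structure(p, class = "sim_params")
}

# Per-site initiation probability from codon class and context.
site_p_init <- function(codon, context, is_cognate, p_init) {
  if (is_cognate) {
    p_init[[paste0("aug_", context)]]
  } else if (codon == "CUG" && context == "weak" &&
             !is.null(p_init$cug_weak)) {
    p_init$cug_weak
  } else {
    p_init[[paste0("nc_", context)]]
  }
}

# First in-frame stop downstream of an initiation at `pos`; 0 = run-off.
orf_stop_from <- function(sequence, pos) {
  n <- nchar(sequence)
  q <- pos + 3L
  while (q + 2L <= n) {
    if (codon_at(sequence, q) %in% STOP_CODONS) return(as.integer(q))
    q <- q + 3L
  }
  0L
}

# Assemble the flat engine input from annotation + parameters.
engine_spec <- function(leader, params, condition = c("nonstress", "stress"),
                        tc_level = NULL, t_max = 1500, no_exclusion = FALSE,
                        burn_in_frac = 0.2, dt_snap = 5, keep_log = FALSE) {
  condition <- match.arg(condition)
  if (is.null(tc_level)) {
    tc_level <- if (condition == "stress") params$tc_level_stress
                else params$tc_level_nonstress
  }
  s <- leader$sequence
  L <- nchar(s)
  st <- leader$elements$starts
  orfs <- leader$elements$orfs

  p <- vapply(seq_len(nrow(st)), function(i) {
    site_p_init(st$codon[i], st$context[i], st$is_cognate[i], params$p_init)
  }, 0)
  p <- pmin(p, 0.999)
  lambda <- params$v_scan * p / (1 - p)
  stops <- vapply(st$pos, function(x) orf_stop_from(s, x), 0L)
  prei <- numeric(nrow(st))
  if (nrow(orfs)) {
    for (i in seq_len(nrow(st))) {
      j <- which(orfs$start == st$pos[i])
      if (length(j) == 1) {
        prei[i] <- if (orfs$is_stst[j]) params$p_rei_stst
                   else if (orfs$rei_permissive[j]) params$p_rei_uorf else 0
      }
    }
  }

  modified <- if (condition == "stress") leader$elements$methyl$modified_stress
              else leader$elements$methyl$modified_nonstress
  me <- leader$elements$methyl

  hp <- leader$elements$hairpins
  sls <- hp[hp$delta_G <= params$sl_stall_cutoff, , drop = FALSE]
  k_unwind <- numeric(nrow(sls))
  if (nrow(sls)) {
    for (i in seq_len(nrow(sls))) {
      destab <- 0
      if (nrow(me)) {
        in_sl <- me$pos >= sls$five_prime_base[i] &
          me$pos <= sls$three_prime_end[i] & me$in_stem & modified
        destab <- sum(in_sl) * params$m6a_stem_destab
      }
      k_unwind[i] <- params$k0_unwind *
        exp((sls$delta_G[i] + destab) / params$dG_scale)
    }
  }

  slow <- rep(1, L)
  if (nrow(me)) {
    road <- me$pos[modified & !me$in_stem]
    slow[road] <- slow[road] * params$m6a_block
  }
  if (nrow(orfs)) {
    for (j in which(orfs$is_stst)) {
      span <- orfs$start[j]:(orfs$stop[j] + 2L)
      slow[span] <- slow[span] * params$stst_block
    }
  }

  list(L = L, cds_start = leader$cds_start,
       site_pos = as.integer(st$pos), site_lambda = lambda,
       site_stop = as.integer(stops), site_prei = prei,
       sl_base = as.integer(sls$five_prime_base),
       sl_end = as.integer(sls$three_prime_end), sl_k = k_unwind,
       slow = slow, k_load = params$k_load, v_scan = params$v_scan,
       v_elong = params$v_elong, k_tc_eff = params$k_tc * tc_level,
       p_tc_load = params$p_tc_load,
       pic_up = leader$pic_model$upstream,
       pic_down = leader$pic_model$downstream,
       fp80_up = as.integer(params$fp80_up),
       fp80_down = as.integer(params$fp80_down),
       mig = leader$pic_model$migration,
       queue_boost = params$queue_boost, mig_decay = params$mig_decay,
       t_max = t_max,
       burn_in = burn_in_frac * t_max, dt_snap = dt_snap,
       no_exclusion = no_exclusion, keep_log = keep_log,
       tc_level = tc_level, site_codon = st$codon,
       site_frame = st$frame_vs_cds, site_cognate = st$is_cognate)
}

#' Simulate translation on an annotated leader
#'
#' Continuous-time stochastic simulation (exponential waiting times) of
#' PIC loading, scanning, TC acquisition, start-codon selection,
#' elongation, stem-loop stalling, steric exclusion and reinitiation.
#' Deterministic for a fixed seed.
#'
#' @param leader A `leader_annotation`.
#' @param params A [sim_params()] object.
#' @param t_max Simulated time (s).
#' @param seed Integer seed.
#' @param condition `"nonstress"` or `"stress"`; selects the TC level.
#' @param tc_level Optional explicit TC level overriding `condition`.
#' @param no_exclusion Disable ribosome-ribosome exclusion (collision-free
#'   mode used for oracle comparisons; stem-loop stalling stays active).
#' @param burn_in_frac Fraction of `t_max` discarded before snapshots.
#' @param dt_snap Snapshot sampling interval (s).
#' @param keep_log Keep a capped event log.
#' @return Object of class `sim_result`: counts (`loads`, `scanned_off`,
#'   `recycled`, `runoff`, `alive_end`), `initiation_counts` and
#'   `proteins` tables, `occupancy` (3 x L matrix: PIC-noTC, PIC-TC, 80S),
#'   `snapshots` data frame, `t_end`, `seed`, and the engine spec.
#' @export
#' @examples
#' ref <- build_reference_leader()
#' res <- simulate_leader(ref, sim_params(), t_max = 200, seed = 1)
#' atf4_output(res)
simulate_leader <- function(leader, params = sim_params(), t_max = 1500,
                            seed = 1L, condition = c("nonstress", "stress"),
                            tc_level = NULL, no_exclusion = FALSE,
                            burn_in_frac = 0.2, dt_snap = 5,
                            keep_log = FALSE) {
  stopifnot(t_max > 0)
  spec <- engine_spec(leader, params, condition, tc_level, t_max,
                      no_exclusion, burn_in_frac, dt_snap, keep_log)
  if (spec$L < spec$pic_up + spec$pic_down) {
    stop("footprint larger than the track")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  raw <- .simulate_track(spec)

  proteins <- data.frame(
    origin = spec$site_pos, codon = spec$site_codon,
    is_cognate = spec$site_cognate, frame_vs_cds = spec$site_frame,
    orf_stop = spec$site_stop, count = raw$protein,
    initiations = raw$init_counts)
  proteins$is_main_frame_runoff <- proteins$orf_stop == 0 &
    proteins$frame_vs_cds == 0
  structure(list(
    loads = raw$loads, scanned_off = raw$scanned_off,
    recycled = raw$recycled, runoff = raw$runoff,
    alive_end = raw$alive_end, n_events = raw$n_events,
    initiation_counts = setNames(raw$init_counts, spec$site_pos),
    proteins = proteins,
    occupancy = raw$occupancy, snapshots = raw$snap,
    n_snapshots = raw$n_snapshots,
    alive = data.frame(species = raw$alive_species, psite = raw$alive_psite),
    event_log = raw$log, t_end = raw$t_end, seed = seed,
    condition = if (is.null(tc_level)) match.arg(condition) else "custom",
    tc_level = spec$tc_level, spec = spec),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: t_end", x$t_end, "s, tc_level", x$tc_level, "\n")
  cat("  loads", x$loads, "| scanned off", x$scanned_off, "| recycled",
      x$recycled, "| run-off", x$runoff, "| alive", x$alive_end, "\n")
  cat("  main-frame run-off output:", atf4_output(x), "\n")
  invisible(x)
}

#' Main-ORF (ATF4-like) protein output of a run
#'
#' Completed syntheses whose origin start codon is in the main reading
#' frame and whose ORF runs off the modeled track (full-length and
#' near-full-length isoforms: AUG1, AUG2, the queue-associated CUG, AUG3,
#' internal in-frame AUGs).
#'
#' @param result A `sim_result`.
#' @return Count of completed main-frame syntheses.
#' @export
atf4_output <- function(result) {
  sum(result$proteins$count[result$proteins$is_main_frame_runoff])
}

#' uORF output of a run
#'
#' Completed syntheses originating at a given uORF start.
#'
#' @param result A `sim_result`.
#' @param start uORF start position.
#' @return Count.
#' @export
uorf_output <- function(result, start) {
  sum(result$proteins$count[result$proteins$origin == start])
}

# Exact event-accounting identity; TRUE for every run.
conservation_ok <- function(result) {
  isTRUE(all.equal(result$loads,
                   result$scanned_off + result$recycled + result$runoff +
                     result$alive_end))
}
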