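## Emulated experimental readouts: reporter fold changes, footprint /
## P-site / frame / disome profiles, and the RNase protection assay.

# Footprint interval of one ribosome record given the engine geometry.
record_footprint <- function(species, psite, spec) {
  if (species == 2) c(psite - spec$fp80_up, psite + spec$fp80_down)
  else c(psite - spec$pic_up, psite + spec$pic_down - 1L)
}

#' Per-start-site protein output table
#'
#' Completed syntheses per origin start codon with product size-class
#' labels: `full` (main-frame run-off from the annotated CDS start),
#' `near-full` (main-frame run-off from nearby downstream starts, e.g.
#' the queue-associated CUG or AUG2/AUG3), `short-isoform` (main-frame
#' run-off from internal starts), `uORF` products, and `upstream` for
#' everything else.
#'
#' @param result A `sim_result`.
#' @return Data frame sorted by decreasing count.
#' @export
protein_outputs <- function(result) {
  pr <- result$proteins
  cds_start <- result$spec$cds_start
  lab <- rep("upstream", nrow(pr))
  lab[pr$orf_stop > 0] <- "uORF"
  main <- pr$is_main_frame_runoff
  lab[main] <- "short-isoform"
  lab[main & pr$origin <= cds_start + 60] <- "near-full"
  lab[main & pr$origin == cds_start] <- "full"
  out <- data.frame(origin = pr$origin, codon = pr$codon,
                    context_cognate = pr$is_cognate,
                    frame_vs_cds = pr$frame_vs_cds,
                    size_class = lab, count = pr$count,
                    initiations = pr$initiations)
  out[order(-out$count), , drop = FALSE]
}

#' Reporter fold change with bootstrap confidence interval
#'
#' Ratio of mean main-ORF outputs between two replicate ensembles, with a
#' percentile bootstrap CI over replicates. This supports all comparison
#' axes of the reporter bookkeeping: mutant vs WT within a condition, or
#' stress vs non-stress within a construct.
#'
#' @param results_num,results_den Numerator / denominator replicates:
#'   lists of `sim_result` objects or numeric vectors of outputs.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @return List with `estimate`, `ci` (length 2), `n`, and `infinite`
#'   flag (zero denominator).
#' @export
fold_change <- function(results_num, results_den, n_boot = 2000,
                        conf = 0.95) {
  as_out <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, atf4_output, 0)
  }
  num <- as_out(results_num); den <- as_out(results_den)
  if (mean(den) == 0) {
    warning("zero denominator ensemble; fold change is infinite")
    return(list(estimate = Inf, ci = c(NA_real_, NA_real_),
                n = c(length(num), length(den)), infinite = TRUE))
  }
  est <- mean(num) / mean(den)
  bs <- vapply(seq_len(n_boot), function(i) {
    m <- mean(sample(num, replace = TRUE))
    d <- mean(sample(den, replace = TRUE))
    if (d == 0) NA_real_ else m / d
  }, 0)
  a <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(quantile(bs, c(a, 1 - a), na.rm = TRUE)),
       n = c(length(num), length(den)), infinite = FALSE)
}

#' Footprint profile of a simulated run
#'
#' Converts snapshot ribosome states into protected-fragment coverage and
#' a P-site histogram per species. P-site assignment uses the true stored
#' geometry (no offset inference is needed).
#'
#' @param result A `sim_result`.
#' @param region Optional interval restricting the profile.
#' @return List with `coverage` (3 x L matrix: PIC-noTC, PIC-TC, 80S),
#'   `psite_hist` (3 x L counts over snapshots), `n_snapshots`.
#' @export
footprint_profile <- function(result, region = NULL) {
  spec <- result$spec
  L <- spec$L
  snap <- result$snapshots
  cov <- matrix(0, 3, L)
  ph <- matrix(0, 3, L)
  if (nrow(snap)) {
    for (i in seq_len(nrow(snap))) {
      sp <- snap$species[i] + 1L
      p <- snap$psite[i]
      if (p >= 1 && p <= L) ph[sp, p] <- ph[sp, p] + 1
      f <- record_footprint(snap$species[i], p, spec)
      a <- max(1L, f[1]); b <- min(L, f[2])
      cov[sp, a:b] <- cov[sp, a:b] + 1
    }
  }
  if (!is.null(region)) {
    keep <- seq(region[1], region[2])
    mask <- rep(0, L); mask[keep] <- 1
    cov <- sweep(cov, 2, mask, `*`)
    ph <- sweep(ph, 2, mask, `*`)
  }
  list(coverage = cov, psite_hist = ph, n_snapshots = result$n_snapshots)
}

#' Disome profile: stacked-80S pairs and fragment 5'-end histogram
#'
#' Within each snapshot, 80S ribosomes whose P sites are exactly one
#' footprint apart form stacked chains. All adjacent pairs are reported
#' in `pairs_per_snapshot`. Nuclease fragments are disjoint, so fragment
#' calling pairs ribosomes greedily from the 3' (stall-anchored) end of
#' each chain; the 5' end of each called disome fragment enters
#' `fragment_5p_hist`, and `modal_spacing` is the most common distance
#' between successive fragment 5' ends within a snapshot.
#'
#' @param result A `sim_result`.
#' @param region Optional interval: only chains whose P sites fall inside
#'   are considered.
#' @param slack Allowed deviation (nt) from the exact footprint gap when
#'   calling stacked pairs.
#' @return List with `fragment_5p_hist` (named counts),
#'   `n_adjacent_pairs`, `modal_spacing` (NA when fewer than two
#'   fragments ever co-occur), and `spacings` (table of observed
#'   spacings).
#' @export
disome_profile <- function(result, region = NULL, slack = 0L) {
  spec <- result$spec
  fp80 <- spec$fp80_up + spec$fp80_down + 1L
  snap <- result$snapshots
  snap <- snap[snap$species == 2, , drop = FALSE]
  if (!is.null(region)) {
    snap <- snap[snap$psite >= region[1] & snap$psite <= region[2], ,
                 drop = FALSE]
  }
  hist5 <- integer(); spacings <- integer(); n_pairs <- 0L
  for (sid in unique(snap$snapshot)) {
    ps <- sort(snap$psite[snap$snapshot == sid])
    if (length(ps) < 2) next
    gaps <- diff(ps)
    stacked <- abs(gaps - fp80) <= slack
    n_pairs <- n_pairs + sum(stacked)
    # chains of consecutively stacked ribosomes
    frag5 <- integer()
    i <- 1L
    while (i <= length(ps)) {
      j <- i
      while (j < length(ps) && stacked[j]) j <- j + 1L
      if (j > i) {
        # greedy non-overlapping pairing from the 3' end of the chain
        members <- rev(ps[i:j])      # 3' -> 5'
        kk <- 1L
        while (kk + 1L <= length(members)) {
          up <- members[kk + 1L]     # 5' ribosome of the pair
          frag5 <- c(frag5, up - spec$fp80_up)
          kk <- kk + 2L
        }
      }
      i <- j + 1L
    }
    if (length(frag5)) {
      hist5 <- c(hist5, frag5)
      if (length(frag5) > 1) {
        spacings <- c(spacings, diff(sort(frag5)))
      }
    }
  }
  tab <- if (length(spacings)) table(spacings) else table(integer())
  modal <- if (length(spacings)) as.integer(names(tab)[which.max(tab)]) else NA_integer_
  list(fragment_5p_hist = table(hist5), n_adjacent_pairs = n_pairs,
       modal_spacing = modal, spacings = tab)
}

#' Frame decomposition of elongating ribosomes in a region
#'
#' Fractions of 80S snapshot dwell within `region` by the reading frame
#' of the origin start codon relative to the main ORF (0 = main frame,
#' -1 = the uORF2 frame on the reference leader, +1 = the third frame).
#'
#' @param result A `sim_result`.
#' @param region Interval (P sites considered).
#' @return Named numeric of fractions summing to 1, or all-NA (flagged
#'   via attribute `undefined`) when the region has no 80S coverage.
#' @export
frame_distribution <- function(result, region) {
  snap <- result$snapshots
  snap <- snap[snap$species == 2 & !is.na(snap$origin) &
                 snap$psite >= region[1] & snap$psite <= region[2], ,
               drop = FALSE]
  out <- c(`0` = 0, `1` = 0, `-1` = 0)
  if (!nrow(snap)) {
    out[] <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  pos2frame <- setNames(result$spec$site_frame,
                        as.character(result$spec$site_pos))
  fr <- pos2frame[as.character(snap$origin)]
  tab <- table(factor(fr, levels = c("0", "1", "-1")))
  out[] <- as.numeric(tab) / sum(tab)
  attr(out, "undefined") <- FALSE
  out
}

#' Amplicons of the ribosome protection assay on the reference leader
#'
#' A1 spans the putative queuing region (uORF2 AUG to just before SL3,
#' 132 nt); A2 the similar-length region immediately downstream of SL3;
#' A3 a similar-length region in the middle of the modeled CDS.
#'
#' @return Data frame with `name`, `start`, `end`, `length`.
#' @export
reference_amplicons <- function() {
  co <- REF_COORDS
  a1 <- c(co$uorf2_start, co$uorf2_start + 131L)
  a2 <- c(co$sl3_end + 3L, co$sl3_end + 134L)
  a3 <- c(co$L - 131L, co$L)
  data.frame(name = c("A1", "A2", "A3"),
             start = c(a1[1], a2[1], a3[1]),
             end = c(a1[2], a2[2], a3[2]),
             length = c(diff(a1), diff(a2), diff(a3)) + 1L)
}

#' Emulated RNase protection assay
#'
#' An amplicon survives digestion in one snapshot iff every nucleotide of
#' its interval is covered by a protected footprint. Formaldehyde
#' cross-linking (`HCHO`) preserves both scanning PICs and 80S; the
#' cycloheximide control (`CHX`) preserves 80S footprints only. Survival
#' is the fraction of snapshots protected; enrichment ratios carry a
#' pseudocount guard of half a count. Without cross-linking, ribosome-mRNA
#' complexes partially dissociate during workup, so each 80S footprint in
#' CHX mode is retained only with probability `chx_retention`.
#'
#' @param results A `sim_result` or list of them (snapshot ensembles are
#'   pooled).
#' @param amplicons Data frame as from [reference_amplicons()].
#' @param mode `"HCHO"` or `"CHX"`.
#' @param chx_retention Per-footprint retention probability in CHX mode.
#' @param seed Seed for the CHX retention thinning.
#' @return Object of class `protection_result`: list with `mode`,
#'   `survival` (named fractions), `enrichment` (named ratios
#'   `A1/A2`, `A1/A3`), `n_snapshots`.
#' @export
protection_assay <- function(results, amplicons = reference_amplicons(),
                             mode = c("HCHO", "CHX"), chx_retention = 0.6,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(results, "sim_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  spec <- results[[1]]$spec
  L <- spec$L
  if (any(amplicons$end > L | amplicons$start < 1)) {
    stop("amplicon outside the leader track")
  }
  keep_species <- if (mode == "HCHO") c(0L, 1L, 2L) else 2L
  surv <- setNames(numeric(nrow(amplicons)), amplicons$name)
  n_snap <- 0L
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  for (res in results) {
    snap <- res$snapshots
    snap <- snap[snap$species %in% keep_species, , drop = FALSE]
    if (mode == "CHX" && chx_retention < 1 && nrow(snap)) {
      snap <- snap[runif(nrow(snap)) < chx_retention, , drop = FALSE]
    }
    n_snap <- n_snap + res$n_snapshots
    for (sid in unique(snap$snapshot)) {
      rows <- snap[snap$snapshot == sid, , drop = FALSE]
      covered <- rep(FALSE, L)
      for (i in seq_len(nrow(rows))) {
        f <- record_footprint(rows$species[i], rows$psite[i], spec)
        a <- max(1L, f[1]); b <- min(L, f[2])
        covered[a:b] <- TRUE
      }
      for (ai in seq_len(nrow(amplicons))) {
        if (all(covered[amplicons$start[ai]:amplicons$end[ai]])) {
          surv[ai] <- surv[ai] + 1
        }
      }
    }
  }
  if (n_snap == 0) stop("empty ensemble: no snapshots")
  surv <- surv / n_snap
  pc <- 0.5 / n_snap
  enr <- c(`A1/A2` = (surv[["A1"]] + pc) / (surv[["A2"]] + pc),
           `A1/A3` = (surv[["A1"]] + pc) / (surv[["A3"]] + pc))
  structure(list(mode = mode, survival = surv, enrichment = enr,
                 n_snapshots = n_snap),
            class = "protection_result")
}

#' @export
print.protection_result <- function(x, ...) {
  cat("protection_result (", x$mode, ", ", x$n_snapshots, " snapshots)\n",
      sep = "")
  cat("  survival:", paste(names(x$survival),
                           signif(x$survival, 3), sep = "=", collapse = " "), "\n")
  cat("  enrichment:", paste(names(x$enrichment),
                             signif(x$enrichment, 3), sep = "=", collapse = " "), "\n")
  invisible(x)
}
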