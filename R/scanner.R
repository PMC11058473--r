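## Sequence/structure feature detection on mRNA leaders.
## Coordinates are 1-based, inclusive, throughout the package; conversion to
## 0-based half-open happens only at the BED/bedGraph I/O boundary.

STOP_CODONS <- c("UAA", "UAG", "UGA")
NEAR_COGNATES <- c("CUG", "GUG", "UUG", "ACG", "AGG", "AAG", "AUA", "AUC", "AUU")

# Normalize a nucleotide string to RNA uppercase; error on anything else.
normalize_rna <- function(sequence) {
  s <- chartr("acgtu", "ACGUU", sequence)
  s <- chartr("T", "U", s)
  bad <- gsub("[ACGU]", "", s)
  if (nzchar(bad)) {
    stop("non-ACGTU characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  s
}

codon_at <- function(sequence, pos) substr(sequence, pos, pos + 2)

# Frame of `pos` relative to `cds_start`, reported as 0, +1 or -1.
frame_vs_cds <- function(pos, cds_start) {
  f <- (pos - cds_start) %% 3
  c(0L, 1L, -1L)[f + 1L]
}

#' Classify the Kozak initiation context of a start codon
#'
#' The two classical determinants are used: a purine (A/G) at position -3
#' and a G at position +4 (numbering the first base of the codon +1).
#' `strong` means both determinants hold, `medium` exactly one, `weak`
#' neither. When the sequence is too short for the -3 or +4 lookup the
#' missing determinant counts as absent and the result is flagged truncated.
#'
#' @param sequence RNA string.
#' @param pos 1-based position of the first base of the start codon.
#' @return A list with `label` ("strong", "medium" or "weak"), `minus3`,
#'   `plus4` (bases or NA) and `truncated`.
#' @export
#' @examples
#' classify_start_context("GCCACCAUGG", 7)$label  # strong
classify_start_context <- function(sequence, pos) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  m3 <- if (pos - 3 >= 1) substr(sequence, pos - 3, pos - 3) else NA_character_
  p4 <- if (pos + 3 <= n) substr(sequence, pos + 3, pos + 3) else NA_character_
  d1 <- isTRUE(m3 %in% c("A", "G"))
  d2 <- isTRUE(p4 == "G")
  label <- c("weak", "medium", "strong")[d1 + d2 + 1L]
  list(label = label, minus3 = m3, plus4 = p4,
       truncated = is.na(m3) || is.na(p4))
}

#' Find upstream open reading frames and start-stop elements
#'
#' Every AUG whose first base lies in `region` opens an ORF that is closed
#' at the first in-frame stop codon (UAA/UAG/UGA), searching to the end of
#' the sequence; ORFs without an in-frame stop are flagged stop-less.
#' An ORF with zero sense codons (AUG immediately followed by a stop) is a
#' start-stop element. An ORF is called REI-permissive when it is short
#' (`rei_max_codons` or fewer sense codons) and terminates upstream of the
#' main ORF start, the configuration that allows the terminating 40S to
#' resume scanning.
#'
#' @param sequence RNA string.
#' @param region Integer pair: first bases of candidate AUGs must lie here.
#' @param cds_start Main-ORF start used for frame and REI classification
#'   (default: beyond the region, so frames are relative to region end).
#' @param rei_max_codons Maximum sense-codon count for REI permissiveness.
#' @return Data frame with columns `start`, `stop` (first base of the stop
#'   codon, NA if stop-less), `n_codons`, `frame_vs_cds`, `is_stst`,
#'   `rei_permissive`, `context`, `stopless`.
#' @export
find_orfs <- function(sequence, region = c(1L, nchar(sequence)),
                      cds_start = nchar(sequence) + 1L,
                      rei_max_codons = 30L) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= n)
  out <- list()
  for (p in seq(region[1], max(region[1], region[2]))) {
    if (p + 2 > n || codon_at(sequence, p) != "AUG") next
    stop_pos <- NA_integer_
    q <- p + 3
    while (q + 2 <= n) {
      if (codon_at(sequence, q) %in% STOP_CODONS) { stop_pos <- q; break }
      q <- q + 3
    }
    n_codons <- if (is.na(stop_pos)) (n - p - 2) %/% 3 else (stop_pos - p - 3) %/% 3
    out[[length(out) + 1]] <- data.frame(
      start = p, stop = stop_pos, n_codons = as.integer(n_codons),
      frame_vs_cds = frame_vs_cds(p, cds_start),
      is_stst = isTRUE(stop_pos == p + 3),
      rei_permissive = !is.na(stop_pos) && stop_pos > p + 3 &&
        n_codons <= rei_max_codons && (stop_pos + 2) < cds_start,
      context = classify_start_context(sequence, p)$label,
      stopless = is.na(stop_pos))
  }
  if (!length(out)) {
    return(data.frame(start = integer(), stop = integer(),
                      n_codons = integer(), frame_vs_cds = integer(),
                      is_stst = logical(), rei_permissive = logical(),
                      context = character(), stopless = logical()))
  }
  do.call(rbind, out)
}

#' Find near-cognate start codons
#'
#' Reports every trinucleotide at Hamming distance one from AUG (CUG, GUG,
#' UUG, ACG, AGG, AAG, AUA, AUC, AUU) together with its frame relative to
#' the main ORF and its Kozak context. AUG itself is excluded.
#'
#' @inheritParams find_orfs
#' @param include_aug Also report cognate AUGs (used by the annotator to
#'   assemble the full start-site table).
#' @return Data frame with `pos`, `codon`, `is_cognate`, `context`,
#'   `frame_vs_cds`.
#' @export
find_near_cognate_starts <- function(sequence, region = c(1L, nchar(sequence) - 2L),
                                     cds_start = nchar(sequence) + 1L,
                                     include_aug = FALSE) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  region[2] <- min(region[2], n - 2L)
  wanted <- if (include_aug) c("AUG", NEAR_COGNATES) else NEAR_COGNATES
  pos <- integer(); codon <- character()
  for (p in seq(region[1], max(region[1], region[2]))) {
    cd <- codon_at(sequence, p)
    if (cd %in% wanted) { pos <- c(pos, p); codon <- c(codon, cd) }
  }
  if (!length(pos)) {
    return(data.frame(pos = integer(), codon = character(),
                      is_cognate = logical(), context = character(),
                      frame_vs_cds = integer()))
  }
  data.frame(
    pos = pos, codon = codon, is_cognate = codon == "AUG",
    context = vapply(pos, function(p) classify_start_context(sequence, p)$label, ""),
    frame_vs_cds = vapply(pos, frame_vs_cds, 0L, cds_start = cds_start))
}

#' Scan for DRACH/RRACH m6A motifs
#'
#' Every 5-mer matching D-R-A-C-H (D = A/G/U, R = A/G, H = A/C/U) is
#' reported; the modifiable adenosine is the third base. Motifs whose first
#' base is also a purine are additionally flagged RRACH. Modification
#' flags and kinetic effect parameters are default-initialized to neutral
#' values (no roadblock, no stem destabilization); assigning non-neutral
#' effects to particular sites is a modeling decision made downstream.
#'
#' @inheritParams find_orfs
#' @return Data frame with `pos` (the A), `motif`, `is_rrach`,
#'   `modified_nonstress`, `modified_stress`, `roadblock_strength`,
#'   `stem_destabilization`.
#' @export
scan_methylation_motifs <- function(sequence, region = c(1L, nchar(sequence))) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  D <- c("A", "G", "U"); R <- c("A", "G"); H <- c("A", "C", "U")
  pos <- integer(); motif <- character(); rr <- logical()
  lo <- max(region[1], 1L); hi <- min(region[2], n)
  for (a in seq(max(lo, 3L), min(hi, n - 2L))) {
    if (substr(sequence, a, a) != "A") next
    w <- substr(sequence, a - 2, a + 2)
    b <- strsplit(w, "")[[1]]
    if (b[1] %in% D && b[2] %in% R && b[4] == "C" && b[5] %in% H) {
      pos <- c(pos, a); motif <- c(motif, w); rr <- c(rr, b[1] %in% R)
    }
  }
  data.frame(pos = pos, motif = motif, is_rrach = rr,
             modified_nonstress = logical(length(pos)),
             modified_stress = logical(length(pos)),
             roadblock_strength = rep(1, length(pos)),
             stem_destabilization = rep(0, length(pos)))
}

#' Predict local hairpin structures by nearest-neighbor dynamic programming
#'
#' Hairpin-only folding: a single stem with bulges and internal loops, no
#' multiloops or pseudoknots. Candidates are extracted greedily (best free
#' energy first, non-overlapping) and reported sorted by `delta_G`.
#'
#' @param sequence RNA string.
#' @param min_stem Minimum number of base pairs in a reported hairpin.
#' @param max_loop Maximum hairpin-loop length reported.
#' @param window Maximum span (nt) of a hairpin, outermost pair inclusive.
#' @param energy_table Energy table, see [default_energy_table()].
#' @return Data frame with `five_prime_base`, `three_prime_end`,
#'   `loop_start`, `loop_end`, `delta_G`, `n_pairs`; the paired positions
#'   of each hairpin are in `attr(, "pairs")`, a list of two-column
#'   matrices (5' partner, 3' partner), outermost pair first.
#' @export
predict_hairpins <- function(sequence, min_stem = 3L, max_loop = 30L,
                             window = 80L, energy_table = default_energy_table()) {
  if (window < 2 * min_stem + 3) {
    stop("window (", window, ") shorter than 2*min_stem + 3")
  }
  sequence <- normalize_rna(sequence)
  hits <- .hairpin_dp(sequence, energy_table_for_dp(energy_table),
                      as.integer(window), 12L, 3L)
  rows <- list(); pair_list <- list()
  for (h in hits) {
    np <- length(h$pair5)
    if (np < min_stem) next
    inner5 <- h$pair5[np]; inner3 <- h$pair3[np]
    loop_len <- inner3 - inner5 - 1
    if (loop_len > max_loop) next
    rows[[length(rows) + 1]] <- data.frame(
      five_prime_base = h$i, three_prime_end = h$j,
      loop_start = inner5 + 1L, loop_end = inner3 - 1L,
      delta_G = h$energy, n_pairs = np)
    pair_list[[length(rows)]] <- cbind(h$pair5, h$pair3)
  }
  if (!length(rows)) {
    res <- data.frame(five_prime_base = integer(), three_prime_end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      delta_G = numeric(), n_pairs = integer())
    attr(res, "pairs") <- list()
    return(res)
  }
  res <- do.call(rbind, rows)
  ord <- order(res$delta_G)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "pairs") <- pair_list[ord]
  res
}

#' Hand-summed energy of an explicit nested pair list
#'
#' Internal-consistency oracle: sums the stack, bulge, internal-loop and
#' hairpin-loop terms of the packaged table over a given structure.
#'
#' @param sequence RNA string.
#' @param pairs Two-column matrix (5' partner, 3' partner), outermost first.
#' @param energy_table Energy table.
#' @return Free energy in kcal/mol.
#' @export
hairpin_energy <- function(sequence, pairs, energy_table = default_energy_table()) {
  sequence <- normalize_rna(sequence)
  .hairpin_energy_of_pairs(sequence, energy_table_for_dp(energy_table),
                           as.integer(pairs[, 1]), as.integer(pairs[, 2]))
}

#' Ribosome queue geometry between a start codon and a stall site
#'
#' How many 80S ribosomes fit between an upstream start codon and the stall
#' position (5' base of a stem-loop), at a fixed footprint size. The 5'-most
#' ribosome sits with its P site on the upstream start; P sites of a fully
#' packed queue are spaced exactly one footprint apart.
#'
#' @param upstream_start P-site position of the 5'-most queued ribosome.
#' @param stall_pos Stall position (5' base of the stem-loop).
#' @param footprint_80S Footprint length in nt (default 30).
#' @return An object of class `queue_geometry`: list with `upstream_start`,
#'   `stall_pos`, `footprint_80S`, `capacity`, `psite_positions`, `remainder`.
#' @export
#' @examples
#' queue_capacity(165, 315, 30)$capacity  # 5
queue_capacity <- function(upstream_start, stall_pos, footprint_80S = 30L) {
  if (stall_pos <= upstream_start) stop("stall_pos must be downstream of upstream_start")
  d <- stall_pos - upstream_start
  cap <- d %/% footprint_80S
  ps <- if (cap > 0) upstream_start + footprint_80S * (seq_len(cap) - 1L) else integer()
  structure(list(upstream_start = upstream_start, stall_pos = stall_pos,
                 footprint_80S = as.integer(footprint_80S),
                 capacity = as.integer(cap), psite_positions = ps,
                 remainder = as.integer(d %% footprint_80S)),
            class = "queue_geometry")
}

#' Footprint geometry of a scanning 48S PIC
#'
#' The PIC covers `upstream` nt from the mRNA entry site up to the P site
#' (excluding it) and `downstream` nt from the P site (including it) to the
#' exit site; a stalled PIC can migrate back and forth by `migration` nt.
#'
#' @param upstream nt protected upstream of the P site (default 12).
#' @param downstream nt protected downstream including the P site (default
#'   20, the midpoint of the observed 15-25 range).
#' @param migration Symmetric migration window in nt (default 15).
#' @export
pic_footprint_model <- function(upstream = 12L, downstream = 20L, migration = 15L) {
  stopifnot(upstream >= 0, downstream >= 1, migration >= 0)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 migration = as.integer(migration)),
            class = "pic_footprint_model")
}

#' P-site window of a PIC stalled at a stem-loop
#'
#' A PIC whose leading edge abuts the stall position has its P site at
#' `stall_pos - downstream`; migration extends the operational window for
#' start-site selection symmetrically.
#'
#' @param stall_pos 5' base of the stem-loop.
#' @param pic_model A [pic_footprint_model()].
#' @param leader Optional `leader_annotation`; when given, start sites
#'   (cognate and near-cognate) whose first base lies in the window are
#'   returned in `$reachable`.
#' @return List with `psite`, `window` (integer pair) and `reachable`
#'   (data frame, possibly empty).
#' @export
stalled_psite_window <- function(stall_pos, pic_model = pic_footprint_model(),
                                 leader = NULL) {
  psite <- stall_pos - pic_model$downstream
  win <- c(psite - pic_model$migration, psite + pic_model$migration)
  reachable <- NULL
  if (!is.null(leader)) {
    st <- leader$elements$starts
    reachable <- st[st$pos >= win[1] & st$pos <= win[2], , drop = FALSE]
  }
  list(psite = psite, window = win, reachable = reachable)
}

#' Detect candidate frameshift signals
#'
#' Heuristic detectors with packaged, documented thresholds: a slippery run
#' is three or more consecutive codons (in any frame) sharing their first
#' two nucleotides (so both tRNAs can re-pair after slippage; identical
#' codons are a special case), or a homopolymeric G/A run of at least 7 nt.
#' A C-tract is a 12-nt window containing at least 8 C with at least 5 of
#' them consecutive. The spacing between a slippery run and the nearest
#' downstream C-tract is reported and flagged optimal at 8 nt.
#'
#' @inheritParams find_orfs
#' @return Data frame with `kind` ("FS-A" for a slippery run with a nearby
#'   downstream C-tract, "FS-B" otherwise, "C-tract"), `start`, `end`,
#'   `frame`, `spacing_to_ctract`, `optimal_spacing`.
#' @export
find_frameshift_signals <- function(sequence, region = c(1L, nchar(sequence))) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  lo <- max(1L, region[1]); hi <- min(n, region[2])
  b <- strsplit(sequence, "")[[1]]

  # C-tracts
  ct <- list()
  p <- lo
  while (p + 11 <= hi) {
    w <- b[p:(p + 11)]
    runs <- rle(w == "C")
    if (sum(w == "C") >= 8 && any(runs$lengths[runs$values] >= 5)) {
      ct[[length(ct) + 1]] <- c(p, p + 11)
      p <- p + 12
    } else p <- p + 1
  }
  ct_start <- vapply(ct, `[`, 0, 1)

  # slippery codon runs, per frame
  sl <- list()
  for (off in 0:2) {
    starts <- seq(lo + off, hi - 2, by = 3)
    if (length(starts) < 3) next
    cods <- vapply(starts, function(s) paste0(b[s:(s + 2)], collapse = ""), "")
    pre2 <- substr(cods, 1, 2)
    r <- 1
    while (r <= length(cods) - 2) {
      k <- r
      while (k < length(cods) && pre2[k + 1] == pre2[r]) k <- k + 1
      if (k - r + 1 >= 3) {
        sl[[length(sl) + 1]] <- c(starts[r], starts[k] + 2, off)
        r <- k + 1
      } else r <- r + 1
    }
  }
  # homopolymeric G/A runs
  runs <- rle(b[lo:hi])
  ends <- cumsum(runs$lengths) + lo - 1
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] %in% c("G", "A") && runs$lengths[i] >= 7) {
      sl[[length(sl) + 1]] <- c(starts[i], ends[i], (starts[i] - 1) %% 3)
    }
  }

  rows <- list()
  for (s in sl) {
    spacing <- NA_integer_
    if (length(ct_start)) {
      down <- ct_start[ct_start > s[2]]
      if (length(down)) spacing <- as.integer(min(down) - s[2] - 1L)
    }
    kind <- if (!is.na(spacing) && spacing <= 20) "FS-A" else "FS-B"
    rows[[length(rows) + 1]] <- data.frame(
      kind = kind, start = s[1], end = s[2], frame = s[3],
      spacing_to_ctract = spacing,
      optimal_spacing = isTRUE(spacing == 8L))
  }
  for (cc in ct) {
    rows[[length(rows) + 1]] <- data.frame(
      kind = "C-tract", start = cc[1], end = cc[2], frame = NA_integer_,
      spacing_to_ctract = NA_integer_, optimal_spacing = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      frame = integer(), spacing_to_ctract = integer(),
                      optimal_spacing = logical()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Annotate a leader sequence with all detected regulatory features
#'
#' Runs the full detector suite: uORFs/start-stop elements upstream of the
#' main ORF, cognate and near-cognate start sites, DRACH/RRACH motifs,
#' hairpins, and frameshift signals. Methylation sites falling inside a
#' hairpin stem are flagged `in_stem`.
#'
#' @param sequence RNA (or DNA; T is converted to U) string.
#' @param cds_start Position of the main-ORF start codon.
#' @param energy_table Energy table for hairpin folding.
#' @param pic_model PIC footprint geometry, stored with the annotation.
#' @param hairpin_min_dG Only hairpins at least this stable (kcal/mol) are
#'   retained in the annotation (weaker folds are noise for the simulator).
#' @param allow_non_aug Tolerate a non-AUG codon at `cds_start` (used when
#'   re-annotating start-codon knockout constructs); otherwise an error
#'   naming the codon found is raised.
#' @param name Leader name.
#' @return A `leader_annotation` object; see [leader_annotation()].
#' @export
annotate_leader <- function(sequence, cds_start,
                            energy_table = default_energy_table(),
                            pic_model = pic_footprint_model(),
                            hairpin_min_dG = -5, allow_non_aug = FALSE,
                            name = "leader") {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  stopifnot(cds_start >= 1, cds_start + 2 <= n)
  cd <- codon_at(sequence, cds_start)
  if (cd != "AUG") {
    if (!allow_non_aug) {
      stop("codon at cds_start is ", cd, ", not AUG")
    }
  }
  orfs <- find_orfs(sequence, c(1L, cds_start - 1L), cds_start = cds_start)
  starts <- find_near_cognate_starts(sequence, c(1L, n - 2L),
                                     cds_start = cds_start, include_aug = TRUE)
  hp <- predict_hairpins(sequence, energy_table = energy_table)
  keep <- hp$delta_G <= hairpin_min_dG
  pairs <- attr(hp, "pairs")[keep]
  hp <- hp[keep, , drop = FALSE]
  attr(hp, "pairs") <- pairs
  me <- scan_methylation_motifs(sequence)
  if (nrow(me)) {
    # stem membership is judged against stall-class hairpins only: a site
    # in a marginal fold acts as a scanning roadblock, not a stem modifier
    hs <- hp[hp$delta_G <= -10, , drop = FALSE]
    me$in_stem <- vapply(me$pos, function(p) {
      any(p >= hs$five_prime_base & p <= hs$three_prime_end &
            !(p >= hs$loop_start & p <= hs$loop_end))
    }, TRUE)
  } else me$in_stem <- logical(0)
  fs <- find_frameshift_signals(sequence)
  leader_annotation(name = name, sequence = sequence, cds_start = cds_start,
                    elements = list(orfs = orfs, starts = starts,
                                    hairpins = hp, methyl = me, fs = fs),
                    pic_model = pic_model)
}
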