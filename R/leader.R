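#' Leader annotation container
#'
#' A leader sequence together with its typed regulatory elements in a
#' single 1-based, inclusive coordinate frame. This is the track consumed
#' by the simulator.
#'
#' @param name Identifier.
#' @param sequence RNA string over A/C/G/U.
#' @param cds_start Position of the main-ORF start codon.
#' @param elements List of detector outputs: `orfs`, `starts`, `hairpins`,
#'   `methyl`, `fs` (see the corresponding `find_*`/`scan_*`/`predict_*`
#'   functions).
#' @param manifest Named list mapping design constraints to realized values
#'   (e.g. `uORF2_AUG_to_SL3_nt`); filled by [build_reference_leader()].
#' @param pic_model PIC footprint geometry.
#' @return Object of class `leader_annotation`.
#' @export
leader_annotation <- function(name, sequence, cds_start, elements,
                              manifest = list(),
                              pic_model = pic_footprint_model()) {
  obj <- structure(list(name = name, sequence = sequence,
                        cds_start = as.integer(cds_start),
                        elements = elements, manifest = manifest,
                        pic_model = pic_model),
                   class = "leader_annotation")
  validate_leader(obj)
  obj
}

#' Validate a leader annotation
#'
#' Checks the container invariants: cds_start in range, element intervals
#' within bounds, element sequences matching the leader sequence at their
#' coordinates (an annotated AUG really reads AUG), and uORF frame/length
#' consistency.
#'
#' @param leader A `leader_annotation`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_leader <- function(leader) {
  s <- leader$sequence
  n <- nchar(s)
  stopifnot(leader$cds_start >= 1, leader$cds_start + 2 <= n)
  el <- leader$elements
  orfs <- el$orfs
  if (nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      if (codon_at(s, orfs$start[i]) != "AUG") {
        stop("ORF at ", orfs$start[i], " does not read AUG")
      }
      if (!is.na(orfs$stop[i])) {
        if (!(codon_at(s, orfs$stop[i]) %in% STOP_CODONS)) {
          stop("ORF stop at ", orfs$stop[i], " is not a stop codon")
        }
        if ((orfs$stop[i] - orfs$start[i]) %% 3 != 0) {
          stop("ORF at ", orfs$start[i], " has out-of-frame stop")
        }
        if (orfs$is_stst[i] && orfs$stop[i] != orfs$start[i] + 3) {
          stop("start-stop element at ", orfs$start[i], " has sense codons")
        }
      }
    }
  }
  st <- el$starts
  if (nrow(st)) {
    for (i in seq_len(nrow(st))) {
      cd <- codon_at(s, st$pos[i])
      ok <- cd == "AUG" || sum(strsplit(cd, "")[[1]] != c("A", "U", "G")) == 1
      if (!ok) stop("start site at ", st$pos[i], " (", cd,
                    ") is neither AUG nor near-cognate")
    }
  }
  hp <- el$hairpins
  if (nrow(hp)) {
    stopifnot(all(hp$five_prime_base >= 1), all(hp$three_prime_end <= n),
              all(hp$loop_end - hp$loop_start + 1 >= 3))
  }
  me <- el$methyl
  if (nrow(me) && any(substr(s, me$pos, me$pos) != "A")) {
    stop("methylation site not on an A")
  }
  invisible(TRUE)
}

#' @export
print.leader_annotation <- function(x, ...) {
  el <- x$elements
  cat("leader_annotation '", x$name, "': ", nchar(x$sequence),
      " nt, CDS at ", x$cds_start, "\n", sep = "")
  cat("  uORFs/St-st:", nrow(el$orfs),
      "| start sites:", nrow(el$starts),
      "| hairpins:", nrow(el$hairpins),
      "| m6A motifs:", nrow(el$methyl),
      "| FS signals:", nrow(el$fs), "\n")
  if (length(x$manifest)) {
    cat("  manifest:",
        paste(names(x$manifest), unlist(x$manifest), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

# uORFs (upstream of the CDS) sorted by start; convenience accessor.
leader_uorfs <- function(leader) {
  o <- leader$elements$orfs
  o[order(o$start), , drop = FALSE]
}
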