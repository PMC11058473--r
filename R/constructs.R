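## Mutant construct registry: declarative edits applied to the reference
## leader, mirroring the reporter construct series (start-codon knockouts,
## stem-loop unfolding mutations, near-cognate and m6A substitutions, and
## in-frame c-Myc insertions).

.registry_cache <- new.env(parent = emptyenv())

#' The packaged construct registry
#'
#' Reads the declarative edit table shipped in `inst/extdata/constructs.json`.
#' Each construct is a named, ordered list of edits: substitutions
#' (`pos`/`old`/`new`) and insertions (`after`/`seq`). Substitution
#' positions always refer to reference coordinates; substitutions are
#' applied before insertions.
#'
#' @return Named list of constructs; each has `description` and `edits`.
#' @export
#' @examples
#' names(construct_registry())
construct_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  path <- system.file("extdata", "constructs.json", package = "riboqueue")
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .registry_cache$reg <- reg
  reg
}

#' Apply a registry construct to a leader
#'
#' Applies the named construct's edits (checking that substituted bases
#' match the reference), re-annotates the edited sequence, and transfers
#' the methylation-site activation flags of surviving sites (positions
#' shifted across insertions). Start-codon knockouts of the main ORF
#' (3AUGMut) are tolerated via `allow_non_aug`.
#'
#' @param leader A `leader_annotation` (normally the reference).
#' @param construct_id Name in [construct_registry()], or `"WT"` for the
#'   unmodified leader.
#' @param energy_table Energy table for re-annotation.
#' @return The edited, re-annotated `leader_annotation`.
#' @export
#' @examples
#' ref <- build_reference_leader()
#' dall <- apply_construct(ref, "d-all")
apply_construct <- function(leader, construct_id,
                            energy_table = default_energy_table()) {
  if (identical(construct_id, "WT")) return(leader)
  reg <- construct_registry()
  if (!construct_id %in% names(reg)) {
    stop("unknown construct_id '", construct_id, "'; see construct_registry()")
  }
  edits <- reg[[construct_id]]$edits
  seqv <- strsplit(leader$sequence, "")[[1]]

  subs <- Filter(function(e) e$type == "sub", edits)
  ins <- Filter(function(e) e$type == "ins", edits)
  for (e in subs) {
    p <- e$pos
    if (seqv[p] != e$old) {
      stop("edit/base mismatch at ", p, ": expected ", e$old,
           ", found ", seqv[p])
    }
    seqv[p] <- e$new
  }
  # apply insertions 3'-most first so earlier coordinates stay valid
  shift_at <- function(p) {
    sum(vapply(ins, function(e) if (e$after < p) nchar(e$seq) else 0L, 0L))
  }
  if (length(ins)) {
    ord <- order(vapply(ins, function(e) e$after, 0), decreasing = TRUE)
    for (e in ins[ord]) {
      seqv <- append(seqv, strsplit(normalize_rna(e$seq), "")[[1]],
                     after = e$after)
    }
  }
  new_cds <- leader$cds_start + shift_at(leader$cds_start)
  out <- annotate_leader(paste(seqv, collapse = ""), new_cds,
                         energy_table = energy_table, allow_non_aug = TRUE,
                         pic_model = leader$pic_model,
                         name = paste0(leader$name, "+", construct_id))

  # carry over methylation activation flags for surviving sites
  old_me <- leader$elements$methyl
  new_me <- out$elements$methyl
  if (nrow(old_me) && nrow(new_me)) {
    for (i in seq_len(nrow(old_me))) {
      np <- old_me$pos[i] + shift_at(old_me$pos[i])
      j <- which(new_me$pos == np)
      if (length(j) == 1) {
        new_me$modified_nonstress[j] <- old_me$modified_nonstress[i]
        new_me$modified_stress[j] <- old_me$modified_stress[i]
        new_me$roadblock_strength[j] <- old_me$roadblock_strength[i]
        new_me$stem_destabilization[j] <- old_me$stem_destabilization[i]
      }
    }
    out$elements$methyl <- new_me
  }
  out$manifest <- list(
    construct = construct_id,
    cds_start = new_cds,
    AUG1_to_SL3_nt = {
      hp <- out$elements$hairpins
      sl <- hp[hp$five_prime_base > new_cds, , drop = FALSE]
      if (nrow(sl)) sl$five_prime_base[which.min(sl$delta_G)] - new_cds else NA_integer_
    })
  out
}

#' Generate a randomized leader for property testing
#'
#' Builds a leader with a configurable architecture: a number of uORFs
#' with given length and spacing ranges, an optional hairpin at a fixed
#' distance downstream of the last uORF start, and filler background free
#' of stray AUGs. Deterministic for a fixed seed.
#'
#' @param arch_spec List with components `n_uorfs` (count), `uorf_codons`
#'   (range), `spacing` (range, nt between elements), `leader_pad` (range,
#'   5' pad), `hairpin` (NULL or list(`stall_to_start` nt, `stem` bp,
#'   `loop` nt)), `cds_codons` (sense codons of modeled CDS).
#' @param seed Integer seed.
#' @param energy_table Energy table for annotation.
#' @return A `leader_annotation`.
#' @export
random_leader <- function(arch_spec = list(), seed,
                          energy_table = default_energy_table()) {
  spec <- modifyList(list(n_uorfs = 1L, uorf_codons = c(2L, 10L),
                          spacing = c(20L, 60L), leader_pad = c(20L, 50L),
                          hairpin = NULL, cds_codons = 40L), arch_spec)
  rng <- function(r) if (length(r) == 1) r else (r[1] + seed %% (r[2] - r[1] + 1L))
  if (any(unlist(spec[c("uorf_codons", "spacing", "leader_pad")]) < 0)) {
    stop("infeasible arch_spec: negative range")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  draw <- function(r) if (length(r) == 1) as.integer(r) else sample(seq(r[1], r[2]), 1)

  pieces <- character(); kinds <- character()
  pad <- draw(spec$leader_pad)
  pieces <- c(pieces, strrep("N", pad)); kinds <- c(kinds, "fill")
  for (k in seq_len(spec$n_uorfs)) {
    nc <- draw(spec$uorf_codons)
    body <- if (nc > 0) strrep("GCU", nc) else ""
    pieces <- c(pieces, paste0("AUG", body, "UAA")); kinds <- c(kinds, "uorf")
    gap <- draw(spec$spacing)
    pieces <- c(pieces, strrep("N", gap)); kinds <- c(kinds, "fill")
  }
  hairpin_block <- NULL
  if (!is.null(spec$hairpin)) {
    hp <- modifyList(list(stall_to_start = 90L, stem = 8L, loop = 5L),
                     spec$hairpin)
    arm5 <- paste(rep(c("G", "C"), length.out = hp$stem), collapse = "")
    arm3 <- paste(rev(chartr("GC", "CG", strsplit(arm5, "")[[1]])), collapse = "")
    hairpin_block <- paste0(arm5, strrep("A", max(3L, hp$loop)), arm3)
  }
  cds <- paste0("AUG", strrep("GCU", spec$cds_codons))
  prefix_len <- sum(nchar(pieces))
  cds_start <- prefix_len + 1L

  s <- paste0(paste(pieces, collapse = ""), cds)
  if (!is.null(hairpin_block)) {
    # place hairpin so its 5' base is stall_to_start nt after the last
    # uORF AUG (or after the CDS AUG when there is no uORF)
    anchors <- cumsum(c(0L, nchar(pieces)))
    uorf_idx <- which(kinds == "uorf")
    anchor <- if (length(uorf_idx)) anchors[tail(uorf_idx, 1)] + 1L else cds_start
    hp_at <- anchor + spec$hairpin$stall_to_start
    if (hp_at <= anchor + 3L) stop("infeasible arch_spec: stall_to_start too short")
    if (hp_at + nchar(hairpin_block) > nchar(s)) {
      s <- paste0(s, strrep("N", hp_at + nchar(hairpin_block) - nchar(s) + 30L))
    }
    substr(s, hp_at, hp_at + nchar(hairpin_block) - 1L) <- hairpin_block
  }
  # fill N background without creating AUGs
  seqv <- strsplit(s, "")[[1]]
  fill <- which(seqv == "N")
  seqv[fill] <- sample(c("A", "C", "U"), length(fill), replace = TRUE)
  for (p in seq_len(length(seqv) - 2)) {
    if (seqv[p] == "A" && seqv[p + 1] == "U" && seqv[p + 2] == "G" &&
        any((p:(p + 2)) %in% fill)) {
      q <- intersect(p:(p + 2), fill)[1]
      seqv[q] <- "C"
    }
  }
  annotate_leader(paste(seqv, collapse = ""), cds_start,
                  energy_table = energy_table,
                  name = sprintf("random-leader-seed%d", seed))
}
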