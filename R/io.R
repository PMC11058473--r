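## Standard-format writers/readers. Internal coordinates are 1-based
## inclusive; BED and bedGraph output is 0-based half-open, converted
## only here at the I/O boundary.

#' Write a per-nucleotide track as bedGraph or TSV
#'
#' @param values Numeric vector over positions 1..L (one value per nt) or
#'   a matrix whose rows are species tracks (rows written as separate
#'   TSV columns; matrices are not supported for bedGraph).
#' @param path Output path.
#' @param format `"bedGraph"` or `"TSV"`.
#' @param chrom Sequence name for bedGraph lines.
#' @param seed Optional seed recorded in a track header comment.
#' @return The path, invisibly.
#' @export
write_tracks <- function(values, path, format = c("bedGraph", "TSV"),
                         chrom = "leader", seed = NULL) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) {
    writeLines(paste0("# seed=", seed), con)
  }
  if (format == "TSV") {
    if (is.matrix(values)) {
      df <- data.frame(pos = seq_len(ncol(values)), t(values))
    } else {
      df <- data.frame(pos = seq_along(values), value = values)
    }
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stopifnot(!is.matrix(values))
    # merge runs of equal values; emit 0-based half-open intervals
    r <- rle(values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    lines <- sprintf("%s\t%d\t%d\t%g", chrom, starts[keep] - 1L,
                     ends[keep], r$values[keep])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a bedGraph track back into a per-nucleotide vector
#'
#' @param path bedGraph file written by [write_tracks()].
#' @param L Track length (default: maximum end coordinate).
#' @return Numeric vector over positions 1..L.
#' @export
read_bedgraph <- function(path, L = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(numeric(if (is.null(L)) 0 else L))
  parts <- strsplit(lines, "\t")
  start0 <- vapply(parts, function(x) as.integer(x[2]), 0L)
  end0 <- vapply(parts, function(x) as.integer(x[3]), 0L)
  val <- vapply(parts, function(x) as.numeric(x[4]), 0)
  if (is.null(L)) L <- max(end0)
  out <- numeric(L)
  for (i in seq_along(val)) out[(start0[i] + 1L):end0[i]] <- val[i]
  out
}

#' Export annotated elements as BED
#'
#' One line per element (uORFs, start-stop, start sites, hairpins, m6A
#' motifs, frameshift signals), 0-based half-open.
#'
#' @param leader A `leader_annotation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_elements_bed <- function(leader, path) {
  el <- leader$elements
  lines <- character()
  add <- function(start, end, name, score = 0) {
    lines <<- c(lines, sprintf("%s\t%d\t%d\t%s\t%g\t+", leader$name,
                               start - 1L, end, name, score))
  }
  orfs <- el$orfs
  for (i in seq_len(nrow(orfs))) {
    nmo <- if (orfs$is_stst[i]) "start-stop" else
      sprintf("uORF_%dcodons", orfs$n_codons[i])
    add(orfs$start[i],
        if (is.na(orfs$stop[i])) orfs$start[i] + 2L else orfs$stop[i] + 2L,
        nmo)
  }
  st <- el$starts
  for (i in seq_len(nrow(st))) {
    add(st$pos[i], st$pos[i] + 2L,
        sprintf("%s_%s", st$codon[i], st$context[i]))
  }
  hp <- el$hairpins
  for (i in seq_len(nrow(hp))) {
    add(hp$five_prime_base[i], hp$three_prime_end[i],
        sprintf("hairpin_dG%.1f", hp$delta_G[i]), hp$delta_G[i])
  }
  me <- el$methyl
  for (i in seq_len(nrow(me))) {
    add(me$pos[i] - 2L, me$pos[i] + 2L,
        if (me$is_rrach[i]) "RRACH" else "DRACH")
  }
  fs <- el$fs
  for (i in seq_len(nrow(fs))) add(fs$start[i], fs$end[i], fs$kind[i])
  writeLines(lines, path)
  invisible(path)
}

#' Dump a leader manifest as JSON
#'
#' @param leader A `leader_annotation`.
#' @param path Output path.
#' @param seed Optional seed recorded in the manifest.
#' @return The path, invisibly.
#' @export
write_manifest_json <- function(leader, path, seed = NULL) {
  m <- leader$manifest
  m$name <- leader$name
  if (!is.null(seed)) m$seed <- seed
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
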