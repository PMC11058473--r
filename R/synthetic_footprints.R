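#' Generate synthetic ribosome footprint reads
#'
#' Samples P-site positions from a given true density (multinomial at the
#' requested depth), draws read lengths from a length distribution, places
#' read extents around each P site with the standard 12-nt 5' offset, and
#' optionally jitters P-site assignment by uniform noise. Used to test the
#' profile readouts independently of the simulator.
#'
#' @param true_psite_density Non-negative numeric vector over positions
#'   (need not be normalized; must have a positive sum).
#' @param depth Total number of reads (> 0).
#' @param read_length_dist Either a single read length or a named numeric
#'   vector of probabilities (names = lengths), e.g.
#'   `c("28" = .3, "30" = .7)`.
#' @param noise Max absolute uniform jitter (nt) added to each P site.
#' @param seed Integer seed; sampling is deterministic per seed.
#' @param p_offset 5' offset of the P site within a read (default 12).
#' @return Data frame with `start`, `end`, `psite`, `length` (1-based,
#'   inclusive read extents, clipped to the density's support).
#' @export
#' @examples
#' fp <- generate_synthetic_footprints(c(rep(0, 49), 1, rep(0, 50)),
#'                                     depth = 100, read_length_dist = 30,
#'                                     noise = 0, seed = 7)
#' table(fp$psite)
generate_synthetic_footprints <- function(true_psite_density, depth,
                                          read_length_dist = 30L,
                                          noise = 0L, seed = 1L,
                                          p_offset = 12L) {
  if (any(true_psite_density < 0)) stop("negative densities")
  if (sum(true_psite_density) <= 0) stop("density sums to zero")
  if (depth <= 0) stop("zero depth")
  L <- length(true_psite_density)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  counts <- as.vector(rmultinom(1, depth, true_psite_density / sum(true_psite_density)))
  psite <- rep(seq_len(L), counts)
  if (noise > 0) {
    psite <- psite + sample(seq(-noise, noise), length(psite), replace = TRUE)
    psite <- pmin(pmax(psite, 1L), L)
  }
  if (length(read_length_dist) == 1 && is.null(names(read_length_dist))) {
    len <- rep(as.integer(read_length_dist), length(psite))
  } else {
    len <- as.integer(sample(as.integer(names(read_length_dist)),
                             length(psite), replace = TRUE,
                             prob = read_length_dist))
  }
  start <- pmax(psite - p_offset, 1L)
  end <- pmin(start + len - 1L, L)
  ord <- order(psite)
  data.frame(start = start[ord], end = end[ord], psite = sort(psite),
             length = len[ord])
}

#' P-site histogram of footprint reads
#'
#' @param reads Data frame from [generate_synthetic_footprints()].
#' @param L Track length (default: max read end).
#' @return Integer vector of counts per position.
#' @export
psite_histogram <- function(reads, L = max(reads$end)) {
  tabulate(reads$psite, nbins = L)
}

#' Disome-length read 5'-end histogram and peak spacing
#'
#' For reads of disome length (~2 footprints), tabulates 5' ends and the
#' spacing between successive peak positions.
#'
#' @param reads Read table with `start` and `length`.
#' @param disome_length Expected disome read length (default 60).
#' @param slack Length tolerance.
#' @return List with `hist5` (table) and `peak_spacing` (diffs between
#'   successive positions with counts at least half the maximum).
#' @export
disome_read_profile <- function(reads, disome_length = 60L, slack = 2L) {
  keep <- abs(reads$length - disome_length) <= slack
  h <- table(reads$start[keep])
  if (!length(h)) return(list(hist5 = h, peak_spacing = integer()))
  peaks <- as.integer(names(h)[h >= max(h) / 2])
  list(hist5 = h, peak_spacing = diff(sort(peaks)))
}
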