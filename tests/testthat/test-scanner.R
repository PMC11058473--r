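test_that("Kozak context classification follows the two-determinant rule", {
  expect_equal(classify_start_context("GCCACCAUGG", 7)$label, "strong")
  expect_equal(classify_start_context("UUUUUUAUGU", 7)$label, "weak")
  expect_equal(classify_start_context("AAAAAAAUGC", 7)$label, "medium")
  expect_equal(classify_start_context("UUUCUUAUGG", 7)$label, "medium")
  # truncation: no -3 base available counts as a missing determinant
  ctx <- classify_start_context("AUGGGG", 1)
  expect_true(ctx$truncated)
  expect_equal(ctx$label, "medium")  # +4 G only
})

test_that("context depends on exactly the -3 and +4 bases", {
  set.seed(42)
  base <- strsplit("NNNANNAUGGNN", "")[[1]]
  labels <- replicate(50, {
    s <- base
    idx <- which(s == "N")
    s[idx] <- sample(c("A", "C", "G", "U"), length(idx), replace = TRUE)
    classify_start_context(paste(s, collapse = ""), 7)$label
  })
  expect_true(all(labels == "strong"))
})

test_that("find_orfs identifies start-stop elements and uORFs with codon counts", {
  # AUG immediately followed by UAA: a start-stop, zero sense codons
  o <- find_orfs("AUGUAAGGG", c(1L, 6L))
  expect_equal(nrow(o), 1)
  expect_true(o$is_stst)
  expect_equal(o$n_codons, 0L)
  # AUG + 3 sense codons + UGA
  o <- find_orfs("CCAUGGCUGCAGGUUGACC", c(1L, 10L))
  expect_equal(o$n_codons, 3L)
  expect_false(o$is_stst)
  expect_equal(o$stop, 15L)
  # stop-less ORF flagged
  o <- find_orfs("CCAUGGCUGCA", c(1L, 5L))
  expect_true(o$stopless)
  # no AUG: empty
  expect_equal(nrow(find_orfs("CCCCCCCCC", c(1L, 7L))), 0)
})

test_that("near-cognate detector reports the nine single-mismatch codons and not AUG", {
  s <- "CCCUGCCC"
  nc <- find_near_cognate_starts(s)
  expect_equal(nc$codon, "CUG")
  expect_equal(nc$pos, 3L)
  s2 <- "CCAUGCC"
  nc2 <- find_near_cognate_starts(s2)
  expect_false("AUG" %in% nc2$codon)
  # exhaustive: all nine variants present once each in a designed string
  variants <- c("CUG", "GUG", "UUG", "ACG", "AGG", "AAG", "AUA", "AUC", "AUU")
  s3 <- paste(vapply(variants, function(v) paste0(v, "CC"), ""), collapse = "")
  nc3 <- find_near_cognate_starts(s3)
  expect_setequal(nc3$codon, variants)
})

test_that("DRACH/RRACH scanner flags motif class and the central A", {
  m <- scan_methylation_motifs("GGACU")
  expect_equal(m$pos, 3L)
  expect_true(m$is_rrach)
  m2 <- scan_methylation_motifs("UGACC")
  expect_equal(nrow(m2), 1)
  expect_false(m2$is_rrach)
  # C at the 4th slot is mandatory
  expect_equal(nrow(scan_methylation_motifs("GGAGU")), 0)
})

test_that("detectors agree with brute-force enumeration on short sequences", {
  set.seed(7)
  D <- c("A", "G", "U"); R <- c("A", "G"); H <- c("A", "C", "U")
  nc_set <- c("CUG", "GUG", "UUG", "ACG", "AGG", "AAG", "AUA", "AUC", "AUU")
  for (rep in 1:60) {
    s <- paste(sample(c("A", "C", "G", "U"), 50, replace = TRUE), collapse = "")
    # brute-force near-cognates
    bf <- which(vapply(1:48, function(p)
      substr(s, p, p + 2) %in% nc_set, TRUE))
    expect_equal(find_near_cognate_starts(s)$pos, bf)
    # brute-force motifs
    bf_m <- which(vapply(3:48, function(a) {
      w <- strsplit(substr(s, a - 2, a + 2), "")[[1]]
      w[3] == "A" && w[1] %in% D && w[2] %in% R && w[4] == "C" && w[5] %in% H
    }, TRUE)) + 2L
    expect_equal(scan_methylation_motifs(s)$pos, bf_m)
    # brute-force ORFs: first AUG positions match
    bf_aug <- which(vapply(1:48, function(p) substr(s, p, p + 2) == "AUG", TRUE))
    expect_equal(find_orfs(s, c(1L, 48L))$start, bf_aug)
  }
})

test_that("queue geometry: capacity, spacing and scaling", {
  q <- queue_capacity(165, 315, 30)
  expect_equal(q$capacity, 5L)
  expect_equal(q$psite_positions, c(165, 195, 225, 255, 285))
  expect_equal(diff(q$psite_positions), rep(30L, 4))
  expect_equal(q$remainder, 0L)
  expect_equal(queue_capacity(10, 39, 30)$capacity, 0L)
  q2 <- queue_capacity(10, 142, 30)
  expect_equal(q2$capacity, 4L)
  expect_equal(q2$remainder, 12L)
  # monotone in distance and scale-invariant
  caps <- vapply(seq(40, 400, by = 15), function(d)
    queue_capacity(1, 1 + d, 30)$capacity, 0L)
  expect_true(all(diff(caps) >= 0))
  for (k in 1:4) {
    expect_equal(queue_capacity(1, 1 + k * 97, k * 30)$capacity,
                 queue_capacity(1, 98, 30)$capacity)
  }
  expect_error(queue_capacity(100, 50), "downstream")
})

test_that("stalled PIC P-site geometry reaches the CUG 20 nt upstream of the stall", {
  pm <- pic_footprint_model(downstream = 20, migration = 15)
  ref <- build_reference_leader()
  sw <- stalled_psite_window(315, pm, ref)
  expect_equal(sw$psite, 295)
  expect_true(any(sw$reachable$pos == 295 & sw$reachable$codon == "CUG"))
  # zero migration restricts to the exact position
  sw0 <- stalled_psite_window(315, pic_footprint_model(downstream = 20, migration = 0), ref)
  expect_equal(sw0$window, c(295, 295))
  # a stall with no nearby starts yields an empty reachable set
  sw_empty <- stalled_psite_window(60, pic_footprint_model(migration = 0), ref)
  expect_equal(nrow(sw_empty$reachable), 0)
})

test_that("frameshift signals: slippery run with 8-nt C-tract spacing flagged optimal", {
  s <- paste0("AAAAAA", "GGAGGAGGA", "AUCUAAUC", "CCCCCUUCGACC", "AAAAAA")
  fs <- find_frameshift_signals(s)
  fsa <- fs[fs$kind == "FS-A", ]
  expect_gte(nrow(fsa), 1)
  expect_true(any(fsa$spacing_to_ctract == 8 & fsa$optimal_spacing))
  expect_true(any(fs$kind == "C-tract"))
  # balanced sequence without runs: empty
  expect_equal(nrow(find_frameshift_signals("ACGUACGUACGUACGUACGU")), 0)
})
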