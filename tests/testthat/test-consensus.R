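# Helpers: fabricate a recovered cluster member table directly.
mk_members <- function(normal_reads, mutated_reads, anchor, d,
                       bp_norm = NULL, bp_mut = NULL) {
  mk <- function(reads, group, bp) {
    if (is.null(bp)) bp <- vapply(reads, function(r) {
      regexpr(anchor, r, fixed = TRUE)[1] - 1L + d
    }, 1L)
    tibble::tibble(
      cluster_id = 1L, anchor = anchor, src = NA_integer_,
      read_id = seq_along(reads), offset = bp - d, group = group,
      strand = "forward", suffix_length = nchar(reads) - (bp - d),
      div_base = substr(reads, bp + 1L, bp + 1L),
      read_seq = reads, bp_col = as.integer(bp))
  }
  dplyr::bind_rows(mk(normal_reads, "normal", bp_norm),
                   mk(mutated_reads, "mutated", bp_mut))
}

pair_of <- function(normal, mutated, b) {
  structure(list(normal = normal, mutated = mutated, b = as.integer(b)),
            class = "consensus_pair")
}

test_that("identical-anchor clusters merge idempotently", {
  d <- 6L
  m <- mk_members(c("GATTACAAGGC", "GATTACAAGGC"), c("GATTACTAGGC"), "GATTAC", d)
  m2 <- m
  m2$cluster_id <- 2L
  cs <- structure(list(members = dplyr::bind_rows(m, m2), clusters = NULL),
                  class = "cluster_set")
  merged <- merge_identical_breakpoints(cs)
  expect_equal(nrow(merged$clusters), 1L)
  # union of identical read sets deduplicates
  expect_equal(nrow(merged$members), 3L)
  twice <- merge_identical_breakpoints(merged)
  expect_identical(twice$members, merged$members)

  # different anchors stay apart
  m3 <- mk_members(c("GATTAGAAGGCTT"), c("GATTAGTAGGCTT"), "GATTAG", d)
  m3$cluster_id <- 3L
  cs2 <- structure(list(members = dplyr::bind_rows(m, m3), clusters = NULL),
                   class = "cluster_set")
  expect_equal(nrow(merge_identical_breakpoints(cs2)$clusters), 2L)
})

test_that("consensus is the exact read for identical error-free reads", {
  d <- 6L
  nr <- rep("TTGATTACCACGTAGG", 6)    # anchor GATTAC at offset 2
  mr <- rep("TTGATTACTACGTAGG", 6)    # divergence C -> T at column 8
  pair <- build_consensus(mk_members(nr, mr, "GATTAC", d), d)
  expect_equal(pair$normal, nr[1])
  expect_equal(pair$mutated, mr[1])
  expect_equal(pair$b, 8L)
  expect_equal(substr(pair$normal, 1, pair$b), substr(pair$mutated, 1, pair$b))
})

test_that("a tied column halts consensus extension", {
  d <- 6L
  # 3 votes A vs 3 votes C two columns right of the divergence base
  nr <- c(rep("GATTACGGATTT", 3), rep("GATTACGGCTTT", 3))
  mr <- rep("GATTACTG", 6)
  pair <- build_consensus(mk_members(nr, mr, "GATTAC", d), d)
  expect_equal(pair$normal, "GATTACGG")   # halted before the {A x3, C x3} tie
  expect_equal(pair$mutated, "GATTACTG")
})

test_that("consensus equals a hand-built per-column majority on noisy reads", {
  set.seed(41)
  d <- 8L
  locus <- random_dna(60)
  anchor <- substr(locus, 21, 28)
  alt_locus <- locus
  old <- substr(locus, 29, 29)
  substr(alt_locus, 29, 29) <- setdiff(BASES, old)[1]
  draw <- function(hap, n = 20) {
    starts <- sample(1:20, n, replace = TRUE)
    reads <- vapply(starts, function(s) substr(hap, s, s + 29), "")
    # one seeded error per draw set, away from the divergence column
    substr(reads[1], 3, 3) <- setdiff(BASES, substr(reads[1], 3, 3))[1]
    reads
  }
  nr <- draw(locus)
  mr <- draw(alt_locus)
  mem <- mk_members(nr, mr, anchor, d)
  pair <- build_consensus(mem, d)
  # oracle: naive per-column vote over the normal reads
  vote_naive <- function(reads, bp) {
    cols <- list()
    for (i in seq_along(reads)) {
      for (j in seq_len(nchar(reads[i]))) {
        rel <- as.character(j - 1L - bp[i])
        cols[[rel]] <- c(cols[[rel]], substr(reads[i], j, j))
      }
    }
    cols
  }
  cols <- vote_naive(nr, mem$bp_col[mem$group == "normal"])
  for (idx in seq_len(nchar(pair$normal))) {
    rel <- as.character(idx - 1L - pair$b)
    v <- cols[[rel]]
    tab <- table(v)
    expect_gte(length(v), 2L)
    expect_true(max(tab) * 2 > length(v))
    expect_equal(substr(pair$normal, idx, idx), names(tab)[which.max(tab)])
  }
})

test_that("variant types are inferred in order with exact alleles", {
  flankL <- "GATTACAGGCATCTTACGGATCGATCGTTA"   # 30 bp anchor-side flank
  R <- "TGGACCTTAGCAGTCGGATT"
  b <- nchar(flankL)
  # SNV
  snv <- classify_variant(pair_of(paste0(flankL, "C", R), paste0(flankL, "T", R), b))
  expect_equal(snv$vtype, "SNV")
  expect_equal(snv$normal_allele, "C")
  expect_equal(snv$mutated_allele, "T")
  # deletion of 3
  del <- classify_variant(pair_of(paste0(flankL, "CAT", R), paste0(flankL, R), b))
  expect_equal(del$vtype, "deletion")
  expect_equal(del$length, 3L)
  expect_equal(del$normal_allele, "CAT")
  expect_equal(del$mutated_allele, "")
  # insertion of 4
  ins <- classify_variant(pair_of(paste0(flankL, R), paste0(flankL, "TCCA", R), b))
  expect_equal(ins$vtype, "insertion")
  expect_equal(ins$mutated_allele, "TCCA")
  # inversion of 8 (non-palindromic, ends chosen so the junction is clean)
  seg8 <- "ACGTACCG"
  inv <- classify_variant(pair_of(paste0(flankL, seg8, R),
                                  paste0(flankL, reverse_complement(seg8), R), b))
  expect_equal(inv$vtype, "inversion")
  expect_equal(inv$length, 8L)
  expect_equal(inv$mutated_allele, reverse_complement(inv$normal_allele))
  # two adjacent substitutions decompose as a complex of 2 SNVs
  Nc <- paste0(flankL, "CA", R)
  Mc <- paste0(flankL, "TC", R)   # not rc("CA"): must not look like an inversion
  cx <- classify_variant(pair_of(Nc, Mc, b))
  expect_equal(cx$vtype, "complex")
  expect_equal(nrow(cx$components), 2L)
  expect_true(all(cx$components$vtype == "SNV"))
  # decomposition round trip
  expect_equal(apply_components(Nc, b, cx$components), substr(Mc, b + 1, nchar(Mc)))
  # degenerate extent falls through to unassigned
  expect_equal(classify_variant(pair_of(flankL, flankL, b))$vtype, "unassigned")
})

test_that("a deletion-classifiable pair is never reported complex", {
  set.seed(43)
  for (i in 1:20) {
    flank <- random_dna(30)
    R <- random_dna(25)
    g <- sample(1:6, 1)
    del_seq <- random_dna(g)
    # enforce a clean junction so the deletion is unambiguous
    if (substr(del_seq, 1, 1) == substr(R, 1, 1)) next
    vc <- classify_variant(pair_of(paste0(flank, del_seq, R),
                                   paste0(flank, R), 30L))
    expect_equal(vc$vtype, "deletion")
    expect_equal(vc$length, g)
  }
})

test_that("unassigned strand mirrors are stitched and re-typed", {
  set.seed(44)
  L <- random_dna(60)
  D <- "ACGGTTACCGAT"                 # 12 bp deletion
  R <- random_dna(60)
  if (substr(D, 1, 1) == substr(R, 1, 1)) substr(R, 1, 1) <- "T"
  if (substr(L, 60, 60) == substr(D, 12, 12)) substr(L, 60, 60) <- "G"
  # forward cluster: 40 bp left flank, right extent truncated to 15
  fwd <- pair_of(paste0(substr(L, 21, 60), substr(paste0(D, R), 1, 15)),
                 paste0(substr(L, 21, 60), substr(R, 1, 15)), 40L)
  expect_equal(classify_variant(fwd)$vtype, "unassigned")
  # reverse cluster (own orientation): anchor right of the junction
  LD <- paste0(L, D)
  rev_pair <- pair_of(
    reverse_complement(paste0(substr(LD, nchar(LD) - 14, nchar(LD)), substr(R, 1, 30))),
    reverse_complement(paste0(substr(L, 46, 60), substr(R, 1, 30))), 30L)
  vc <- reinfer_unassigned(fwd, rev_pair)
  expect_equal(vc$vtype, "deletion")
  expect_equal(vc$length, 12L)
  expect_equal(vc$normal_allele, D)
  # stitching with no consistent overlap leaves the call unassigned
  vc2 <- reinfer_unassigned(fwd, pair_of(random_dna(40), random_dna(40), 20L))
  expect_equal(vc2$vtype, "unassigned")
})

test_that("strand-mirrored call records merge into one forward call", {
  d <- 6L
  nr <- rep("TTGATTACCACGTAGGAT", 6)
  mr <- rep("TTGATTACTACGTAGGAT", 6)
  fwd_pair <- build_consensus(mk_members(nr, mr, "GATTAC", d), d)
  # in rc coordinates (reads of 18 bp, SNV at 0-based col 8) the divergence
  # sits at col 9 and the anchor is the rc of original cols 10..15 (1-based)
  rev_pair <- build_consensus(
    mk_members(reverse_complement(nr), reverse_complement(mr),
               reverse_complement(substr(nr[1], 10, 15)), d,
               bp_norm = rep(9L, 6), bp_mut = rep(9L, 6)), d)
  rec <- function(pair, id) {
    list(cluster_id = id, anchor = substr(pair$normal, pair$b - d + 1, pair$b),
         vc = classify_variant(pair), n_norm = 6L, n_mut = 6L, q = 1,
         merged_from = 1L)
  }
  merged <- merge_reverse_complement_clusters(list(rec(fwd_pair, 1L), rec(rev_pair, 2L)))
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$n_norm, 12L)
  expect_equal(merged[[1]]$merged_from, 2L)
  expect_equal(merged[[1]]$vc$vtype, "SNV")
  # unrelated calls never merge; strand-specific mode is the identity
  other <- rec(pair_of(paste0(random_dna(20), "A", random_dna(10)),
                       paste0(random_dna(20), "C", random_dna(10)), 20L), 3L)
  expect_length(merge_reverse_complement_clusters(list(rec(fwd_pair, 1L), other)), 2L)
  expect_length(merge_reverse_complement_clusters(list(rec(fwd_pair, 1L), rec(rev_pair, 2L)),
                                                  strand_specific = TRUE), 2L)
})
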