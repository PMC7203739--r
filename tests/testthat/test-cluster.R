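# Build a sorted batch from explicit normal/mutated reads (forward only).
sorted_batch <- function(normal, mutated, d) {
  db <- read_db(normal, mutated, strand_specific = TRUE)
  sort_suffix_refs(collect_suffixes(db, "", d), db)
}

test_that("a divergent column with both groups registers exactly one cluster", {
  d <- 9L
  anchor <- "AAACCCTTT"
  tail <- "GGATCAGT"
  normal <- rep(paste0(anchor, "C", tail), 6)
  mutated <- rep(paste0(anchor, "T", tail), 6)
  db <- read_db(normal, mutated, strand_specific = TRUE)
  cs <- scan_clusters(sorted_batch(normal, mutated, d), d)
  # only the run anchored on the full shared 9-mer diverges at column d+1
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$anchor, anchor)
  m <- cs$members[cs$members$cluster_id == 1L, ]
  nd <- m$div_base[m$group == "normal"]
  md <- m$div_base[m$group == "mutated"]
  expect_identical(nd, rep("C", 6))
  expect_identical(md, rep("T", 6))

  # identical reads across groups: no divergence, no cluster
  cs2 <- scan_clusters(sorted_batch(normal, normal, d), d)
  expect_equal(nrow(cs2$clusters), 0L)

  # divergence only within the normal group: rejected (both groups required)
  norm_only <- c(rep(paste0(anchor, "C", tail), 3),
                 rep(paste0(anchor, "G", tail), 3))
  mut_other <- rep("TTTTTTTTTTTTTTTTTT", 4)
  cs3 <- scan_clusters(sorted_batch(norm_only, mut_other, d), d)
  expect_equal(nrow(cs3$clusters), 0L)
})

test_that("read recovery orients members and deduplicates per read/strand", {
  d <- 3L
  # reads TTAAACCC vs TTAAACCG first diverge at column 7, so the divergent
  # cluster is anchored on "ACC" (suffix offset 4); breakpoint col = offset + d
  db <- read_db("TTAAACCC", "TTAAACCG", strand_specific = TRUE)
  cs <- scan_clusters(sort_suffix_refs(collect_suffixes(db, "", d), db), d)
  rec <- recover_reads(cs, db, d)
  m <- rec$members[rec$members$anchor == "ACC" & rec$members$group == "normal", ]
  expect_equal(m$read_seq, "TTAAACCC")
  expect_equal(m$bp_col, m$offset + d)
  expect_equal(m$offset, 4L)

  # reverse member: rc("GGGTTTAA") = "TTAAACCC" diverges from mutated
  # "TTAAGCCC" at column 4 -> cluster anchored "TAA", offset 1, oriented read
  db2 <- read_db("GGGTTTAA", "TTAAGCCC", strand_specific = FALSE)
  cs2 <- scan_clusters(sort_suffix_refs(collect_suffixes(db2, "", d), db2), d)
  rec2 <- recover_reads(cs2, db2, d)
  m2 <- rec2$members[rec2$members$group == "normal" &
                     rec2$members$strand == "reverse" &
                     rec2$members$anchor == "TAA", ]
  expect_true("TTAAACCC" %in% m2$read_seq)
  expect_equal(m2$offset, 1L)
  expect_equal(m2$bp_col, 4L)

  # duplicate suffix offsets of one read collapse to one member
  d3 <- 4L
  rep_read_n <- "ACACACACGT"     # anchor ACAC occurs at offsets 0 and 2
  rep_read_m <- "ACACACACTT"
  db3 <- read_db(rep(rep_read_n, 3), rep(rep_read_m, 3), strand_specific = TRUE)
  cs3 <- scan_clusters(sort_suffix_refs(collect_suffixes(db3, "", d3), db3), d3)
  rec3 <- recover_reads(cs3, db3, d3)
  dup <- rec3$members |>
    dplyr::count(.data$cluster_id, .data$group, .data$read_id, .data$strand)
  expect_true(all(dup$n == 1L))
})

test_that("variant fraction counts covering reads against the normal majority", {
  d <- 6L
  anchor <- "GATTAC"
  mk <- function(base, n, tail = "ACGTAGG") rep(paste0(anchor, base, tail), n)
  run_q <- function(n_alt, n_ref, n_norm = 10) {
    normal <- mk("C", n_norm)
    mutated <- c(mk("T", n_alt), mk("C", n_ref))
    db <- read_db(normal, mutated, strand_specific = TRUE)
    cs <- recover_reads(scan_clusters(sorted_batch(normal, mutated, d), d), db, d)
    variant_fraction(cs)
  }
  expect_equal(run_q(10, 0)$q, 1.0)
  expect_equal(run_q(5, 5)$q, 0.5)
  expect_equal(run_q(1, 19)$q, 0.05)
  st <- run_q(5, 5)
  expect_equal(st$norm_major, "C")
  expect_equal(st$n_norm, 10L)
  expect_equal(st$n_mut, 10L)
  expect_equal(st$contamination, 0)
})

test_that("filters reject in the documented order", {
  base <- tibble::tibble(cluster_id = 1L, anchor = "A", n_norm = 10L,
                         n_mut = 10L, norm_major = "C", q = 0.95,
                         contamination = 0)
  p <- filter_params(cmin = 6, cmax = 28, qmin = 0.9, qmax = 1.0)
  expect_equal(apply_filters(base, p)$reason, "accept")
  expect_equal(apply_filters(dplyr::mutate(base, n_norm = 5L), p)$reason,
               "too_few_reads")
  expect_equal(apply_filters(dplyr::mutate(base, n_norm = 30L, n_mut = 30L),
                             filter_params(cmax = 28))$reason, "too_many_reads")
  expect_equal(apply_filters(dplyr::mutate(base, q = 0.5), p)$reason,
               "q_out_of_range")
  expect_equal(apply_filters(dplyr::mutate(base, contamination = 0.2), p)$reason,
               "normal_contaminated")
  # first failing rule wins: support failure masks q failure
  expect_equal(apply_filters(dplyr::mutate(base, n_mut = 2L, q = 0.2), p)$reason,
               "too_few_reads")
  # preset windows
  expect_equal(filter_params(mode = "het")$qmin, 0.35)
  expect_equal(filter_params(mode = "pure")$qmax, 1.0)
  expect_error(filter_params(qmin = 0.9, qmax = 0.5),
               class = "directvc_domain_error")
})

test_that("raising cmin or narrowing the q window never adds clusters", {
  set.seed(31)
  stats <- tibble::tibble(cluster_id = 1:200, anchor = as.character(1:200),
                          n_norm = rpois(200, 10), n_mut = rpois(200, 10),
                          norm_major = "A", q = runif(200),
                          contamination = runif(200, 0, 0.1))
  acc <- function(p) which(apply_filters(stats, p)$accepted)
  base <- acc(filter_params(cmin = 4, cmax = 40, qmin = 0.2, qmax = 0.9))
  expect_true(all(acc(filter_params(cmin = 8, cmax = 40, qmin = 0.2, qmax = 0.9)) %in% base))
  expect_true(all(acc(filter_params(cmin = 4, cmax = 40, qmin = 0.4, qmax = 0.8)) %in% base))
  expect_true(all(acc(filter_params(cmin = 8, cmax = 40, qmin = 0.5, qmax = 0.7)) %in% base))
})

test_that("the partitioned scan agrees with the all-pairs brute-force oracle", {
  set.seed(32)
  for (rep in 1:8) {
    fx <- micro_fixture()
    d <- 8L
    expected <- brute_force_clusters(fx$normal, fx$mutated, d,
                                     cmin = 2, cmax = 1000, qmin = 0, qmax = 1)
    got <- pipeline_clusters(fx$normal, fx$mutated, d, k = 1)
    expect_identical(got$anchor, expected$anchor)
    expect_equal(got$n_norm, expected$n_norm, ignore_attr = TRUE)
    expect_equal(got$n_mut, expected$n_mut, ignore_attr = TRUE)
    expect_equal(got$q, expected$q, ignore_attr = TRUE)
  }
})
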