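# Minimal located-call row factory
call_row <- function(vtype, na, ma, len, b, cons_n, cons_m, id = 1L) {
  tibble::tibble(vtype = vtype, normal_allele = na, mutated_allele = ma,
                 length = as.integer(len), breakpoint_col = as.integer(b),
                 cluster_id = as.integer(id), anchor = substr(cons_n, 1, b),
                 n_norm = 10L, n_mut = 10L, q = 1,
                 normal_consensus = cons_n, mutated_consensus = cons_m,
                 merged_from = 1L)
}

test_that("exact-match locating assigns unique, oriented coordinates", {
  set.seed(51)
  ref <- random_dna(10000)
  # plant a consensus (plus-strand unique)
  b <- 30L
  cons <- substr(ref, 4001, 4070)
  snv <- call_row("SNV", substr(ref, 4031, 4031), "A", 1, b, cons,
                  paste0(substr(cons, 1, 30), "A", substr(cons, 32, 70)))
  located <- locate_calls(snv, c(ref = ref))
  expect_equal(located$status, "located")
  expect_equal(located$pos, 4031L)
  expect_equal(located$contig, "ref")
  expect_equal(located$ref_strand, "+")

  # the same call expressed in reverse orientation locates identically
  rc_cons <- reverse_complement(cons)
  rc_b <- nchar(cons) - 1L - b
  snv_rc <- call_row("SNV", reverse_complement(substr(ref, 4031, 4031)),
                     "T", 1, rc_b, rc_cons, rc_cons)
  loc_rc <- locate_calls(snv_rc, c(ref = ref))
  expect_equal(loc_rc$status, "located")
  expect_equal(loc_rc$ref_strand, "-")
  expect_equal(loc_rc$pos, 4031L)
  expect_equal(loc_rc$normal_allele, substr(ref, 4031, 4031))

  # a repeated consensus is ambiguous, a corrupted one unmapped
  ref2 <- paste0(ref, substr(ref, 4001, 4100))
  amb <- locate_calls(snv, c(ref = ref2))
  expect_equal(amb$status, "ambiguous")
  bad <- snv
  bad$normal_consensus <- paste0("TTTT", random_dna(40))
  expect_equal(locate_calls(bad, c(ref = ref))$status, "unmapped")
})

test_that("minus-strand indels re-anchor onto the forward strand", {
  set.seed(52)
  ref <- random_dna(8000)
  # deletion of ref[3001..3005]; reverse-orientation cluster consensus
  del_seq <- substr(ref, 3001, 3005)
  cons_fwd <- substr(ref, 2961, 3040)       # normal consensus around it
  b <- 40L                                   # 0-based col of ref pos 3001
  rc_cons <- reverse_complement(cons_fwd)
  rc_b <- nchar(cons_fwd) - 1L - (b + 5L - 1L)  # divergence approached from the right
  del_rc <- call_row("deletion", reverse_complement(del_seq), "", 5,
                     rc_b, rc_cons, rc_cons)
  loc <- locate_calls(del_rc, c(ref = ref))
  expect_equal(loc$status, "located")
  expect_equal(loc$pos, 3001L)
  expect_equal(loc$normal_allele, del_seq)
})

test_that("consensus FASTA export round-trips", {
  set.seed(53)
  rows <- dplyr::bind_rows(lapply(1:3, function(i) {
    cons <- random_dna(60)
    call_row("SNV", "A", "C", 1, 30, cons, cons, id = i)
  }))
  fa <- withr::local_tempfile(fileext = ".fa")
  export_consensus_fasta(rows, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_length(back, 3L)
  expect_identical(as.character(back, use.names = FALSE), rows$normal_consensus)
  expect_match(names(back)[1], "^1\\|SNV\\|30$")
  expect_warning(export_consensus_fasta(rows[0, ], fa), "no calls")
})

test_that("TSV report round-trips and VCF follows the anchoring convention", {
  set.seed(54)
  ref <- random_dna(6000)
  cons1 <- substr(ref, 1201, 1260)
  cons2 <- substr(ref, 2501, 2570)
  rows <- dplyr::bind_rows(
    call_row("SNV", substr(ref, 1234, 1234),
             setdiff(c("A", "C", "G", "T"), substr(ref, 1234, 1234))[1],
             1, 33, cons1, cons1, id = 1),
    call_row("deletion", substr(ref, 2531, 2533), "", 3, 30, cons2, cons2, id = 2))
  located <- locate_calls(rows, c(chr_toy = ref))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_calls(located, tsv)
  back <- read_calls_tsv(tsv)
  for (col in c("cluster_id", "vtype", "normal_allele", "mutated_allele",
                "length", "n_norm", "n_mut", "q", "breakpoint_col",
                "contig", "pos", "status")) {
    expect_identical(back[[col]], located[[col]], info = col)
  }

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls(located, vcf, format = "vcf")
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)
  snv_f <- strsplit(body[1], "\t")[[1]]
  expect_equal(snv_f[1], "chr_toy")
  expect_equal(as.integer(snv_f[2]), 1234L)
  expect_equal(snv_f[4], substr(ref, 1234, 1234))
  del_f <- strsplit(body[2], "\t")[[1]]
  expect_equal(as.integer(del_f[2]), 2530L)   # anchored one base left
  expect_equal(del_f[4], substr(ref, 2530, 2533))
  expect_equal(del_f[5], substr(ref, 2530, 2530))
  expect_error(write_calls(rows, vcf, format = "vcf"),
               class = "directvc_usage_error")
})
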