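# Run code under a temporary RNG state seeded with `seed` (NULL = leave the
# current stream untouched).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() treats a length-1 vector as 1:n; this does not
resample <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

#' Generate a random reference sequence
#'
#' I.i.d. ACGT sequence at a given GC fraction; a desk-scale stand-in for a
#' real chromosome. Deterministic under `seed`.
#'
#' @param length Reference length in bp (>= 1000).
#' @param gc_fraction Expected GC content (default 0.41, human-like).
#' @param seed Optional RNG seed.
#' @return A character string of length `length`.
#' @export
make_reference <- function(length, gc_fraction = 0.41, seed = NULL) {
  if (!is.numeric(length) || length < 1000) {
    abort("`length` must be >= 1000", class = "directvc_domain_error")
  }
  with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
           gc_fraction / 2, (1 - gc_fraction) / 2)
    paste(sample(.BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Implant variants into a reference
#'
#' Places the requested variants as a chain of non-overlapping events whose
#' inter-variant spacing is drawn uniformly from `spacing` (default 25-50
#' bp), the chain centred in the reference; types are shuffled over the
#' chain. SNVs substitute to a different base, insertions insert random
#' sequence, deletions excise, inversions reverse-complement a segment.
#'
#' @param reference Reference sequence (character string).
#' @param n_snv,n_ins,n_del,n_inv Variant counts per type.
#' @param indel_size Integer range of insertion/deletion sizes (default 1-10).
#' @param inv_size Integer range of inversion sizes (default 8-12).
#' @param spacing Integer range of distances between consecutive variant
#'   positions (default 25-50).
#' @param seed Optional RNG seed.
#' @return List with `mutated` (the mutated reference) and `truth` (tibble:
#'   `vtype`, `contig`, `pos` (1-based, in normal-reference coordinates;
#'   for insertions the reference base before which the insertion occurs),
#'   `normal_allele`, `mutated_allele`, `length`, `spacing`).
#' @export
implant_variants <- function(reference, n_snv = 0L, n_ins = 0L, n_del = 0L,
                             n_inv = 0L, indel_size = c(1L, 10L),
                             inv_size = c(8L, 12L), spacing = c(25L, 50L),
                             seed = NULL) {
  n <- n_snv + n_ins + n_del + n_inv
  stopifnot(n >= 1L)
  len <- nchar(reference)
  max_span <- max(indel_size[2L], inv_size[2L])
  if (spacing[1L] <= max_span) {
    abort("minimum spacing must exceed the largest variant span",
          class = "directvc_domain_error")
  }
  with_seed(seed, {
    pool <- rep(c("SNV", "insertion", "deletion", "inversion"),
                c(n_snv, n_ins, n_del, n_inv))
    types <- pool[sample.int(n, n)]
    gaps <- resample(spacing[1L]:spacing[2L], n)
    margin <- 200L
    span <- sum(gaps)
    if (span + 2L * margin > len) {
      abort(sprintf(
        "cannot place %d variants at this spacing in a %d bp reference; use fewer variants or a longer reference",
        n, len), class = "directvc_domain_error")
    }
    start <- margin + (len - span - 2L * margin) %/% 2L
    pos <- start + cumsum(gaps)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      p <- pos[i]
      vt <- types[i]
      if (vt == "SNV") {
        ref_b <- substr(reference, p, p)
        alt_b <- resample(setdiff(.BASES, ref_b))
        recs[[i]] <- tibble(vtype = vt, pos = p, normal_allele = ref_b,
                            mutated_allele = alt_b, length = 1L)
      } else if (vt == "deletion") {
        s <- resample(indel_size[1L]:indel_size[2L])
        recs[[i]] <- tibble(vtype = vt, pos = p,
                            normal_allele = substr(reference, p, p + s - 1L),
                            mutated_allele = "", length = s)
      } else if (vt == "insertion") {
        s <- resample(indel_size[1L]:indel_size[2L])
        recs[[i]] <- tibble(vtype = vt, pos = p, normal_allele = "",
                            mutated_allele = paste(sample(.BASES, s, replace = TRUE),
                                                   collapse = ""),
                            length = s)
      } else {
        s <- resample(inv_size[1L]:inv_size[2L])
        segm <- substr(reference, p, p + s - 1L)
        recs[[i]] <- tibble(vtype = vt, pos = p, normal_allele = segm,
                            mutated_allele = reverse_complement(segm),
                            length = s)
      }
    }
    truth <- dplyr::bind_rows(recs) |>
      dplyr::mutate(contig = "ref", .before = "pos") |>
      dplyr::mutate(spacing = c(NA_integer_, gaps[-1L]))
    list(mutated = apply_truth_table(reference, truth), truth = truth)
  })
}

#' Apply a truth table to a reference
#'
#' Reconstructs the mutated reference from the normal reference and a truth
#' table; `implant_variants()` satisfies
#' `apply_truth_table(ref, truth) == mutated` exactly.
#'
#' @param reference Normal reference (character string).
#' @param truth Truth tibble as produced by [implant_variants()].
#' @return The mutated reference string.
#' @export
apply_truth_table <- function(reference, truth) {
  truth <- dplyr::arrange(truth, .data$pos)
  out <- character(0)
  cursor <- 1L   # next normal-reference base not yet emitted
  for (i in seq_len(nrow(truth))) {
    p <- truth$pos[i]; vt <- truth$vtype[i]
    na <- truth$normal_allele[i]; ma <- truth$mutated_allele[i]
    out <- c(out, substr(reference, cursor, p - 1L))
    if (vt == "SNV" || vt == "inversion") {
      out <- c(out, ma)
      cursor <- p + nchar(na)
    } else if (vt == "deletion") {
      cursor <- p + nchar(na)
    } else if (vt == "insertion") {
      out <- c(out, ma)
      cursor <- p
    }
  }
  out <- c(out, substr(reference, cursor, nchar(reference)))
  paste(out, collapse = "")
}

#' Simulate short reads from a haplotype
#'
#' Emulates a simple uniform-coverage Illumina-like simulator: fragments of
#' length Normal(`fragment_mean`, `fragment_sd`) (truncated at
#' `read_length`) start uniformly on the sequence; in paired mode mate 1 is
#' the fragment start and mate 2 the reverse complement of the fragment end,
#' and each fragment is drawn from either genome strand with probability
#' 1/2 (non-strand-specific). Substitution errors are i.i.d. per base at
#' `error_rate`; qualities are a constant character (the caller never uses
#' them). For a heterozygous sample pass both haplotypes: each fragment is
#' drawn from either with probability 1/2.
#'
#' @param sequence A haplotype string, or list of two haplotypes.
#' @param coverage Target fold-coverage.
#' @param read_length Read length (default 50).
#' @param fragment_mean,fragment_sd Fragment size distribution (defaults
#'   200, 10).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param paired Paired-end if `TRUE` (default).
#' @param seed Optional RNG seed.
#' @return List with `read1` and (paired only) `read2` character vectors.
#' @export
simulate_reads <- function(sequence, coverage, read_length = 50L,
                           fragment_mean = 200L, fragment_sd = 10L,
                           error_rate = 0.001, paired = TRUE, seed = NULL) {
  stopifnot(coverage > 0, fragment_mean >= read_length)
  haps <- if (is.list(sequence)) unlist(sequence) else sequence
  len <- nchar(haps[1L])
  with_seed(seed, {
    if (paired) {
      n_frag <- round(len * coverage / (2 * read_length))
      fl <- pmin(pmax(round(stats::rnorm(n_frag, fragment_mean, fragment_sd)),
                      read_length), len)
      hap <- if (length(haps) > 1L) sample.int(length(haps), n_frag, replace = TRUE)
             else rep(1L, n_frag)
      hl <- nchar(haps)[hap]
      fl <- pmin(fl, hl)
      start <- floor(stats::runif(n_frag) * (hl - fl + 1)) + 1L
      frag <- substr(haps[hap], start, start + fl - 1L)
      r1 <- substr(frag, 1L, read_length)
      r2 <- reverse_complement(substr(frag, fl - read_length + 1L, fl))
      flip <- stats::runif(n_frag) < 0.5
      tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
      list(read1 = add_errors(r1, error_rate),
           read2 = add_errors(r2, error_rate))
    } else {
      n_reads <- round(len * coverage / read_length)
      hap <- if (length(haps) > 1L) sample.int(length(haps), n_reads, replace = TRUE)
             else rep(1L, n_reads)
      hl <- nchar(haps)[hap]
      start <- floor(stats::runif(n_reads) * (hl - read_length + 1)) + 1L
      r <- substr(haps[hap], start, start + read_length - 1L)
      flip <- stats::runif(n_reads) < 0.5
      r[flip] <- reverse_complement(r[flip])
      list(read1 = add_errors(r, error_rate))
    }
  })
}

# i.i.d. substitution errors (uses the current RNG stream)
add_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) == 1L)
  rl <- rl[1L]
  total <- length(reads) * rl
  hit <- which(stats::runif(total) < rate)
  if (length(hit) == 0L) return(reads)
  ri <- (hit - 1L) %/% rl + 1L
  pj <- (hit - 1L) %% rl + 1L
  shift <- sample.int(3L, length(hit), replace = TRUE)
  for (t in seq_along(hit)) {
    old <- substr(reads[ri[t]], pj[t], pj[t])
    new <- .BASES[(match(old, .BASES) - 1L + shift[t]) %% 4L + 1L]
    substr(reads[ri[t]], pj[t], pj[t]) <- new
  }
  reads
}

#' Write reads to FASTQ
#'
#' Four-line records with constant quality characters.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param prefix Read name prefix.
#' @param mate Mate number appended to names (e.g. `"/1"`), or `""`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read", mate = "") {
  n <- length(reads)
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- sprintf("@%s_%d%s", prefix, seq_len(n), mate)
  lines[seq(2L, by = 4L, length.out = n)] <- reads
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- strrep("I", nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Build a complete synthetic benchmark
#'
#' Generates a random reference, implants variants, simulates reads for the
#' normal group (normal haplotype) and the mutated group (mutated haplotype;
#' in heterozygous mode a 50/50 draw of both haplotypes per fragment), and
#' writes reference FASTA, FASTQ files, truth TSV and a JSON manifest of all
#' parameters to `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param ref_length Reference length (default 100000).
#' @param n_snv,n_ins,n_del,n_inv Implanted variant counts.
#' @param indel_size,inv_size,spacing Ranges passed to [implant_variants()].
#' @param coverage Fold-coverage per group (default 30).
#' @param read_length,fragment_mean,fragment_sd,error_rate,paired Read
#'   simulation parameters (defaults 50, 200, 10, 0.001, TRUE).
#' @param zygosity `"pure"` (every mutated-group fragment from the mutated
#'   haplotype) or `"heterozygous"` (50/50).
#' @param gc_fraction Reference GC content.
#' @param seed RNG seed controlling the whole benchmark.
#' @return List: `reference`, `mutated`, `truth`, `files` (named paths).
#' @export
simulate_benchmark <- function(out_dir, ref_length = 100000L,
                               n_snv = 100L, n_ins = 15L, n_del = 15L,
                               n_inv = 0L, indel_size = c(1L, 10L),
                               inv_size = c(8L, 12L), spacing = c(25L, 50L),
                               coverage = 30, read_length = 50L,
                               fragment_mean = 200L, fragment_sd = 10L,
                               error_rate = 0.001, paired = TRUE,
                               zygosity = c("pure", "heterozygous"),
                               gc_fraction = 0.41, seed = 1L) {
  zygosity <- match.arg(zygosity)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  reference <- make_reference(ref_length, gc_fraction, seed = seed)
  imp <- implant_variants(reference, n_snv = n_snv, n_ins = n_ins,
                          n_del = n_del, n_inv = n_inv,
                          indel_size = indel_size, inv_size = inv_size,
                          spacing = spacing, seed = seed + 1L)
  norm_reads <- simulate_reads(reference, coverage, read_length,
                               fragment_mean, fragment_sd, error_rate,
                               paired, seed = seed + 2L)
  mut_input <- if (zygosity == "pure") imp$mutated else list(imp$mutated, reference)
  mut_reads <- simulate_reads(mut_input, coverage, read_length,
                              fragment_mean, fragment_sd, error_rate,
                              paired, seed = seed + 3L)
  files <- list(reference = file.path(out_dir, "reference.fa"),
                truth = file.path(out_dir, "truth.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  ref_set <- Biostrings::DNAStringSet(reference)
  names(ref_set) <- "ref"
  Biostrings::writeXStringSet(ref_set, files$reference)
  readr::write_tsv(imp$truth, files$truth)
  for (grp in c("normal", "mutated")) {
    rd <- if (grp == "normal") norm_reads else mut_reads
    if (paired) {
      files[[paste0(grp, "_1")]] <- file.path(out_dir, paste0(grp, "_1.fq"))
      files[[paste0(grp, "_2")]] <- file.path(out_dir, paste0(grp, "_2.fq"))
      write_fastq(rd$read1, files[[paste0(grp, "_1")]], prefix = grp, mate = "/1")
      write_fastq(rd$read2, files[[paste0(grp, "_2")]], prefix = grp, mate = "/2")
    } else {
      files[[grp]] <- file.path(out_dir, paste0(grp, ".fq"))
      write_fastq(rd$read1, files[[grp]], prefix = grp)
    }
  }
  manifest <- list(ref_length = ref_length, n_snv = n_snv, n_ins = n_ins,
                   n_del = n_del, n_inv = n_inv, indel_size = indel_size,
                   inv_size = inv_size, spacing = spacing,
                   coverage = coverage, read_length = read_length,
                   fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                   error_rate = error_rate, paired = paired,
                   zygosity = zygosity, gc_fraction = gc_fraction,
                   seed = seed)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA)
  list(reference = reference, mutated = imp$mutated, truth = imp$truth,
       files = files)
}
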