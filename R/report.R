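read_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reference)) {
    nm <- names(reference)
    if (is.null(nm)) nm <- paste0("contig", seq_along(reference))
    x <- Biostrings::DNAStringSet(reference)
    names(x) <- nm
    return(x)
  }
  abort("`reference` must be a FASTA path, DNAStringSet or named character vector")
}

# Re-express one event found at a minus-strand hit [s, e] (1-based, the
# interval where the reverse complement of the consensus matches) on the
# forward reference strand. col is the 0-based consensus column of the event.
orient_event <- function(vtype, col, na, ma, len, strand, s, e) {
  if (strand == "+") {
    return(list(pos = s + col, na = na, ma = ma))
  }
  switch(vtype,
    SNV = list(pos = e - col, na = reverse_complement(na),
               ma = reverse_complement(ma)),
    deletion = list(pos = e - col - len + 1L, na = reverse_complement(na), ma = ""),
    insertion = list(pos = e - col + 1L, na = "", ma = reverse_complement(ma)),
    inversion = list(pos = e - col - len + 1L, na = reverse_complement(na),
                     ma = na),
    list(pos = e - col, na = na, ma = ma))
}

#' Assign genomic coordinates to calls by exact matching
#'
#' Desk-scale surrogate for post-mapping the consensus normal sequences with
#' an external read mapper: each call's normal consensus is searched as an
#' exact substring of the reference on both strands. A unique hit locates
#' the call (1-based position of the event, alleles re-oriented to the
#' forward reference strand); zero or multiple hits leave it `unmapped` /
#' `ambiguous`. For alignment-based locating, export the consensus with
#' [export_consensus_fasta()] and map externally.
#'
#' @param x A `variant_calls` object or its calls tibble.
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @return The calls tibble with `contig`, `pos`, `ref_strand`, `status`
#'   (`located` / `ambiguous` / `unmapped`) and `ref_before` (reference base
#'   preceding `pos`, used for VCF anchoring), sorted by (contig, pos).
#' @export
locate_calls <- function(x, reference) {
  calls <- if (inherits(x, "variant_calls")) x$calls else x
  ref <- read_reference(reference)
  refs_chr <- as.character(ref)
  calls$contig <- NA_character_
  calls$pos <- NA_integer_
  calls$ref_strand <- NA_character_
  calls$status <- "unmapped"
  calls$ref_before <- NA_character_
  if (nrow(calls) == 0L) return(calls)
  # one search per distinct consensus (complex components share theirs)
  for (cons in unique(calls$normal_consensus)) {
    rows <- which(calls$normal_consensus == cons)
    hits <- list()
    for (ci in seq_along(refs_chr)) {
      for (std in c("+", "-")) {
        pat <- if (std == "+") cons else reverse_complement(cons)
        mt <- Biostrings::matchPattern(pat, ref[[ci]])
        if (length(mt) > 0L) {
          for (h in seq_along(mt)) {
            hits[[length(hits) + 1L]] <- list(
              contig = names(ref)[ci], s = BiocGenerics::start(mt)[h],
              e = BiocGenerics::end(mt)[h], strand = std, ci = ci)
          }
        }
      }
    }
    if (length(hits) == 0L) next
    if (length(hits) > 1L) { calls$status[rows] <- "ambiguous"; next }
    h <- hits[[1L]]
    for (r in rows) {
      ev <- orient_event(calls$vtype[r], calls$breakpoint_col[r],
                         calls$normal_allele[r], calls$mutated_allele[r],
                         calls$length[r], h$strand, h$s, h$e)
      calls$contig[r] <- h$contig
      calls$pos[r] <- ev$pos
      calls$normal_allele[r] <- ev$na
      calls$mutated_allele[r] <- ev$ma
      calls$ref_strand[r] <- h$strand
      calls$status[r] <- "located"
      if (ev$pos > 1L) {
        calls$ref_before[r] <- substr(refs_chr[h$ci], ev$pos - 1L, ev$pos - 1L)
      }
    }
  }
  dplyr::arrange(calls, is.na(.data$pos), .data$contig, .data$pos,
                 .data$cluster_id)
}

#' Export consensus normal sequences as FASTA
#'
#' One record per call row, header `cluster_id|vtype|breakpoint_col`,
#' sequence the consensus normal sequence -- suitable input for any external
#' mapper when exact matching is not enough.
#'
#' @param calls A `variant_calls` object or calls tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_consensus_fasta <- function(calls, path) {
  calls <- if (inherits(calls, "variant_calls")) calls$calls else calls
  if (nrow(calls) == 0L) {
    warn("no calls to export; writing empty FASTA")
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(calls$normal_consensus)
  names(x) <- sprintf("%d|%s|%d", calls$cluster_id, calls$vtype,
                      calls$breakpoint_col)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.tsv_cols <- c("cluster_id", "vtype", "normal_allele", "mutated_allele",
               "length", "n_norm", "n_mut", "q", "breakpoint_col",
               "contig", "pos", "status", "normal_consensus",
               "mutated_consensus")

#' Write a call report
#'
#' TSV: one row per variant with the full evidence (alleles, support,
#' variant fraction, consensus pair, location status). VCF 4.2 (located
#' calls only): indels are left-anchored on the preceding reference base per
#' VCF convention; INFO carries SVTYPE, SUPPORT (mutated-group reads) and VF
#' (variant fraction).
#'
#' @param calls A `variant_calls` object or a (located) calls tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  calls <- if (inherits(calls, "variant_calls")) calls$calls else calls
  if (format == "tsv") {
    out <- calls
    for (col in .tsv_cols) if (!col %in% names(out)) out[[col]] <- NA
    readr::write_tsv(out[, .tsv_cols], path)
    return(invisible(path))
  }
  if (!"pos" %in% names(calls)) {
    abort("VCF output requires located calls (run locate_calls() first)",
          class = "directvc_usage_error")
  }
  loc <- calls[!is.na(calls$pos) & calls$status == "located", ]
  lines <- c("##fileformat=VCFv4.2",
             "##source=directvc",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant type\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Mutated-group supporting reads\">",
             "##INFO=<ID=VF,Number=1,Type=Float,Description=\"Variant fraction q\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (r in seq_len(nrow(loc))) {
    vt <- loc$vtype[r]; pos <- loc$pos[r]
    na <- loc$normal_allele[r]; ma <- loc$mutated_allele[r]
    anch <- loc$ref_before[r]
    if (vt == "SNV" || vt == "inversion") {
      ref_f <- na; alt_f <- ma
    } else if (vt == "deletion") {
      if (is.na(anch)) next
      ref_f <- paste0(anch, na); alt_f <- anch; pos <- pos - 1L
    } else if (vt == "insertion") {
      if (is.na(anch)) next
      ref_f <- anch; alt_f <- paste0(anch, ma); pos <- pos - 1L
    } else next
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=%s;SUPPORT=%d;VF=%.4f",
      loc$contig[r], pos, paste0("dvc", loc$cluster_id[r]), ref_f, alt_f,
      toupper(substr(vt, 1L, 3L)), loc$n_mut[r], loc$q[r]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Re-read a TSV call report
#'
#' Inverse of `write_calls(format = "tsv")` for the columns it writes.
#'
#' @param path TSV path.
#' @return A calls tibble.
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cluster_id = readr::col_integer(), vtype = readr::col_character(),
    normal_allele = readr::col_character(),
    mutated_allele = readr::col_character(),
    length = readr::col_integer(), n_norm = readr::col_integer(),
    n_mut = readr::col_integer(), q = readr::col_double(),
    breakpoint_col = readr::col_integer(), contig = readr::col_character(),
    pos = readr::col_integer(), status = readr::col_character(),
    normal_consensus = readr::col_character(),
    mutated_consensus = readr::col_character())) |>
    dplyr::mutate(dplyr::across(c("normal_allele", "mutated_allele"),
                                \(x) dplyr::coalesce(x, "")))
}
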