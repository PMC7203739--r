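#' Enumerate the 4^k prefix partitions
#'
#' All length-`k` ACGT strings in lexicographic order (A < C < G < T). Each
#' prefix defines one independently processed suffix batch, so the whole
#' suffix set is split into `4^k` partitions whose batches can be sorted and
#' released one at a time. `k = 0` yields the single empty prefix, i.e. no
#' partitioning. The choice of `k` never changes the final call set, only the
#' peak size of a batch.
#'
#' @param k Prefix length, 0 to 8.
#' @return Character vector of `4^k` prefixes, strictly increasing; the
#'   attribute `k` records the prefix length.
#' @examples
#' list_prefixes(1) # "A" "C" "G" "T"
#' @export
list_prefixes <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 8 || k != round(k)) {
    abort("`k` must be a single integer in 0..8", class = "directvc_domain_error")
  }
  k <- as.integer(k)
  if (k == 0L) return(structure("", k = 0L))
  g <- do.call(expand.grid,
               c(rep(list(.BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  p <- do.call(paste0, rev(g))
  structure(sort(p, method = "radix"), k = k)
}

#' Combine the two sample groups into an oriented read table
#'
#' Decodes both packed stores and lays the reads out as one tibble, one row
#' per oriented read. In non-strand-specific mode every read additionally
#' appears reverse-complemented with `strand = "reverse"`, so that a
#' breakpoint sequenced on either strand can anchor a cluster.
#'
#' @param normal,mutated `packed_read_store` objects (or plain character
#'   vectors of reads, mainly for tests).
#' @param strand_specific If `FALSE` (default), include reverse complements.
#' @return A tibble with columns `seq`, `group`, `strand`, `read_id` (dense
#'   1-based ID within its group).
#' @export
read_db <- function(normal, mutated, strand_specific = FALSE) {
  grab <- function(x) {
    if (inherits(x, "packed_read_store")) store_sequences(x) else as.character(x)
  }
  ns <- grab(normal)
  ms <- grab(mutated)
  one <- function(seqs, group) {
    fwd <- tibble(seq = seqs, group = group, strand = "forward",
                  read_id = seq_along(seqs))
    if (strand_specific || length(seqs) == 0L) return(fwd)
    dplyr::bind_rows(fwd, tibble(seq = reverse_complement(seqs), group = group,
                                 strand = "reverse", read_id = seq_along(seqs)))
  }
  dplyr::bind_rows(one(ns, "normal"), one(ms, "mutated"))
}

# All suffix occurrences of length >= d: parallel vectors over db rows.
# Returns list(src, offset) with offset 0-based.
enumerate_suffixes <- function(db, d) {
  lens <- nchar(db$seq)
  n_suf <- pmax(lens - d + 1L, 0L)
  src <- rep.int(seq_len(nrow(db)), n_suf)
  offset <- sequence(n_suf) - 1L
  list(src = src, offset = offset)
}

suffix_ref_tibble <- function(db, src, offset) {
  tibble(src = src,
         read_id = db$read_id[src],
         offset = offset,
         group = db$group[src],
         strand = db$strand[src],
         suffix_length = nchar(db$seq)[src] - offset)
}

#' Collect the suffixes of one prefix partition
#'
#' Every suffix occurrence of length at least `d` whose first
#' `nchar(prefix)` bases equal `prefix`, across both groups and (in
#' non-strand-specific mode) both strands of `db`.
#'
#' @param db An oriented read table from [read_db()].
#' @param prefix The partition's k-mer (`""` collects every suffix).
#' @param d Minimum suffix length; must be at least `nchar(prefix)`.
#' @return A suffix reference tibble: `src` (row of `db`), `read_id`,
#'   `offset` (0-based start within the oriented read), `group`, `strand`,
#'   `suffix_length`.
#' @export
collect_suffixes <- function(db, prefix, d) {
  k <- nchar(prefix)
  if (d < k) abort("`d` must be >= nchar(prefix)", class = "directvc_domain_error")
  e <- enumerate_suffixes(db, d)
  if (k > 0L && length(e$src) > 0L) {
    key <- substring(db$seq[e$src], e$offset + 1L, e$offset + k)
    keep <- key == prefix
    e$src <- e$src[keep]
    e$offset <- e$offset[keep]
  }
  suffix_ref_tibble(db, e$src, e$offset)
}

#' Lexicographically sort suffix references
#'
#' Orders the references by the full text of their suffixes (C locale, so a
#' proper prefix sorts before any extension of it), breaking exact-text ties
#' deterministically by (group, strand, read_id, offset) to make runs
#' byte-reproducible.
#'
#' @param refs A suffix reference tibble (see [collect_suffixes()]).
#' @param db The oriented read table the references point into.
#' @return `refs` reordered, with the suffix text attached as column `text`.
#' @export
sort_suffix_refs <- function(refs, db) {
  text <- substring(db$seq[refs$src], refs$offset + 1L)
  o <- order(text, refs$group, refs$strand, refs$read_id, refs$offset,
             method = "radix")
  out <- refs[o, ]
  out$text <- text[o]
  out
}
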