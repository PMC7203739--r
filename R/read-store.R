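#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# 2-bit code table: A=00, C=01, G=10, T=11
.BASES <- c("A", "C", "G", "T")

.base_codes <- local({
  x <- rep(NA_integer_, 128L)
  x[utf8ToInt("A")] <- 0L
  x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L
  x[utf8ToInt("T")] <- 3L
  x
})

#' Pack a DNA sequence into 2 bits per base
#'
#' Encodes an ACGT-only sequence with the fixed code A=00, C=01, G=10, T=11,
#' four bases per byte (first base in the two most significant bits). This is
#' the storage primitive of the packed read store: a base costs 2 bits instead
#' of the usual 8.
#'
#' @param seq A single character string over A/C/G/T (lower case is accepted
#'   and uppercased first).
#' @return An object of class `packed_dna`: a list with `bytes` (raw vector)
#'   and `n_bases` (integer). The empty string encodes to zero bytes.
#' @seealso [decode_sequence()], [as_bitstring()]
#' @examples
#' p <- encode_sequence("ACGT")
#' as_bitstring(p)        # "00011011"
#' decode_sequence(p)     # "ACGT"
#' @export
encode_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) {
    return(structure(list(bytes = raw(0), n_bases = 0L), class = "packed_dna"))
  }
  codes <- .base_codes[utf8ToInt(seq)]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    abort(sprintf("non-ACGT character '%s' at position %d",
                  substr(seq, bad, bad), bad),
          class = "directvc_encoding_error")
  }
  pad <- (-n) %% 4L
  codes <- c(codes, integer(pad))
  m <- matrix(codes, nrow = 4L)
  bytes <- as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
  structure(list(bytes = bytes, n_bases = as.integer(n)), class = "packed_dna")
}

#' Decode a 2-bit packed DNA sequence
#'
#' Inverse of [encode_sequence()]: `decode_sequence(encode_sequence(s)) == s`
#' for every ACGT string `s`.
#'
#' @param packed A `packed_dna` object or a raw vector of packed bytes.
#' @param length Number of bases to decode; defaults to the stored length for
#'   `packed_dna` input (required for raw input).
#' @return A character string.
#' @export
decode_sequence <- function(packed, length = NULL) {
  if (inherits(packed, "packed_dna")) {
    bytes <- packed$bytes
    if (is.null(length)) length <- packed$n_bases
  } else {
    bytes <- as.raw(packed)
    if (is.null(length)) abort("`length` is required for raw input")
  }
  length <- as.integer(length)
  if (length < 0L || length > 4L * base::length(bytes)) {
    abort(sprintf("cannot decode %d bases from %d bytes",
                  length, base::length(bytes)),
          class = "directvc_bounds_error")
  }
  if (length == 0L) return("")
  b <- as.integer(bytes)
  codes <- rbind(b %/% 64L, (b %/% 16L) %% 4L, (b %/% 4L) %% 4L, b %% 4L)
  codes <- codes[seq_len(length)]
  intToUtf8(utf8ToInt("ACGT")[codes + 1L])
}

#' @rdname encode_sequence
#' @param x A `packed_dna` object.
#' @return `as_bitstring()` returns the bit string, two characters per base.
#' @export
as_bitstring <- function(x) {
  stopifnot(inherits(x, "packed_dna"))
  if (x$n_bases == 0L) return("")
  bits <- c("00", "01", "10", "11")
  s <- decode_sequence(x)
  paste(bits[.base_codes[utf8ToInt(s)] + 1L], collapse = "")
}

#' @export
print.packed_dna <- function(x, ...) {
  cat(sprintf("<packed_dna: %d bases, %d bytes>\n", x$n_bases, length(x$bytes)))
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick reverse complement; vectorised over input. An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq Character vector of ACGT sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTacgt]", seq))) {
    abort("non-ACGT character in input", class = "directvc_encoding_error")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

#' Per-read index overhead of the block addressing scheme
#'
#' Reads are grouped into blocks of `block_size`; each read carries a 2-byte
#' in-block offset header and each block one 8-byte address, so the amortised
#' index cost is `2 + 8 / block_size` bytes per read (2.125 for the default
#' block size of 64).
#'
#' @param block_size Reads per block (integer >= 1).
#' @return Bytes of index overhead per read.
#' @examples
#' index_overhead_bytes(64) # 2.125
#' @export
index_overhead_bytes <- function(block_size) {
  if (!is.numeric(block_size) || length(block_size) != 1L || block_size < 1) {
    abort("`block_size` must be a single integer >= 1",
          class = "directvc_domain_error")
  }
  2 + 8 / block_size
}

# Vectorised packing of many reads; returns list(bytes = raw, offsets, nbytes)
# where offsets are 0-based byte offsets into the concatenated payload.
pack_many <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) {
    return(list(payload = raw(0), nbytes = integer(0)))
  }
  lens <- nchar(seqs)
  pad <- (-lens) %% 4L
  padded <- ifelse(pad > 0L, paste0(seqs, strrep("A", pad)), seqs)
  big <- paste(padded, collapse = "")
  codes <- .base_codes[utf8ToInt(big)]
  m <- matrix(codes, nrow = 4L)
  payload <- as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
  list(payload = payload, nbytes = as.integer((lens + pad) %/% 4L))
}

read_fastq_sequences <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      abort(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
            class = "directvc_parse_error")
    }
  )
  toupper(as.character(x, use.names = FALSE))
}

#' Load FASTQ reads into a 2-bit packed block store
#'
#' Reads one (single-end) or two (paired-end) FASTQ files for one sample
#' group and stores every retained read 2-bit packed, 64 reads per block with
#' 2-byte in-block offset headers. Base qualities are parsed only to validate
#' the FASTQ format; they are never used for filtering. Reads containing any
#' non-ACGT symbol (N, IUPAC codes) and reads shorter than `min_length`
#' cannot take part in breakpoint detection and are dropped with a count.
#' Paired-end mates are stored as independent reads.
#'
#' @param fastq_paths Character vector of one or two FASTQ paths (plain or
#'   gzip).
#' @param group_label `"normal"` or `"mutated"`.
#' @param min_length Minimum retained read length (reads shorter than `d + 1`
#'   cannot contribute a divergence column; the caller passes `d + 1`).
#' @param block_size Reads per block (default 64).
#' @return A `packed_read_store` with fields `group_label`, `blocks` (raw
#'   vectors: 2-byte headers then packed reads), `lengths`, `n_reads`,
#'   `n_dropped`.
#' @export
load_reads <- function(fastq_paths, group_label = c("normal", "mutated"),
                       min_length = 1L, block_size = 64L) {
  group_label <- match.arg(group_label)
  stopifnot(length(fastq_paths) %in% 1:2)
  seq_sets <- lapply(fastq_paths, read_fastq_sequences)
  if (length(seq_sets) == 2L &&
      length(seq_sets[[1L]]) != length(seq_sets[[2L]])) {
    abort(sprintf("paired FASTQ files have %d vs %d records",
                  length(seq_sets[[1L]]), length(seq_sets[[2L]])),
          class = "directvc_input_error")
  }
  seqs <- unlist(seq_sets, use.names = FALSE)
  n_parsed <- length(seqs)
  keep <- !grepl("[^ACGT]", seqs) & nchar(seqs) >= min_length
  dropped <- n_parsed - sum(keep)
  seqs <- seqs[keep]
  new_packed_read_store(seqs, group_label,
                        n_dropped = dropped, block_size = block_size,
                        source = fastq_paths)
}

# Build a store directly from in-memory character sequences.
new_packed_read_store <- function(seqs, group_label, n_dropped = 0L,
                                  block_size = 64L, source = character(0)) {
  block_size <- as.integer(block_size)
  n <- length(seqs)
  packed <- pack_many(seqs)
  blocks <- vector("list", ceiling(n / block_size))
  if (n > 0L) {
    byte_ends <- cumsum(packed$nbytes)
    byte_starts <- byte_ends - packed$nbytes
    block_of <- (seq_len(n) - 1L) %/% block_size
    for (b in seq_along(blocks)) {
      idx <- which(block_of == b - 1L)
      rel <- packed$nbytes[idx]
      # in-block byte offsets of each read, relative to the end of the
      # header area, stored big-endian in 2 bytes
      off <- cumsum(rel) - rel
      header <- as.raw(rbind(off %/% 256L, off %% 256L))
      payload <- packed$payload[(byte_starts[idx[1L]] + 1L):byte_ends[idx[length(idx)]]]
      blocks[[b]] <- c(header, payload)
    }
  }
  structure(
    list(group_label = group_label, blocks = blocks,
         block_size = block_size, lengths = as.integer(nchar(seqs)),
         n_reads = n, n_dropped = as.integer(n_dropped), source = source),
    class = "packed_read_store"
  )
}

#' @export
print.packed_read_store <- function(x, ...) {
  cat(sprintf(
    "<packed_read_store: %s group, %d reads (%d dropped), %d blocks of %d, %.3f index bytes/read>\n",
    x$group_label, x$n_reads, x$n_dropped, length(x$blocks), x$block_size,
    index_overhead_bytes(x$block_size)))
  invisible(x)
}

#' Retrieve one read from a packed store by its dense ID
#'
#' @param store A `packed_read_store`.
#' @param i 1-based read ID (reads are numbered densely in load order).
#' @return The read sequence as a character string.
#' @export
get_read <- function(store, i) {
  stopifnot(inherits(store, "packed_read_store"))
  i <- as.integer(i)
  if (i < 1L || i > store$n_reads) {
    abort(sprintf("read ID %d out of range 1..%d", i, store$n_reads),
          class = "directvc_bounds_error")
  }
  bs <- store$block_size
  b <- (i - 1L) %/% bs + 1L
  j <- (i - 1L) %% bs + 1L
  block <- store$blocks[[b]]
  n_in_block <- min(bs, store$n_reads - (b - 1L) * bs)
  header_bytes <- 2L * n_in_block
  off <- as.integer(block[2L * j - 1L]) * 256L + as.integer(block[2L * j])
  len <- store$lengths[i]
  nby <- ((len + 3L) %/% 4L)
  bytes <- block[(header_bytes + off + 1L):(header_bytes + off + nby)]
  decode_sequence(bytes, len)
}

#' Decode all reads of a packed store
#'
#' Returns the stored reads, in ID order, as a character vector. This is the
#' working representation used by the suffix-partitioning stage.
#'
#' @param store A `packed_read_store`.
#' @return Character vector of length `store$n_reads`.
#' @export
store_sequences <- function(store) {
  stopifnot(inherits(store, "packed_read_store"))
  n <- store$n_reads
  if (n == 0L) return(character(0))
  bs <- store$block_size
  out <- character(n)
  for (b in seq_along(store$blocks)) {
    block <- store$blocks[[b]]
    first <- (b - 1L) * bs + 1L
    last <- min(b * bs, n)
    idx <- first:last
    header_bytes <- 2L * length(idx)
    payload <- block[(header_bytes + 1L):length(block)]
    big <- decode_sequence(payload, 4L * length(payload))
    nby <- (store$lengths[idx] + 3L) %/% 4L
    starts <- cumsum(nby) - nby          # 0-based byte offsets
    out[idx] <- substring(big, starts * 4L + 1L,
                          starts * 4L + store$lengths[idx])
  }
  out
}
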