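#' Merge clusters indicating the identical breakpoint
#'
#' Clusters whose anchors (the substring on the left of the breakpoint) are
#' identical are combined into one cluster: members are unioned and
#' deduplicated per (group, read, strand), and support is recomputed
#' downstream. Idempotent.
#'
#' @param cs A recovered `cluster_set`.
#' @return A `cluster_set` with one cluster per distinct anchor, cluster IDs
#'   renumbered densely in anchor lexicographic order.
#' @export
merge_identical_breakpoints <- function(cs) {
  m <- cs$members
  if (nrow(m) == 0L) return(cs)
  anchors <- sort(unique(m$anchor), method = "radix")
  m$cluster_id <- match(m$anchor, anchors)
  m <- m |>
    dplyr::arrange(.data$cluster_id, .data$group, .data$read_id,
                   .data$strand, .data$offset) |>
    dplyr::distinct(.data$cluster_id, .data$group, .data$read_id,
                    .data$strand, .keep_all = TRUE)
  clusters <- m |>
    dplyr::group_by(.data$cluster_id, .data$anchor) |>
    dplyr::summarise(n_members = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(partition_prefix = NA_character_)
  structure(list(members = m, clusters = clusters), class = "cluster_set")
}

# Column-wise vote over one group's aligned reads.
# reads: character vector; bp_col: 0-based divergence column within each read.
# Returns list(cols = 0-based column index relative to divergence column,
#              base = majority base or NA, covering = counts).
vote_columns <- function(reads, bp_col) {
  n <- length(reads)
  lens <- nchar(reads)
  lo <- -max(bp_col)                 # leftmost relative column
  hi <- max(lens - 1L - bp_col)      # rightmost relative column
  width <- hi - lo + 1L
  mat <- matrix(NA_character_, nrow = n, ncol = width)
  for (i in seq_len(n)) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    start <- -bp_col[i] - lo + 1L
    mat[i, start:(start + lens[i] - 1L)] <- ch
  }
  base <- rep(NA_character_, width)
  covering <- integer(width)
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    covering[j] <- length(col)
    if (length(col) >= 2L) {
      tab <- table(col)
      if (max(tab) * 2L > length(col)) base[j] <- names(tab)[which.max(tab)]
    }
  }
  list(rel = lo:hi, base = base, covering = covering)
}

# Extend a voted column set outward from the anchor.
# Returns the consensus string and the 0-based index of the divergence column
# within it, or NULL when the divergence column itself is undecidable.
extend_consensus <- function(v, anchor_text, d) {
  rel <- v$rel
  at <- function(r) { i <- match(r, rel); if (is.na(i)) NA_character_ else v$base[i] }
  # rightward from the divergence column (relative col 0)
  right <- character(0)
  r <- 0L
  repeat {
    b <- at(r)
    if (is.na(b)) break
    right <- c(right, b)
    r <- r + 1L
  }
  if (length(right) == 0L) return(NULL)
  # leftward from just before the anchor
  left <- character(0)
  r <- -as.integer(d) - 1L
  repeat {
    b <- at(r)
    if (is.na(b)) break
    left <- c(b, left)
    r <- r - 1L
  }
  seqs <- paste0(paste(left, collapse = ""), anchor_text,
                 paste(right, collapse = ""))
  list(text = seqs, b = length(left) + as.integer(d))
}

#' Build the consensus normal/mutated pair of a cluster
#'
#' Reads are aligned by their known in-read breakpoint columns (the shared
#' d-mer anchor fixes the alignment; no realignment is performed). Per group,
#' each column outside the anchor receives the base held by a strict
#' majority (> 50%) of the reads covering it, with at least 2 covering reads;
#' extension halts independently leftward and rightward at the first
#' undecidable column. Only mutated-group reads carrying a variant base
#' (divergence-column base different from the normal majority) vote for the
#' mutated consensus: in a heterozygous sample about half the mutated-group
#' reads are reference-like and would otherwise vote the consensus back to
#' reference. If either voting population has fewer than 2 reads covering
#' the divergence column the cluster yields no consensus (`NULL`).
#'
#' The two consensus sequences are finally trimmed on the left to their
#' common flank (always at least the d-mer anchor), so that
#' `normal[1..b] == mutated[1..b]` with `b` the 0-based breakpoint column.
#'
#' @param members Member tibble of one cluster (from a recovered
#'   `cluster_set`), with `read_seq`, `bp_col`, `group`, `div_base`.
#' @param d Anchor length.
#' @param norm_major The normal group's majority base at the divergence
#'   column (from [variant_fraction()]); recomputed if `NULL`.
#' @return A `consensus_pair` (list: `normal`, `mutated`, `b`) or `NULL`.
#' @export
build_consensus <- function(members, d, norm_major = NULL) {
  nm <- members[members$group == "normal", ]
  mm <- members[members$group == "mutated", ]
  if (is.null(norm_major)) {
    dv <- nm$div_base[nm$div_base != ""]
    if (length(dv) == 0L) return(NULL)
    tab <- sort(table(dv), decreasing = TRUE)
    norm_major <- names(tab)[1L]
  }
  carriers <- mm[mm$div_base != "" & mm$div_base != norm_major, ]
  if (sum(nm$div_base != "") < 2L || nrow(carriers) < 2L) return(NULL)
  anchor_text <- members$anchor[1L]
  vn <- vote_columns(nm$read_seq, nm$bp_col)
  vm <- vote_columns(carriers$read_seq, carriers$bp_col)
  en <- extend_consensus(vn, anchor_text, d)
  em <- extend_consensus(vm, anchor_text, d)
  if (is.null(en) || is.null(em)) return(NULL)
  # trim left flanks to their common suffix (>= anchor by construction)
  j <- 0L
  max_j <- min(en$b, em$b)
  while (j < max_j &&
         substr(en$text, en$b - j, en$b - j) ==
         substr(em$text, em$b - j, em$b - j)) {
    j <- j + 1L
  }
  normal <- substr(en$text, en$b - j + 1L, nchar(en$text))
  mutated <- substr(em$text, em$b - j + 1L, nchar(em$text))
  structure(list(normal = normal, mutated = mutated, b = j), # 0-based column
            class = "consensus_pair")
}

#' @export
print.consensus_pair <- function(x, ...) {
  cat(sprintf("<consensus_pair: breakpoint col %d>\n  N: %s\n  M: %s\n",
              x$b, x$normal, x$mutated))
  invisible(x)
}

# substring by 0-based start and length; NA when not fully available
seg <- function(s, start0, len) {
  if (len <= 0L || start0 + len > nchar(s)) return(NA_character_)
  substr(s, start0 + 1L, start0 + len)
}

#' Infer the variant type of a consensus pair
#'
#' Compares the normal and mutated consensus sequences at and after the
#' breakpoint column `b`, testing types in the fixed order deletion /
#' insertion (smallest gap first, deletion on a tie), SNV, inversion
#' (smallest length first), complex; the first confirmed type wins, and a
#' pair that confirms no type is `unassigned`. Every test demands a run of
#' matching bases beyond the event as confirmation -- `m` when the
#' consensus extents allow it, shrinking to the available extent otherwise
#' with a floor of 5 matched bases for indels and inversions and 3 for
#' SNVs (a cluster detected on a single strand often has a short right
#' extent; demanding the full window there would leave real small indels
#' unassigned).
#'
#' A complex breakpoint is aligned globally with unit edit costs over the
#' full remaining extents; it is accepted when the edit script has at most
#' `max_edit_runs` runs of edits and ends in a matched run of at least `m`
#' bases, and is then decomposed into individual SNV / insertion / deletion
#' components (one SNV per substituted base).
#'
#' @param pair A `consensus_pair`.
#' @param m Match-confirmation length (default 10).
#' @param gmax Largest indel gap to test (default: whatever the extents
#'   allow).
#' @param max_edit_runs Maximum edit runs for complex decomposition
#'   (default 5).
#' @return A `variant_call` list: `vtype` (`SNV`, `insertion`, `deletion`,
#'   `inversion`, `complex`, `unassigned`), `normal_allele`,
#'   `mutated_allele`, `length`, `breakpoint_col` (0-based, within the
#'   consensus), `consensus`, and for decomposed complexes `components`
#'   (tibble with per-component `vtype`, `col`, alleles, `length`).
#' @export
classify_variant <- function(pair, m = 10L, gmax = NULL, max_edit_runs = 5L) {
  Nc <- pair$normal; Mc <- pair$mutated; b <- pair$b
  ext_n <- nchar(Nc) - b
  ext_m <- nchar(Mc) - b
  call <- function(vtype, na = "", ma = "", len = 0L, components = NULL) {
    structure(list(vtype = vtype, normal_allele = na, mutated_allele = ma,
                   length = as.integer(len), breakpoint_col = b,
                   consensus = pair, components = components),
              class = "variant_call")
  }
  if (ext_n <= 0L || ext_m <= 0L) return(call("unassigned"))

  # 1. indel, smallest gap first; deletion reported on a tie. The
  # confirmation window shrinks to the available extent (floor of 5 matched
  # bases) so that a single-strand cluster with a short right extent can
  # still be typed.
  floor_id <- min(m, 5L)
  g_top <- if (is.null(gmax)) max(ext_n, ext_m) else as.integer(gmax)
  for (g in seq_len(max(g_top, 0L))) {
    w_del <- min(m, ext_n - g, ext_m)
    if (w_del >= floor_id &&
        identical(seg(Nc, b + g, w_del), seg(Mc, b, w_del))) {
      return(call("deletion", na = seg(Nc, b, g), len = g))
    }
    w_ins <- min(m, ext_m - g, ext_n)
    if (w_ins >= floor_id &&
        identical(seg(Mc, b + g, w_ins), seg(Nc, b, w_ins))) {
      return(call("insertion", ma = seg(Mc, b, g), len = g))
    }
    if (w_del < floor_id && w_ins < floor_id) break
  }

  # 2. SNV: single substitution, flanks match over (possibly shortened) window
  m_snv <- min(m, ext_n - 1L, ext_m - 1L)
  if (m_snv >= min(m, 3L) &&
      substr(Nc, b + 1L, b + 1L) != substr(Mc, b + 1L, b + 1L) &&
      identical(seg(Nc, b + 1L, m_snv), seg(Mc, b + 1L, m_snv))) {
    return(call("SNV", na = substr(Nc, b + 1L, b + 1L),
                ma = substr(Mc, b + 1L, b + 1L), len = 1L))
  }

  # 3. inversion, smallest length first, flank confirmation as for indels
  l_top <- min(ext_n, ext_m) - floor_id
  if (l_top >= 2L) {
    for (l in 2:l_top) {
      w_inv <- min(m, ext_n - l, ext_m - l)
      segn <- seg(Nc, b, l)
      if (identical(seg(Mc, b, l), reverse_complement(segn)) &&
          identical(seg(Nc, b + l, w_inv), seg(Mc, b + l, w_inv))) {
        return(call("inversion", na = segn, ma = seg(Mc, b, l), len = l))
      }
    }
  }

  # 4. complex: global unit-cost edit script over the full remaining extents
  if (ext_n >= m + 2L && ext_m >= m + 2L) {
    A <- substr(Nc, b + 1L, nchar(Nc))
    B <- substr(Mc, b + 1L, nchar(Mc))
    # indels cost marginally more than substitutions so that contiguous
    # SNVs decompose as substitutions, not as equal-cost insert/delete pairs
    tr <- attr(utils::adist(A, B, counts = TRUE,
                            costs = list(insertions = 1.01, deletions = 1.01,
                                         substitutions = 1)),
               "trafos")[1L, 1L]
    ops <- strsplit(tr, "", fixed = TRUE)[[1L]]
    r <- rle(ops)
    n_edit_runs <- sum(r$values != "M")
    last_match <- r$values[length(r$values)] == "M" &&
      r$lengths[length(r$lengths)] >= m
    if (n_edit_runs >= 1L && n_edit_runs <= max_edit_runs && last_match) {
      comps <- decompose_edit_script(r, A, B, b)
      return(call("complex", na = A, ma = B,
                  len = sum(comps$length), components = comps))
    }
  }
  call("unassigned")
}

# Turn an rle'd M/S/I/D edit script into component calls.
# i/j are 0-based cursors into A (normal, from col b) and B (mutated).
decompose_edit_script <- function(r, A, B, b) {
  i <- 0L; j <- 0L
  out <- list()
  for (t in seq_along(r$values)) {
    op <- r$values[t]; L <- r$lengths[t]
    if (op == "M") {
      i <- i + L; j <- j + L
    } else if (op == "S") {
      for (u in seq_len(L)) {
        out[[length(out) + 1L]] <- tibble(
          vtype = "SNV", col = b + i + u - 1L,
          normal_allele = substr(A, i + u, i + u),
          mutated_allele = substr(B, j + u, j + u), length = 1L)
      }
      i <- i + L; j <- j + L
    } else if (op == "D") {
      out[[length(out) + 1L]] <- tibble(
        vtype = "deletion", col = b + i,
        normal_allele = substr(A, i + 1L, i + L),
        mutated_allele = "", length = L)
      i <- i + L
    } else if (op == "I") {
      out[[length(out) + 1L]] <- tibble(
        vtype = "insertion", col = b + i, normal_allele = "",
        mutated_allele = substr(B, j + 1L, j + L), length = L)
      j <- j + L
    }
  }
  dplyr::bind_rows(out)
}

# Length-L windows of the consensus pair containing the breakpoint column,
# plus their reverse complements: the strand-merge evidence sets.
rc_merge_sets <- function(pair, L = 15L) {
  win <- function(s, b) {
    from <- max(0L, b - L + 1L)
    to <- min(b, nchar(s) - L)
    if (to < from) return(character(0))
    starts <- from:to
    unique(substring(s, starts + 1L, starts + L))
  }
  S <- win(pair$normal, pair$b)
  Sp <- win(pair$mutated, pair$b)
  list(S = S, S_bar = if (length(S)) reverse_complement(S) else character(0),
       S_prime = Sp,
       S_prime_bar = if (length(Sp)) reverse_complement(Sp) else character(0))
}

# Exact-overlap stitch of Y onto X (same orientation), requiring a unique
# maximal overlap of >= min_overlap identical bases. The merged string keeps
# X's coordinate frame (any part of Y left of X's start is discarded).
stitch_strings <- function(X, Y, min_overlap = 15L) {
  nx <- nchar(X); ny <- nchar(Y)
  if (nx < min_overlap || ny < min_overlap) return(NULL)
  best <- NULL; best_ov <- -1L; n_best <- 0L
  for (o in seq.int(-(ny - min_overlap), nx - min_overlap)) {
    lo <- max(0L, o); hi <- min(nx, o + ny)       # overlap on X, 0-based
    ov <- hi - lo
    if (ov < min_overlap) next
    if (substr(X, lo + 1L, hi) == substr(Y, lo - o + 1L, hi - o)) {
      if (ov > best_ov) { best <- o; best_ov <- ov; n_best <- 1L }
      else if (ov == best_ov) n_best <- n_best + 1L
    }
  }
  if (is.null(best) || n_best > 1L) return(NULL)
  right_ext <- if (best + ny > nx) substr(Y, nx - best + 1L, ny) else ""
  paste0(X, right_ext)
}

#' Re-infer the type of an unassigned strand-merged breakpoint
#'
#' When both strand-mirrored clusters of a breakpoint are unassigned, their
#' consensus pairs are stitched on an exact overlap (>= `min_overlap` bases)
#' into one longer pair -- the reverse side re-oriented to forward -- and
#' the variant type inferred again on the extended pair. Typical rescue:
#' an indel too large for either side's right extent alone. If no unique
#' consistent overlap exists the call stays unassigned.
#'
#' @param fwd_pair,rev_pair The forward-orientation `consensus_pair` and the
#'   reverse-orientation one (still in its own orientation).
#' @param m,max_edit_runs Passed to [classify_variant()].
#' @param min_overlap Minimum exact overlap for stitching (default 15).
#' @return A `variant_call` (possibly still unassigned) carrying the
#'   stitched pair when stitching succeeded.
#' @export
reinfer_unassigned <- function(fwd_pair, rev_pair, m = 10L,
                               max_edit_runs = 5L, min_overlap = 15L) {
  Yn <- reverse_complement(rev_pair$normal)
  Ym <- reverse_complement(rev_pair$mutated)
  sn <- stitch_strings(fwd_pair$normal, Yn, min_overlap)
  sm <- stitch_strings(fwd_pair$mutated, Ym, min_overlap)
  if (is.null(sn) || is.null(sm)) {
    return(classify_variant(fwd_pair, m = m, max_edit_runs = max_edit_runs))
  }
  pair <- structure(list(normal = sn, mutated = sm, b = fwd_pair$b),
                    class = "consensus_pair")
  classify_variant(pair, m = m, max_edit_runs = max_edit_runs)
}
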