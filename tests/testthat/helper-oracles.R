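# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (plain loops, no shared code with
# the package internals) so it can serve as a cross-check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_naive <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# character-by-character lexicographic comparison (prefix < extension)
lex_less <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  for (i in seq_len(min(na, nb))) {
    ca <- substr(a, i, i); cb <- substr(b, i, i)
    if (ca != cb) return(ca < cb)
  }
  na < nb
}

# O(n^2) sort of strings using lex_less only
lex_sort_naive <- function(x) {
  out <- character(0)
  pool <- x
  while (length(pool) > 0) {
    m <- 1
    for (i in seq_along(pool)) if (lex_less(pool[i], pool[m])) m <- i
    out <- c(out, pool[m])
    pool <- pool[-m]
  }
  out
}

# FASTQ writer for fixtures
write_fixture_fastq <- function(seqs, path) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0("@r", i), seqs[i], "+",
               strrep("F", nchar(seqs[i])))
  }
  writeLines(lines, path)
  path
}

# Brute-force breakpoint-cluster oracle: compares every pair of suffixes
# directly (no partitioning, no sorting). Returns the accepted clusters as a
# data.frame of (anchor, n_norm, n_mut, q) for direct set comparison with
# the pipeline.
brute_force_clusters <- function(normal_reads, mutated_reads, d,
                                 cmin = 2, cmax = 1000, qmin = 0, qmax = 1,
                                 pnorm_max = 0.05, strand_specific = FALSE) {
  suf <- list()
  add <- function(reads, group) {
    for (i in seq_along(reads)) {
      variants <- list(list(seq = reads[i], strand = "forward"))
      if (!strand_specific) {
        variants <- c(variants, list(list(seq = rc_naive(reads[i]),
                                          strand = "reverse")))
      }
      for (v in variants) {
        L <- nchar(v$seq)
        for (off in 0:(L - d)) {
          if (L - off < d) next
          suf[[length(suf) + 1]] <<- list(
            text = substr(v$seq, off + 1, L), group = group, read = i,
            strand = v$strand, seq = v$seq, off = off)
        }
      }
    }
  }
  add(normal_reads, "normal")
  add(mutated_reads, "mutated")
  anchors <- vapply(suf, function(s) substr(s$text, 1, d), "")
  accepted <- list()
  for (a in unique(anchors)) {
    members <- suf[anchors == a]
    divs <- vapply(members, function(s) substr(s$text, d + 1, d + 1), "")
    groups <- vapply(members, function(s) s$group, "")
    if (length(unique(divs[divs != ""])) < 2) next
    if (!("normal" %in% groups) || !("mutated" %in% groups)) next
    # one vote per (group, read, strand)
    key <- paste(groups, vapply(members, function(s) s$read, 1),
                 vapply(members, function(s) s$strand, ""))
    keep <- !duplicated(key)
    members <- members[keep]; divs <- divs[keep]; groups <- groups[keep]
    n_norm <- sum(groups == "normal"); n_mut <- sum(groups == "mutated")
    nd <- divs[groups == "normal" & divs != ""]
    md <- divs[groups == "mutated" & divs != ""]
    if (length(nd) == 0 || length(md) == 0) next
    tab <- table(nd)
    major <- names(tab)[order(-tab, names(tab))][1]
    q <- sum(md != major) / length(md)
    contamination <- sum(nd != major) / length(nd)
    if (min(n_norm, n_mut) < cmin) next
    if (max(n_norm, n_mut) > cmax) next
    if (q < qmin || q > qmax) next
    if (contamination > pnorm_max) next
    accepted[[length(accepted) + 1]] <-
      data.frame(anchor = a, n_norm = n_norm, n_mut = n_mut, q = q)
  }
  if (length(accepted) == 0) {
    return(data.frame(anchor = character(0), n_norm = integer(0),
                      n_mut = integer(0), q = numeric(0)))
  }
  out <- do.call(rbind, accepted)
  out[order(out$anchor), , drop = FALSE]
}

# Pipeline counterpart used in oracle-equivalence tests: partitions, sorts,
# scans and filters exactly as call_variants does, returning the same shape
# as brute_force_clusters.
pipeline_clusters <- function(normal_reads, mutated_reads, d, k = 1,
                              params = filter_params(cmin = 2, cmax = 1000,
                                                     qmin = 0, qmax = 1),
                              strand_specific = FALSE) {
  db <- read_db(normal_reads, mutated_reads, strand_specific = strand_specific)
  acc <- list()
  for (prefix in list_prefixes(k)) {
    refs <- collect_suffixes(db, prefix, d)
    if (nrow(refs) == 0) next
    cs <- scan_clusters(sort_suffix_refs(refs, db), d, prefix)
    if (nrow(cs$clusters) == 0) next
    cs <- recover_reads(cs, db, d)
    st <- apply_filters(variant_fraction(cs), params)
    st <- st[st$accepted, c("anchor", "n_norm", "n_mut", "q")]
    if (nrow(st) > 0) acc[[length(acc) + 1]] <- st
  }
  if (length(acc) == 0) {
    return(data.frame(anchor = character(0), n_norm = integer(0),
                      n_mut = integer(0), q = numeric(0)))
  }
  out <- as.data.frame(dplyr::bind_rows(acc))
  out[order(out$anchor), , drop = FALSE]
}

# Micro-fixture: reads sampled from a small genome, mutated group carries one
# substitution. Returns list(normal, mutated) character vectors (<= 50 reads).
micro_fixture <- function(genome_len = 60, read_len = 20, n_reads = 20,
                          d = 8) {
  g <- random_dna(genome_len)
  p <- sample(20:(genome_len - 20), 1)
  alt <- sample(setdiff(BASES, substr(g, p, p)), 1)
  gm <- g
  substr(gm, p, p) <- alt
  draw <- function(hap) {
    starts <- sample(genome_len - read_len + 1, n_reads, replace = TRUE)
    vapply(starts, function(s) substr(hap, s, s + read_len - 1), "")
  }
  list(normal = draw(g), mutated = draw(gm))
}

# Apply decomposed complex components back onto the normal consensus tail;
# used for the decomposition round-trip check.
apply_components <- function(Nc, b, comps) {
  s <- substr(Nc, b + 1, nchar(Nc))
  comps <- comps[order(comps$col, decreasing = TRUE), ]
  for (i in seq_len(nrow(comps))) {
    at <- comps$col[i] - b   # 0-based within s
    if (comps$vtype[i] == "SNV") {
      substr(s, at + 1, at + 1) <- comps$mutated_allele[i]
    } else if (comps$vtype[i] == "deletion") {
      s <- paste0(substr(s, 1, at), substr(s, at + comps$length[i] + 1, nchar(s)))
    } else if (comps$vtype[i] == "insertion") {
      s <- paste0(substr(s, 1, at), comps$mutated_allele[i],
                  substr(s, at + 1, nchar(s)))
    }
  }
  s
}

# Deterministically construct a four-locus genome with clean (unshiftable)
# junctions: one SNV, one 3 bp deletion, one 4 bp insertion, one 8 bp
# inversion, all far apart. Returns list(reference, mutated, truth).
four_locus_fixture <- function(seed = 42) {
  set.seed(seed)
  ref <- random_dna(4000)
  fix_at <- function(ref, pos, s) {
    paste0(substr(ref, 1, pos - 1), s, substr(ref, pos + nchar(s), nchar(ref)))
  }
  # SNV at 600
  snv_pos <- 600
  snv_ref <- substr(ref, snv_pos, snv_pos)
  snv_alt <- setdiff(BASES, snv_ref)[1]
  # deletion of 3 at 1400: make the deleted seq and flanks unambiguous
  del_pos <- 1400
  ref <- fix_at(ref, del_pos - 1, "G")       # base before
  ref <- fix_at(ref, del_pos, "ACT")         # deleted segment
  ref <- fix_at(ref, del_pos + 3, "G")       # first base after != A and != T
  # insertion of 4 before 2200
  ins_pos <- 2200
  ins_seq <- "TCCA"
  ref <- fix_at(ref, ins_pos - 1, "G")       # base before != A (ins end)
  ref <- fix_at(ref, ins_pos, "G")           # base after != T (ins start)
  # inversion of 8 at 3000: segment with seg[1] != comp(seg[8]),
  # seg[8] != comp(seg[1])
  inv_pos <- 3000
  inv_seq <- "ACGTACCG"
  ref <- fix_at(ref, inv_pos, inv_seq)
  truth <- tibble::tibble(
    vtype = c("SNV", "deletion", "insertion", "inversion"),
    contig = "ref",
    pos = c(snv_pos, del_pos, ins_pos, inv_pos),
    normal_allele = c(snv_ref, "ACT", "", inv_seq),
    mutated_allele = c(snv_alt, "", ins_seq, rc_naive(inv_seq)),
    length = c(1L, 3L, 4L, 8L),
    spacing = NA_integer_)
  list(reference = ref, mutated = apply_truth_table(ref, truth),
       truth = truth)
}
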