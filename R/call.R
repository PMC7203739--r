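#' Merge strand-mirrored breakpoint clusters
#'
#' In non-strand-specific mode the same breakpoint is typically detected
#' twice, once per strand orientation. Two calls are recognised as mirrors
#' when a length-`L` window containing the breakpoint of one call's normal
#' consensus reverse-complements into such a window of the other's, and
#' likewise for the mutated consensus. Mirrored calls are merged into a
#' single forward-orientation call: support counts are summed, the
#' orientation is canonicalised to the cluster with the lexicographically
#' smaller anchor (or to the typed side when only one side was typed), and a
#' pair that is unassigned on both sides is stitched and re-typed with
#' [reinfer_unassigned()].
#'
#' @param records List of internal call records (as built by
#'   [call_variants()]); each carries `anchor`, `vc` (a `variant_call`),
#'   `n_norm`, `n_mut`, `q`.
#' @param L Window length for the mirror test (default 15).
#' @param m,max_edit_runs Passed on to re-typing.
#' @param strand_specific If `TRUE` the operation is the identity.
#' @return The merged list of records.
#' @export
merge_reverse_complement_clusters <- function(records, L = 15L, m = 10L,
                                              max_edit_runs = 5L,
                                              strand_specific = FALSE) {
  n <- length(records)
  if (strand_specific || n < 2L) return(records)
  sets <- lapply(records, function(r) rc_merge_sets(r$vc$consensus, L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (length(intersect(sets[[i]]$S, sets[[j]]$S_bar)) > 0L &&
          length(intersect(sets[[i]]$S_prime, sets[[j]]$S_prime_bar)) > 0L) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (g in unique(root)) {
    grp <- records[root == g]
    merged <- grp[[1L]]
    if (length(grp) > 1L) {
      for (other in grp[-1L]) merged <- merge_mirror_pair(merged, other, m, max_edit_runs, L)
    }
    out[[length(out) + 1L]] <- merged
  }
  out
}

merge_mirror_pair <- function(a, b, m, max_edit_runs, L) {
  canon_first <- a$anchor <= b$anchor
  primary <- if (canon_first) a else b
  other <- if (canon_first) b else a
  ta <- primary$vc$vtype != "unassigned"
  tb <- other$vc$vtype != "unassigned"
  vc <- if (ta) {
    primary$vc
  } else if (tb) {
    primary <- other
    other$vc
  } else {
    reinfer_unassigned(primary$vc$consensus, other$vc$consensus,
                       m = m, max_edit_runs = max_edit_runs, min_overlap = L)
  }
  n_mut <- a$n_mut + b$n_mut
  list(cluster_id = min(a$cluster_id, b$cluster_id),
       anchor = primary$anchor, vc = vc,
       n_norm = a$n_norm + b$n_norm, n_mut = n_mut,
       q = (a$q * a$n_mut + b$q * b$n_mut) / n_mut,
       merged_from = a$merged_from + b$merged_from)
}

#' Call variants by direct read comparison
#'
#' The full reference-free pipeline: load (or accept preloaded) normal and
#' mutated read stores, enumerate all read suffixes of length at least `d`
#' on both strands, process the `4^k` prefix partitions sequentially --
#' sorting each batch lexicographically, scanning it for breakpoint clusters
#' (shared d-mer anchor, divergent column d+1, both groups present),
#' recovering member reads and applying the support/variant-fraction filters
#' -- then build per-cluster consensus pairs, type each breakpoint (indel,
#' SNV, inversion, complex, in that order), merge strand-mirrored clusters
#' and re-type breakpoints that were unassigned on both strands.
#' Decomposed complex breakpoints are registered as individual variants.
#' Each partition's suffix batch is released before the next is built, so
#' peak memory is bounded by one partition.
#'
#' @param normal,mutated FASTQ path(s) (length 1 or 2) or
#'   `packed_read_store` objects.
#' @param d Anchor / minimum suffix length (default 30).
#' @param k Partition prefix length (default 3; any value gives the same
#'   calls).
#' @param params Cluster filters from [filter_params()].
#' @param strand_specific If `TRUE`, skip reverse-complement processing.
#' @param m Match-confirmation length for typing (default 10).
#' @param L Window/overlap length for strand merging (default 15).
#' @param max_edit_runs Complex decomposition limit (default 5).
#' @param verbose Log per-partition progress and keep a reject audit table.
#' @return A `variant_calls` object: `calls` (tibble, one row per reported
#'   variant), `params`, and `stats` (reads loaded/dropped, clusters
#'   registered/accepted, reject reasons, consensus failures).
#' @examples
#' \dontrun{
#' res <- call_variants("normal_1.fq", "mutated_1.fq",
#'                      params = filter_params(mode = "pure"))
#' tidy(res)
#' }
#' @export
call_variants <- function(normal, mutated, d = 30L, k = 3L,
                          params = filter_params(),
                          strand_specific = FALSE, m = 10L, L = 15L,
                          max_edit_runs = 5L, verbose = FALSE) {
  d <- as.integer(d); k <- as.integer(k)
  if (d < k) abort("`d` must be >= `k`", class = "directvc_usage_error")
  if (d < 1L) abort("`d` must be >= 1", class = "directvc_usage_error")
  stopifnot(inherits(params, "filter_params"))

  as_store <- function(x, label) {
    if (inherits(x, "packed_read_store")) return(x)
    load_reads(x, label, min_length = d + 1L)
  }
  ns <- as_store(normal, "normal")
  ms <- as_store(mutated, "mutated")
  if (ns$n_reads == 0L) abort("no usable normal reads", class = "directvc_usage_error")
  if (ms$n_reads == 0L) abort("no usable mutated reads", class = "directvc_usage_error")

  db <- read_db(ns, ms, strand_specific = strand_specific)
  suf <- enumerate_suffixes(db, d)
  prefixes <- list_prefixes(k)
  if (k > 0L) {
    key <- substring(db$seq[suf$src], suf$offset + 1L, suf$offset + k)
    parts <- split(seq_along(suf$src), key)
  } else {
    parts <- list(seq_along(suf$src))
    names(parts) <- ""
  }

  accepted_members <- list()
  n_registered <- 0L
  n_accepted <- 0L
  reject_reasons <- c(too_few_reads = 0L, too_many_reads = 0L,
                      q_out_of_range = 0L, normal_contaminated = 0L)
  audit <- if (verbose) list() else NULL

  for (prefix in prefixes) {
    idx <- if (k == 0L) parts[[1L]] else parts[[prefix]]
    if (is.null(idx) || length(idx) == 0L) next
    refs <- suffix_ref_tibble(db, suf$src[idx], suf$offset[idx])
    sorted <- sort_suffix_refs(refs, db)
    cs <- scan_clusters(sorted, d, partition_prefix = prefix)
    rm(refs, sorted)
    n_registered <- n_registered + nrow(cs$clusters)
    if (nrow(cs$clusters) > 0L) {
      cs <- recover_reads(cs, db, d)
      stats <- apply_filters(variant_fraction(cs), params)
      rej <- table(stats$reason[!stats$accepted])
      reject_reasons[names(rej)] <- reject_reasons[names(rej)] + as.integer(rej)
      if (verbose) {
        audit[[length(audit) + 1L]] <-
          dplyr::select(stats, "anchor", "n_norm", "n_mut", "q", "reason")
      }
      acc <- stats$cluster_id[stats$accepted]
      n_accepted <- n_accepted + length(acc)
      if (length(acc) > 0L) {
        accepted_members[[length(accepted_members) + 1L]] <-
          cs$members[cs$members$cluster_id %in% acc, ]
      }
    }
    if (verbose) {
      message(sprintf("partition %-3s: %7d suffixes, %5d clusters, %3d accepted",
                      ifelse(prefix == "", "-", prefix), length(idx),
                      nrow(cs$clusters),
                      if (nrow(cs$clusters)) sum(stats$accepted) else 0L))
    }
    rm(cs)
  }
  rm(suf, parts)

  records <- list()
  n_consensus_failed <- 0L
  if (length(accepted_members) > 0L) {
    all_m <- dplyr::bind_rows(accepted_members)
    # re-key (anchors are unique across partitions, but renumber densely)
    cs <- structure(list(members = all_m, clusters = NULL), class = "cluster_set")
    cs <- merge_identical_breakpoints(cs)
    stats <- variant_fraction(cs)
    by_cluster <- split(cs$members, cs$members$cluster_id)
    for (cid in stats$cluster_id) {
      mem <- by_cluster[[as.character(cid)]]
      st <- stats[stats$cluster_id == cid, ]
      pair <- build_consensus(mem, d, norm_major = st$norm_major)
      if (is.null(pair)) { n_consensus_failed <- n_consensus_failed + 1L; next }
      vc <- classify_variant(pair, m = m, max_edit_runs = max_edit_runs)
      records[[length(records) + 1L]] <-
        list(cluster_id = cid, anchor = st$anchor, vc = vc,
             n_norm = st$n_norm, n_mut = st$n_mut, q = st$q, merged_from = 1L)
    }
  }

  records <- merge_reverse_complement_clusters(
    records, L = L, m = m, max_edit_runs = max_edit_runs,
    strand_specific = strand_specific)
  # deterministic output order and IDs, independent of k
  if (length(records) > 0L) {
    ord <- order(vapply(records, `[[`, character(1), "anchor"), method = "radix")
    records <- records[ord]
    for (i in seq_along(records)) records[[i]]$cluster_id <- i
  }

  calls <- records_to_calls(records)
  structure(list(
    calls = calls,
    params = list(d = d, k = k, cmin = params$cmin, cmax = params$cmax,
                  qmin = params$qmin, qmax = params$qmax,
                  pnorm_max = params$pnorm_max,
                  strand_specific = strand_specific, m = m, L = L,
                  max_edit_runs = max_edit_runs),
    stats = list(n_reads_normal = ns$n_reads, n_reads_mutated = ms$n_reads,
                 n_dropped_normal = ns$n_dropped, n_dropped_mutated = ms$n_dropped,
                 clusters_registered = n_registered,
                 clusters_accepted = n_accepted,
                 reject_reasons = reject_reasons,
                 consensus_failures = n_consensus_failed),
    audit = if (verbose && length(audit)) dplyr::bind_rows(audit) else NULL),
    class = "variant_calls")
}

# Flatten call records to the report tibble; decomposed complexes become
# individual variant rows.
records_to_calls <- function(records) {
  rows <- list()
  for (r in records) {
    vc <- r$vc
    base <- tibble(cluster_id = r$cluster_id, anchor = r$anchor,
                   n_norm = r$n_norm, n_mut = r$n_mut, q = r$q,
                   normal_consensus = vc$consensus$normal,
                   mutated_consensus = vc$consensus$mutated,
                   merged_from = r$merged_from)
    if (vc$vtype == "complex" && !is.null(vc$components) &&
        nrow(vc$components) > 0L) {
      comp <- vc$components
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(vtype = comp$vtype, normal_allele = comp$normal_allele,
               mutated_allele = comp$mutated_allele, length = comp$length,
               breakpoint_col = comp$col),
        base[rep(1L, nrow(comp)), ])
    } else {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(vtype = vc$vtype, normal_allele = vc$normal_allele,
               mutated_allele = vc$mutated_allele, length = vc$length,
               breakpoint_col = vc$breakpoint_col),
        base)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(vtype = character(0), normal_allele = character(0),
                  mutated_allele = character(0), length = integer(0),
                  breakpoint_col = integer(0), cluster_id = integer(0),
                  anchor = character(0), n_norm = integer(0),
                  n_mut = integer(0), q = numeric(0),
                  normal_consensus = character(0),
                  mutated_consensus = character(0), merged_from = integer(0)))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("<variant_calls: %d variants from %d clusters (%d registered)>\n",
              nrow(x$calls), length(unique(x$calls$cluster_id)),
              x$stats$clusters_registered))
  print(dplyr::count(x$calls, .data$vtype))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variant call set
#'
#' @param x A `variant_calls` object.
#' @param ... Unused.
#' @return The calls tibble, one row per reported variant.
#' @method tidy variant_calls
#' @export
tidy.variant_calls <- function(x, ...) x$calls

#' One-row summary of a variant call set
#'
#' @param x A `variant_calls` object.
#' @param ... Unused.
#' @return One-row tibble: reads per group, clusters registered/accepted,
#'   variants by headline class.
#' @method glance variant_calls
#' @export
glance.variant_calls <- function(x, ...) {
  tibble(n_reads_normal = x$stats$n_reads_normal,
         n_reads_mutated = x$stats$n_reads_mutated,
         clusters_registered = x$stats$clusters_registered,
         n_calls = nrow(x$calls),
         n_snv = sum(x$calls$vtype == "SNV"),
         n_indel = sum(x$calls$vtype %in% c("insertion", "deletion")),
         n_inversion = sum(x$calls$vtype == "inversion"),
         n_unassigned = sum(x$calls$vtype == "unassigned"))
}

#' Plot the composition of a variant call set
#'
#' Bar chart of call counts per variant type, filled by support (the variant
#' fraction q).
#'
#' @param object A `variant_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variant_calls
#' @export
autoplot.variant_calls <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$vtype, fill = cut(.data$q, c(0, .5, .9, 1)))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "variant type", y = "calls", fill = "variant fraction q") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
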