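#' Filtering parameters for breakpoint clusters
#'
#' Bundles the read-support and variant-fraction cutoffs applied to every
#' registered breakpoint cluster. `cmin`/`cmax` bound the number of distinct
#' supporting reads per group; `qmin`/`qmax` bound the variant fraction q in
#' the mutated group; `pnorm_max` bounds the tolerated contamination of the
#' normal group by variant-carrying reads (expected to be very low, <= 5%,
#' in real settings). The `mode` presets mirror the two study settings: a
#' pure (homozygous) mutated sample carries the variant in essentially every
#' read (q in 0.9-1.0), a heterozygous sample in about half (q in 0.35-0.6).
#'
#' @param cmin Minimum reads per group (default 6).
#' @param cmax Maximum reads per group (default 28).
#' @param qmin,qmax Variant-fraction window (defaults 0.9, 1.0).
#' @param pnorm_max Maximum tolerated normal-group contamination (default 0.05).
#' @param mode Optional preset `"pure"` (0.9-1.0) or `"het"` (0.35-0.6);
#'   overrides `qmin`/`qmax`.
#' @return A `filter_params` list.
#' @export
filter_params <- function(cmin = 6L, cmax = 28L, qmin = 0.9, qmax = 1.0,
                          pnorm_max = 0.05, mode = NULL) {
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("pure", "het"))
    if (mode == "pure") { qmin <- 0.9; qmax <- 1.0 } else { qmin <- 0.35; qmax <- 0.6 }
  }
  if (!(cmin >= 1 && cmin <= cmax)) {
    abort("need 1 <= cmin <= cmax", class = "directvc_domain_error")
  }
  if (!(qmin >= 0 && qmin <= qmax && qmax <= 1)) {
    abort("need 0 <= qmin <= qmax <= 1", class = "directvc_domain_error")
  }
  structure(list(cmin = as.integer(cmin), cmax = as.integer(cmax),
                 qmin = qmin, qmax = qmax, pnorm_max = pnorm_max),
            class = "filter_params")
}

#' Scan a sorted suffix batch for breakpoint clusters
#'
#' One linear pass over the sorted batch. A maximal run of consecutive
#' suffixes sharing their first `d` bases (the anchor) is registered as a
#' potential breakpoint cluster when (a) at least two distinct bases occur at
#' column `d + 1` among members long enough to have one, and (b) both sample
#' groups are represented. Divergence is required at exactly column `d + 1`:
#' a later divergence re-appears at column `d + 1` of the cluster anchored
#' further downstream, so this rule avoids duplicate registration.
#'
#' @param sorted_refs Output of [sort_suffix_refs()] (must carry `text`).
#' @param d Anchor length / minimum suffix length.
#' @param partition_prefix The k-mer that produced the batch (metadata).
#' @return A `cluster_set`: list with `members` (tibble: `cluster_id`,
#'   `anchor`, `src`, `read_id`, `offset`, `group`, `strand`,
#'   `suffix_length`, `div_base` -- `""` for length-d members) and `clusters`
#'   (tibble: `cluster_id`, `anchor`, `partition_prefix`, `n_members`).
#' @export
scan_clusters <- function(sorted_refs, d, partition_prefix = "") {
  empty <- list(
    members = tibble(cluster_id = integer(0), anchor = character(0),
                     src = integer(0), read_id = integer(0),
                     offset = integer(0), group = character(0),
                     strand = character(0), suffix_length = integer(0),
                     div_base = character(0)),
    clusters = tibble(cluster_id = integer(0), anchor = character(0),
                      partition_prefix = character(0), n_members = integer(0)))
  class(empty) <- "cluster_set"
  if (nrow(sorted_refs) == 0L) return(empty)
  stopifnot(!is.null(sorted_refs$text))
  anchor <- substr(sorted_refs$text, 1L, d)
  run_id <- cumsum(anchor != dplyr::lag(anchor, default = ""))
  div <- substr(sorted_refs$text, d + 1L, d + 1L)
  grp_norm <- sorted_refs$group == "normal"
  # per-run registration conditions, vectorised
  reg <- vapply(split(seq_along(run_id), run_id), function(ii) {
    dv <- div[ii]
    dv <- dv[dv != ""]
    length(unique(dv)) >= 2L && any(grp_norm[ii]) && !all(grp_norm[ii])
  }, logical(1))
  keep_runs <- as.integer(names(reg))[reg]
  if (length(keep_runs) == 0L) return(empty)
  keep <- run_id %in% keep_runs
  cluster_id <- match(run_id[keep], keep_runs)
  members <- tibble(cluster_id = cluster_id,
                    anchor = anchor[keep],
                    src = sorted_refs$src[keep],
                    read_id = sorted_refs$read_id[keep],
                    offset = sorted_refs$offset[keep],
                    group = sorted_refs$group[keep],
                    strand = sorted_refs$strand[keep],
                    suffix_length = sorted_refs$suffix_length[keep],
                    div_base = div[keep])
  clusters <- members |>
    dplyr::group_by(.data$cluster_id, .data$anchor) |>
    dplyr::summarise(n_members = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(partition_prefix = partition_prefix, .before = "n_members")
  structure(list(members = members, clusters = clusters), class = "cluster_set")
}

#' Recover the member reads of each cluster
#'
#' Attaches to every member its full oriented read (already
#' reverse-complemented for `strand = "reverse"` members) and the 0-based
#' in-read column of the divergence base, `offset + d`. A read contributing
#' several qualifying suffix offsets on the same strand is collapsed to one
#' member (one vote per read per strand), keeping the smallest offset.
#'
#' @param cs A `cluster_set` from [scan_clusters()].
#' @param db The oriented read table.
#' @param d Anchor length.
#' @return The `cluster_set` with `members` gaining `read_seq` and `bp_col`,
#'   deduplicated per (cluster, group, read, strand).
#' @export
recover_reads <- function(cs, db, d) {
  m <- cs$members
  if (nrow(m) > 0L && any(m$src < 1L | m$src > nrow(db))) {
    abort("dangling read reference", class = "directvc_internal_error")
  }
  m <- m |>
    dplyr::arrange(.data$cluster_id, .data$group, .data$read_id,
                   .data$strand, .data$offset) |>
    dplyr::distinct(.data$cluster_id, .data$group, .data$read_id,
                    .data$strand, .keep_all = TRUE)
  m$read_seq <- db$seq[m$src]
  m$bp_col <- m$offset + as.integer(d)
  cs$members <- m
  cs$clusters$n_members <- NULL
  cs$clusters <- dplyr::left_join(
    cs$clusters,
    dplyr::count(m, .data$cluster_id, name = "n_members"),
    by = "cluster_id")
  cs
}

#' Per-cluster support counts and variant fraction
#'
#' For each cluster: the distinct-read support per group, the normal group's
#' majority base at the divergence column, the variant fraction
#' `q` = (mutated reads whose divergence-column base differs from the normal
#' majority) / (mutated reads covering that column), and the analogous
#' contamination fraction of the normal group. Members whose suffix is
#' exactly `d` long have no base at the divergence column and do not enter
#' the fractions.
#'
#' @param cs A recovered `cluster_set` (see [recover_reads()]).
#' @return The `clusters` tibble extended with `n_norm`, `n_mut`,
#'   `norm_major`, `q`, `contamination`.
#' @export
variant_fraction <- function(cs) {
  m <- cs$members
  if (nrow(m) == 0L) {
    return(dplyr::mutate(cs$clusters, n_norm = integer(0), n_mut = integer(0),
                         norm_major = character(0), q = numeric(0),
                         contamination = numeric(0)))
  }
  counts <- m |>
    dplyr::count(.data$cluster_id, .data$group, name = "n_reads") |>
    tidyr::pivot_wider(names_from = "group", values_from = "n_reads",
                       values_fill = 0L) |>
    dplyr::rename(n_norm = "normal", n_mut = "mutated")
  cov <- dplyr::filter(m, .data$div_base != "")
  major <- cov |>
    dplyr::filter(.data$group == "normal") |>
    dplyr::count(.data$cluster_id, .data$div_base) |>
    dplyr::arrange(.data$cluster_id, dplyr::desc(.data$n), .data$div_base) |>
    dplyr::distinct(.data$cluster_id, .keep_all = TRUE) |>
    dplyr::select("cluster_id", norm_major = "div_base")
  fr <- cov |>
    dplyr::left_join(major, by = "cluster_id") |>
    dplyr::group_by(.data$cluster_id, .data$group) |>
    dplyr::summarise(frac = mean(.data$div_base != .data$norm_major),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "frac")
  if (!"mutated" %in% names(fr)) fr$mutated <- NA_real_
  if (!"normal" %in% names(fr)) fr$normal <- NA_real_
  fr <- dplyr::select(fr, "cluster_id", q = "mutated", contamination = "normal")
  cs$clusters |>
    dplyr::left_join(counts, by = "cluster_id") |>
    dplyr::left_join(major, by = "cluster_id") |>
    dplyr::left_join(fr, by = "cluster_id") |>
    dplyr::mutate(contamination = dplyr::coalesce(.data$contamination, 0))
}

#' Apply the cluster quality filters
#'
#' Verdict per cluster, testing in fixed order and reporting the first
#' failure: `too_few_reads` (min support < cmin), `too_many_reads`
#' (max support > cmax), `q_out_of_range` (q outside \[qmin, qmax\] or
#' undefined), `normal_contaminated` (normal contamination > pnorm_max);
#' otherwise `accept`. Raising `cmin` or narrowing the q window can only
#' shrink the accepted set.
#'
#' @param stats Cluster statistics tibble from [variant_fraction()].
#' @param params A [filter_params()] object.
#' @return `stats` with columns `accepted` (logical) and `reason`
#'   (`"accept"` or the first failing rule).
#' @export
apply_filters <- function(stats, params) {
  stopifnot(inherits(params, "filter_params"))
  reason <- dplyr::case_when(
    pmin(stats$n_norm, stats$n_mut) < params$cmin ~ "too_few_reads",
    pmax(stats$n_norm, stats$n_mut) > params$cmax ~ "too_many_reads",
    is.na(stats$q) | stats$q < params$qmin | stats$q > params$qmax ~ "q_out_of_range",
    stats$contamination > params$pnorm_max ~ "normal_contaminated",
    TRUE ~ "accept")
  stats$accepted <- reason == "accept"
  stats$reason <- reason
  stats
}
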