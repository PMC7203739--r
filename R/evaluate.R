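#' Match predicted calls against a truth table
#'
#' Greedy one-to-one matching per variant class. A prediction matches a
#' truth record when the types agree, the positions differ by at most the
#' class tolerance (0 for SNVs, `tol` for indels and inversions -- small
#' position shifts are inherent to breakpoint representation of indels in
#' repetitive context), SNV alleles agree exactly, and indel/inversion
#' lengths agree within `tol_len`. Candidate pairs are taken closest-first
#' with deterministic ties (truth position, then cluster ID). Decomposed
#' complex calls arrive as individual rows and are matched individually;
#' only located predictions can match.
#'
#' @param predictions Located calls tibble (from [locate_calls()]).
#' @param truth Truth tibble (from [implant_variants()]).
#' @param tol Position tolerance for indels/inversions (default 5).
#' @param tol_snv Position tolerance for SNVs (default 0).
#' @param tol_len Length tolerance for indels/inversions (default 5).
#' @return List: `pairs` (tibble `pred_row`, `truth_row`, `vtype`, `dpos`),
#'   `n_pred` (located predictions per class), `n_truth`, plus the
#'   tolerances used.
#' @export
match_calls <- function(predictions, truth, tol = 5L, tol_snv = 0L,
                        tol_len = 5L) {
  preds <- predictions
  preds$pred_row <- seq_len(nrow(preds))
  if (!"status" %in% names(preds)) preds$status <- "located"
  preds <- preds[preds$status == "located" & !is.na(preds$pos), ]
  truth$truth_row <- seq_len(nrow(truth))
  pairs <- list()
  for (cls in intersect(unique(truth$vtype), unique(preds$vtype))) {
    p <- preds[preds$vtype == cls, ]
    t <- truth[truth$vtype == cls, ]
    if (nrow(p) == 0L || nrow(t) == 0L) next
    ptol <- if (cls == "SNV") tol_snv else tol
    cand <- tidyr::expand_grid(i = seq_len(nrow(p)), j = seq_len(nrow(t)))
    cand$dpos <- abs(p$pos[cand$i] - t$pos[cand$j])
    ok <- cand$dpos <= ptol
    if (cls == "SNV") {
      ok <- ok & p$normal_allele[cand$i] == t$normal_allele[cand$j] &
        p$mutated_allele[cand$i] == t$mutated_allele[cand$j]
    } else {
      ok <- ok & abs(p$length[cand$i] - t$length[cand$j]) <= tol_len
    }
    cand <- cand[ok, ]
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand$dpos, t$pos[cand$j], p$cluster_id[cand$i]), ]
    used_p <- logical(nrow(p)); used_t <- logical(nrow(t))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble(
        pred_row = p$pred_row[i], truth_row = t$truth_row[j],
        vtype = cls, dpos = cand$dpos[r])
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble(pred_row = integer(0), truth_row = integer(0),
           vtype = character(0), dpos = integer(0))
  list(pairs = pairs,
       predictions = preds,
       truth = truth,
       tol = tol, tol_snv = tol_snv, tol_len = tol_len)
}

#' Compute sensitivity, PPV and F-measure from a matching
#'
#' Per variant class, for the combined indel class (insertions + deletions)
#' and overall: TP (matched pairs), FP (unmatched predictions), FN
#' (unmatched truth records); sensitivity = TP/(TP+FN),
#' PPV = TP/(TP+FP), F = their harmonic mean. When a class has no
#' predictions PPV is reported as 0 with `ppv_undefined = TRUE`.
#'
#' @param matching Output of [match_calls()].
#' @return A `variant_eval` object; its `metrics` tibble has one row per
#'   class plus `indel` and `overall`.
#' @export
compute_metrics <- function(matching) {
  preds <- matching$predictions
  truth <- matching$truth
  pairs <- matching$pairs
  one <- function(name, pred_sel, truth_sel) {
    tp <- sum(pairs$pred_row %in% preds$pred_row[pred_sel])
    fp <- sum(pred_sel) - tp
    fn <- sum(truth_sel) - sum(pairs$truth_row %in% truth$truth_row[truth_sel])
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    undef <- tp + fp == 0
    ppv <- if (undef) 0 else tp / (tp + fp)
    f <- if (!is.na(sens) && sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
    tibble(class = name, TP = tp, FP = fp, FN = fn,
           sensitivity = sens, ppv = ppv, f_measure = f,
           ppv_undefined = undef)
  }
  classes <- sort(unique(c(truth$vtype, preds$vtype)))
  metrics <- dplyr::bind_rows(
    lapply(classes, function(cl) one(cl, preds$vtype == cl, truth$vtype == cl)),
    one("indel", preds$vtype %in% c("insertion", "deletion"),
        truth$vtype %in% c("insertion", "deletion")),
    one("overall", rep(TRUE, nrow(preds)), rep(TRUE, nrow(truth))))
  structure(list(metrics = metrics, pairs = pairs,
                 n_pred = nrow(preds), n_truth = nrow(truth),
                 tol = matching$tol, tol_snv = matching$tol_snv,
                 tol_len = matching$tol_len),
            class = "variant_eval")
}

#' Evaluate located calls against a truth table
#'
#' Convenience wrapper: [match_calls()] then [compute_metrics()].
#'
#' @inheritParams match_calls
#' @return A `variant_eval` object.
#' @export
evaluate_calls <- function(predictions, truth, tol = 5L, tol_snv = 0L,
                           tol_len = 5L) {
  compute_metrics(match_calls(predictions, truth, tol = tol,
                              tol_snv = tol_snv, tol_len = tol_len))
}

#' @export
print.variant_eval <- function(x, ...) {
  cat(sprintf("<variant_eval: %d predictions vs %d truth records>\n",
              x$n_pred, x$n_truth))
  print(as.data.frame(x$metrics))
  invisible(x)
}

#' @rdname evaluate_calls
#' @param x A `variant_eval` object.
#' @param ... Unused.
#' @method tidy variant_eval
#' @export
tidy.variant_eval <- function(x, ...) x$metrics

#' @rdname evaluate_calls
#' @method glance variant_eval
#' @export
glance.variant_eval <- function(x, ...) {
  ov <- x$metrics[x$metrics$class == "overall", ]
  tibble(TP = ov$TP, FP = ov$FP, FN = ov$FN,
         sensitivity = ov$sensitivity, ppv = ov$ppv,
         f_measure = ov$f_measure, n_pred = x$n_pred, n_truth = x$n_truth)
}

#' Plot per-class predictive performance
#'
#' @param object A `variant_eval` object.
#' @param ... Unused.
#' @return A ggplot object: sensitivity, PPV and F-measure per class.
#' @method autoplot variant_eval
#' @export
autoplot.variant_eval <- function(object, ...) {
  object$metrics |>
    dplyr::select("class", "sensitivity", "ppv", "f_measure") |>
    tidyr::pivot_longer(-"class", names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$class, y = .data$value,
                                 fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
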