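# Per-caller error-profile estimation from a verification selection.
# Verification outcomes are taken as ground truth. Counts are defined over
# the selected variants only:
#   TP — selected, called by the caller, true
#   FP — selected, called by the caller, false
#   FN — selected, true, but NOT called by the caller (another caller made it)
# Selected false variants the caller did not call contribute nothing.

#' Confusion counts for one caller over a selection
#'
#' @param profile a `call_profile`.
#' @param selection a `selection` over `profile`.
#' @param truth a `truth_table` labelling every selected variant.
#' @param caller caller identifier.
#' @return Named integer vector `c(TP, FP, FN)`.
#' @export
confusion_counts <- function(profile, selection, truth, caller) {
  keys <- selection_keys(selection)
  called <- keys %in% caller_calls(profile, caller)
  tr <- truth_lookup(truth, keys)
  c(TP = sum(called & tr), FP = sum(called & !tr), FN = sum(!called & tr))
}

#' Precision, recall and F1 from confusion counts
#'
#' precision = TP / (TP + FP); recall = TP / (TP + FN);
#' F1 = 2 * precision * recall / (precision + recall).
#'
#' A score whose denominator is empty is undefined (`NA`): precision when no
#' selected call was made by the caller, recall when the selection holds no
#' true variant relevant to the caller; F1 is `NA` whenever either factor
#' is. When precision and recall are both defined and both zero, F1 is 0.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return List with `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(8, 2, 0)
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  list(precision = precision, recall = recall,
       f1 = f1_score(precision, recall))
}

f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Overlap-level groups of a caller's selected calls
#'
#' Supports the weighted precision mode: the caller's selected calls are
#' grouped by overlap level (how many callers made the call), each group's
#' precision is computed from the selected calls in it, and the group weight
#' is the caller's *total* call count — verified and unverified — at that
#' level. Levels at which the caller has calls but none were selected carry
#' no defined group precision and are excluded.
#'
#' @inheritParams confusion_counts
#' @return data.frame with one row per overlap level holding at least one
#'   selected call by the caller: `level`, `weight`, `n_selected`, `TP`,
#'   `FP`, `precision`.
#' @export
overlap_group_weights <- function(profile, selection, truth, caller) {
  all_keys <- caller_calls(profile, caller)
  sel <- intersect(selection_keys(selection), all_keys)
  full_counts <- table(profile$level[all_keys])
  if (length(sel) == 0L) {
    return(data.frame(level = integer(), weight = integer(),
                      n_selected = integer(), TP = integer(), FP = integer(),
                      precision = numeric()))
  }
  lv <- profile$level[sel]
  tr <- truth_lookup(truth, sel)
  levels_used <- sort(unique(lv))
  tp <- vapply(levels_used, function(g) sum(tr[lv == g]), 0L)
  n_sel <- vapply(levels_used, function(g) sum(lv == g), 0L)
  data.frame(
    level = as.integer(levels_used),
    weight = as.integer(full_counts[as.character(levels_used)]),
    n_selected = as.integer(n_sel),
    TP = as.integer(tp),
    FP = as.integer(n_sel - tp),
    precision = tp / n_sel
  )
}

#' Overlap-weighted precision for one caller
#'
#' The weighted average of the per-overlap-level group precisions (see
#' [overlap_group_weights()]), weighted by the caller's total call count at
#' each level. Unique calls thereby count in proportion to how much of the
#' caller's output they represent, rather than how often the selection
#' happened to sample them — removing the composition bias that
#' overlap-level-skewed strategies induce in the default precision.
#'
#' @inheritParams confusion_counts
#' @return Weighted precision in `[0, 1]`, or `NA` if the selection contains
#'   no call by this caller.
#' @export
weighted_precision <- function(profile, selection, truth, caller) {
  g <- overlap_group_weights(profile, selection, truth, caller)
  if (nrow(g) == 0L) return(NA_real_)
  sum(g$weight * g$precision) / sum(g$weight)
}

#' Estimate per-caller metrics from a selection
#'
#' One record per caller in the profile. In `"weighted"` mode the precision
#' is the overlap-weighted precision and recall is unchanged; F1 combines
#' the mode's precision with the recall.
#'
#' @inheritParams confusion_counts
#' @param mode `"default"` or `"weighted"`.
#' @return data.frame with columns `caller`, `mode`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`, `F1` (undefined scores as `NA`).
#' @export
evaluate_callers <- function(profile, selection, truth, mode = "default") {
  mode <- match.arg(mode, c("default", "weighted"))
  rows <- lapply(profile$callers, function(cl) {
    cc <- confusion_counts(profile, selection, truth, cl)
    m <- precision_recall_f1(cc[["TP"]], cc[["FP"]], cc[["FN"]])
    if (mode == "weighted") {
      m$precision <- weighted_precision(profile, selection, truth, cl)
      m$f1 <- f1_score(m$precision, m$recall)
    }
    data.frame(caller = cl, mode = mode,
               TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
               precision = m$precision, recall = m$recall, F1 = m$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full-prediction-set metrics
#'
#' The reference scores a subset selection is judged against. Under the
#' `"union"` baseline every variant in the call union counts as selected, so
#' subset metrics converge exactly to these scores as the budget approaches
#' the union size. Under the `"all-mutations"` baseline (the default), FN
#' additionally counts true mutations that no caller predicted, giving each
#' caller its recall against the complete mutation set; this requires
#' `truth` to list every true mutation.
#'
#' @param profile a `call_profile`.
#' @param truth a `truth_table` covering all profile variants (and, for
#'   `"all-mutations"`, every true mutation).
#' @param baseline `"all-mutations"` or `"union"`.
#' @return data.frame as [evaluate_callers()], plus a `baseline` column.
#' @export
full_set_metrics <- function(profile, truth, baseline = "all-mutations") {
  baseline <- match.arg(baseline, c("all-mutations", "union"))
  full_sel <- selection_from_keys(profile, profile$variants$key,
                                  strategy = "full_set")
  out <- evaluate_callers(profile, full_sel, truth, mode = "default")
  if (baseline == "all-mutations") {
    missed <- sum(truth$labels) - sum(truth_lookup(truth, profile$variants$key))
    if (missed > 0L) {
      out$FN <- out$FN + missed
      for (i in seq_len(nrow(out))) {
        m <- precision_recall_f1(out$TP[i], out$FP[i], out$FN[i])
        out$recall[i] <- m$recall
        out$F1[i] <- m$f1
      }
    }
  }
  out$baseline <- baseline
  out
}

#' Difference between subset and full-set F1
#'
#' The core accuracy measure for a selection strategy: the caller's F1
#' estimated from the verified subset minus its F1 over the full prediction
#' set. `NA` (missing data) if either score is undefined.
#'
#' @param subset_record,full_record single metrics rows (data.frame or list
#'   with `caller` and `F1`) for the same caller.
#' @return Signed numeric difference, or `NA`.
#' @export
f1_difference <- function(subset_record, full_record) {
  if (!identical(as.character(subset_record$caller),
                 as.character(full_record$caller)))
    stop("records belong to different callers", call. = FALSE)
  s <- subset_record$F1
  f <- full_record$F1
  if (is.na(s) || is.na(f)) NA_real_ else s - f
}
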