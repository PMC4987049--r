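# The evaluation protocol for ranked essential-protein predictions:
# top-k true-essential counts, confusion counts at a top-fraction cutoff,
# the six derived statistics, precision-recall and jackknife curves, and
# pairwise method-difference analysis. All routines take a ranking as
# produced by rank_proteins() (a data frame with a `protein` column) or a
# plain character vector of identifiers in rank order.

as_ordering <- function(pred) {
  if (is.data.frame(pred)) {
    stopifnot("protein" %in% names(pred))
    return(as.character(pred$protein))
  }
  as.character(pred)
}

#' True-essential counts among the top k predictions
#'
#' @param pred A ranking: the data frame from [rank_proteins()] or a
#'   character vector of protein ids in descending-score order.
#' @param essentials Character vector of known-essential identifiers.
#' @param ks Integer ranks at which to count (default the conventional
#'   100, 200, ..., 600).
#' @return Named integer vector, one count per k.
#' @export
top_k_true <- function(pred, essentials, ks = seq(100L, 600L, by = 100L)) {
  ordering <- as_ordering(pred)
  ks <- as.integer(ks)
  if (any(ks < 1L) || any(ks > length(ordering))) {
    stop("top_k_true: every k must be between 1 and the number of ranked ",
         "proteins (", length(ordering), ")", call. = FALSE)
  }
  hit <- cumsum(ordering %in% essentials)
  stats::setNames(as.integer(hit[ks]), ks)
}

#' Confusion counts at a top-fraction cutoff
#'
#' Calls the top `floor(fraction * n)` ranked proteins predicted-essential
#' and the rest predicted-nonessential, then counts TP/FP/TN/FN against the
#' annotation. Proteins without essentiality annotation count as
#' nonessential. The integer cutoff used is returned so that rounding
#' conventions are always visible.
#'
#' @inheritParams top_k_true
#' @param fraction Fraction of the ranking called essential; must be in
#'   (0, 1). Default 0.2, the conventional top-20% cutoff.
#' @return A list of class `confusion_counts` with elements `TP`, `FP`,
#'   `TN`, `FN` and `cutoff`.
#' @export
confusion_at_fraction <- function(pred, essentials, fraction = 0.2) {
  ordering <- as_ordering(pred)
  n <- length(ordering)
  if (n == 0L) stop("confusion_at_fraction: empty ranking", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("confusion_at_fraction: fraction must be in (0, 1)", call. = FALSE)
  }
  k <- floor(fraction * n)
  is_ess <- ordering %in% essentials
  predicted <- seq_len(n) <= k
  out <- list(
    TP = sum(predicted & is_ess),
    FP = sum(predicted & !is_ess),
    TN = sum(!predicted & !is_ess),
    FN = sum(!predicted & is_ess),
    cutoff = k
  )
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts (cutoff k = %d):\n", x$cutoff))
  cat(sprintf("  TP=%d  FP=%d  TN=%d  FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' The six ranking statistics from confusion counts
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, positive
#' and negative predictive values `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
#' the F-measure (harmonic mean of SN and PPV) and accuracy
#' `ACC = (TP+TN)/(P+N)`. Requires at least one essential (`P > 0`) and one
#' nonessential (`N > 0`) protein in the scored set.
#'
#' @param counts A `confusion_counts` object (or a list with TP/FP/TN/FN).
#' @return Named numeric vector `SN, SP, PPV, NPV, F, ACC`, all in `[0,1]`.
#' @export
confusion_statistics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  p <- tp + fn
  n <- tn + fp
  if (p == 0 || n == 0) {
    stop("confusion_statistics: needs both essential (P) and nonessential ",
         "(N) proteins in the scored set", call. = FALSE)
  }
  sn <- tp / p
  sp <- tn / n
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  f <- if (sn + ppv > 0) 2 * sn * ppv / (sn + ppv) else 0
  acc <- (tp + tn) / (p + n)
  c(SN = sn, SP = sp, PPV = ppv, NPV = npv, F = f, ACC = acc)
}

#' Precision-recall curve over the full ranking
#'
#' One row per rank `n`: the cumulative true-positive count `TP(n)`,
#' `precision(n) = TP(n)/n` and `recall(n) = TP(n)/P`, with `P` the number
#' of essentials in the scored set (must be > 0).
#'
#' @inheritParams top_k_true
#' @return Data frame with columns `rank`, `tp`, `precision`, `recall`.
#' @export
pr_curve <- function(pred, essentials) {
  ordering <- as_ordering(pred)
  p <- sum(ordering %in% essentials)
  if (p == 0L) {
    stop("pr_curve: no essential protein in the scored set", call. = FALSE)
  }
  n <- seq_along(ordering)
  tp <- cumsum(ordering %in% essentials)
  data.frame(rank = n, tp = as.integer(tp),
             precision = tp / n, recall = tp / p)
}

#' Jackknife curve: cumulative true essentials by rank
#'
#' The y-axis of the standard jackknife validation plot: for each rank `n`,
#' the number of true essential proteins among the top `n`.
#'
#' @inheritParams top_k_true
#' @return Data frame with columns `rank` and `tp`.
#' @export
jackknife_curve <- function(pred, essentials) {
  ordering <- as_ordering(pred)
  data.frame(rank = seq_along(ordering),
             tp = as.integer(cumsum(ordering %in% essentials)))
}

#' Recall at the precision-recall break-even point
#'
#' The recall value at the largest rank where precision >= recall; reported
#' as a stability summary of a single method's curve.
#'
#' @inheritParams top_k_true
#' @return A single recall value (0 if precision < recall everywhere).
#' @export
break_even_point <- function(pred, essentials) {
  curve <- pr_curve(pred, essentials)
  ok <- which(curve$precision >= curve$recall)
  if (length(ok) == 0L) return(0)
  curve$recall[max(ok)]
}

#' Top-k set differences between two ranking methods
#'
#' Compares the top-`k` sets A and B of two rankings of the same network:
#' the overlap |A ∩ B|, the two difference sets, and how many true
#' essentials each difference set contains.
#'
#' @param pred_a,pred_b Two rankings (see [top_k_true()] for accepted
#'   forms).
#' @inheritParams top_k_true
#' @param k Depth of the compared prediction sets (default 100).
#' @return A list with `k`, `intersection_size`, `a_only_size`,
#'   `b_only_size`, `essential_in_a_only`, `essential_in_b_only`, and the
#'   member vectors `a_top`, `b_top`, `a_only`, `b_only`, `intersection`.
#' @export
method_difference <- function(pred_a, pred_b, essentials, k = 100L) {
  oa <- as_ordering(pred_a)
  ob <- as_ordering(pred_b)
  k <- as.integer(k)
  if (k < 1L || k > length(oa) || k > length(ob)) {
    stop("method_difference: k must be within both ranking lengths",
         call. = FALSE)
  }
  a <- oa[seq_len(k)]
  b <- ob[seq_len(k)]
  both <- intersect(a, b)
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  list(
    k = k,
    intersection_size = length(both),
    a_only_size = length(a_only),
    b_only_size = length(b_only),
    essential_in_a_only = sum(a_only %in% essentials),
    essential_in_b_only = sum(b_only %in% essentials),
    a_top = a, b_top = b,
    a_only = a_only, b_only = b_only, intersection = both
  )
}

#' Full evaluation report for one ranking
#'
#' Bundles the standard protocol: top-k counts, the confusion counts and
#' six statistics at a top-fraction cutoff, and the break-even point.
#'
#' @inheritParams top_k_true
#' @param ks Ranks for [top_k_true()]; ranks beyond the list length are
#'   dropped with a message.
#' @param fraction Cutoff for [confusion_at_fraction()].
#' @return A list with `top_k`, `confusion`, `statistics`, `break_even`.
#' @export
evaluate_ranking <- function(pred, essentials,
                             ks = seq(100L, 600L, by = 100L),
                             fraction = 0.2) {
  ordering <- as_ordering(pred)
  ks <- ks[ks <= length(ordering)]
  if (length(ks) == 0L) {
    message("evaluate_ranking: all requested ks exceed the ranking length; ",
            "using k = ", length(ordering))
    ks <- length(ordering)
  }
  conf <- confusion_at_fraction(ordering, essentials, fraction)
  list(
    top_k = top_k_true(ordering, essentials, ks),
    confusion = conf,
    statistics = confusion_statistics(conf),
    break_even = break_even_point(ordering, essentials)
  )
}
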