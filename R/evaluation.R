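#' Attach essentiality labels to a ranking
#'
#' Restricts a reference list of essential protein identifiers to the ranked
#' universe (identifiers absent from the ranking are dropped with a reported
#' count) and packages ranking, scores and labels for the evaluation
#' functions.
#'
#' @param st a [score_table] (or named numeric vector of scores).
#' @param essential character vector of essential protein identifiers.
#' @return object of class `labeled_ranking`: list with `ranking` (ordered
#'   identifiers), `scores` (named, in ranking order), `essential`
#'   (character vector restricted to the ranking), `labels` (0/1 in ranking
#'   order) and `n_dropped`.
#' @export
labeled_ranking <- function(st, essential) {
  if (inherits(st, "score_table")) {
    ranking <- st$protein
    scores <- stats::setNames(st$score, st$protein)
  } else {
    stt <- score_table(st, method = "scores")
    ranking <- stt$protein
    scores <- stats::setNames(stt$score, stt$protein)
  }
  essential <- unique(as.character(essential))
  kept <- intersect(essential, ranking)
  n_dropped <- length(essential) - length(kept)
  if (n_dropped > 0L)
    message(sprintf("labeled_ranking: %d essential id(s) not in the ranked universe; dropped",
                    n_dropped))
  structure(list(ranking = ranking, scores = scores, essential = kept,
                 labels = as.integer(ranking %in% kept),
                 n_dropped = n_dropped),
            class = "labeled_ranking")
}

#' Confusion counts at a top-k cutoff
#'
#' The top `k` ranked proteins are predicted essential, the rest
#' non-essential.
#'
#' @param lr a [labeled_ranking].
#' @param k cutoff, between 1 and the number of ranked proteins. Defaults to
#'   the number of known essential proteins in the universe — the cutoff at
#'   which sensitivity equals precision and specificity equals the negative
#'   predictive value, the fingerprint of published per-method metric
#'   tables.
#' @return list of class `confusion_counts` with integers `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_at_cutoff <- function(lr, k = length(lr$essential)) {
  stopifnot(inherits(lr, "labeled_ranking"))
  p <- length(lr$ranking)
  if (k < 1L || k > p) stop("cutoff k must be in [1, ", p, "]")
  tp <- sum(lr$labels[seq_len(k)])
  n_ess <- length(lr$essential)
  structure(list(TP = tp, FP = k - tp, FN = n_ess - tp,
                 TN = p - k - (n_ess - tp)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' `FPR = FP/(TN+FP)`, precision `PPV = TP/(TP+FP)`, negative predictive
#' value `NPV = TN/(TN+FN)`, `F = 2TP/(2TP+FP+FN)`,
#' `ACC = (TP+TN)/total` and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Any 0/0 ratio is reported as 0 with a warning.
#'
#' @param counts a `confusion_counts` object (or list with `TP`, `FP`, `TN`,
#'   `FN`).
#' @return named numeric vector with elements `SN`, `SP`, `FPR`, `PPV`,
#'   `NPV`, `F`, `ACC`, `MCC`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (tp + fn == 0L || tn + fp == 0L)
    stop("both classes must be present to compute classification metrics")
  div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is 0/0; reported as 0", what))
      return(0)
    }
    num / den
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(SN = tp / (tp + fn),
    SP = tn / (tn + fp),
    FPR = fp / (tn + fp),
    PPV = div(tp, tp + fp, "PPV"),
    NPV = div(tn, tn + fn, "NPV"),
    F = div(2 * tp, 2 * tp + fp + fn, "F-measure"),
    ACC = (tp + tn) / (tp + fp + tn + fn),
    MCC = if (mcc_den == 0) {
      warning("MCC is 0/0; reported as 0"); 0
    } else (tp * tn - fp * fn) / mcc_den)
}

# ROC sweep over distinct score thresholds (ties enter together, giving
# diagonal segments) with trapezoidal AUC.
.roc_core <- function(scores, labels) {
  pos <- sum(labels == 1L)
  neg <- sum(labels == 0L)
  if (pos == 0L || neg == 0L)
    stop("ROC requires both essential and non-essential proteins")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(y)[last] / pos)
  fpr <- c(0, cumsum(1 - y)[last] / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' ROC curve and AUC of a labelled ranking
#'
#' The curve is swept over the distinct score values, so tied proteins enter
#' together and produce diagonal segments; the AUC (trapezoidal rule) then
#' equals the tie-corrected Mann--Whitney statistic
#' \eqn{P(s_{ess} > s_{non}) + \frac{1}{2} P(s_{ess} = s_{non})}.
#'
#' @param lr a [labeled_ranking].
#' @return list with `roc` (data frame of `FPR`, `TPR` points from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(lr) {
  stopifnot(inherits(lr, "labeled_ranking"))
  .roc_core(unname(lr$scores), lr$labels)
}

#' ROC/AUC restricted to the top fraction of a ranking
#'
#' Keeps the top `ceiling(fraction * P)` ranked proteins (both their scores
#' and labels) and computes [roc_auc()] on that subset — the head-of-ranking
#' comparison used when full-list ROC curves are dominated by the easy tail.
#'
#' @param lr a [labeled_ranking].
#' @param fraction fraction of the ranking to keep, in (0, 1\].
#' @return as [roc_auc()].
#' @export
roc_auc_top_fraction <- function(lr, fraction = 0.2) {
  stopifnot(inherits(lr, "labeled_ranking"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- ceiling(fraction * length(lr$ranking))
  idx <- seq_len(m)
  .roc_core(unname(lr$scores)[idx], lr$labels[idx])
}

#' Jackknife curve of cumulative essential counts
#'
#' Element `m` is the number of essential proteins among the top `m` ranked
#' proteins; plotted against `m` this is the standard sorting-methodology
#' comparison curve for essentiality rankers.
#'
#' @param lr a [labeled_ranking].
#' @return integer vector of length `P` (number of ranked proteins),
#'   nondecreasing, ending at the number of essential proteins in the
#'   universe.
#' @export
jackknife_curve <- function(lr) {
  stopifnot(inherits(lr, "labeled_ranking"))
  cumsum(lr$labels)
}

#' Essential counts in top percentage slices
#'
#' For each percentage `p` the slice is the top `ceiling(p * P / 100)`
#' ranked proteins (ceiling keeps small-network slices nonempty).
#'
#' @param lr a [labeled_ranking].
#' @param percents percentages in (0, 100\].
#' @return named integer vector: essential count per percentage.
#' @export
top_percent_counts <- function(lr, percents = c(1, 5, 10, 15, 20, 25)) {
  stopifnot(inherits(lr, "labeled_ranking"))
  if (any(percents <= 0 | percents > 100))
    stop("percents must lie in (0, 100]")
  jk <- jackknife_curve(lr)
  m <- ceiling(percents * length(lr$ranking) / 100)
  stats::setNames(jk[m], paste0("top", percents, "%"))
}

#' Overlap analysis of two methods' top-N sets
#'
#' Compares the top-`top_n` protein sets `A` and `B` of two score tables:
#' the intersection size and, for each side of the symmetric difference, the
#' set size, the essential count and the essential percentage — the standard
#' did-the-new-method-find-different-essentials table.
#'
#' @param a,b [score_table]s over the same protein universe.
#' @param essential character vector of essential identifiers.
#' @param top_n number of top-ranked proteins per method.
#' @return list with `top_n`, `intersection` (size of `A` \eqn{\cap} `B`),
#'   and `a_only`/`b_only`, each a list `size`, `essential`, `essential_pct`
#'   (percentage of essentials within the difference set; 0 with
#'   `empty = TRUE` when the difference is empty).
#' @export
overlap_analysis <- function(a, b, essential, top_n = 100L) {
  stopifnot(inherits(a, "score_table"), inherits(b, "score_table"))
  if (!setequal(a$protein, b$protein))
    stop("score tables must cover the same protein universe")
  if (top_n > nrow(a)) stop("top_n exceeds the protein universe size")
  ta <- a$protein[seq_len(top_n)]
  tb <- b$protein[seq_len(top_n)]
  side <- function(only) {
    n_ess <- length(intersect(only, essential))
    list(size = length(only), essential = n_ess,
         essential_pct = if (length(only) == 0L) 0 else 100 * n_ess / length(only),
         empty = length(only) == 0L)
  }
  list(top_n = top_n,
       methods = c(attr(a, "method"), attr(b, "method")),
       intersection = length(intersect(ta, tb)),
       a_only = side(setdiff(ta, tb)),
       b_only = side(setdiff(tb, ta)))
}

#' Full evaluation report for one ranking
#'
#' Bundles the battery applied to each method in a benchmark: confusion
#' counts and metrics at the `k =` number-of-essentials cutoff, full and
#' top-fraction ROC/AUC, the jackknife curve and top-percentage counts.
#'
#' @param st a [score_table].
#' @param essential character vector of essential identifiers.
#' @param top_fraction fraction for the restricted ROC (default 0.2).
#' @param percents top percentages to report.
#' @return list of class `eval_report` with elements `method`, `counts`,
#'   `metrics`, `roc`, `auc`, `roc_top`, `auc_top`, `jackknife`, `topk`.
#' @export
evaluate_ranking <- function(st, essential, top_fraction = 0.2,
                             percents = c(1, 5, 10, 15, 20, 25)) {
  lr <- labeled_ranking(st, essential)
  counts <- confusion_at_cutoff(lr)
  full <- roc_auc(lr)
  top <- tryCatch(roc_auc_top_fraction(lr, top_fraction),
                  error = function(e) list(roc = NULL, auc = NA_real_))
  structure(list(method = attr(st, "method"),
                 counts = counts,
                 metrics = classification_metrics(counts),
                 roc = full$roc, auc = full$auc,
                 roc_top = top$roc, auc_top = top$auc,
                 jackknife = jackknife_curve(lr),
                 topk = top_percent_counts(lr, percents)),
            class = "eval_report")
}
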