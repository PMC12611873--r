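#' Area under the ROC curve
#'
#' AUC as the probability that a randomly chosen presence receives a higher
#' score than a randomly chosen absence, with ties counted one half
#' (midrank Mann-Whitney form).
#'
#' @param scores numeric prediction scores.
#' @param labels presence/absence labels (logical, or coercible 0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both presences and absences")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic with optimizing threshold
#'
#' TSS = sensitivity + specificity - 1 evaluated at the best classification
#' threshold. Candidate thresholds are the midpoints of consecutive sorted
#' unique scores (a score counts as presence when it exceeds the threshold
#' strictly). Ties between equally good thresholds are broken toward the
#' threshold nearest 0.5, then toward the larger one. Constant scores admit
#' no discriminating threshold: TSS 0 at threshold 0.5.
#'
#' @inheritParams auc_score
#' @return List with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels))
    stop("TSS requires both presences and absences")
  u <- sort(unique(scores))
  if (length(u) < 2)
    return(list(tss = 0, threshold = 0.5, sensitivity = 1, specificity = 0))
  thr <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(thr, function(t) mean(scores[labels] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] <= t), numeric(1))
  tss <- sens + spec - 1
  best <- which(tss == max(tss))
  if (length(best) > 1) {
    d <- abs(thr[best] - 0.5)
    best <- best[d == min(d)]
    best <- best[which.max(thr[best])]
  }
  list(tss = tss[best], threshold = thr[best],
       sensitivity = sens[best], specificity = spec[best])
}
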