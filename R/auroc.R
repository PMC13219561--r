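# AUROC via the midrank (Mann-Whitney) identity; macro one-vs-rest for the
# multi-class case.

#' Binary AUROC with midrank tie handling
#'
#' Computed from the rank-sum identity: ties contribute half a concordant
#' pair, so identical scores for all samples give exactly 0.5.
#'
#' @param scores numeric scores, higher means more positive.
#' @param positive logical (or 0/1) vector marking positives.
#' @return AUROC in `[0, 1]`, or `NA` if either class is absent.
#' @examples
#' aurocBinary(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
aurocBinary <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Macro one-vs-rest AUROC plus accuracy from a probability matrix.
queryMetrics <- function(probs, labels, nClasses) {
  perClass <- rep(NA_real_, nClasses)
  for (c in seq_len(nClasses)) {
    pos <- labels == c
    if (!any(pos) || all(pos)) next
    perClass[c] <- aurocBinary(probs[, c], pos)
  }
  if (anyNA(perClass))
    warning("class(es) absent from the query; dropped from the macro AUROC")
  pred <- max.col(probs, ties.method = "first")
  list(auroc = mean(perClass, na.rm = TRUE),
       accuracy = mean(pred == labels),
       perClassAuroc = perClass)
}

#' Macro one-vs-rest AUROC for multi-class scores
#'
#' Each class present in the labels contributes a one-vs-rest binary AUROC
#' on its score column; classes missing from the labels are dropped with a
#' warning.
#'
#' @param probs numeric matrix `n x C` of class scores.
#' @param labels integer labels in `1..C`.
#' @return list with `auroc` (macro mean), `accuracy`, `perClassAuroc`.
#' @export
macroAUROC <- function(probs, labels) {
  queryMetrics(as.matrix(probs), as.integer(labels), ncol(probs))
}
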