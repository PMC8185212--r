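#' Rank decoys by score
#'
#' Stable descending sort: equal scores keep their input order.
#'
#' @param decoyIds character vector.
#' @param scores numeric vector.
#' @param labels optional logical/integer vector (1 = correct).
#' @param classes optional quality classes (characters or factors).
#' @return data.frame (decoyId, score, rank, and label/class when given),
#'   sorted by decreasing score.
#' @export
rankDecoys <- function(decoyIds, scores, labels = NULL, classes = NULL) {
  stopifnot(length(decoyIds) > 0, length(scores) == length(decoyIds))
  o <- order(-scores)   # radix sort: stable for ties
  out <- data.frame(decoyId = decoyIds[o], score = scores[o],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- as.integer(as.logical(labels))[o]
  if (!is.null(classes)) out$class <- as.character(classes)[o]
  out
}

#' Hit-rate curve over targets
#'
#' For each rank cutoff k the fraction of targets with at least one correct
#' decoy among the top k.
#'
#' @param targets named list of ranked data.frames (see [rankDecoys()])
#'   with a `label` column.
#' @param kMax largest rank cutoff.
#' @return numeric vector of length `kMax` (non-decreasing, in \[0, 1\]).
#' @export
hitRate <- function(targets, kMax) {
  stopifnot(length(targets) > 0, kMax >= 1)
  hits <- vapply(targets, .firstHitRank, numeric(1))
  vapply(seq_len(kMax), function(k) mean(hits <= k), numeric(1))
}

.firstHitRank <- function(ranked) {
  i <- which(ranked$label == 1)
  if (length(i) == 0) Inf else min(i)
}

#' Top-k hit indicator of a single ranked target
#' @param ranked a ranked data.frame with a `label` column.
#' @param k rank cutoff.
#' @return TRUE if a correct decoy appears within the top k.
#' @export
hasHit <- function(ranked, k) .firstHitRank(ranked) <= k

#' Group-averaged hit rate
#'
#' Per-group mean of the per-target top-k hit indicator, re-averaged over
#' groups (redundancy-aware accounting).
#'
#' @param targets named list of ranked data.frames.
#' @param groups named character vector mapping target id to group id.
#' @param k rank cutoff.
#' @return fraction in \[0, 1\].
#' @export
groupedHitRate <- function(targets, groups, k) {
  ids <- names(targets)
  if (is.null(ids) || !all(ids %in% names(groups)))
    stop("every target needs a group assignment")
  ind <- vapply(targets, hasHit, logical(1), k = k)
  mean(tapply(as.numeric(ind), groups[ids], mean))
}

#' Cumulative quality counts in the top k
#'
#' Counts of decoys of acceptable-or-better, medium-or-better, and high
#' quality among the top `k` ranked models (nested: high <= medium <=
#' acceptable).
#'
#' @param ranked ranked data.frame with a `class` column (values
#'   incorrect/acceptable/medium/high).
#' @param k rank cutoff.
#' @return named integer vector (acceptable, medium, high).
#' @export
topKQualityCounts <- function(ranked, k) {
  top <- utils::head(ranked, k)
  if (is.null(top$class) || anyNA(top$class))
    stop("quality class missing for a top-k decoy")
  cl <- factor(top$class, levels = c("incorrect", "acceptable", "medium",
                                     "high"), ordered = TRUE)
  if (anyNA(cl)) stop("unknown quality class value")
  c(acceptable = sum(cl >= "acceptable"),
    medium = sum(cl >= "medium"),
    high = sum(cl >= "high"))
}
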