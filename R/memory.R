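## Detail-level memory scoring and inter-rater agreement.  Scoring of free
## text against an answer key is human work; these tools start at per-rater
## tallies of correct and incorrect details.

#' Memory accuracy from a detail tally
#'
#' The proportion of correct responses — the number of correct details
#' divided by the total number of details, correct and incorrect — in
#' percent.  A response that matches the answer key in one attribute but
#' not another (say, a belt that was worn but was brown, not black)
#' contributes one correct and one incorrect detail, giving 50%.
#'
#' @param n_correct,n_incorrect Non-negative detail counts (vectorised);
#'   each total must be at least 1.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
memory_accuracy <- function(n_correct, n_incorrect) {
  if (any(n_correct < 0) || any(n_incorrect < 0)) stop("counts must be >= 0")
  total <- n_correct + n_incorrect
  if (any(total < 1)) stop("each tally needs at least one scored detail")
  100 * n_correct / total
}

#' Inter-rater agreement on detail tallies
#'
#' Pearson correlations between two raters' correct-detail counts and,
#' separately, their incorrect-detail counts, over the participants both
#' raters scored.
#'
#' @param tallies_r1,tallies_r2 `data.frame`s with columns `participant`,
#'   `n_correct`, `n_incorrect` (one row per participant per rater).
#' @return List with `r_correct`, `r_incorrect`, and `n_shared`.
#' @export
interrater_agreement <- function(tallies_r1, tallies_r2) {
  shared <- intersect(tallies_r1$participant, tallies_r2$participant)
  if (length(shared) < 3) stop("need at least 3 shared participants")
  a <- tallies_r1[match(shared, tallies_r1$participant), ]
  b <- tallies_r2[match(shared, tallies_r2$participant), ]
  for (v in c("n_correct", "n_incorrect")) {
    if (stats::sd(a[[v]]) == 0 || stats::sd(b[[v]]) == 0)
      stop("zero variance in ", v, " for one rater; correlation undefined")
  }
  list(r_correct = stats::cor(a$n_correct, b$n_correct),
       r_incorrect = stats::cor(a$n_incorrect, b$n_incorrect),
       n_shared = length(shared))
}
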