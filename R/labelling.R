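# Multi-rater quality labels: majority-vote consensus and Fleiss kappa.

quality_levels <- c("B", "F", "E")

#' Majority vote over three quality labels
#'
#' Unanimous votes win outright; a 2-of-3 majority decides otherwise; if all
#' three raters disagree the pulse is conservatively labelled B (unusable).
#'
#' @param votes character vector of exactly 3 labels in `{B, F, E}`.
#' @return single consensus label.
#' @export
majority_vote <- function(votes) {
  if (length(votes) != 3L) stop_parameter("majority_vote needs exactly 3 votes")
  if (any(!votes %in% quality_levels))
    stop_parameter("votes must be in {B, F, E}")
  tab <- table(factor(votes, levels = quality_levels))
  if (max(tab) == 1L) return("B")
  names(tab)[which.max(tab)]
}

#' Consensus labels for a rater-vote table
#'
#' Applies [majority_vote()] row-wise to the `rater_*` columns.
#'
#' @param labels `data.frame` with columns `rater_1`, `rater_2`, `rater_3`.
#' @return the table with a `consensus` column added/replaced.
#' @export
consensus_labels <- function(labels) {
  rcols <- grep("^rater_", names(labels), value = TRUE)
  if (length(rcols) != 3L) stop_parameter("expected exactly 3 rater_* columns")
  labels$consensus <- vapply(seq_len(nrow(labels)), function(i)
    majority_vote(as.character(unlist(labels[i, rcols]))), character(1))
  labels
}

#' Fleiss kappa for multi-rater agreement
#'
#' Chance-corrected agreement for n raters assigning N items to k categories,
#' from the items x categories count matrix:
#' kappa = (Pbar - Pe) / (1 - Pe), where Pbar is the mean within-item
#' agreement and Pe the chance agreement from the marginal category
#' proportions.
#'
#' @param counts integer matrix, `counts[i, j]` = number of raters assigning
#'   item i to category j; every row must sum to the same number of raters
#'   (>= 2).
#' @return kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  n_raters <- rowSums(counts)
  if (length(unique(n_raters)) != 1L)
    stop_parameter("every item must be rated by the same number of raters")
  n <- n_raters[1L]
  if (n < 2L) stop_parameter("need at least 2 raters per item")
  N <- nrow(counts)
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (N * n)
  p_e <- sum(p_j^2)
  if (p_e >= 1) pq_error("ppgqc_undefined_agreement_error",
                         "chance agreement is 1; kappa undefined")
  (p_bar - p_e) / (1 - p_e)
}

#' Rater votes to a count matrix
#'
#' @param labels `data.frame` with `rater_*` columns of labels in `{B, F, E}`.
#' @return items x 3 count matrix with columns B, F, E.
#' @export
vote_counts <- function(labels) {
  rcols <- grep("^rater_", names(labels), value = TRUE)
  if (!length(rcols)) stop_parameter("no rater_* columns found")
  m <- sapply(quality_levels, function(lv)
    rowSums(labels[, rcols, drop = FALSE] == lv))
  m <- matrix(as.integer(m), ncol = 3L,
              dimnames = list(NULL, quality_levels))
  m
}
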