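#' Aggregate five expert recommendations into a board subscore
#'
#' Each of five board members recommends an integer value in 0-3 for a
#' subscore. The board subscore is the mode of the recommendations. With
#' five raters over four levels there is either a unique mode or exactly
#' one 2-2-1 count pattern; in the tied case the singleton value `t` acts
#' as tiebreaker: if `t` lies strictly between the two tied values it is
#' returned itself (a compromise), otherwise the tied value nearer to `t`
#' is returned (`t` weighs the balance to one side).
#'
#' @param panel integer vector of exactly five recommendations, each in
#'   0-3 (order irrelevant).
#' @return integer board subscore in 0-3.
#' @examples
#' board_subscore(c(1, 1, 2, 3, 3)) # compromise -> 2
#' board_subscore(c(0, 1, 1, 2, 2)) # weight     -> 1
#' board_subscore(c(1, 1, 2, 2, 3)) # weight     -> 2
#' @export
board_subscore <- function(panel) {
  if (length(panel) != 5L)
    stop("a rater panel has exactly five recommendations", call. = FALSE)
  panel <- as.integer(panel)
  if (any(is.na(panel)) || any(panel < 0L | panel > 3L))
    stop("recommendations must be integers in 0-3", call. = FALSE)

  counts <- tabulate(panel + 1L, nbins = 4L)
  top <- max(counts)
  modes <- which(counts == top) - 1L
  if (length(modes) == 1L) return(modes)

  # with 5 raters the only non-unique pattern is 2-2-1
  tied <- modes                       # two distinct tied values
  t_val <- which(counts == 1L) - 1L   # the singleton tiebreaker
  if (t_val > min(tied) && t_val < max(tied)) {
    t_val                             # compromise: t between the tied pair
  } else {
    tied[which.min(abs(tied - t_val))] # weight: tied value nearer to t
  }
}

#' Assemble a full expert-board assessment
#'
#' Applies [board_subscore()] to one five-rater panel per subscore and sums
#' the six board subscores into the total SMS (0 = no findings, 18 = most
#' critical).
#'
#' @param panels a data frame with columns `subscore`, `rater`, `value`
#'   (five rows per subscore; all six subscores present), e.g. one
#'   patient's slice of a cohort's `raters` table.
#' @return one-row tibble with the six board subscores and `sms`.
#' @export
board_assessment <- function(panels) {
  subs <- sms_subscores()
  missing <- setdiff(subs, unique(panels$subscore))
  if (length(missing))
    stop("missing rater panel(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  scores <- vapply(subs, function(s) {
    board_subscore(panels$value[panels$subscore == s])
  }, integer(1))
  out <- tibble::as_tibble(as.list(scores))
  out$sms <- sum(scores)
  out
}

#' Board labels for every patient of a cohort
#'
#' @param raters a rater table (columns `patient_id`, `subscore`, `rater`,
#'   `value`), e.g. `cohort$raters`.
#' @return tibble with one row per patient: `patient_id`, the six board
#'   subscores, and `sms`.
#' @export
board_scores <- function(raters) {
  raters |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ board_assessment(.x)) |>
    dplyr::ungroup()
}
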