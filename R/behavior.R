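#' Object-recognition indices D1 and D2
#'
#' From a continuous recognition session: per-trial D1 is the novel-object
#' exploration time minus the familiar-object exploration time; cumulative
#' D1 sums this over all trials that presented a familiar object (a trial
#' without one, typically trial 1, contributes to total exploration but
#' not to D1); D2 is cumulative D1 divided by the total exploration time
#' of both object types, a ratio in `[-1, 1]`.
#'
#' @param session A [recognition_session()].
#' @return An object of class `recognition_indices`: `d1_per_trial`
#'   (`NA` where no familiar object), `cumulative_d1` (s), `d2`,
#'   `total_exploration` (s). `d2` is `NA` when total exploration is zero
#'   (undefined, not zero preference).
#' @export
recognition_indices <- function(session) {
  stopifnot(inherits(session, "recognition_session"))
  has_fam <- !is.na(session$familiar)
  if (!any(has_fam))
    stop("at least one trial with a familiar object is required")
  d1 <- ifelse(has_fam, session$novel - session$familiar, NA_real_)
  cum_d1 <- sum(session$novel[has_fam]) - sum(session$familiar[has_fam])
  total <- sum(session$novel) + sum(session$familiar[has_fam])
  d2 <- if (total > 0) cum_d1 / total else NA_real_
  structure(list(d1_per_trial = d1, cumulative_d1 = cum_d1, d2 = d2,
                 total_exploration = total),
            class = "recognition_indices")
}

#' @export
print.recognition_indices <- function(x, ...) {
  cat(sprintf("<recognition: cumulative D1 %.1f s, D2 %.3f over %.1f s>\n",
              x$cumulative_d1, x$d2, x$total_exploration))
  invisible(x)
}

#' Spatial-alternation score
#'
#' Percentage of trials on which the animal alternated correctly (chose
#' the arm opposite its forced sample run). Chance performance is 50 %.
#'
#' @param session An [alternation_session()].
#' @return Percent correct in `[0, 100]`.
#' @export
alternation_score <- function(session) {
  stopifnot(inherits(session, "alternation_session"))
  100 * mean(session$choices)
}
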