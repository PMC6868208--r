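#' Number of clips in a session
#'
#' Behaviour is coded on short fixed-length clips cut from each observation
#' session; a behaviour is scored present for a clip when at least one fish
#' of the shoal performed it at any point during the clip. A 30 min session
#' cut into 10 s clips gives 180 clips.
#'
#' @param session_duration_s Session length in seconds.
#' @param clip_duration_s Clip length in seconds (default 10).
#'
#' @return Integer clip count. Errors if the session is not an exact number
#'   of clips.
#' @examples
#' segment_clips(1800) # 180
#' @export
segment_clips <- function(session_duration_s, clip_duration_s = 10) {
  if (session_duration_s <= 0 || clip_duration_s <= 0) {
    abort("durations must be strictly positive")
  }
  n <- session_duration_s / clip_duration_s
  if (abs(n - round(n)) > 1e-9) {
    abort(sprintf(
      "partial clip: %g s is not a whole number of %g s clips",
      session_duration_s, clip_duration_s
    ))
  }
  as.integer(round(n))
}

check_behaviour_table <- function(behaviour) {
  required <- c("group_id", "condition", "clip_index", "behaviour", "present")
  missing <- setdiff(required, names(behaviour))
  if (length(missing) > 0L) {
    abort(paste0("behaviour table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(behaviour$present %in% c(0L, 1L))) {
    abort("`present` must be binary (0/1)")
  }
  invisible(behaviour)
}

#' Random clip subsample for intra-observer reliability
#'
#' Selects a reproducible uniform random subsample of clips (across all
#' groups and conditions) for second-pass coding, sized
#' `round(fraction * total clips)`. With the default study design of 23
#' groups, 2 conditions and 180 clips each, a 10% subsample is 828 clips.
#'
#' @param behaviour Long-format behaviour tibble with columns
#'   `group_id, condition, clip_index, behaviour, present`.
#' @param fraction Fraction of clips to rescore, in `(0, 1]`. Default 0.10.
#' @param seed Optional integer seed for a reproducible draw.
#'
#' @return Tibble of selected clip identifiers: `group_id, condition,
#'   clip_index`, in random rescoring order.
#' @export
reliability_subsample <- function(behaviour, fraction = 0.10, seed = NULL) {
  check_behaviour_table(behaviour)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  clips <- dplyr::distinct(behaviour, .data$group_id, .data$condition, .data$clip_index)
  if (nrow(clips) == 0L) abort("no clips in behaviour table")
  n_pick <- round(fraction * nrow(clips))
  if (!is.null(seed)) set.seed(seed)
  clips[sample.int(nrow(clips), n_pick), ]
}

check_coder_pair <- function(coder1, coder2) {
  if (length(coder1) != length(coder2)) {
    abort("coder vectors must have equal length")
  }
  if (length(coder1) == 0L) abort("coder vectors must be non-empty")
  invisible(NULL)
}

#' Percent agreement between two coders
#'
#' @param coder1,coder2 Equal-length coding vectors (any type comparable
#'   with `==`; typically 0/1 presence codes).
#'
#' @return Percentage of positions on which the coders agree, in `[0, 100]`.
#' @examples
#' percent_agreement(c(1, 0, 1, 0), c(1, 0, 0, 0)) # 75
#' @export
percent_agreement <- function(coder1, coder2) {
  check_coder_pair(coder1, coder2)
  100 * mean(coder1 == coder2)
}

#' Cohen's kappa for two binary coders
#'
#' Chance-corrected agreement, `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the product of the coders' marginal rates. Two
#' degenerate cases arise with constant coders (`p_e = 1`): if both coders
#' are constant and identical, agreement is perfect and kappa is defined as
#' 1; if constant and different, kappa is defined as 0 with a warning.
#'
#' @param coder1,coder2 Equal-length binary (0/1) vectors.
#'
#' @return Scalar kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)) # 1
#' @export
cohens_kappa <- function(coder1, coder2) {
  check_coder_pair(coder1, coder2)
  if (!all(coder1 %in% c(0, 1)) || !all(coder2 %in% c(0, 1))) {
    abort("coder vectors must be binary (0/1)")
  }
  p_o <- mean(coder1 == coder2)
  p1 <- mean(coder1)
  p2 <- mean(coder2)
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  constant1 <- p1 %in% c(0, 1)
  constant2 <- p2 %in% c(0, 1)
  if (constant1 && constant2) {
    if (p_o >= 1 - 1e-12) return(1)
    warn("both coders constant but different; kappa undefined, returning 0")
    return(0)
  }
  if (p_e >= 1 - 1e-12) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Intra-observer reliability per behaviour
#'
#' Joins a first-pass and a second-pass coding of the same clips and reports
#' percent agreement and Cohen's kappa per behaviour.
#'
#' @param coding1,coding2 Long-format behaviour tibbles (columns
#'   `group_id, condition, clip_index, behaviour, present`) covering the
#'   same clips.
#'
#' @return Tibble with columns `behaviour, percent_agreement, kappa,
#'   n_clips_rescored`.
#' @export
reliability_stats <- function(coding1, coding2) {
  check_behaviour_table(coding1)
  check_behaviour_table(coding2)
  joined <- dplyr::inner_join(
    coding1, coding2,
    by = c("group_id", "condition", "clip_index", "behaviour"),
    suffix = c("_1", "_2")
  )
  if (nrow(joined) == 0L) abort("the two codings share no clips")
  joined |>
    dplyr::group_by(.data$behaviour) |>
    dplyr::summarise(
      percent_agreement = percent_agreement(.data$present_1, .data$present_2),
      kappa = cohens_kappa(.data$present_1, .data$present_2),
      n_clips_rescored = dplyr::n(),
      .groups = "drop"
    )
}

#' Remove rarely observed behaviours
#'
#' Drops behaviours whose overall presence, pooled over all clips of both
#' conditions, is below `min_presence`; a behaviour present in exactly
#' `min_presence` of clips is retained (strict-less removal).
#'
#' @inheritParams reliability_subsample
#' @param min_presence Minimum pooled presence fraction (default 0.10).
#'
#' @return A list with `retained` (behaviour names kept), `removed`
#'   (names dropped), `presence` (per-behaviour pooled presence tibble) and
#'   `behaviour` (the filtered table).
#' @export
rare_behaviour_filter <- function(behaviour, min_presence = 0.10) {
  check_behaviour_table(behaviour)
  presence <- behaviour |>
    dplyr::group_by(.data$behaviour) |>
    dplyr::summarise(presence = mean(.data$present), n_clips = dplyr::n(),
                     .groups = "drop")
  retained <- presence$behaviour[presence$presence >= min_presence]
  list(
    retained = retained,
    removed = setdiff(presence$behaviour, retained),
    presence = presence,
    behaviour = dplyr::filter(behaviour, .data$behaviour %in% retained)
  )
}
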