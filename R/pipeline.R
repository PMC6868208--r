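#' Assemble the candidate-metric catalogue
#'
#' Aligns the per-frame group metrics with the clip-level behaviours by
#' their common 10 s sampling interval (frame index = clip index) and
#' returns the observation matrix handed to the collinearity screen.
#' Centroid coordinates are bookkeeping, not candidate metrics, and are
#' dropped.
#'
#' @param metrics Per-frame metric tibble from [frame_metrics()].
#' @param behaviour Long-format behaviour tibble.
#'
#' @return A list with `values` (one column per candidate metric),
#'   `keys` (group_id/condition/frame_index per row) and `info`
#'   ([metric_info()] metadata).
#' @export
build_metric_catalogue <- function(metrics, behaviour) {
  check_behaviour_table(behaviour)
  wide <- behaviour |>
    tidyr::pivot_wider(names_from = "behaviour", values_from = "present") |>
    dplyr::rename(frame_index = "clip_index")
  joined <- dplyr::inner_join(metrics, wide,
                              by = c("group_id", "condition", "frame_index"))
  if (nrow(joined) == 0L) {
    abort("metrics and behaviour tables share no group/condition/interval rows")
  }
  keys <- joined[, c("group_id", "condition", "frame_index")]
  values <- joined[, setdiff(names(joined),
                             c(names(keys), "centroid_x_cm", "centroid_y_cm"))]
  list(values = values, keys = keys, info = default_metric_info(names(values)))
}

check_group_sets <- function(...) {
  tables <- list(...)
  groups <- lapply(tables, function(t) sort(unique(as.character(t$group_id))))
  ref <- groups[[1]]
  for (i in seq_along(groups)[-1]) {
    if (!identical(groups[[i]], ref)) {
      abort(sprintf(
        "mismatched group sets between inputs: '%s' vs '%s'",
        paste(setdiff(ref, groups[[i]]), collapse = ","),
        paste(setdiff(groups[[i]], ref), collapse = ",")
      ))
    }
  }
  invisible(ref)
}

#' Run the full group stress-response analysis
#'
#' End-to-end pipeline: per-frame metric computation, rare-behaviour
#' filtering, collinearity screening and metric selection, then one
#' condition-difference likelihood-ratio test per retained metric (Gaussian
#' LMM for continuous per-frame metrics, binomial GLMM for clip-level
#' behaviours) with Bonferroni correction over the family. Whole-body
#' cortisol, when supplied, is tested log-transformed in its own
#' a-priori model (values at or below zero are raised to half the assay
#' detection limit before the log, with a warning).
#'
#' @param positions Long-format position tibble (see [frame_metrics()]).
#' @param behaviour Long-format behaviour tibble.
#' @param body_lengths Body-length tibble.
#' @param cortisol Optional cortisol tibble (`group_id, condition, fish_id,
#'   cortisol_ng_per_g`).
#' @param tank A [tank_geometry()].
#' @param multiplier Association threshold in mean body lengths (default 2).
#' @param selection_threshold Collinearity threshold on `|r|` (default 0.2).
#' @param min_presence Rare-behaviour cutoff (default 0.10).
#' @param transforms Named list of response transforms; default log for the
#'   coefficient of variation of nearest-neighbour distance.
#' @param responses Responses to test; `NULL` (default) tests the metrics
#'   retained by the selection step.
#' @param priority Selection priority order, see [select_metrics()].
#' @param cortisol_in_family Count the cortisol test inside the Bonferroni
#'   family? Default `FALSE` (its own a-priori test).
#' @param detection_limit_ng_ml Assay detection limit used to floor
#'   non-positive cortisol values at half its value (default 0.0567).
#' @param lmm_control,glmm_control Optional lme4 control objects.
#'
#' @return Object of class `shoal_analysis`: list with `metrics`,
#'   `behaviour_filter`, `catalogue`, `correlations`, `selection`,
#'   `results` (tibble with `p_bonferroni`), `cortisol_result`, `m` and
#'   `provenance`.
#' @examples
#' study <- simulate_study(simulation_config(n_groups = 4, n_frames = 30), seed = 2)
#' fit <- run_full_analysis(study$positions, study$behaviour,
#'                          study$body_lengths, study$cortisol)
#' summary(fit)
#' @export
run_full_analysis <- function(positions, behaviour, body_lengths,
                              cortisol = NULL,
                              tank = tank_geometry(),
                              multiplier = 2,
                              selection_threshold = 0.2,
                              min_presence = 0.10,
                              transforms = list(cv_nnd = "log"),
                              responses = NULL,
                              priority = NULL,
                              cortisol_in_family = FALSE,
                              detection_limit_ng_ml = 0.0567,
                              lmm_control = lme4::lmerControl(),
                              glmm_control = lme4::glmerControl()) {
  tank <- as_tank(tank)
  if (is.null(cortisol)) {
    check_group_sets(positions, behaviour, body_lengths)
  } else {
    check_group_sets(positions, behaviour, body_lengths, cortisol)
  }

  metrics <- frame_metrics(positions, tank, body_lengths, multiplier)
  filt <- rare_behaviour_filter(behaviour, min_presence)
  catalogue <- build_metric_catalogue(metrics, filt$behaviour)
  correlations <- metric_correlations(catalogue$values, catalogue$info)
  selection <- select_metrics(correlations, threshold = selection_threshold,
                              priority = priority)
  responses <- responses %||% selection$retained

  kinds <- stats::setNames(catalogue$info$data_kind, catalogue$info$name)
  fits <- purrr::map(responses, function(resp) {
    if (identical(kinds[[resp]], "binary")) {
      data <- filt$behaviour |>
        dplyr::filter(.data$behaviour == resp) |>
        dplyr::rename(!!resp := "present")
      fit_glmm_binomial_lrt(data, resp, control = glmm_control)
    } else {
      tr <- transforms[[resp]] %||% "none"
      fit_lmm_lrt(metrics, resp, transform = tr, control = lmm_control)
    }
  })
  names(fits) <- responses

  cortisol_result <- NULL
  if (!is.null(cortisol)) {
    cort <- cortisol
    if (any(cort$cortisol_ng_per_g <= 0)) {
      warn(sprintf(
        "%d cortisol value(s) at or below 0 floored to half the detection limit (%g)",
        sum(cort$cortisol_ng_per_g <= 0), detection_limit_ng_ml / 2
      ))
      cort$cortisol_ng_per_g <- pmax(cort$cortisol_ng_per_g,
                                     detection_limit_ng_ml / 2)
    }
    cortisol_result <- fit_lmm_lrt(cort, "cortisol_ng_per_g", transform = "log",
                                   control = lmm_control)
  }

  m <- length(responses) + as.integer(cortisol_in_family && !is.null(cortisol_result))
  results <- purrr::map_dfr(fits, glance)
  results$p_bonferroni <- bonferroni_adjust(results$p_raw, m = m)
  if (!is.null(cortisol_result)) {
    cort_row <- glance(cortisol_result)
    cort_row$p_bonferroni <- bonferroni_adjust(
      cort_row$p_raw, m = if (cortisol_in_family) m else 1L
    )
    results <- dplyr::bind_rows(results, cort_row)
  }

  structure(
    list(metrics = metrics, behaviour_filter = filt, catalogue = catalogue,
         correlations = correlations, selection = selection,
         fits = fits, cortisol_result = cortisol_result,
         results = results, m = m,
         provenance = list(
           multiplier = multiplier, selection_threshold = selection_threshold,
           min_presence = min_presence, transforms = transforms,
           responses = responses, cortisol_in_family = cortisol_in_family,
           n_groups = length(unique(positions$group_id)),
           r_version = as.character(getRversion()),
           timestamp = format(Sys.time(), tz = "UTC")
         )),
    class = "shoal_analysis"
  )
}

#' @exportS3Method base::print
print.shoal_analysis <- function(x, ...) {
  cat(sprintf("<shoal_analysis> %d responses tested (Bonferroni m = %d)\n",
              nrow(x$results), x$m))
  print(x$results[, c("response", "family", "chi_sq", "p_bonferroni")])
  invisible(x)
}

#' Report table for a fitted analysis
#'
#' One row per tested response with the direction of the condition
#' difference (which condition is higher), the likelihood-ratio statistic
#' and the Bonferroni-adjusted p-value.
#'
#' @param object A `shoal_analysis`.
#' @param ... Unused.
#' @return Invisibly, the report tibble (also printed).
#' @exportS3Method base::summary
summary.shoal_analysis <- function(object, ...) {
  ref <- condition_levels(object$metrics$condition)
  report <- object$results |>
    dplyr::mutate(
      higher_under = dplyr::case_when(
        is.na(.data$estimate) ~ NA_character_,
        .data$estimate < 0 ~ ref[1],
        TRUE ~ ref[2]
      ),
      signif = dplyr::case_when(
        is.na(.data$p_bonferroni) ~ "",
        .data$p_bonferroni < 0.001 ~ "***",
        .data$p_bonferroni < 0.01 ~ "**",
        .data$p_bonferroni < 0.05 ~ "*",
        TRUE ~ "n.s."
      )
    ) |>
    dplyr::select("response", "family", "transform", "higher_under",
                  "chi_sq", "df", "p_raw", "p_bonferroni", "signif")
  print(report, n = Inf)
  invisible(report)
}

#' @exportS3Method generics::tidy
tidy.shoal_analysis <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.shoal_analysis <- function(x, ...) {
  tibble(
    n_responses = length(x$provenance$responses),
    n_retained = length(x$selection$retained),
    n_groups = x$provenance$n_groups,
    m_bonferroni = x$m,
    all_significant = all(x$results$p_bonferroni[
      x$results$response %in% x$provenance$responses] < 0.05)
  )
}
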