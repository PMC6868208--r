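condition_levels <- function(x) {
  u <- unique(as.character(x))
  if (setequal(u, c("immediate", "after_24h"))) c("immediate", "after_24h") else sort(u)
}

check_observation_table <- function(data, response) {
  missing <- setdiff(c(response, "condition", "group_id"), names(data))
  if (length(missing) > 0L) {
    abort(paste0("observation table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (length(unique(data$group_id)) < 2L) {
    abort("need at least 2 groups: the group random effect is unidentifiable with one group")
  }
  if (length(unique(data$condition)) != 2L) {
    abort("`condition` must have exactly 2 levels")
  }
  invisible(data)
}

new_lrt_result <- function(response, family, transform, fit_full, fit_null,
                           n_obs, n_groups, converged, flag) {
  chi_sq <- df <- p_raw <- NA_real_
  estimate <- NA_real_
  if (!is.null(fit_full) && !is.null(fit_null)) {
    ll_full <- as.numeric(logLik(fit_full))
    ll_null <- as.numeric(logLik(fit_null))
    chi_sq <- max(0, 2 * (ll_full - ll_null))
    df <- attr(logLik(fit_full), "df") - attr(logLik(fit_null), "df")
    p_raw <- pchisq(chi_sq, df = df, lower.tail = FALSE)
    fe <- lme4::fixef(fit_full)
    estimate <- unname(fe[length(fe)]) # condition contrast vs reference level
  }
  structure(
    list(response = response, family = family, transform = transform,
         chi_sq = chi_sq, df = df, p_raw = p_raw, estimate = estimate,
         n_obs = n_obs, n_groups = n_groups, converged = converged,
         flag = flag, fit_full = fit_full, fit_null = fit_null),
    class = "shoal_lrt"
  )
}

fit_status <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 && length(msgs) == 0L
  flag <- if (isTRUE(lme4::isSingular(fit))) "singular" else ""
  if (!converged) flag <- paste(c(flag[nzchar(flag)], "non-convergence"), collapse = ";")
  list(converged = converged, flag = flag)
}

#' Condition-difference test for a continuous response (Gaussian LMM)
#'
#' Fits, by maximum likelihood (not REML), a linear mixed model
#' `response ~ condition + (1 | group_id)` and the null model without the
#' condition term, and compares them with a likelihood-ratio test
#' (chi-squared on 1 df). The group random intercept controls for the
#' repeated observation of each group in both conditions.
#'
#' @param data Observation table with columns `condition`, `group_id` and
#'   the response column.
#' @param response Name of the (continuous) response column.
#' @param transform `"none"` or `"log"`; `"log"` requires strictly positive
#'   values.
#' @param control Optional [lme4::lmerControl()] passed to the fits.
#'
#' @return An object of class `shoal_lrt`; see [glance.shoal_lrt()] for the
#'   one-row summary and [tidy.shoal_lrt()] for the fixed effects. Singular
#'   random-effect fits are returned with a warning and `flag = "singular"`.
#' @examples
#' study <- simulate_study(simulation_config(n_groups = 4, n_frames = 20), seed = 1)
#' m <- frame_metrics(study$positions, tank_geometry(), study$body_lengths)
#' glance(fit_lmm_lrt(m, "distance_to_wall_cm"))
#' @export
fit_lmm_lrt <- function(data, response, transform = c("none", "log"),
                        control = lme4::lmerControl()) {
  transform <- match.arg(transform)
  check_observation_table(data, response)
  y <- data[[response]]
  if (!is.numeric(y)) abort(sprintf("response '%s' must be numeric", response))
  if (transform == "log") {
    if (any(y <= 0)) {
      abort(sprintf("log transform of '%s': values must be strictly positive (consider an offset for zeros)", response))
    }
    y <- log(y)
  }
  d <- data.frame(
    .y = y,
    condition = factor(as.character(data$condition), levels = condition_levels(data$condition)),
    group_id = factor(data$group_id)
  )
  fit_full <- tryCatch(
    suppressMessages(lme4::lmer(.y ~ condition + (1 | group_id), data = d,
                                REML = FALSE, control = control)),
    error = function(e) e
  )
  fit_null <- tryCatch(
    suppressMessages(lme4::lmer(.y ~ 1 + (1 | group_id), data = d,
                                REML = FALSE, control = control)),
    error = function(e) e
  )
  finalize_lrt(response, "gaussian_lmm", transform, fit_full, fit_null,
               nrow(d), nlevels(d$group_id))
}

#' Condition-difference test for a binary response (binomial GLMM)
#'
#' Fits, by maximum likelihood with the Laplace approximation, a logistic
#' mixed model `response ~ condition + (1 | group_id)` and its null model
#' without the condition term, comparing them with a likelihood-ratio test.
#' Intended for clip-level behaviour presence/absence responses.
#'
#' @inheritParams fit_lmm_lrt
#' @param response Name of the binary (0/1) response column.
#' @param control Optional [lme4::glmerControl()].
#'
#' @return An object of class `shoal_lrt`. Degenerate responses (all 0 or
#'   all 1) and failed fits are returned flagged, never as an error.
#' @export
fit_glmm_binomial_lrt <- function(data, response,
                                  control = lme4::glmerControl()) {
  check_observation_table(data, response)
  y <- data[[response]]
  if (!all(y %in% c(0, 1))) abort(sprintf("response '%s' must be binary (0/1)", response))
  d <- data.frame(
    .y = y,
    condition = factor(as.character(data$condition), levels = condition_levels(data$condition)),
    group_id = factor(data$group_id)
  )
  if (length(unique(y)) < 2L) {
    warn(sprintf("response '%s' is constant; degenerate fit flagged", response))
    return(new_lrt_result(response, "binomial_glmm", "none", NULL, NULL,
                          nrow(d), nlevels(d$group_id), FALSE, "degenerate"))
  }
  fit_full <- tryCatch(
    suppressMessages(lme4::glmer(.y ~ condition + (1 | group_id), data = d,
                                 family = stats::binomial(), nAGQ = 1L,
                                 control = control)),
    error = function(e) e
  )
  fit_null <- tryCatch(
    suppressMessages(lme4::glmer(.y ~ 1 + (1 | group_id), data = d,
                                 family = stats::binomial(), nAGQ = 1L,
                                 control = control)),
    error = function(e) e
  )
  finalize_lrt(response, "binomial_glmm", "none", fit_full, fit_null,
               nrow(d), nlevels(d$group_id))
}

finalize_lrt <- function(response, family, transform, fit_full, fit_null,
                         n_obs, n_groups) {
  if (inherits(fit_full, "error") || inherits(fit_null, "error")) {
    msg <- conditionMessage(if (inherits(fit_full, "error")) fit_full else fit_null)
    warn(sprintf("model fit for '%s' failed: %s", response, msg))
    return(new_lrt_result(response, family, transform, NULL, NULL,
                          n_obs, n_groups, FALSE, paste0("fit-error: ", msg)))
  }
  status_full <- fit_status(fit_full)
  status_null <- fit_status(fit_null)
  converged <- status_full$converged && status_null$converged
  flag <- paste(unique(c(status_full$flag[nzchar(status_full$flag)],
                         status_null$flag[nzchar(status_null$flag)])),
                collapse = ";")
  if (grepl("singular", flag)) {
    warn(sprintf("singular random-effect fit for '%s'; result returned", response))
  }
  new_lrt_result(response, family, transform, fit_full, fit_null,
                 n_obs, n_groups, converged, flag)
}

#' @exportS3Method base::print
print.shoal_lrt <- function(x, ...) {
  cat(sprintf(
    "<shoal_lrt> %s (%s%s): chi-sq(%s) = %.4g, p = %.3g [%d obs, %d groups%s]\n",
    x$response, x$family,
    if (x$transform != "none") paste0(", ", x$transform) else "",
    format(x$df), x$chi_sq, x$p_raw, x$n_obs, x$n_groups,
    if (nzchar(x$flag)) paste0(", ", x$flag) else ""
  ))
  invisible(x)
}

#' Tidy a condition-difference LRT
#'
#' @param x A `shoal_lrt` object.
#' @param ... Unused.
#' @return `tidy()`: tibble of fixed effects of the full model (term,
#'   estimate, std.error, statistic). `glance()`: one-row tibble with
#'   `response, family, transform, chi_sq, df, p_raw, estimate, n_obs,
#'   n_groups, converged, flag`.
#' @exportS3Method generics::tidy
tidy.shoal_lrt <- function(x, ...) {
  if (is.null(x$fit_full)) return(tibble())
  co <- summary(x$fit_full)$coefficients
  tibble(term = rownames(co), estimate = co[, 1],
         std.error = co[, 2], statistic = co[, 3])
}

#' @rdname tidy.shoal_lrt
#' @exportS3Method generics::glance
glance.shoal_lrt <- function(x, ...) {
  tibble(response = x$response, family = x$family, transform = x$transform,
         chi_sq = x$chi_sq, df = x$df, p_raw = x$p_raw, estimate = x$estimate,
         n_obs = x$n_obs, n_groups = x$n_groups, converged = x$converged,
         flag = x$flag)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and caps at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Family size (default: `length(p)`).
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' bonferroni_adjust(c(0.01, 0.3), m = 5) # 0.05, 1
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must be in [0, 1]")
  if (m < 1) abort("`m` must be >= 1")
  pmin(1, m * p)
}

#' Paired t-test sample size
#'
#' Smallest number of paired groups giving at least the target power for a
#' two-sided paired t-test at a given minimum effect size and standard
#' deviation of within-pair differences. The original study design (minimum
#' whole-body-cortisol effect of 4 ng/g against an upper-range SD of
#' 5.6 ng/g at 90% power) gives 23 groups.
#'
#' @param effect Minimum effect size to detect (same units as `sd`).
#' @param sd Standard deviation of the paired differences.
#' @param power Target power, in `(0, 1)` (default 0.90).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Integer: smallest n with power >= `power`.
#' @examples
#' paired_t_sample_size(effect = 4, sd = 5.6)
#' @export
paired_t_sample_size <- function(effect, sd, power = 0.90, alpha = 0.05) {
  if (effect <= 0 || sd <= 0) abort("`effect` and `sd` must be strictly positive")
  if (power <= 0 || power >= 1) abort("`power` must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  sol <- stats::power.t.test(delta = effect, sd = sd, sig.level = alpha,
                             power = power, type = "paired")
  n <- max(2L, as.integer(floor(sol$n)))
  power_at <- function(n) {
    stats::power.t.test(n = n, delta = effect, sd = sd, sig.level = alpha,
                        type = "paired")$power
  }
  while (power_at(n) < power) n <- n + 1L
  while (n > 2L && power_at(n - 1L) >= power) n <- n - 1L
  n
}
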