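#' Metric catalogue metadata
#'
#' Describes each candidate metric entering the collinearity screen: its
#' category (used to guarantee every category keeps at least one metric) and
#' whether its observations are continuous or binary (used to pick the
#' correlation method per pair).
#'
#' @param name Character vector of metric names.
#' @param category One of `"behavioural", "social", "proximity", "spatial"`
#'   per metric (recycled if length 1).
#' @param data_kind `"continuous"` or `"binary"` per metric (recycled).
#'
#' @return Tibble with columns `name, category, data_kind`.
#' @export
metric_info <- function(name, category, data_kind) {
  category <- rep_len(category, length(name))
  data_kind <- rep_len(data_kind, length(name))
  bad <- setdiff(category, c("behavioural", "social", "proximity", "spatial"))
  if (length(bad) > 0L) {
    abort(paste0("unknown metric category: ", paste(bad, collapse = ", ")))
  }
  if (!all(data_kind %in% c("continuous", "binary"))) {
    abort("`data_kind` must be 'continuous' or 'binary'")
  }
  tibble(name = name, category = category, data_kind = data_kind)
}

# metadata for the metrics this package itself produces
default_metric_info <- function(names) {
  categories <- c(
    mean_nnd_cm = "proximity", cv_nnd = "proximity",
    mean_interindividual_distance_cm = "proximity",
    expanse_cm = "proximity", convex_hull_area_cm2 = "proximity",
    distance_to_wall_cm = "spatial",
    density = "social", n_subgroups = "social", largest_subgroup_size = "social",
    erratic_movement = "behavioural", top_half = "behavioural"
  )
  kinds <- c(erratic_movement = "binary", top_half = "binary")
  unknown <- setdiff(names, names(categories))
  if (length(unknown) > 0L) {
    abort(paste0("no default metadata for metric(s): ", paste(unknown, collapse = ", "),
                 "; supply `info` explicitly via metric_info()"))
  }
  metric_info(names, categories[names],
              ifelse(names %in% names(kinds), "binary", "continuous"))
}

#' Correlation method for a metric pair
#'
#' Pairs of continuous metrics use Spearman rank correlation when either
#' metric looks non-normal (Shapiro-Wilk at `alpha`, on a subsample of at
#' most 5000 values) and Pearson otherwise; any pair involving a binary
#' metric uses Pearson (equivalent to the point-biserial / phi coefficient).
#'
#' @param a,b Numeric observation vectors for the two metrics.
#' @param kind_a,kind_b `"continuous"` or `"binary"`.
#' @param alpha Normality-test significance level (default 0.05).
#'
#' @return `"spearman"` or `"pearson"`.
#' @export
choose_correlation_method <- function(a, b, kind_a = "continuous",
                                      kind_b = "continuous", alpha = 0.05) {
  if (kind_a == "binary" || kind_b == "binary") return("pearson")
  if (!looks_normal(a, alpha) || !looks_normal(b, alpha)) return("spearman")
  "pearson"
}

looks_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || sd(x) == 0) return(FALSE)
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  stats::shapiro.test(x)$p.value >= alpha
}

#' Mixed-method correlation matrix over candidate metrics
#'
#' Computes all pairwise correlations between candidate metrics, choosing
#' Spearman or Pearson per pair via [choose_correlation_method()]. Missing
#' values are handled with pairwise-complete observations. Zero-variance
#' metrics get correlation 0 against everything, with a warning.
#'
#' @param values Tibble (or data frame) of aligned observations, one column
#'   per metric, one row per observation.
#' @param info Optional [metric_info()] tibble; defaults to the package's
#'   own metric metadata when all columns are package metrics.
#' @param alpha Normality-test level for the method choice.
#'
#' @return An object of class `shoal_corr`: list with `r` (symmetric
#'   correlation matrix, unit diagonal), `method` (per-pair method labels),
#'   `info`, and `n_pairwise` (pairwise-complete observation counts).
#' @export
metric_correlations <- function(values, info = NULL, alpha = 0.05) {
  values <- as_tibble(values)
  if (ncol(values) < 2L) abort("need at least 2 metrics")
  if (nrow(values) < 3L) abort("need at least 3 observations")
  if (is.null(info)) info <- default_metric_info(names(values))
  missing_meta <- setdiff(names(values), info$name)
  if (length(missing_meta) > 0L) {
    abort(paste0("`info` lacks metadata for: ", paste(missing_meta, collapse = ", ")))
  }
  kinds <- stats::setNames(info$data_kind, info$name)

  m <- ncol(values)
  nm <- names(values)
  r <- diag(1, m)
  method <- matrix("", m, m, dimnames = list(nm, nm))
  n_pw <- matrix(nrow(values), m, m, dimnames = list(nm, nm))
  dimnames(r) <- list(nm, nm)

  zero_var <- vapply(values, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(zero_var)) {
    warn(paste0("zero-variance metric(s), correlations set to 0: ",
                paste(nm[zero_var], collapse = ", ")))
  }
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- values[[i]]; b <- values[[j]]
      ok <- is.finite(a) & is.finite(b)
      n_pw[i, j] <- n_pw[j, i] <- sum(ok)
      meth <- choose_correlation_method(a[ok], b[ok], kinds[[nm[i]]], kinds[[nm[j]]],
                                        alpha)
      method[i, j] <- method[j, i] <- meth
      rij <- if (zero_var[i] || zero_var[j]) 0 else
        cor(a[ok], b[ok], method = meth)
      r[i, j] <- r[j, i] <- rij
    }
  }
  structure(list(r = r, method = method, info = info, n_pairwise = n_pw),
            class = "shoal_corr")
}

#' @exportS3Method base::print
print.shoal_corr <- function(x, digits = 2, ...) {
  cat(sprintf("<shoal_corr> %d metrics, %d observations\n",
              ncol(x$r), max(x$n_pairwise)))
  print(round(x$r, digits))
  invisible(x)
}

default_priority <- function(names) {
  canonical <- c("density", "cv_nnd", "distance_to_wall_cm",
                 "erratic_movement", "top_half")
  c(intersect(canonical, names), sort(setdiff(names, canonical)))
}

#' Prune collinear metrics
#'
#' Selects a non-collinear subset of metrics: a greedy pass in priority
#' order accepts a metric only if its absolute correlation with every
#' already-accepted metric is strictly below `threshold` (so `|r|` exactly
#' at the threshold counts as correlated and blocks acceptance). Afterwards,
#' any metric category left empty is backfilled with that category's metric
#' with the smallest maximum `|r|` against the accepted set (ties broken by
#' priority); such constraint-forced admissions are flagged in the audit log.
#'
#' @param corr A `shoal_corr` from [metric_correlations()] (or a bare
#'   symmetric correlation matrix plus an `info` argument).
#' @param threshold Collinearity threshold on `|r|` (default 0.2: metrics
#'   with `|r| < 0.2` are considered uncorrelated).
#' @param priority Character vector ordering all metrics, most-preferred
#'   first. Defaults to the canonical five stress metrics (density, CV of
#'   nearest-neighbour distance, wall distance, erratic movement, swimming
#'   height) followed by the rest alphabetically.
#' @param info [metric_info()] metadata; taken from `corr` when present.
#' @param exact Use exhaustive search instead of the greedy pass (only for
#'   small catalogues, <= 15 metrics): among all subsets whose pairwise
#'   `|r|` are below the threshold, picks the one the priority order
#'   prefers lexicographically. Intended as an oracle for testing.
#'
#' @return Object of class `shoal_selection`: list with `retained`
#'   (metric names, in priority order), `threshold`, `forced` (names
#'   admitted only to cover a category), and `audit` (tibble logging every
#'   exclusion / admission decision).
#' @export
select_metrics <- function(corr, threshold = 0.2, priority = NULL, info = NULL,
                           exact = FALSE) {
  if (inherits(corr, "shoal_corr")) {
    info <- info %||% corr$info
    r <- corr$r
  } else {
    r <- corr
  }
  if (is.null(info)) abort("`info` metadata is required")
  nm <- colnames(r)
  if (is.null(nm) || length(nm) == 0L) abort("correlation matrix must have metric names")
  priority <- priority %||% default_priority(nm)
  if (!setequal(priority, nm)) {
    abort("`priority` must contain exactly the metrics of the correlation matrix")
  }

  a <- abs(r[priority, priority, drop = FALSE])
  accepted <- if (exact) {
    if (length(priority) > 15L) abort("exact search limited to <= 15 metrics")
    exact_selection(a, threshold)
  } else {
    greedy_selection(a, threshold)
  }
  retained <- priority[accepted]

  audit <- purrr::map_dfr(seq_along(priority), function(i) {
    if (accepted[i]) {
      tibble(metric = priority[i], action = "accepted",
             against = NA_character_, r = NA_real_, reason = "below threshold")
    } else {
      prior <- which(accepted & seq_along(priority) < i)
      conflicts <- prior[a[i, prior] >= threshold - 1e-12]
      worst <- if (length(conflicts)) conflicts[which.max(a[i, conflicts])] else NA
      tibble(metric = priority[i], action = "excluded",
             against = if (is.na(worst[1])) NA_character_ else priority[worst],
             r = if (is.na(worst[1])) NA_real_ else r[priority[i], priority[worst]],
             reason = "correlated with accepted metric")
    }
  })

  # category coverage: backfill any empty category
  cats <- stats::setNames(info$category, info$name)
  forced <- character(0)
  for (cat in unique(cats[nm])) {
    members <- nm[cats[nm] == cat]
    if (!any(members %in% retained)) {
      max_r <- vapply(members, function(mtr) {
        if (length(retained) == 0L) 0 else max(a[mtr, retained])
      }, numeric(1))
      pick <- members[order(max_r, match(members, priority))][1]
      retained <- c(retained, pick)
      forced <- c(forced, pick)
      audit <- dplyr::bind_rows(audit, tibble(
        metric = pick, action = "forced",
        against = NA_character_, r = max_r[[pick]],
        reason = sprintf("category '%s' would be empty", cat)
      ))
    }
  }
  retained <- priority[priority %in% retained]

  structure(
    list(retained = retained, threshold = threshold, forced = forced,
         priority = priority, audit = audit),
    class = "shoal_selection"
  )
}

# greedy acceptance over the |r| matrix already ordered by priority;
# boundary rule: |r| >= threshold blocks (within numerical tolerance)
greedy_selection <- function(a, threshold = 0.2) {
  n <- nrow(a)
  accepted <- logical(n)
  for (i in seq_len(n)) {
    prior <- which(accepted)
    accepted[i] <- length(prior) == 0L || all(a[i, prior] < threshold - 1e-12)
  }
  accepted
}

# exhaustive oracle: lexicographically-first (by priority order) maximal
# subset with all pairwise |r| below threshold
exact_selection <- function(a, threshold = 0.2) {
  n <- nrow(a)
  best <- NULL
  for (code in seq_len(2^n) - 1L) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1L)))
    idx <- which(sel)
    if (length(idx) > 1L) {
      pairs <- a[idx, idx, drop = FALSE][upper.tri(diag(length(idx)))]
      if (any(pairs >= threshold - 1e-12)) next
    }
    if (is.null(best) || lex_prefer(sel, best)) best <- sel
  }
  # keep only maximal: greedy fill of remaining compatible metrics preserves
  # validity and lexicographic preference, so `best` is already maximal
  best
}

# TRUE when subset x is preferred over y under priority-lexicographic order
lex_prefer <- function(x, y) {
  d <- which(x != y)
  if (length(d) == 0L) return(FALSE)
  x[d[1]]
}

#' @exportS3Method base::print
print.shoal_selection <- function(x, ...) {
  cat(sprintf("<shoal_selection> %d metrics retained at |r| < %g\n",
              length(x$retained), x$threshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$forced) > 0L) {
    cat("  category-forced:", paste(x$forced, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.shoal_selection <- function(x, ...) x$audit
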