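corr_from <- function(r_matrix, names) {
  dimnames(r_matrix) <- list(names, names)
  r_matrix
}

test_that("correlation method follows data kind and normality", {
  set.seed(71)
  gauss1 <- rnorm(300)
  gauss2 <- rnorm(300)
  lnorm <- exp(rnorm(300, sd = 1.5))
  expect_equal(choose_correlation_method(gauss1, gauss2), "pearson")
  expect_equal(choose_correlation_method(lnorm, gauss1), "spearman")
  expect_equal(choose_correlation_method(rbinom(300, 1, 0.5), gauss1,
                                         kind_a = "binary"), "pearson")
})

test_that("correlation matrix matches an independent per-pair computation", {
  set.seed(72)
  n <- 200
  values <- tibble::tibble(
    a = rnorm(n), b = rnorm(n), c = exp(rnorm(n, sd = 1.4)),
    d = rbinom(n, 1, 0.4)
  )
  info <- metric_info(c("a", "b", "c", "d"),
                      c("proximity", "spatial", "social", "behavioural"),
                      c("continuous", "continuous", "continuous", "binary"))
  corr <- metric_correlations(values, info)

  expect_equal(diag(corr$r), rep(1, 4), ignore_attr = TRUE)
  expect_identical(corr$r, t(corr$r))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      meth <- corr$method[i, j]
      expect_equal(corr$r[i, j],
                   cor(values[[i]], values[[j]], method = meth))
    }
  }
  # binary pairs are pearson; the lognormal column forces spearman
  expect_equal(corr$method["a", "d"], "pearson")
  expect_equal(corr$method["a", "c"], "spearman")

  # self-correlation 1 and negation -1
  v2 <- tibble::tibble(a = values$a, neg = -values$a)
  info2 <- metric_info(c("a", "neg"), "proximity", "continuous")
  corr2 <- metric_correlations(v2, info2)
  expect_equal(corr2$r["a", "neg"], -1)
})

test_that("zero-variance metrics are flagged with correlation 0", {
  set.seed(73)
  values <- tibble::tibble(a = rnorm(50), flat = rep(2, 50))
  info <- metric_info(c("a", "flat"), "proximity", "continuous")
  expect_warning(corr <- metric_correlations(values, info), "zero-variance")
  expect_equal(corr$r["a", "flat"], 0)
})

test_that("greedy selection keeps uncorrelated metrics in priority order", {
  nm <- c("m1", "m2", "m3")
  info <- metric_info(nm, "proximity", "continuous")

  ident <- corr_from(diag(3), nm)
  sel <- select_metrics(ident, info = info, priority = nm)
  expect_equal(sel$retained, nm)

  pair <- corr_from(diag(3), nm)
  pair["m1", "m2"] <- pair["m2", "m1"] <- 0.9
  sel2 <- select_metrics(pair, info = info, priority = nm)
  expect_equal(sel2$retained, c("m1", "m3"))
  expect_true("m2" %in% sel2$audit$metric[sel2$audit$action == "excluded"])

  # |r| exactly at the threshold counts as correlated
  boundary <- corr_from(diag(2), c("a", "b"))
  boundary["a", "b"] <- boundary["b", "a"] <- 0.2
  info2 <- metric_info(c("a", "b"), "proximity", "continuous")
  sel3 <- select_metrics(boundary, info = info2, priority = c("a", "b"))
  expect_equal(sel3$retained, "a")
})

test_that("greedy selection equals the exhaustive oracle on constructed matrices", {
  set.seed(74)
  for (rep in 1:40) {
    k <- sample(4:8, 1)
    nm <- paste0("m", seq_len(k))
    r <- matrix(runif(k * k, -1, 1), k)
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    diag(r) <- 1
    r <- corr_from(r, nm)
    info <- metric_info(nm, "proximity", "continuous")
    greedy <- select_metrics(r, info = info, priority = nm)
    exact <- select_metrics(r, info = info, priority = nm, exact = TRUE)
    expect_equal(setdiff(greedy$retained, greedy$forced),
                 setdiff(exact$retained, exact$forced))
    # no retained pair correlated at or above threshold, unless forced
    kept <- setdiff(greedy$retained, greedy$forced)
    if (length(kept) > 1) {
      off <- abs(r[kept, kept])[upper.tri(diag(length(kept)))]
      expect_true(all(off < 0.2))
    }
  }
})

test_that("the retained set is maximal under the greedy order", {
  set.seed(75)
  for (rep in 1:20) {
    k <- 6
    nm <- paste0("m", seq_len(k))
    r <- matrix(runif(k * k, -0.6, 0.6), k)
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    diag(r) <- 1
    r <- corr_from(r, nm)
    info <- metric_info(nm, "proximity", "continuous")
    sel <- select_metrics(r, info = info, priority = nm)
    kept <- setdiff(sel$retained, sel$forced)
    for (m in setdiff(nm, sel$retained)) {
      expect_true(any(abs(r[m, kept]) >= 0.2 - 1e-12))
    }
  }
})

test_that("raising the threshold never shrinks the retained set", {
  set.seed(76)
  k <- 7
  nm <- paste0("m", seq_len(k))
  r <- matrix(runif(k * k, -0.9, 0.9), k)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 1
  r <- corr_from(r, nm)
  info <- metric_info(nm, "proximity", "continuous")
  sizes <- vapply(c(0.1, 0.2, 0.4, 0.6, 0.95), function(th) {
    length(select_metrics(r, threshold = th, info = info, priority = nm)$retained)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("empty categories are backfilled and logged as forced", {
  nm <- c("sociab", "spread", "wallhug")
  info <- metric_info(nm, c("social", "proximity", "spatial"), "continuous")
  r <- corr_from(diag(3), nm)
  r["sociab", "wallhug"] <- r["wallhug", "sociab"] <- 0.8
  sel <- select_metrics(r, info = info, priority = nm)
  expect_true("wallhug" %in% sel$retained)   # only spatial metric
  expect_equal(sel$forced, "wallhug")
  expect_true(any(sel$audit$action == "forced"))
  expect_equal(tidy(sel), sel$audit)
})
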