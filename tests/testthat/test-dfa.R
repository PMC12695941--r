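# hand-coded SSCP pieces for the two-group Fisher cross-check
.sscp_oracle <- function(X, g) {
  g <- as.factor(g)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  list(W = W, m1 = colMeans(X[g == levels(g)[1], , drop = FALSE]),
       m2 = colMeans(X[g == levels(g)[2], , drop = FALSE]))
}

# small gaussian test tables with controllable group separation
sim_groups <- function(n_per, means, sd = 1, p = length(means[[1]]), seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(means), function(g) {
    X <- matrix(rnorm(n_per * p, sd = sd), n_per, p)
    X <- sweep(X, 2, means[[g]], "+")
    data.frame(group = sprintf("g%d", g), X)
  })
  df <- do.call(rbind, rows)
  names(df)[-1] <- paste0("x", seq_len(p))
  df
}

test_that("multicollinearity screen drops exact linear dependences only", {
  set.seed(10)
  df <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  df$dup <- df$a
  expect_setequal(screen_multicollinearity(df, c("a", "b", "c", "dup")),
                  c("a", "b", "c"))        # exactly one of the duplicated pair
  df$s <- df$b + df$c
  kept <- screen_multicollinearity(df, c("a", "b", "c", "s"))
  expect_length(kept, 3L)
  expect_true("a" %in% kept)
  # mutually independent features all retained
  expect_identical(screen_multicollinearity(df, c("a", "b", "c")),
                   c("a", "b", "c"))
  expect_error(screen_multicollinearity(data.frame(a = 1:5), "a", 2), NA)
})

test_that("stepwise selection finds signal and ignores noise", {
  means <- list(c(0, 0, 0, 0), c(10, 0, 0, 0))  # x1 separates by 10 SD
  df <- sim_groups(10, means, seed = 2)
  sel <- stepwise_select(df, "group", paste0("x", 1:4))
  expect_equal(sel[1], "x1")

  # all-noise features rarely clear F-to-enter 3.84
  n_selected <- vapply(1:50, function(s) {
    null <- sim_groups(10, list(rep(0, 5), rep(0, 5)), seed = 100 + s)
    length(stepwise_select(null, "group", paste0("x", 1:5)))
  }, numeric(1))
  expect_gte(mean(n_selected <= 1), 0.9)

  # vanishing thresholds reduce to the full model
  loose <- stepwise_criteria(f_to_enter = 1e-8, f_to_remove = 1e-9)
  sel_all <- stepwise_select(df, "group", paste0("x", 1:4), loose)
  expect_setequal(sel_all, paste0("x", 1:4))
})

test_that("canonical fit: eigen structure, Wilks and chi-squared formulae", {
  df <- sim_groups(12, list(c(0, 0), c(3, 0), c(0, 3)), seed = 3)
  m <- dfa(group ~ x1 + x2, df, stepwise = FALSE, screen = FALSE)
  expect_length(m$eigenvalues, 2L)   # min(p, g-1)
  expect_true(all(diff(m$eigenvalues) <= 0))
  expect_equal(sum(m$explained_variation), 100)
  expect_equal(m$wilks_lambda, rev(cumprod(rev(1 / (1 + m$eigenvalues)))))
  N <- nrow(df)
  expect_equal(m$chi_squared,
               -(N - 1 - (2 + 3) / 2) * log(m$wilks_lambda))
  expect_true(all(m$wilks_lambda > 0 & m$wilks_lambda <= 1))
  expect_equal(sum(m$priors), 1)

  # two groups, one feature: a single function carrying everything
  df2 <- sim_groups(8, list(0, 2), p = 1, seed = 4)
  m2 <- dfa(group ~ x1, df2, stepwise = FALSE, screen = FALSE)
  expect_length(m2$eigenvalues, 1L)
  expect_equal(m2$explained_variation, 100)

  # identical groups: no separation at all
  base <- sim_groups(10, list(c(0, 0)), seed = 5)
  dup <- rbind(transform(base, group = "g1"), transform(base, group = "g2"))
  m3 <- dfa(group ~ x1 + x2, dup, stepwise = FALSE, screen = FALSE)
  expect_lt(max(m3$eigenvalues), 1e-10)
  expect_gt(min(m3$wilks_lambda), 1 - 1e-8)
})

test_that("discriminant scores have unit pooled within-group variance", {
  df <- sim_groups(15, list(c(0, 0, 0), c(2, 1, 0), c(0, 2, 1)), seed = 6)
  m <- dfa(group ~ x1 + x2 + x3, df, stepwise = FALSE, screen = FALSE)
  sc <- m$scores
  g <- m$groups
  for (j in seq_len(ncol(sc))) {
    within <- sum(tapply(sc[, j], g, function(v) sum((v - mean(v))^2)))
    expect_equal(within / (nrow(df) - nlevels(g)), 1, tolerance = 1e-8)
  }
  # centroids are the group means of the scores
  expect_equal(m$group_centroids["g2", 1],
               mean(sc[g == "g2", 1]))
})

test_that("two-group solution is collinear with the Fisher discriminant", {
  for (s in 1:5) {
    df <- sim_groups(9, list(c(0, 0, 0), c(1, 2, -1)), seed = 40 + s)
    m <- dfa(group ~ x1 + x2 + x3, df, stepwise = FALSE, screen = FALSE)
    X <- as.matrix(df[paste0("x", 1:3)])
    s1 <- .sscp_oracle(X, df$group)
    fisher <- solve(s1$W) %*% (s1$m1 - s1$m2)
    v <- m$coefficients[, 1]
    cosang <- abs(sum(fisher * v)) / sqrt(sum(fisher^2) * sum(v^2))
    expect_equal(cosang, 1, tolerance = 1e-8)
  }
})

test_that("classification agrees with MASS::lda under matched priors", {
  df <- sim_groups(20, list(c(0, 0, 0, 0), c(2, 0, 1, 0), c(0, 2, 0, 1)), seed = 7)
  m <- dfa(group ~ x1 + x2 + x3 + x4, df, stepwise = FALSE, screen = FALSE)
  ours <- predict(m)
  ref <- MASS::lda(group ~ x1 + x2 + x3 + x4, df,
                   prior = as.numeric(m$priors))
  theirs <- predict(ref)$class
  expect_equal(as.character(ours), as.character(theirs))

  # uniform priors too
  mu <- dfa(group ~ x1 + x2 + x3 + x4, df, priors = "uniform",
            stepwise = FALSE, screen = FALSE)
  refu <- MASS::lda(group ~ x1 + x2 + x3 + x4, df, prior = rep(1 / 3, 3))
  expect_equal(as.character(predict(mu)), as.character(predict(refu)$class))
})

test_that("LOOCV matches MASS::lda CV=TRUE and is perfect when separable", {
  df <- sim_groups(12, list(c(0, 0), c(2.5, 1), c(-1, 2.5)), seed = 8)
  cv <- classify_loocv(group ~ x1 + x2, df, stepwise = FALSE, screen = FALSE)
  ref <- MASS::lda(group ~ x1 + x2, df, prior = as.numeric(cv$priors), CV = TRUE)
  counts_ref <- table(df$group, ref$class)
  expect_equal(as.vector(cv$confusion_counts), as.vector(counts_ref))
  expect_equal(cv$overall_correct,
               100 * sum(diag(counts_ref)) / nrow(df))

  # far-separated clusters (between/within SD ratio 10) classify perfectly
  far <- sim_groups(8, list(c(0, 0), c(10, 10)), seed = 9)
  cvf <- classify_loocv(group ~ x1 + x2, far, stepwise = FALSE, screen = FALSE)
  expect_equal(cvf$overall_correct, 100)
  expect_true(all(diag(cvf$confusion_pct) == 100))
  expect_equal(sum(cvf$confusion_pct[1, ]), 100)
})

test_that("confusion rows are percentages summing to 100", {
  ft <- desk_meow_features()
  cv <- classify_loocv(ind_formula(ft), ft)
  expect_true(all(abs(rowSums(cv$confusion_pct) - 100) < 0.1))
  expect_equal(sum(cv$per_group_n), nrow(ft))
  expect_equal(cv$chance_level, 12.5)
})

test_that("posterior ties resolve by the larger prior, then label order", {
  df <- data.frame(group = c("A", "A", "B", "B", "B", "B"),
                   x = c(-1, 1, 3, 4, 4, 5))
  m <- dfa(group ~ x, df, stepwise = FALSE, screen = FALSE)
  # the point at 2 is equidistant from both means under pooled variance
  expect_equal(as.character(predict(m, data.frame(x = 2))), "B")  # prior 4/6 wins
  mu <- dfa(group ~ x, df, priors = "uniform", stepwise = FALSE, screen = FALSE)
  expect_equal(as.character(predict(mu, data.frame(x = 2))), "A")  # label order
})

test_that("group sizes below the hold-out minimum are rejected", {
  df <- data.frame(group = c("A", "B", "B", "B"), x = rnorm(4))
  expect_error(classify_loocv(group ~ x, df), "at least 2|below 2")
})

test_that("chance level and the exact binomial test follow their closed forms", {
  expect_equal(chance_level(14), 100 / 14)          # 7.14%
  expect_equal(round(chance_level(14), 2), 7.14)
  expect_equal(round(chance_level(21), 2), 4.76)
  expect_equal(chance_level(8), 12.5)
  expect_equal(round(chance_level(6), 1), 16.7)
  expect_error(chance_level(1), ">= 2")

  expect_equal(binomial_exceeds_chance(10, 10, 0.5), 0.5^10)
  expect_equal(binomial_exceeds_chance(0, 10, 0.3), 1)
  brute <- sum(sapply(7:10, function(i) choose(10, i) * 0.125^i * 0.875^(10 - i)))
  expect_equal(binomial_exceeds_chance(7, 10, 0.125), brute)
  expect_error(binomial_exceeds_chance(11, 10, 0.5), "k_correct")
  expect_error(binomial_exceeds_chance(5, 10, 1), "chance")
})

test_that("empty stepwise selection falls back to priors-only classification", {
  set.seed(123)
  null <- sim_groups(6, list(rep(0, 3), rep(0, 3), rep(0, 3)), seed = 99)
  strict <- stepwise_criteria(f_to_enter = 1e6, f_to_remove = 10)
  cv <- classify_loocv(group ~ x1 + x2 + x3, null, criteria = strict)
  expect_length(cv$selected_features, 0L)
  expect_true(is.finite(cv$overall_correct))
})
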