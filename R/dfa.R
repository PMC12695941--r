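# Stepwise canonical discriminant function analysis: Wilks'-lambda variable
# selection, eigendecomposition of the within/between SSCP pencil, linear
# classification with pooled covariance and group-size priors, leave-one-out
# cross-validation, and exact binomial tests against chance.

#' Stepwise selection criteria
#'
#' Defaults are the conventional thresholds of commercial DFA software:
#' F-to-enter 3.84, F-to-remove 2.71, minimum tolerance 0.001.
#'
#' @param f_to_enter Partial F needed to enter a variable (> `f_to_remove`).
#' @param f_to_remove Partial F below which an entered variable is removed.
#' @param tolerance_min Minimum tolerance (1 - R^2 against the other
#'   features) for the multicollinearity screen, in (0, 1).
#' @param max_steps Step cap guarding against enter/remove cycling.
#' @return A `stepwise_criteria` list.
#' @export
stepwise_criteria <- function(f_to_enter = 3.84, f_to_remove = 2.71,
                              tolerance_min = 0.001, max_steps = 50L) {
  if (!(f_to_enter > f_to_remove && f_to_remove > 0))
    stop("stepwise_criteria: need f_to_enter > f_to_remove > 0")
  if (tolerance_min <= 0 || tolerance_min >= 1)
    stop("stepwise_criteria: tolerance_min must lie in (0, 1)")
  structure(list(f_to_enter = f_to_enter, f_to_remove = f_to_remove,
                 tolerance_min = tolerance_min, max_steps = as.integer(max_steps)),
            class = "stepwise_criteria")
}

# within- and between-group SSCP matrices
.sscp <- function(X, g) {
  g <- droplevels(as.factor(g))
  grand <- colMeans(X)
  levs <- levels(g)
  p <- ncol(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  means <- matrix(NA_real_, length(levs), p,
                  dimnames = list(levs, colnames(X)))
  ng <- integer(length(levs))
  for (i in seq_along(levs)) {
    Xi <- X[g == levs[i], , drop = FALSE]
    mi <- colMeans(Xi)
    means[i, ] <- mi
    ng[i] <- nrow(Xi)
    W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + ng[i] * tcrossprod(mi - grand)
  }
  list(W = W, B = B, T = W + B, means = means, ng = ng, grand = grand,
       levels = levs)
}

# Wilks' lambda det(W)/det(T) on a feature subset
.wilks <- function(X, g, cols) {
  s <- .sscp(X[, cols, drop = FALSE], g)
  dW <- det(s$W)
  dT <- det(s$T)
  if (dT <= 0) return(NA_real_)
  max(0, dW / dT)
}

#' Multicollinearity screen by tolerance
#'
#' Iteratively drops the feature with the lowest tolerance (1 - R^2 of that
#' feature regressed on the remaining ones) while any tolerance falls below
#' `tolerance_min`. Among equally offending features the later-listed one is
#' dropped, so the retained list is order-stable.
#'
#' @param data Data frame containing the features.
#' @param features Character vector of feature column names.
#' @param tolerance_min Threshold in (0, 1).
#' @return Character vector of retained features, in input order.
#' @export
screen_multicollinearity <- function(data, features, tolerance_min = 0.001) {
  keep <- features
  repeat {
    if (length(keep) < 2L) break
    tol <- vapply(seq_along(keep), function(j) {
      # perfect fits are exactly what the screen looks for; silence lm's warning
      fit <- stats::lm(stats::reformulate(keep[-j], response = keep[j]), data = data)
      1 - suppressWarnings(summary(fit))$r.squared
    }, numeric(1))
    bad <- which(tol < tolerance_min)
    if (!length(bad)) break
    worst <- max(bad[tol[bad] <= min(tol[bad]) + 1e-10])  # ties: drop the later one
    keep <- keep[-worst]
  }
  if (!length(keep)) stop("screen_multicollinearity: all features dropped")
  keep
}

#' Stepwise feature selection by Wilks' lambda
#'
#' Classical forward-with-removal procedure: at each step the candidate that
#' most reduces overall Wilks' lambda enters if its partial F meets
#' `f_to_enter`; entered variables whose partial F falls below `f_to_remove`
#' are removed; iteration stops when nothing changes or `max_steps` is hit.
#' The partial F for a variable v given q variables in the model is
#' F = ((Lambda_q / Lambda_{q+v}) - 1) (N - g - q) / (g - 1).
#'
#' @param data Data frame with features and the grouping column.
#' @param group Name of the grouping column.
#' @param features Candidate feature names (already screened).
#' @param criteria A [stepwise_criteria()].
#' @return Character vector of selected features in entry order (possibly
#'   empty when nothing clears `f_to_enter`).
#' @export
stepwise_select <- function(data, group, features,
                            criteria = stepwise_criteria()) {
  X <- as.matrix(data[, features, drop = FALSE])
  g <- droplevels(as.factor(data[[group]]))
  N <- nrow(X)
  ng <- nlevels(g)
  current <- character(0)
  lambda_cur <- 1
  partial_f <- function(lambda_small, lambda_big, q) {
    ((lambda_small / lambda_big) - 1) * (N - ng - q) / (ng - 1)
  }
  for (step in seq_len(criteria$max_steps)) {
    changed <- FALSE
    cand <- setdiff(features, current)
    if (length(cand)) {
      lam <- vapply(cand, function(f) .wilks(X, g, c(current, f)), numeric(1))
      ok <- !is.na(lam)
      if (any(ok)) {
        best <- cand[ok][which.min(lam[ok])]
        lam_best <- min(lam[ok])
        if (partial_f(lambda_cur, lam_best, length(current)) >= criteria$f_to_enter) {
          current <- c(current, best)
          lambda_cur <- lam_best
          changed <- TRUE
        }
      }
    }
    repeat {
      if (length(current) < 2L) break
      lam_wo <- vapply(current, function(f)
        .wilks(X, g, setdiff(current, f)), numeric(1))
      f_rm <- partial_f(lam_wo, lambda_cur, length(current) - 1L)
      drop_idx <- which(f_rm < criteria$f_to_remove)
      if (!length(drop_idx)) break
      victim <- drop_idx[which.min(f_rm[drop_idx])]
      lambda_cur <- lam_wo[victim]
      current <- setdiff(current, current[victim])
      changed <- TRUE
    }
    if (!changed) break
  }
  current
}

#' Fit a discriminant function analysis
#'
#' Canonical discriminant solution on the features selected by the
#' multicollinearity screen and (optionally) Wilks'-lambda stepwise selection.
#' Eigenvalues come from the within/between SSCP pencil (solved through a
#' Cholesky-whitened symmetric eigenproblem); coefficients are scaled to unit
#' pooled within-group variance of the discriminant scores. For each function
#' k the cumulative Wilks' lambda is Lambda_k = prod_{i >= k} 1/(1 + lambda_i)
#' and the chi-squared statistic is -(N - 1 - (p + g)/2) ln Lambda_k.
#'
#' @param formula `group ~ feature1 + feature2 + ...` or `group ~ .` (all
#'   other numeric columns).
#' @param data Data frame of features plus the grouping column.
#' @param priors `"proportional"` (to observed group sizes) or `"uniform"`.
#' @param stepwise Apply stepwise selection? If `FALSE`, all screened
#'   features enter.
#' @param criteria A [stepwise_criteria()].
#' @param screen Apply the multicollinearity screen first?
#' @return An object of class `vocsig_dfa` with components
#'   `selected_features`, `eigenvalues`, `explained_variation`,
#'   `wilks_lambda`, `chi_squared` (with `chi_df`, `chi_p`), `coefficients`,
#'   `grand_mean`, `group_centroids`, `group_means`, `pooled_cov`, `priors`,
#'   `counts`, `scores` (training-call coordinates) and `groups`.
#' @export
dfa <- function(formula, data, priors = c("proportional", "uniform"),
                stepwise = TRUE, criteria = stepwise_criteria(),
                screen = TRUE) {
  priors_mode <- match.arg(priors)
  mf <- stats::model.frame(formula, data = data)
  g <- droplevels(as.factor(mf[[1L]]))
  feats <- names(mf)[-1L]
  num_ok <- vapply(mf[feats], is.numeric, logical(1))
  feats <- feats[num_ok]
  if (length(feats) < 1L) stop("dfa: no numeric features on the right-hand side")
  if (nlevels(g) < 2L) stop("dfa: need at least 2 groups")
  if (any(table(g) < 2L)) stop("dfa: every group needs at least 2 rows")
  if (anyNA(mf[feats])) stop("dfa: missing feature values are not allowed")
  work <- data.frame(.group = g, mf[feats], check.names = FALSE)
  if (screen) feats <- screen_multicollinearity(work, feats, criteria$tolerance_min)
  selected <- if (stepwise) stepwise_select(work, ".group", feats, criteria) else feats
  fit <- .fit_canonical(as.matrix(work[, selected, drop = FALSE]), g, priors_mode,
                        allow_empty = length(selected) == 0L)
  fit$selected_features <- selected
  fit$screened_features <- feats
  fit$groups <- g
  fit$priors_mode <- priors_mode
  fit$criteria <- criteria
  fit$data <- work
  fit$call <- match.call()
  class(fit) <- "vocsig_dfa"
  fit
}

.fit_canonical <- function(X, g, priors_mode, allow_empty = FALSE) {
  g <- droplevels(as.factor(g))
  N <- length(g)
  ng_lev <- nlevels(g)
  priors <- if (priors_mode == "proportional") as.vector(table(g)) / N
            else rep(1 / ng_lev, ng_lev)
  names(priors) <- levels(g)
  if (ncol(X) == 0L) {
    if (!allow_empty) stop("dfa: no features selected")
    return(list(eigenvalues = numeric(0), explained_variation = numeric(0),
                wilks_lambda = numeric(0), chi_squared = numeric(0),
                chi_df = integer(0), chi_p = numeric(0),
                coefficients = matrix(0, 0, 0), grand_mean = numeric(0),
                group_centroids = matrix(0, ng_lev, 0, dimnames = list(levels(g), NULL)),
                group_means = matrix(0, ng_lev, 0, dimnames = list(levels(g), NULL)),
                pooled_cov = matrix(0, 0, 0), priors = priors,
                counts = table(g), n = N,
                scores = matrix(0, N, 0)))
  }
  p <- ncol(X)
  s <- .sscp(X, g)
  L <- tryCatch(t(chol(s$W)), error = function(e)
    stop("dfa: singular within-group covariance on features [",
         paste(colnames(X), collapse = ", "), "]"))
  C <- forwardsolve(L, t(forwardsolve(L, s$B)))
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  m <- min(p, ng_lev - 1L)
  lambda <- pmax(0, e$values[seq_len(m)])
  V <- backsolve(t(L), e$vectors[, seq_len(m), drop = FALSE])
  V <- V * sqrt(N - ng_lev)                   # unit pooled within-group score variance
  for (j in seq_len(ncol(V))) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  dimnames(V) <- list(colnames(X), paste0("DF", seq_len(m)))
  explained <- explained_variation(lambda)
  wilks <- rev(cumprod(rev(1 / (1 + lambda))))
  chi_fac <- N - 1 - (p + ng_lev) / 2
  chi_sq <- -chi_fac * log(wilks)
  chi_df <- (p - seq_len(m) + 1L) * (ng_lev - seq_len(m) + 1L)
  scores <- sweep(X, 2, s$grand) %*% V
  centroids <- apply(scores, 2, function(col) tapply(col, g, mean))
  centroids <- matrix(centroids, nrow = ng_lev,
                      dimnames = list(levels(g), colnames(V)))
  list(eigenvalues = lambda, explained_variation = explained,
       wilks_lambda = wilks, chi_squared = chi_sq, chi_df = chi_df,
       chi_p = stats::pchisq(chi_sq, chi_df, lower.tail = FALSE),
       coefficients = V, grand_mean = s$grand,
       group_centroids = centroids, group_means = s$means,
       pooled_cov = s$W / (N - ng_lev), priors = priors,
       counts = table(g), n = N, scores = scores)
}

# linear discriminant classification with pooled covariance; ties broken by
# larger prior, then by group label order
.classify_linear <- function(X, means, pooled_cov, priors) {
  Sinv <- solve(pooled_cov)
  A <- means %*% Sinv                           # g x p
  const <- -0.5 * rowSums(A * means) + log(priors)
  d <- X %*% t(A) + matrix(const, nrow(X), length(priors), byrow = TRUE)
  post <- exp(d - apply(d, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- rownames(means)
  cls <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    mx <- max(d[i, ])
    tie <- which(d[i, ] >= mx - 1e-12 * max(1, abs(mx)))
    if (length(tie) > 1L) tie <- tie[order(-priors[tie], tie)][1L]
    cls[i] <- rownames(means)[tie]
  }
  list(class = factor(cls, levels = rownames(means)), posterior = post)
}

#' @export
print.vocsig_dfa <- function(x, ...) {
  cat("Discriminant function analysis\n")
  cat(sprintf("  %d groups, %d calls, priors: %s\n",
              nlevels(x$groups), x$n, x$priors_mode))
  cat("  selected features:",
      if (length(x$selected_features)) paste(x$selected_features, collapse = ", ")
      else "(none cleared F-to-enter)", "\n")
  if (length(x$eigenvalues)) {
    tab <- rbind(Eigenvalue = round(x$eigenvalues, 2),
                 `Explained variation [%]` = round(x$explained_variation, 1),
                 `Wilks' Lambda` = round(x$wilks_lambda, 2),
                 `Chi-squared` = round(x$chi_squared, 2))
    colnames(tab) <- paste0("DF", seq_along(x$eigenvalues))
    print(tab)
  }
  invisible(x)
}

#' @export
summary.vocsig_dfa <- function(object, ...) {
  out <- list(model_fit = data.frame(
                fn = seq_along(object$eigenvalues),
                eigenvalue = object$eigenvalues,
                explained_variation_pct = object$explained_variation,
                wilks_lambda = object$wilks_lambda,
                chi_squared = object$chi_squared,
                df = object$chi_df, p = object$chi_p),
              selected_features = object$selected_features,
              priors = object$priors, counts = object$counts)
  class(out) <- "summary.vocsig_dfa"
  out
}

#' @export
print.summary.vocsig_dfa <- function(x, ...) {
  print(x$model_fit, digits = 4)
  cat("Selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.vocsig_dfa <- function(object, ...) object$coefficients

#' Predict from a fitted DFA
#'
#' @param object A [dfa()] fit.
#' @param newdata Data frame containing the selected feature columns
#'   (defaults to the training data).
#' @param type `"class"` (posterior-maximal group), `"posterior"`, or
#'   `"scores"` (discriminant-function coordinates).
#' @param ... Unused.
#' @return Factor, posterior matrix, or score matrix according to `type`.
#' @export
predict.vocsig_dfa <- function(object, newdata = NULL,
                               type = c("class", "posterior", "scores"), ...) {
  type <- match.arg(type)
  df <- if (is.null(newdata)) object$data else newdata
  if (length(object$selected_features) == 0L) {
    if (type == "scores") return(matrix(0, nrow(df), 0))
    post <- matrix(object$priors, nrow(df), length(object$priors), byrow = TRUE,
                   dimnames = list(NULL, names(object$priors)))
    if (type == "posterior") return(post)
    win <- names(object$priors)[order(-object$priors)][1L]
    return(factor(rep(win, nrow(df)), levels = levels(object$groups)))
  }
  X <- as.matrix(df[, object$selected_features, drop = FALSE])
  if (type == "scores")
    return(sweep(X, 2, object$grand_mean) %*% object$coefficients)
  res <- .classify_linear(X, object$group_means, object$pooled_cov, object$priors)
  if (type == "posterior") res$posterior else res$class
}

#' @export
plot.vocsig_dfa <- function(x, ...) {
  if (length(x$eigenvalues) < 2L) stop("plot.vocsig_dfa: need at least 2 functions")
  sc <- x$scores[, 1:2]
  cols <- grDevices::rainbow(nlevels(x$groups))[as.integer(x$groups)]
  graphics::plot(sc, col = cols, pch = as.integer(x$groups) %% 25,
                 xlab = sprintf("DF1 (%.1f%%)", x$explained_variation[1]),
                 ylab = sprintf("DF2 (%.1f%%)", x$explained_variation[2]), ...)
  graphics::points(x$group_centroids[, 1:2], pch = 8, cex = 1.5)
  invisible(x)
}

#' Percent variation explained per discriminant function
#'
#' @param eigenvalues Non-negative eigenvalues of a discriminant solution.
#' @return 100 * eigenvalue / sum(eigenvalues) for each function.
#' @export
explained_variation <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stop("explained_variation: eigenvalues must be >= 0")
  if (sum(eigenvalues) == 0) return(rep(NA_real_, length(eigenvalues)))
  100 * eigenvalues / sum(eigenvalues)
}

#' Chance classification level
#'
#' @param n_groups Number of groups (>= 2).
#' @return Expected correct-classification percentage under random
#'   assignment, 100 / n_groups.
#' @export
chance_level <- function(n_groups) {
  if (!is.numeric(n_groups) || n_groups < 2) stop("chance_level: n_groups must be >= 2")
  100 / n_groups
}

#' Exact one-sided binomial test against chance
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, chance): is the
#' observed classification success greater than expected by chance?
#'
#' @param k_correct Number of correctly classified calls.
#' @param n_total Total number of calls.
#' @param chance Chance success probability in (0, 1).
#' @return The exact p-value.
#' @export
binomial_exceeds_chance <- function(k_correct, n_total, chance) {
  if (k_correct < 0 || k_correct > n_total)
    stop("binomial_exceeds_chance: need 0 <= k_correct <= n_total")
  if (chance <= 0 || chance >= 1)
    stop("binomial_exceeds_chance: chance must lie in (0, 1)")
  stats::pbinom(k_correct - 1, n_total, chance, lower.tail = FALSE)
}

#' Leave-one-out cross-validated classification
#'
#' Each call is classified by a discriminant model refitted on the remaining
#' N - 1 calls. By default the feature selection of the full-data fit is held
#' fixed across folds (the standard leave-one-out classification of DFA
#' software); `nested = TRUE` re-runs screening and stepwise selection inside
#' every fold. Priors are computed once from the full group sizes.
#'
#' @param formula,data,priors,criteria,screen As in [dfa()].
#' @param stepwise Apply stepwise selection (on the full data unless nested)?
#' @param nested Re-select features within each fold?
#' @return An object of class `vocsig_loocv`: confusion matrix in row
#'   percentages and counts, per-group n, `overall_correct` (%),
#'   `chance_level` (%), `binomial_p`, and the selected features.
#' @export
classify_loocv <- function(formula, data, priors = c("proportional", "uniform"),
                           criteria = stepwise_criteria(), stepwise = TRUE,
                           screen = TRUE, nested = FALSE) {
  priors_mode <- match.arg(priors)
  mf <- stats::model.frame(formula, data = data)
  g <- droplevels(as.factor(mf[[1L]]))
  feats_all <- names(mf)[-1L]
  work <- data.frame(.group = g, mf[feats_all], check.names = FALSE)
  N <- nrow(work)
  if (any(table(g) < 2L))
    stop("classify_loocv: a group would be reduced below 2 members during hold-out")
  priors_vec <- if (priors_mode == "proportional") as.vector(table(g)) / N
                else rep(1 / nlevels(g), nlevels(g))
  names(priors_vec) <- levels(g)

  select_on <- function(d) {
    f <- feats_all
    if (screen) f <- screen_multicollinearity(d, f, criteria$tolerance_min)
    if (stepwise) f <- stepwise_select(d, ".group", f, criteria) else f
  }
  selected_full <- select_on(work)
  predicted <- factor(rep(NA_character_, N), levels = levels(g))
  for (i in seq_len(N)) {
    train <- work[-i, , drop = FALSE]
    sel <- if (nested) select_on(train) else selected_full
    if (length(sel) == 0L) {
      predicted[i] <- names(priors_vec)[order(-priors_vec)][1L]
      next
    }
    s <- .sscp(as.matrix(train[, sel, drop = FALSE]), train$.group)
    pooled <- s$W / (nrow(train) - nlevels(g))
    Xi <- matrix(as.numeric(work[i, sel]), 1L, dimnames = list(NULL, sel))
    predicted[i] <- .classify_linear(Xi, s$means, pooled, priors_vec)$class
  }
  counts <- table(truth = g, predicted = predicted)
  pct <- 100 * counts / rowSums(counts)
  k_correct <- sum(diag(counts))
  res <- list(confusion_pct = pct, confusion_counts = counts,
              per_group_n = table(g),
              overall_correct = 100 * k_correct / N,
              chance_level = chance_level(nlevels(g)),
              binomial_p = binomial_exceeds_chance(k_correct, N, 1 / nlevels(g)),
              selected_features = selected_full, priors = priors_vec,
              n = N, nested = nested)
  class(res) <- "vocsig_loocv"
  res
}

#' @export
print.vocsig_loocv <- function(x, ...) {
  cat(sprintf("Leave-one-out classification: %.1f%% correct (chance %.2f%%, exact binomial p %s)\n",
              x$overall_correct, x$chance_level, format.pval(x$binomial_p, digits = 3)))
  cat("Selected features:",
      if (length(x$selected_features)) paste(x$selected_features, collapse = ", ")
      else "(none)", "\n")
  cat("Confusion matrix (row %):\n")
  print(round(x$confusion_pct, 1))
  invisible(x)
}
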