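# Within-group dispersion in discriminant signal space: per-call Euclidean
# distance to the own-group centroid, a one-way ANOVA on those distances with
# partial eta squared, and post-hoc pairwise contrasts.

#' Project calls into discriminant signal space
#'
#' Maps each call to its scores on the first `n_functions` discriminant
#' functions of a fitted model.
#'
#' @param model A [dfa()] fit.
#' @param data Data frame with the model's selected feature columns
#'   (defaults to the training data).
#' @param group Name of the grouping column used for centroids (defaults to
#'   the model's grouping).
#' @param n_functions `"all"` or an integer count of leading functions.
#' @return An object of class `signal_space`: `coordinates` (calls x
#'   functions), `group_labels`, `n_functions_used`.
#' @export
project_to_signal_space <- function(model, data = NULL, group = NULL,
                                    n_functions = "all") {
  avail <- length(model$eigenvalues)
  if (avail < 1L) stop("project_to_signal_space: model has no discriminant functions")
  k <- if (identical(n_functions, "all")) avail else as.integer(n_functions)
  if (k > avail)
    stop("project_to_signal_space: n_functions (", k, ") exceeds available functions (", avail, ")")
  if (k < 1L) stop("project_to_signal_space: n_functions must be >= 1")
  sc <- stats::predict(model, newdata = data, type = "scores")[, seq_len(k), drop = FALSE]
  labels <- if (is.null(data)) model$groups else droplevels(as.factor(data[[group]]))
  structure(list(coordinates = sc, group_labels = labels, n_functions_used = k),
            class = "signal_space")
}

#' Distances to own-group centroids
#'
#' Centroids are the mean coordinates of each group in the projected data
#' (not the model's training centroids), so held-out projections work too.
#'
#' @param space A [project_to_signal_space()] result.
#' @return List with `distances` (per call), `group_mean_distance` (per
#'   group) and `centroids`.
#' @export
dispersion_distances <- function(space) {
  g <- droplevels(as.factor(space$group_labels))
  if (any(table(g) < 2L))
    stop("dispersion_distances: every group needs at least 2 calls")
  X <- space$coordinates
  cent <- apply(X, 2, function(col) tapply(col, g, mean))
  cent <- matrix(cent, nrow = nlevels(g), dimnames = list(levels(g), colnames(X)))
  d <- sqrt(rowSums((X - cent[as.integer(g), , drop = FALSE])^2))
  list(distances = d, group_labels = g,
       group_mean_distance = tapply(d, g, mean), centroids = cent)
}

#' ANOVA on dispersion distances
#'
#' One-way ANOVA of the per-call centroid distances on the group factor, with
#' partial eta squared (SS_between / (SS_between + SS_within)) and post-hoc
#' pairwise contrasts (Tukey HSD by default, Bonferroni-adjusted pairwise t
#' tests by flag).
#'
#' @param distances Numeric vector of per-call distances.
#' @param group_labels Factor of group memberships.
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @return An object of class `vocsig_dispersion` with `anova_F`,
#'   `df_between`, `df_within`, `p_value`, `partial_eta_squared`,
#'   `group_mean_distance` and the `posthoc` table (`pair`, `p_adjusted`).
#' @export
dispersion_anova <- function(distances, group_labels,
                             posthoc = c("tukey", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  g <- droplevels(as.factor(group_labels))
  if (nlevels(g) < 2L) stop("dispersion_anova: need at least 2 groups")
  if (any(table(g) < 2L)) stop("dispersion_anova: every group needs at least 2 calls")
  if (stats::var(distances) == 0)
    stop("dispersion_anova: zero total variance in distances")
  fit <- stats::aov(distances ~ g)
  a <- stats::anova(fit)
  ssb <- a[["Sum Sq"]][1L]
  ssw <- a[["Sum Sq"]][2L]
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$g
    post <- data.frame(pair = rownames(tk), p_adjusted = tk[, "p adj"],
                       row.names = NULL, stringsAsFactors = FALSE)
  } else {
    pt <- stats::pairwise.t.test(distances, g, p.adjust.method = "bonferroni")$p.value
    pairs <- which(!is.na(pt), arr.ind = TRUE)
    post <- data.frame(pair = paste(rownames(pt)[pairs[, 1]],
                                    colnames(pt)[pairs[, 2]], sep = "-"),
                       p_adjusted = pt[pairs], stringsAsFactors = FALSE)
  }
  res <- list(anova_F = a[["F value"]][1L],
              df_between = a[["Df"]][1L], df_within = a[["Df"]][2L],
              p_value = a[["Pr(>F)"]][1L],
              partial_eta_squared = ssb / (ssb + ssw),
              group_mean_distance = tapply(distances, g, mean),
              distances = distances, group_labels = g,
              posthoc = post, posthoc_method = posthoc)
  class(res) <- "vocsig_dispersion"
  res
}

#' Within-group dispersion analysis of a fitted DFA
#'
#' Convenience chain: project into signal space, compute centroid distances,
#' run the dispersion ANOVA.
#'
#' @inheritParams project_to_signal_space
#' @inheritParams dispersion_anova
#' @return A `vocsig_dispersion` object (see [dispersion_anova()]), with the
#'   per-call distances attached.
#' @export
dispersion <- function(model, data = NULL, group = NULL, n_functions = "all",
                       posthoc = c("tukey", "bonferroni")) {
  space <- project_to_signal_space(model, data, group, n_functions)
  dd <- dispersion_distances(space)
  out <- dispersion_anova(dd$distances, dd$group_labels, posthoc)
  out$n_functions_used <- space$n_functions_used
  out
}

#' @export
print.vocsig_dispersion <- function(x, ...) {
  cat(sprintf("Dispersion ANOVA: F(%d, %d) = %.3f, p = %s, partial eta^2 = %.2f\n",
              x$df_between, x$df_within, x$anova_F,
              format.pval(x$p_value, digits = 3), x$partial_eta_squared))
  cat("Group mean centroid distances:\n")
  print(round(x$group_mean_distance, 3))
  cat(sprintf("Post-hoc (%s):\n", x$posthoc_method))
  print(transform(x$posthoc, p_adjusted = signif(p_adjusted, 3)))
  invisible(x)
}

#' @export
plot.vocsig_dispersion <- function(x, ...) {
  graphics::boxplot(split(x$distances, x$group_labels),
                    ylab = "Distance to group centroid", ...)
  invisible(x)
}
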