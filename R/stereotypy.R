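# Beecher's stereotypy/information index: per-parameter one-way F statistics
# with individual identity as the factor, converted to bits per signal via
# H_s = log2 sqrt((F + n - 1)/n) and summed over parameters; 2^H_S is the
# number of individuals the signal could encode.

#' Per-parameter F statistics for individual identity
#'
#' For each feature, the univariate one-way ANOVA F (between/within
#' mean-square ratio) with the grouping factor as the single explanatory
#' variable, df_between = g - 1, df_within = N - g. With a single factor,
#' type II sums of squares coincide with type I, so a plain `anova(lm())`
#' fit is used.
#'
#' @param data Data frame of features plus the grouping column.
#' @param group Name of the grouping column (e.g. `"individual_id"`).
#' @param features Feature column names (default: the MFCC columns).
#' @return Named numeric vector of F statistics with attributes `df_between`
#'   and `df_within`.
#' @export
per_parameter_F <- function(data, group, features = mfcc_columns(data)) {
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) < 2L) stop("per_parameter_F: need at least 2 groups")
  if (any(table(g) < 2L)) stop("per_parameter_F: every group needs at least 2 rows")
  Fs <- vapply(features, function(f) {
    within_var <- tapply(data[[f]], g, stats::var)
    if (all(within_var < .Machine$double.eps * max(1, abs(mean(data[[f]])))^2))
      stop("per_parameter_F: zero within-group variance for feature '", f, "'")
    a <- stats::anova(stats::lm(data[[f]] ~ g))
    a[["F value"]][1L]
  }, numeric(1))
  attr(Fs, "df_between") <- nlevels(g) - 1L
  attr(Fs, "df_within") <- length(g) - nlevels(g)
  Fs
}

#' Stereotypy index of one parameter
#'
#' H_s = log2 sqrt((F + n_bar - 1) / n_bar) bits, where n_bar is the mean
#' number of calls per individual. F below 1 (less between- than
#' within-individual variance) would give negative bits; such contributions
#' are clipped to 0 since information cannot be negative.
#'
#' @param F One-way ANOVA F statistic (>= 0); vectorized.
#' @param n_bar Mean calls per individual (>= 1).
#' @return Bits per signal contributed by the parameter.
#' @export
stereotypy_index <- function(F, n_bar) {
  if (any(F < 0)) stop("stereotypy_index: F must be >= 0")
  if (n_bar < 1) stop("stereotypy_index: n_bar must be >= 1")
  pmax(0, log2(sqrt((F + n_bar - 1) / n_bar)))
}

#' Total encoded information
#'
#' Sum of the per-parameter H_s contributions (no decorrelation across
#' parameters; the contributions of the raw coefficients are added directly).
#'
#' @param per_parameter_Hs Numeric vector of per-parameter bits (missing
#'   entries count as 0).
#' @return Total H_S in bits.
#' @export
total_information <- function(per_parameter_Hs) {
  if (!length(per_parameter_Hs)) stop("total_information: empty contribution set")
  sum(per_parameter_Hs, na.rm = TRUE)
}

#' Number of encodable individuals
#'
#' @param total_Hs Total signature information in bits (>= 0).
#' @return 2^total_Hs, the number of unique individuals distinguishable with
#'   that many binary decisions.
#' @export
capacity <- function(total_Hs) {
  if (any(total_Hs < 0)) stop("capacity: total_Hs must be >= 0")
  2^total_Hs
}

#' Mean number of calls per individual
#'
#' @param data Data frame with one row per call.
#' @param group Name of the individual-identity column.
#' @return Total calls divided by number of individuals.
#' @export
mean_calls_per_individual <- function(data, group = "individual_id") {
  if (!nrow(data)) stop("mean_calls_per_individual: empty table")
  nrow(data) / length(unique(data[[group]]))
}

#' Signature information of a call set
#'
#' Computes per-parameter F statistics for individual identity, converts each
#' to bits via [stereotypy_index()], sums them to the total signature
#' information H_S, and reports the capacity 2^H_S. A PCA-decorrelated
#' variant (contributions computed on principal-component scores of the
#' features) is available behind `decorrelate = TRUE`; the default sums the
#' raw per-coefficient contributions.
#'
#' @param data Data frame of per-call features.
#' @param group Individual-identity column name.
#' @param features Feature columns (default: the MFCC columns).
#' @param n_bar Mean calls per individual; computed from the data when `NULL`.
#' @param decorrelate Compute contributions on PCA scores instead of raw
#'   features (off by default).
#' @return An object of class `vocsig_stereotypy` with `per_parameter_F`,
#'   `per_parameter_Hs`, `n_bar`, `total_Hs` and `capacity`.
#' @export
stereotypy <- function(data, group = "individual_id",
                       features = mfcc_columns(data), n_bar = NULL,
                       decorrelate = FALSE) {
  if (is.null(n_bar)) n_bar <- mean_calls_per_individual(data, group)
  work <- data
  feats <- features
  if (decorrelate) {
    pc <- stats::prcomp(data[, features, drop = FALSE], center = TRUE, scale. = FALSE)
    scores <- as.data.frame(pc$x)
    names(scores) <- paste0("pc", seq_along(scores))
    work <- cbind(scores, data[group])
    feats <- names(scores)
  }
  Fs <- per_parameter_F(work, group, feats)
  hs <- stereotypy_index(Fs, n_bar)
  total <- total_information(hs)
  res <- list(per_parameter_F = Fs, per_parameter_Hs = hs,
              df_between = attr(Fs, "df_between"),
              df_within = attr(Fs, "df_within"),
              n_bar = n_bar, total_Hs = total, capacity = capacity(total),
              decorrelated = decorrelate)
  class(res) <- "vocsig_stereotypy"
  res
}

#' @export
print.vocsig_stereotypy <- function(x, ...) {
  cat(sprintf("Signature information (n_bar = %.2f calls/individual%s)\n",
              x$n_bar, if (x$decorrelated) ", PCA-decorrelated" else ""))
  tab <- data.frame(F = round(unclass(x$per_parameter_F), 2),
                    Hs_bits = round(x$per_parameter_Hs, 3))
  print(tab)
  cat(sprintf("Total H_S = %.2f bits; capacity 2^H_S = %.2f individuals\n",
              x$total_Hs, x$capacity))
  invisible(x)
}

#' Report table for a stereotypy result
#'
#' @param x A [stereotypy()] result.
#' @return Data frame `feature, F, df_between, df_within, Hs_bits` with footer
#'   rows `total_Hs_bits` and `capacity_individuals`.
#' @export
stereotypy_report <- function(x) {
  tab <- data.frame(feature = names(x$per_parameter_F),
                    F = as.numeric(x$per_parameter_F),
                    df_between = x$df_between, df_within = x$df_within,
                    Hs_bits = as.numeric(x$per_parameter_Hs),
                    stringsAsFactors = FALSE)
  rbind(tab,
        data.frame(feature = "total_Hs_bits", F = NA, df_between = NA,
                   df_within = NA, Hs_bits = x$total_Hs),
        data.frame(feature = "capacity_individuals", F = NA, df_between = NA,
                   df_within = NA, Hs_bits = x$capacity))
}
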