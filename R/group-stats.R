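#' One-way ANOVA with Tukey HSD and Benjamini-Hochberg correction
#'
#' The group-comparison workhorse for survey responses (total carbon
#' emission, ebullition contribution, alpha_C, ...) across grassland
#' types: a one-way ANOVA, Tukey's HSD pairwise comparisons via the
#' studentized range, a Benjamini-Hochberg adjustment across the pairwise
#' family, and a compact-letter display at `alpha`. When the residuals
#' reject Shapiro-Wilk normality at 0.05 (and all values are positive),
#' the response is log10-transformed first (`log_transform = "auto"`).
#'
#' With every observation identical in every group the ANOVA is
#' degenerate; the overall p-value is reported as 1 (no evidence of
#' differences).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor); at least 2 groups with
#'   at least 2 observations each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param log_transform `"auto"` (default), `"never"` or `"always"`.
#' @return An object of class `group_comparison`: list with `group_stats`
#'   (n, mean, se per group), `f_statistic`, `p_value`, `pairwise` (one
#'   row per pair: difference, Tukey p, BH-adjusted p), `letters` (compact
#'   letter display), `log_transformed`, `alpha`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(10, 0), rnorm(10, 3), rnorm(10, 3))
#' anova_tukey(x, rep(c("AS", "AM", "SM"), each = 10))
#' @export
anova_tukey <- function(values, groups, alpha = 0.05,
                        log_transform = c("auto", "never", "always")) {
  log_transform <- match.arg(log_transform)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")

  logged <- FALSE
  if (log_transform == "always" ||
      (log_transform == "auto" && all(values > 0) &&
       length(values) >= 3 && length(values) <= 5000)) {
    res <- stats::residuals(stats::lm(values ~ groups))
    wants_log <- log_transform == "always" ||
      (stats::sd(res) > 0 && stats::shapiro.test(res)$p.value < 0.05)
    if (wants_log && all(values > 0)) {
      values <- log10(values)
      logged <- TRUE
    }
  }

  means <- tapply(values, groups, mean)
  resid_scale <- max(abs(values - means[groups]))
  degenerate <- resid_scale <= 1e-10 * max(1, max(abs(values)))

  if (degenerate) {
    # zero within-group variance: equal means -> no evidence; unequal -> certain
    lv <- levels(groups)
    cmb <- utils::combn(rev(lv), 2)
    pairs <- paste(cmb[1, ], cmb[2, ], sep = "-")
    same <- abs(means[cmb[1, ]] - means[cmb[2, ]]) == 0
    if (all(same)) { f_stat <- 0; p_val <- 1 } else { f_stat <- Inf; p_val <- 0 }
    p_tukey <- ifelse(same, 1, 0)
    diffs <- unname(means[cmb[1, ]] - means[cmb[2, ]])
  } else {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    f_stat <- tab[["F value"]][1]
    p_val <- tab[["Pr(>F)"]][1]
    hsd <- stats::TukeyHSD(fit)$groups
    pairs <- rownames(hsd)
    p_tukey <- hsd[, "p adj"]
    diffs <- hsd[, "diff"]
  }
  p_bh <- stats::p.adjust(p_tukey, method = "BH")

  gs <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(values, groups, mean)),
    se = as.numeric(tapply(values, groups, stats::sd) /
                      sqrt(table(groups)))
  )
  letters <- compact_letters(levels(groups), pairs, p_tukey < alpha)

  structure(
    list(group_stats = gs, f_statistic = f_stat, p_value = p_val,
         pairwise = data.frame(pair = pairs, diff = unname(diffs),
                               p_tukey = unname(p_tukey),
                               p_bh = unname(p_bh), row.names = NULL),
         letters = letters, log_transformed = logged, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F = %.3g, p = %.3g\n",
              if (x$log_transformed) " (log10 response)" else "",
              x$f_statistic, x$p_value))
  gs <- x$group_stats
  gs$letters <- x$letters[gs$group]
  print(gs, row.names = FALSE)
  cat("Tukey HSD pairwise comparisons (BH-adjusted in p_bh):\n")
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

# Insert-absorb compact letter display from a significance pattern.
# sig[i] is TRUE when the groups of pairs[i] ("a-b") differ; assumes group
# labels themselves contain no "-".
#' @keywords internal
compact_letters <- function(group_levels, pairs, sig) {
  cols <- list(group_levels)  # start: one column holding all groups
  split_pairs <- strsplit(pairs, "-", fixed = TRUE)
  for (i in which(sig)) {
    a <- split_pairs[[i]][1]; b <- split_pairs[[i]][2]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns contained in (or duplicating) another
    drop <- rep(FALSE, length(new_cols))
    for (k in seq_along(new_cols)) {
      for (l in seq_along(new_cols)) {
        if (k == l || drop[k] || drop[l]) next
        if (all(new_cols[[k]] %in% new_cols[[l]]) &&
            (length(new_cols[[k]]) < length(new_cols[[l]]) || l < k)) {
          drop[k] <- TRUE
        }
      }
    }
    cols <- new_cols[!drop]
  }
  out <- vapply(group_levels, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col,
                                logical(1)))], collapse = "")
  }, character(1))
  names(out) <- group_levels
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values;
#' adjusted values are monotone in the raw values and capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Boxplot outlier screening
#'
#' Flags values outside the Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`,
#' with quartiles taken as Tukey hinges (the convention of the classical
#' boxplot procedure). With fewer than 4 values screening is skipped with
#' a warning and nothing is flagged.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector, `TRUE` where flagged as an outlier.
#' @examples
#' boxplot_outliers(c(1, 2, 3, 4, 100))
#' @export
boxplot_outliers <- function(values, k = 1.5) {
  flagged <- rep(FALSE, length(values))
  finite <- is.finite(values)
  if (sum(finite) < 4) {
    warning("fewer than 4 values: outlier screening skipped")
    return(flagged)
  }
  fn <- stats::fivenum(values[finite])  # Tukey hinges
  iqr <- fn[4] - fn[2]
  lo <- fn[2] - k * iqr
  hi <- fn[4] + k * iqr
  flagged[finite] <- values[finite] < lo | values[finite] > hi
  flagged
}
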