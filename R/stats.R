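#' One-way ANOVA with LSD post-hoc tests and Hochberg correction
#'
#' Compares group means by one-way analysis of variance, then performs all
#' pairwise Least Significant Difference t-tests (pooled within-group
#' variance, the ANOVA residual mean square) and applies the Hochberg
#' step-up adjustment to the pairwise P-values. Homogeneous subsets are
#' formed by greedy merging of mean-ordered groups whose pairwise adjusted
#' P-values all exceed `alpha`.
#'
#' @param data A data frame.
#' @param value Name of the numeric column to compare (string).
#' @param group Name of the grouping column (string).
#' @param alpha Significance level for the subsets.
#' @return An object of class `group_comparison`: `groups` (per-group n,
#'   mean, SD), `anova` (F, df, P), `pairwise` (raw and adjusted P per pair),
#'   `subsets` (list of character vectors), `degenerate` (groups with fewer
#'   than 2 values, reported rather than dropped silently).
#' @export
group_anova <- function(data, value, group = "group", alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  counts <- table(g)
  degenerate <- names(counts)[counts < 2]
  keep <- !(g %in% degenerate)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("need at least two groups with >= 2 values each")

  means <- tapply(y, g, mean)
  sds <- tapply(y, g, sd)
  ns <- tapply(y, g, length)
  k <- nlevels(g); N <- length(y)
  ss_between <- sum(ns * (means - mean(y))^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1; df2 <- N - k
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  Fstat <- ms_between / ms_within
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)

  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  pw <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = as.numeric(means[pairs[1, ]] - means[pairs[2, ]]),
    se = as.numeric(sqrt(ms_within * (1 / ns[pairs[1, ]] +
                                        1 / ns[pairs[2, ]])))
  )
  pw$t <- pw$diff / pw$se
  pw$df <- df2
  pw$p = 2 * pt(abs(pw$t), df2, lower.tail = FALSE)
  pw$p_adj <- p.adjust(pw$p, method = "hochberg")

  subsets <- .homogeneous_subsets(lv[order(means[lv])], pw, alpha)

  structure(list(
    groups = tibble(group = lv, n = as.integer(ns[lv]),
                    mean = as.numeric(means[lv]), sd = as.numeric(sds[lv])),
    anova = tibble(F = Fstat, df1 = df1, df2 = df2, p = pval,
                   ms_between = ms_between, ms_within = ms_within),
    pairwise = as_tibble(pw),
    subsets = subsets,
    degenerate = degenerate,
    alpha = alpha,
    adjustment = "hochberg"
  ), class = "group_comparison")
}

# Greedy construction: walk groups in mean order, extend the current subset
# while every new pairwise adjusted P stays >= alpha.
.homogeneous_subsets <- function(ordered_groups, pairwise, alpha) {
  padj <- function(a, b) {
    hit <- (pairwise$group1 == a & pairwise$group2 == b) |
      (pairwise$group1 == b & pairwise$group2 == a)
    pairwise$p_adj[hit][1]
  }
  n <- length(ordered_groups)
  subsets <- vector("list", n)
  for (i in seq_len(n)) {
    cur <- ordered_groups[i]
    j <- i + 1
    while (j <= n &&
           all(vapply(cur, function(a) padj(a, ordered_groups[j]) >= alpha,
                      logical(1)))) {
      cur <- c(cur, ordered_groups[j])
      j <- j + 1
    }
    subsets[[i]] <- cur
  }
  # drop subsets fully contained in another
  keep <- vapply(seq_along(subsets), function(a) {
    !any(vapply(seq_along(subsets), function(b) {
      b != a && all(subsets[[a]] %in% subsets[[b]])
    }, logical(1)))
  }, logical(1))
  subsets[keep]
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA: F(", x$anova$df1, ",", x$anova$df2, ") =",
      format(x$anova$F, digits = 5), ", P =",
      format.pval(x$anova$p, digits = 4), "\n")
  print(x$groups)
  cat("Homogeneous subsets (LSD,", x$adjustment, "adjusted, alpha =",
      x$alpha, "):\n")
  for (s in x$subsets) cat("  {", paste(s, collapse = ", "), "}\n")
  if (length(x$degenerate)) {
    cat("Degenerate groups (n < 2, excluded):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$anova

#' Percentile-trimmed subset
#'
#' Retains the values between the lower and upper sample percentiles
#' (defaults: 20th to 80th), used to blunt the influence of outlying
#' estimates. Percentiles use linear interpolation between closest ranks
#' ([stats::quantile()] type 7). The band is attached to the result as the
#' `trim_band` attribute and is reused when a trimmed vector is trimmed
#' again, so the operation is idempotent.
#'
#' @param x Numeric vector (length >= 5).
#' @param lower,upper Percentile bounds in percent.
#' @return The trimmed numeric vector (order preserved), with the applied
#'   band in the `trim_band` attribute.
#' @export
trimmed_subset <- function(x, lower = 20, upper = 80) {
  band <- attr(x, "trim_band")
  x_ok <- x[is.finite(x)]
  if (is.null(band)) {
    if (length(x_ok) < 5) abort("need at least 5 finite values to trim")
    band <- quantile(x_ok, probs = c(lower, upper) / 100, type = 7,
                     names = FALSE)
  }
  out <- x_ok[x_ok >= band[1] & x_ok <= band[2]]
  attr(out, "trim_band") <- band
  out
}

#' Pairwise correlation panel
#'
#' Pearson correlations between index columns across subjects, with
#' pairwise-complete handling of missing values and significance tiers
#' (`**` P < 0.001, `*` P < 0.01, `NS` otherwise). Constant columns are
#' flagged undefined rather than propagated as NaN.
#'
#' @param data Data frame of per-subject index values.
#' @param vars Columns to correlate (default: all numeric columns).
#' @param min_pairs Minimum complete pairs per cell.
#' @return A tibble of class `index_correlations` (`var1`, `var2`, `r`, `n`,
#'   `p`, `significance`); the correlation matrix itself is in the `matrix`
#'   attribute (unit diagonal, symmetric).
#' @export
correlation_matrix <- function(data, vars = NULL, min_pairs = 3) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  k <- length(vars)
  m <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(m) <- 1
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- data[[vars[i]]]; y <- data[[vars[j]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < min_pairs || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        rows[[length(rows) + 1]] <- tibble(
          var1 = vars[i], var2 = vars[j], r = NA_real_, n = n, p = NA_real_,
          significance = "undefined")
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate)
      m[i, j] <- m[j, i] <- r
      tier <- if (ct$p.value < 0.001) "**" else if (ct$p.value < 0.01) "*"
        else "NS"
      rows[[length(rows) + 1]] <- tibble(
        var1 = vars[i], var2 = vars[j], r = r, n = n, p = ct$p.value,
        significance = tier)
    }
  }
  out <- bind_rows(rows)
  attr(out, "matrix") <- m
  class(out) <- c("index_correlations", class(out))
  out
}

#' Per-group coefficient of variation summary
#'
#' Sample CV (SD over mean, n-1 denominator) of a quantity within each
#' group, and the unweighted average CV across groups.
#'
#' @param data Data frame.
#' @param value Numeric column name (string).
#' @param group Grouping column name (string).
#' @return A list with `by_group` (tibble: group, n, mean, sd, cv) and
#'   `average_cv` (unweighted mean of the group CVs). Groups with zero mean
#'   are flagged with `NA` CV.
#' @export
cv_summary <- function(data, value, group = "group") {
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  by_group <- tibble(group = levels(g)) |>
    mutate(
      n = as.integer(tapply(y, g, length)[.data$group]),
      mean = as.numeric(tapply(y, g, mean)[.data$group]),
      sd = as.numeric(tapply(y, g, sd)[.data$group]),
      cv = ifelse(.data$mean == 0, NA_real_, .data$sd / .data$mean)
    )
  if (any(by_group$n < 2)) abort("every group needs at least 2 values")
  list(by_group = by_group,
       average_cv = mean(by_group$cv, na.rm = FALSE))
}
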