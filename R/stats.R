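# Factor-level comparisons: Friedman and Wilcoxon signed-rank tests over the
# nine distance classes (classes as blocks), one-way ANOVA / t test on
# per-slice densities, and Student-Newman-Keuls compact letter displays.

test_result <- function(test, statistic, p_value, groups = NULL, letters = NULL,
                        details = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), groups = groups,
                 letters = letters, details = details),
            class = "oildrops_test")
}

#' @export
print.oildrops_test <- function(x, ...) {
  cat(x$test, ": statistic =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$letters)) {
    cat("letters:\n")
    print(x$letters)
  }
  invisible(x)
}

#' Friedman test of factor levels over the nine distance classes
#'
#' Treats the nine classes as blocks and the factor levels as treatments on
#' the level-mean class values (rows of
#' [class_distribution_matrix()]). Mid-ranks and the standard tie correction
#' are used; p comes from the chi-square approximation.
#'
#' @param m levels x 9 matrix (>= 3 levels).
#' @return `oildrops_test`.
#' @export
friedman_classes <- function(m) {
  if (nrow(m) < 3)
    stop_oildrops("Friedman needs >= 3 levels; use wilcoxon_paired for 2", "usage_error")
  ft <- friedman.test(t(m))   # rows = blocks (classes), cols = treatments
  if (is.nan(ft$statistic)) ft$statistic <- 0; if (is.nan(ft$p.value)) ft$p.value <- 1
  test_result("friedman", ft$statistic, ft$p.value, groups = rownames(m),
              details = list(df = unname(ft$parameter)))
}

#' Paired Wilcoxon signed-rank test over the nine distance classes
#'
#' Compares two factor levels on their nine paired class means. Zero
#' differences are dropped (standard signed-rank rule); the exact
#' distribution is used for n <= 25 when there are no ties.
#'
#' @param a,b length-9 vectors of class means for the two levels.
#' @return `oildrops_test`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b))
    stop_oildrops("class vectors must be aligned", "usage_error")
  d <- a - b
  if (all(d == 0)) {
    warning("all class differences are zero; p = 1")
    return(test_result("wilcoxon", 0, 1))
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = TRUE))
  test_result("wilcoxon", wt$statistic, wt$p.value)
}

#' One-way ANOVA (or t test) on per-slice total densities
#'
#' Fixed-effects one-way ANOVA across factor levels. Levels with fewer than
#' two slices are excluded with a warning. With exactly two levels a t test
#' is equivalent (pooled variant: F = t^2); set `welch = TRUE` for the
#' Welch t test instead.
#'
#' @param values per-slice total densities.
#' @param groups factor levels, same length.
#' @param welch use Welch's t for the two-level case.
#' @return `oildrops_test` with details (df, MSE, group means/sizes) needed
#'   by [snk_letters()].
#' @export
anova_density <- function(values, groups, welch = FALSE) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(paste("excluding level(s) with < 2 slices:", paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) stop_oildrops("ANOVA needs >= 2 levels with >= 2 slices", "usage_error")
  n <- length(values)
  means <- tapply(values, g, mean)
  sizes <- as.numeric(table(g))
  ss_between <- sum(sizes * (means - mean(values))^2)
  ss_within <- sum((values - means[g])^2)
  df1 <- k - 1; df2 <- n - k
  mse <- ss_within / df2
  if (k == 2 && welch) {
    a <- values[g == levels(g)[1]]; b <- values[g == levels(g)[2]]
    tt <- t.test(a, b)
    return(test_result("t_test", tt$statistic, tt$p.value, groups = levels(g),
                       details = list(df = unname(tt$parameter), welch = TRUE,
                                      means = means, sizes = sizes, mse = mse, df_error = df2)))
  }
  f <- if (mse > 0) ss_between / df1 / mse else 0
  p <- if (mse > 0) pf(f, df1, df2, lower.tail = FALSE) else 1
  test_result("anova", f, p, groups = levels(g),
              details = list(df = c(df1, df2), means = means, sizes = sizes,
                             mse = mse, df_error = df2))
}

#' Pooled-variance t test on two groups of densities
#'
#' @param a,b numeric vectors.
#' @param welch use Welch's correction instead of pooling.
#' @return `oildrops_test`.
#' @export
t_test_density <- function(a, b, welch = FALSE) {
  tt <- t.test(a, b, var.equal = !welch)
  test_result("t_test", tt$statistic, tt$p.value,
              details = list(df = unname(tt$parameter), welch = welch))
}

#' Student-Newman-Keuls compact letter display
#'
#' Stepwise studentized-range procedure at level `alpha` on the group means
#' from a one-way ANOVA. Means are sorted; a range of p adjacent means is
#' declared homogeneous when its studentized range is below
#' `qtukey(1 - alpha, p, df)`; non-significant ranges are not subdivided
#' (the SNK protection rule). Unbalanced designs use the harmonic mean of
#' the group sizes in the standard error. Groups sharing a letter do not
#' differ at `alpha`.
#'
#' @param means named vector of group means.
#' @param sizes group sizes (same order).
#' @param mse ANOVA mean-square error.
#' @param df error degrees of freedom.
#' @param alpha significance level.
#' @return named character vector of letters, in the input group order.
#' @export
snk_letters <- function(means, sizes, mse, df, alpha = 0.05) {
  if (df <= 0) stop_oildrops("error df must be positive", "usage_error")
  k <- length(means)
  nms <- names(means) %||% as.character(seq_len(k))
  if (k == 1) return(stats::setNames("a", nms))
  n_h <- k / sum(1 / sizes)                 # harmonic mean group size
  se <- sqrt(mse / n_h)
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  # collect maximal homogeneous (non-significant) ranges, with protection
  homogeneous <- list()
  test_range <- function(i, j) {
    p <- j - i + 1
    if (p < 2) return(invisible())
    q_obs <- if (se > 0) (ms[i] - ms[j]) / se else if (ms[i] > ms[j]) Inf else 0
    if (q_obs < qtukey(1 - alpha, p, df)) {
      homogeneous[[length(homogeneous) + 1]] <<- c(i, j)
    } else {
      test_range(i, j - 1)
      test_range(i + 1, j)
    }
  }
  test_range(1, k)
  # keep maximal intervals only
  iv <- unique(homogeneous)
  iv <- Filter(function(ab) !any(vapply(iv, function(cd)
    (cd[1] < ab[1] && cd[2] >= ab[2]) || (cd[1] <= ab[1] && cd[2] > ab[2]), logical(1))), iv)
  # singletons for groups covered by no interval
  covered <- rep(FALSE, k)
  for (ab in iv) covered[ab[1]:ab[2]] <- TRUE
  for (i in which(!covered)) iv[[length(iv) + 1]] <- c(i, i)
  iv <- iv[order(vapply(iv, `[`, numeric(1), 1))]
  letters_sorted <- rep("", k)
  for (j in seq_along(iv)) {
    rng <- iv[[j]][1]:iv[[j]][2]
    letters_sorted[rng] <- paste0(letters_sorted[rng], letters[j])
  }
  out <- character(k)
  out[ord] <- letters_sorted
  stats::setNames(out, nms)
}

#' Run the full statistical battery for one factor
#'
#' Class-distribution comparison (Friedman for >= 3 levels, paired Wilcoxon
#' for 2) on counts and densities, plus one-way ANOVA on per-slice total
#' densities with SNK letters.
#'
#' @param profiles list of [build_profile()] results (with meta).
#' @param factor factor name.
#' @param alpha significance level for the SNK letters.
#' @param welch Welch variant for two-level density comparison.
#' @return list of `oildrops_test` objects.
#' @export
compare_factor <- function(profiles, factor = "clone", alpha = 0.05, welch = FALSE) {
  out <- list()
  for (value in c("count", "density")) {
    m <- class_distribution_matrix(profiles, factor, value)
    out[[paste0("classes_", value)]] <- if (nrow(m) >= 3) friedman_classes(m)
      else wilcoxon_paired(m[1, ], m[2, ])
  }
  levels <- vapply(profiles, function(p) meta_level(p$meta, factor), character(1))
  dens <- vapply(profiles, function(p) p$total_density, numeric(1))
  av <- anova_density(dens, levels, welch = welch)
  if (av$test == "anova") {
    d <- av$details
    av$letters <- snk_letters(d$means, d$sizes, d$mse, d$df_error, alpha)
  }
  out$density_anova <- av
  out
}
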