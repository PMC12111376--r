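#' One-way between-subjects ANOVA
#'
#' Standard decomposition of the total sum of squares into between-group and
#' within-group parts; the F statistic is referred to the F(df1, df2)
#' distribution. Used to compare samples stored under different humidities at
#' the same storage time.
#'
#' @param data Data frame with columns `value` (numeric) and `group`
#'   (factor-like); at least 2 groups with at least 2 observations each.
#' @return List with `F`, `df1`, `df2`, `p`, plus the fitted `aov` object in
#'   `$fit` and per-group summaries in `$groups` (means, sizes) and the
#'   pooled `MS_error`/`df_error` needed by [tukey_hsd()].
#' @export
oneway_anova <- function(data) {
  stopifnot(is.data.frame(data), all(c("value", "group") %in% names(data)))
  data$group <- factor(data$group)
  n_per <- table(data$group)
  if (nlevels(data$group) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  if (any(n_per < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  fit <- stats::aov(value ~ group, data = data)
  tab <- summary(fit)[[1]]
  means <- tapply(data$value, data$group, mean)
  res <- list(
    F = tab["group", "F value"],
    df1 = tab["group", "Df"],
    df2 = tab["Residuals", "Df"],
    p = tab["group", "Pr(>F)"],
    MS_error = tab["Residuals", "Mean Sq"],
    df_error = tab["Residuals", "Df"],
    groups = data.frame(group = names(means), mean = as.numeric(means),
                        n = as.integer(n_per[names(means)])),
    fit = fit
  )
  # no between-group variation (up to rounding): report F = 0, p = 1
  if (!is.finite(res$F) ||
      tab["group", "Sum Sq"] < 1e-12 * (sum(data$value^2) + 1)) {
    res$F <- 0; res$p <- 1
  }
  structure(res, class = "anova_result")
}

#' One-way repeated-measures ANOVA
#'
#' For a balanced subject-by-time table the subject effect is partitioned out
#' and the time effect is tested against the subject-by-time interaction:
#' `F = MS_time / MS_(subject x time)`. No sphericity correction is applied
#' (a warning notes the assumption); reported degrees of freedom are
#' uncorrected.
#'
#' @param data Data frame with columns `value`, `group` (the time level) and
#'   `subject`; exactly one observation per subject per level (balanced — no
#'   imputation is attempted).
#' @return List with `F`, `df1`, `df2`, `p`, `MS_error`, `df_error`,
#'   per-level summaries in `$groups`.
#' @export
repeated_measures_anova <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("value", "group", "subject") %in% names(data)))
  data$group <- factor(data$group)
  data$subject <- factor(data$subject)
  tab <- table(data$subject, data$group)
  if (any(tab != 1L))
    stop("unbalanced subject x time table: exactly one observation per ",
         "subject per level is required (no imputation)", call. = FALSE)
  warning("sphericity is assumed; degrees of freedom are uncorrected",
          call. = FALSE)
  fit <- stats::aov(value ~ group + Error(subject), data = data)
  within <- summary(fit)[["Error: Within"]][[1]]
  means <- tapply(data$value, data$group, mean)
  res <- list(
    F = within["group", "F value"],
    df1 = within["group", "Df"],
    df2 = within["Residuals", "Df"],
    p = within["group", "Pr(>F)"],
    MS_error = within["Residuals", "Mean Sq"],
    df_error = within["Residuals", "Df"],
    groups = data.frame(group = names(means), mean = as.numeric(means),
                        n = as.integer(table(data$group)[names(means)])),
    fit = fit
  )
  if (!is.finite(res$F) ||
      within["group", "Sum Sq"] < 1e-12 * (sum(data$value^2) + 1)) {
    res$F <- 0; res$p <- 1
  }
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%g, %g) = %.4g, p = %.4g\n", x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Tukey honest significant differences
#'
#' All-pairs comparison using the studentized range: for groups i and j,
#' `q_ij = |mean_i - mean_j| / sqrt(MS_error/2 * (1/n_i + 1/n_j))`, declared
#' significant when q exceeds the critical value of the studentized range
#' distribution at (k groups, df_error, alpha). Critical values come from the
#' studentized range quantile function (numerically integrated, no table).
#'
#' @param means Named numeric vector of group means.
#' @param ns Group sizes (recycled if length 1).
#' @param MS_error Pooled error mean square, > 0.
#' @param df_error Error degrees of freedom, >= 1.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class `tukey_result`: data frame `$pairwise` with
#'   columns `group_i`, `group_j`, `diff`, `q`, `p`, `significant`;
#'   `$critical` the critical q; `$letters` the compact letter display.
#' @export
tukey_hsd <- function(means, ns, MS_error, df_error, alpha = 0.05) {
  if (!is.numeric(MS_error) || MS_error <= 0)
    stop("'MS_error' must be > 0", call. = FALSE)
  if (!is.numeric(df_error) || df_error < 1)
    stop("'df_error' must be >= 1", call. = FALSE)
  k <- length(means)
  if (k < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  ns <- rep_len(ns, k)
  crit <- stats::qtukey(1 - alpha, nmeans = k, df = df_error)
  ij <- utils::combn(k, 2)
  q <- abs(means[ij[1, ]] - means[ij[2, ]]) /
    sqrt(MS_error / 2 * (1 / ns[ij[1, ]] + 1 / ns[ij[2, ]]))
  pw <- data.frame(
    group_i = names(means)[ij[1, ]],
    group_j = names(means)[ij[2, ]],
    diff = as.numeric(means[ij[1, ]] - means[ij[2, ]]),
    q = as.numeric(q),
    p = stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE),
    significant = as.numeric(q) > crit,
    row.names = NULL
  )
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  sig[cbind(ij[1, ], ij[2, ])] <- pw$significant
  sig[cbind(ij[2, ], ij[1, ])] <- pw$significant
  letters <- compact_letter_display(sig, means = means)
  structure(list(pairwise = pw, critical = crit, alpha = alpha,
                 letters = letters),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %g, critical q = %.3f)\n",
              x$alpha, x$critical))
  print(x$pairwise)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Compact letter display for pairwise comparisons
#'
#' Insert-and-absorb assignment of letters so that two groups share a letter
#' if and only if they are not significantly different — the lettering
#' convention of figure annotations in storage studies. Letters are assigned
#' with groups ordered by descending mean (ties broken lexicographically by
#' label); the output is verified against the pairwise relation by exhaustive
#' enumeration on every call.
#'
#' @param significant Symmetric logical matrix; `significant[i, j]` is TRUE
#'   when groups i and j differ significantly. Dimnames supply group labels.
#' @param means Optional named means used only to order the letters.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(significant, means = NULL) {
  if (!is.matrix(significant) || !is.logical(significant) ||
      nrow(significant) != ncol(significant))
    stop("'significant' must be a square logical matrix", call. = FALSE)
  if (!isTRUE(all.equal(significant, t(significant))) ||
      any(diag(significant)))
    stop("inconsistent significance relation: must be symmetric with a ",
         "FALSE diagonal", call. = FALSE)
  k <- nrow(significant)
  labels <- rownames(significant)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  ord <- if (is.null(means)) order(labels)
         else order(-as.numeric(means)[match(labels, names(means))], labels)

  classes <- list(seq_len(k))
  pairs <- which(significant & upper.tri(significant), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    nxt <- list()
    for (cl in classes) {
      if (i %in% cl && j %in% cl) {
        nxt <- c(nxt, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else nxt <- c(nxt, list(cl))
    }
    # absorb classes contained in another class
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a != b && keep[a] && keep[b] &&
          all(nxt[[a]] %in% nxt[[b]]) &&
          (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) keep[a] <- FALSE
    }
    classes <- nxt[keep]
  }
  # order classes by the best-ranked member so 'a' goes to the top group
  rank_of <- order(ord)  # position of each group in display order
  classes <- classes[order(vapply(classes, function(cl) min(rank_of[cl]),
                                  numeric(1)))]
  lab <- vapply(seq_len(k), function(g) {
    idx <- which(vapply(classes, function(cl) g %in% cl, logical(1)))
    paste(letters[idx], collapse = "")
  }, character(1))
  names(lab) <- labels

  # self-check: share a letter <=> not significantly different
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    share <- length(intersect(strsplit(lab[i], "")[[1]],
                              strsplit(lab[j], "")[[1]])) > 0
    if (share == significant[i, j])
      stop("internal error: letter display inconsistent with the pairwise ",
           "relation for ", labels[i], " vs ", labels[j], call. = FALSE)
  }
  lab
}

#' Tukey HSD directly from tidy group data
#'
#' Convenience wrapper: runs [oneway_anova()] (or
#' [repeated_measures_anova()] when a `subject` column is present) and feeds
#' the pooled error term into [tukey_hsd()].
#'
#' @param data Tidy data frame `value,group` (+ optional `subject`).
#' @param alpha Family-wise level.
#' @return A list with `anova` and `tukey` components.
#' @export
tukey_hsd_groups <- function(data, alpha = 0.05) {
  an <- if ("subject" %in% names(data))
    suppressWarnings(repeated_measures_anova(data))
  else oneway_anova(data)
  means <- stats::setNames(an$groups$mean, an$groups$group)
  list(anova = an,
       tukey = tukey_hsd(means, an$groups$n, an$MS_error, an$df_error, alpha))
}
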