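# Group statistics for condition comparisons.

#' Compare measurement groups
#'
#' Two-group comparisons use a two-tailed Student's t test with pooled
#' variance (the default) or Welch's t; three or more groups use a one-way
#' ANOVA F test. Degenerate input (all groups constant) returns `p = 1`
#' when the means are equal and `p = 0` otherwise, by convention.
#'
#' @param groups list of numeric vectors (n >= 2 each); exactly 2 for the
#'   t tests, >= 2 for ANOVA.
#' @param test `"student_t"`, `"welch_t"`, or `"oneway_anova"`.
#' @return an object of class `group_comparison`: per-group summaries
#'   (n, mean, sd), `statistic`, `df`, `p` (two-tailed), `test`.
#' @export
#' @examples
#' compare_groups(list(control = c(6.5, 7.7, 5.3, 6.5),
#'                     treated = c(2.2, 3.4, 1.0, 2.2)))
compare_groups <- function(groups,
                           test = c("student_t", "welch_t", "oneway_anova")) {
  test <- match.arg(test)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two numeric vectors",
         call. = FALSE)
  }
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("each group must have n >= 2", call. = FALSE)
  if (test %in% c("student_t", "welch_t") && length(groups) != 2L) {
    stop("t tests require exactly two groups", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  summaries <- data.frame(
    group = names(groups), n = ns,
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    row.names = NULL)

  all_const <- all(summaries$sd == 0)
  means_equal <- length(unique(summaries$mean)) == 1L

  if (test == "oneway_anova") {
    if (all_const) {
      stat <- if (means_equal) 0 else Inf
      p <- if (means_equal) 1 else 0
      df <- c(length(groups) - 1L, sum(ns) - length(groups))
    } else {
      x <- unlist(groups)
      g <- factor(rep(names(groups), times = ns))
      ow <- stats::oneway.test(x ~ g, var.equal = TRUE)
      stat <- unname(ow$statistic)
      df <- unname(ow$parameter)
      p <- ow$p.value
      if (!is.finite(p) && stat == 0) p <- 1
    }
  } else {
    if (all_const) {
      stat <- if (means_equal) 0 else sign(summaries$mean[1] -
                                           summaries$mean[2]) * Inf
      p <- if (means_equal) 1 else 0
      df <- if (test == "student_t") sum(ns) - 2L else NA_real_
    } else {
      tt <- stats::t.test(groups[[1]], groups[[2]],
                          var.equal = (test == "student_t"))
      stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
  }
  structure(list(summaries = summaries, statistic = stat, df = df,
                 p = p, test = test),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- switch(x$test, student_t = "Student's t (pooled, two-tailed)",
                welch_t = "Welch's t (two-tailed)",
                oneway_anova = "one-way ANOVA F")
  cat(sprintf("<group_comparison> %s\n", lab))
  for (i in seq_len(nrow(x$summaries))) {
    s <- x$summaries[i, ]
    cat(sprintf("  %s: n = %d, mean = %.4g, sd = %.4g\n",
                s$group, s$n, s$mean, s$sd))
  }
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 4), collapse = ", "), x$p))
  invisible(x)
}
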