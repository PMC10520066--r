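#' Shapiro-Wilk normality check
#'
#' @param values Numeric sample, 3-5000 non-constant values.
#' @return A list with `statistic` (W) and `p`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires 3-5000 values", call. = FALSE)
  }
  if (sd(values) == 0) stop("constant input", call. = FALSE)
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Equal-variance Student's t computed directly from the two groups'
#' mean, SD (sample, n-1 denominator) and n — the form that reproduces a
#' published table's p-values from its printed "mean +/- SD" cells:
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`,
#' `t = (mean2 - mean1) / (sp sqrt(1/n1 + 1/n2))`, df = n1+n2-2,
#' two-tailed p.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return A list with `t`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("negative SD", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    # degenerate: both groups constant
    return(list(t = if (mean1 == mean2) 0 else Inf * sign(mean2 - mean1),
                df = df, p = if (mean1 == mean2) 1 else 0))
  }
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Normality-gated two-group comparison
#'
#' The test-selection policy used for the group tables: each group is
#' checked with Shapiro-Wilk (gate at p > 0.05); if both pass, the groups
#' are compared with the pooled (equal-variance) Student's t-test,
#' otherwise with the Mann-Whitney U test (exact for groups of up to 8
#' without ties, normal approximation with continuity and tie correction
#' above). Two-tailed throughout. The policy can be forced.
#'
#' @param values_a,values_b Numeric samples (n >= 3 each for `auto`).
#' @param policy `"auto"`, `"pooled_t"` or `"mann_whitney"`.
#' @param label_a,label_b Group labels carried into the result.
#' @param variable Variable name carried into the result.
#' @return An object of class `somnark_comparison`; see [tidy()] /
#'   [glance()].
#' @export
compare_groups <- function(values_a, values_b, policy = c("auto", "pooled_t",
                                                          "mann_whitney"),
                           label_a = "A", label_b = "B",
                           variable = NA_character_) {
  policy <- match.arg(policy)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("empty group", call. = FALSE)
  }
  norm_p <- c(NA_real_, NA_real_)
  if (policy == "auto") {
    if (length(values_a) < 3 || length(values_b) < 3) {
      stop("auto policy needs n >= 3 per group", call. = FALSE)
    }
    norm_p <- c(
      if (sd(values_a) > 0) normality_check(values_a)$p else 1,
      if (sd(values_b) > 0) normality_check(values_b)$p else 1
    )
    test <- if (all(norm_p > 0.05)) "pooled_t" else "mann_whitney"
  } else {
    test <- policy
  }

  if (test == "pooled_t") {
    ht <- t.test(values_b, values_a, var.equal = TRUE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    n_small <- max(length(values_a), length(values_b)) <= 8
    ties <- anyDuplicated(c(values_a, values_b)) > 0
    ht <- suppressWarnings(
      wilcox.test(values_b, values_a, exact = n_small && !ties,
                  correct = TRUE)
    )
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }

  structure(
    list(
      variable = variable,
      summaries = tibble::tibble(
        group = c(label_a, label_b),
        n = c(length(values_a), length(values_b)),
        mean = c(mean(values_a), mean(values_b)),
        sd = c(sd(values_a), sd(values_b))
      ),
      test = test, statistic = statistic, p = p,
      normality_p = stats::setNames(norm_p, c(label_a, label_b))
    ),
    class = "somnark_comparison"
  )
}

#' @export
print.somnark_comparison <- function(x, ...) {
  s <- x$summaries
  cat("<somnark_comparison>", if (!is.na(x$variable)) x$variable else "",
      "\n")
  for (i in 1:2) {
    cat(sprintf("  %s: %.3f +/- %.3f (n=%d)\n", s$group[i], s$mean[i],
                s$sd[i], s$n[i]))
  }
  cat(sprintf("  %s: p = %.3f\n", x$test, x$p))
  invisible(x)
}

#' Tidy / glance methods for two-group comparisons
#'
#' `tidy()` returns one row per group (n, mean, sd, normality p);
#' `glance()` returns a one-row summary (test, statistic, two-tailed p).
#'
#' @param x A `somnark_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy somnark_comparison
#' @export
tidy.somnark_comparison <- function(x, ...) {
  dplyr::mutate(x$summaries, normality_p = unname(x$normality_p),
                variable = x$variable, .before = 1)
}

#' @rdname tidy.somnark_comparison
#' @method glance somnark_comparison
#' @export
glance.somnark_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, test = x$test,
                 statistic = x$statistic, p = x$p)
}

#' Build group-comparison report tables from per-animal metrics
#'
#' Takes long-format per-animal metrics (one value per animal and metric),
#' compares the two groups metric by metric with the normality-gated policy
#' of [compare_groups()], and returns a report in the mean +/- SD layout of
#' a sleep-structure or HRV table (p to 3 decimals in the formatted
#' column). Rows with missing values are computed on the animals available,
#' with the per-group n reported.
#'
#' @param metrics Tibble with columns `animal_id`, `group`, `metric`,
#'   `value`.
#' @param group_order Optional character(2) giving the reference group
#'   first; defaults to sorted unique groups.
#' @param policy Test policy passed to [compare_groups()].
#' @return A tibble with one row per metric: per-group n/mean/sd, the test
#'   used, `p`, and a formatted `p_3dp` column.
#' @export
build_report <- function(metrics, group_order = NULL,
                         policy = c("auto", "pooled_t", "mann_whitney")) {
  policy <- match.arg(policy)
  stopifnot(all(c("animal_id", "group", "metric", "value") %in%
                  names(metrics)))
  groups <- group_order %||% sort(unique(as.character(metrics$group)))
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)

  metrics |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(df, key) {
      a <- df$value[df$group == groups[1]]
      b <- df$value[df$group == groups[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(
          n_1 = length(a), mean_1 = mean(a), sd_1 = sd(a),
          n_2 = length(b), mean_2 = mean(b), sd_2 = sd(b),
          test = NA_character_, statistic = NA_real_, p = NA_real_,
          p_3dp = NA_character_
        ))
      }
      cmp <- compare_groups(a, b, policy = policy,
                            label_a = groups[1], label_b = groups[2],
                            variable = key$metric)
      tibble::tibble(
        n_1 = length(a), mean_1 = mean(a), sd_1 = sd(a),
        n_2 = length(b), mean_2 = mean(b), sd_2 = sd(b),
        test = cmp$test, statistic = cmp$statistic, p = cmp$p,
        p_3dp = sprintf("%.3f", cmp$p)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::rename_with(~ sub("_1$", paste0("_", groups[1]), .x)) |>
    dplyr::rename_with(~ sub("_2$", paste0("_", groups[2]), .x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
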