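#' One-way repeated-measures ANOVA over the six condition x configuration cells
#'
#' Treats the six PCL-condition x loading-configuration combinations as the
#' levels of a single within-specimen factor (the design behind one p-value
#' per measure row) and computes the classical within-subject F test:
#' treatment and subject sums of squares are removed from the total, the
#' residual (subject x treatment interaction) is the error term. Post-hoc
#' pairwise paired t tests are Bonferroni-adjusted; by default each cell is
#' compared against the unloaded intact baseline (5 comparisons), optionally
#' all 15 pairs. Significance is stratified as `ns` (p > 0.01), `**`
#' (0.001 < p <= 0.01), `***` (p <= 0.001).
#'
#' A Greenhouse-Geisser sphericity correction is available but off by
#' default. Specimens with incomplete cells are dropped with a warning.
#'
#' @param table A measure table (or delta table; a `delta` column is used as
#'   the value) containing one measure.
#' @param measure Which measure to analyse (required if the table holds
#'   several).
#' @param posthoc `"baseline"` (default) or `"all"` pairwise family.
#' @param gg Apply the Greenhouse-Geisser epsilon correction to the omnibus
#'   p-value.
#' @return An object of class `rm_anova` with the F statistic, degrees of
#'   freedom, p-value, significance stratum, and a tibble of post-hoc
#'   comparisons. Supports [generics::tidy()] and [generics::glance()].
#' @export
rm_anova <- function(table, measure = NULL, posthoc = c("baseline", "all"), gg = FALSE) {
  posthoc <- match.arg(posthoc)
  value_col <- if ("delta" %in% names(table)) "delta" else "value"
  tb <- tibble::as_tibble(table)
  if (!is.null(measure)) tb <- tb[tb$measure == measure, ]
  if (!nrow(tb)) rlang::abort("No rows for the requested measure.")
  if (length(unique(tb$measure)) > 1L) {
    rlang::abort("Table holds several measures; pass `measure = `.")
  }
  measure <- tb$measure[1]
  tb$cell <- paste(tb$condition, tb$configuration, sep = "/")
  wide <- tb |>
    dplyr::select("specimen_id", "cell", value = dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
  cells <- setdiff(names(wide), "specimen_id")
  complete <- stats::complete.cases(wide[cells])
  if (any(!complete)) {
    rlang::warn(sprintf(
      "Dropping %d specimen(s) with incomplete cells: %s.",
      sum(!complete), paste(wide$specimen_id[!complete], collapse = ", ")
    ))
    wide <- wide[complete, ]
  }
  Y <- as.matrix(wide[cells])
  n <- nrow(Y)
  k <- ncol(Y)
  if (n < 2L || k < 2L) {
    rlang::abort("Need at least 2 specimens with complete data (and 2 cells).")
  }
  grand <- mean(Y)
  ss_treat <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- max(ss_tot - ss_treat - ss_subj, 0)
  df_t <- k - 1L
  df_e <- (n - 1L) * (k - 1L)
  if (ss_err <= .Machine$double.eps * ss_tot) {
    if (ss_treat <= .Machine$double.eps * max(ss_tot, 1)) {
      f <- 0
      p <- 1 # all cells identical within specimen: no evidence of any effect
    } else {
      f <- Inf
      p <- 0
    }
    eps <- 1
  } else {
    f <- (ss_treat / df_t) / (ss_err / df_e)
    eps <- if (gg) gg_epsilon(Y) else 1
    p <- stats::pf(f, eps * df_t, eps * df_e, lower.tail = FALSE)
  }
  base_cell <- "intact/d0"
  pairs <- if (posthoc == "baseline") {
    if (!base_cell %in% cells) {
      rlang::abort("Baseline cell intact/d0 absent; cannot form baseline comparisons.")
    }
    cbind(base_cell, setdiff(cells, base_cell))
  } else {
    t(utils::combn(cells, 2L))
  }
  m <- nrow(pairs)
  ph <- purrr::map_dfr(seq_len(m), function(i) {
    d <- Y[, pairs[i, 2]] - Y[, pairs[i, 1]]
    if (stats::sd(d) <= .Machine$double.eps * max(abs(d), 1)) {
      praw <- if (all(abs(d) <= .Machine$double.eps)) 1 else 0
      tstat <- NA_real_
    } else {
      tt <- stats::t.test(d)
      praw <- tt$p.value
      tstat <- unname(tt$statistic)
    }
    tibble::tibble(
      cell_a = pairs[i, 1], cell_b = pairs[i, 2],
      mean_diff = mean(d), t = tstat,
      p_raw = praw, p_adj = min(1, m * praw)
    )
  })
  ph$stratum <- significance_stratum(ph$p_adj)
  structure(
    list(
      measure = measure,
      n = n, k = k,
      F = f, df = c(df_t, df_e), epsilon = eps,
      p = p, stratum = significance_stratum(p),
      posthoc = ph, posthoc_family = posthoc,
      ss = c(treatment = ss_treat, subject = ss_subj, error = ss_err)
    ),
    class = "rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the double-centred covariance matrix
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  C <- diag(k) - 1 / k
  S <- C %*% S %*% C
  num <- sum(diag(S))^2
  den <- (k - 1) * sum(S^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

significance_stratum <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", "ns"))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "<rm_anova> %s: F(%d, %d) = %.3f, p = %.4g (%s), n = %d specimens\n",
    x$measure, x$df[1], x$df[2], x$F, x$p, x$stratum, x$n
  ))
  cat(sprintf(
    "  post-hoc (%s family, Bonferroni m = %d):\n",
    x$posthoc_family, nrow(x$posthoc)
  ))
  ph <- x$posthoc
  for (i in seq_len(nrow(ph))) {
    cat(sprintf(
      "  %s vs %s: diff %.2f, p_adj = %.4g (%s)\n",
      ph$cell_b[i], ph$cell_a[i], ph$mean_diff[i], ph$p_adj[i], ph$stratum[i]
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rm_anova <- function(x, ...) {
  dplyr::mutate(x$posthoc, measure = x$measure, .before = 1L)
}

#' @exportS3Method generics::glance
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    n = x$n, k = x$k,
    statistic = x$F, df = x$df[1], df_error = x$df[2],
    epsilon = x$epsilon,
    p.value = x$p, stratum = x$stratum
  )
}

#' Paired effect size: mean difference over its SD
#'
#' `d = mean(diff) / sd(diff)` with the sample (n - 1) standard deviation —
#' the effect size used to power paired stress-MRI comparisons.
#'
#' @param paired_differences Numeric vector of within-specimen differences
#'   (n >= 2).
#' @return The effect size `d`.
#' @export
effect_size <- function(paired_differences) {
  d <- as.numeric(paired_differences)
  if (length(d) < 2L) rlang::abort("Need at least 2 paired differences.")
  s <- stats::sd(d)
  if (s <= .Machine$double.eps * max(abs(d), 1)) {
    rlang::abort("Zero standard deviation: effect size undefined.")
  }
  mean(d) / s
}

#' Power of a two-tailed paired t test
#'
#' Exact noncentral-t power at sample size `n`: the probability that |T|
#' exceeds the two-sided critical value when T follows a noncentral t with
#' n - 1 degrees of freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n Number of pairs.
#' @param d Effect size (mean paired difference / SD).
#' @param alpha Two-tailed type-I error (default 0.05).
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Minimum paired sample size for a target power
#'
#' Smallest `n >= 2` whose two-tailed paired t test reaches the requested
#' power under the noncentral-t alternative with noncentrality `d * sqrt(n)`.
#'
#' @param d Effect size (> 0).
#' @param power Target power (default 0.8).
#' @param alpha Two-tailed type-I error (default 0.05).
#' @param n_max Search bound (error if exceeded).
#' @return Minimum integer n.
#' @examples
#' sample_size_paired(d = 1.4) # the study's planning effect size
#' @export
sample_size_paired <- function(d, power = 0.8, alpha = 0.05, n_max = 1e5) {
  stopifnot(d > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  for (n in 2:n_max) {
    if (power_paired_t(n, d, alpha) >= power) return(as.integer(n))
  }
  rlang::abort(sprintf("No n <= %g reaches power %.2f at d = %g.", n_max, power, d))
}

#' Study summary table: delta means +/- SD with ANOVA p per measure
#'
#' Formats a delta table the way laxity studies report their results: one
#' row per measure, one `mean +/- SD` column per condition x configuration
#' (the identically-zero unloaded intact column is omitted), the
#' repeated-measures ANOVA p-value and its significance stratum appended.
#'
#' @param deltas A delta table from [compute_deltas()].
#' @param anova Optional named list of `rm_anova` objects keyed by measure
#'   (computed from `deltas` if missing).
#' @param measures Measures to include (default: all in `deltas`, 3D block
#'   first).
#' @return A tibble, one row per measure; columns `Delta1[intact]`,
#'   `Delta0[partial]`, `Delta1[partial]`, `Delta0[complete]`,
#'   `Delta1[complete]`, `p`, `stratum`.
#' @export
summary_table <- function(deltas, anova = NULL, measures = NULL) {
  if (!nrow(deltas)) {
    return(tibble::tibble(measure = character(0)))
  }
  if (is.null(measures)) {
    present <- unique(deltas$measure)
    measures <- c(
      intersect(c(MEASURE_NAMES_3D, MEASURE_NAMES_2D), present),
      setdiff(present, c(MEASURE_NAMES_3D, MEASURE_NAMES_2D))
    )
  }
  summ <- summarize_deltas(deltas)
  cols <- tibble::tribble(
    ~condition, ~configuration, ~label,
    "intact", "d1", "Delta1[intact]",
    "partial", "d0", "Delta0[partial]",
    "partial", "d1", "Delta1[partial]",
    "complete", "d0", "Delta0[complete]",
    "complete", "d1", "Delta1[complete]"
  )
  purrr::map_dfr(measures, function(ms) {
    row <- tibble::tibble(measure = ms)
    for (i in seq_len(nrow(cols))) {
      s <- summ[summ$measure == ms &
        summ$condition == cols$condition[i] &
        summ$configuration == cols$configuration[i], ]
      row[[cols$label[i]]] <- if (nrow(s)) {
        if (s$n > 1L) sprintf("%.1f ± %.1f", s$mean, s$sd) else sprintf("%.1f", s$mean)
      } else {
        NA_character_
      }
    }
    a <- if (!is.null(anova)) {
      anova[[ms]]
    } else {
      tryCatch(rm_anova(deltas, measure = ms), error = function(e) NULL)
    }
    row$p <- if (is.null(a)) NA_real_ else a$p
    row$stratum <- if (is.null(a)) NA_character_ else a$stratum
    row
  })
}
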