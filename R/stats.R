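#' Condition-level summaries (mean, SEM, n)
#'
#' Per-condition, per-parameter mean, standard error of the mean
#' (`sd / sqrt(n)`) and sample size. Conditions with fewer than two rows are
#' flagged and should be excluded from hypothesis tests.
#'
#' @param table A [simulate_experiment()] table, or any data frame with a
#'   `concentration` column and numeric parameter columns.
#' @param parameters Parameter column names to summarise.
#' @return A data frame of class `condition_summary` with columns
#'   `concentration`, `parameter`, `mean`, `sem`, `n`, `flagged`.
#' @export
summarize_conditions <- function(table,
                                 parameters = c("tau1", "tau2", "tau_avg_amp",
                                                "tau_avg_int", "ratio")) {
  parameters <- intersect(parameters, names(table))
  if (!length(parameters)) stop("no parameter columns found", call. = FALSE)
  conds <- sort(unique(table$concentration))
  out <- do.call(rbind, lapply(conds, function(cc) {
    sub <- table[table$concentration == cc, , drop = FALSE]
    do.call(rbind, lapply(parameters, function(p) {
      v <- sub[[p]]
      n <- sum(is.finite(v))
      data.frame(concentration = cc, parameter = p,
                 mean = if (n > 0) mean(v, na.rm = TRUE) else NA_real_,
                 sem = if (n > 1) stats::sd(v, na.rm = TRUE) / sqrt(n) else NA_real_,
                 n = n, flagged = n < 2)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' One-way analysis of variance across conditions
#'
#' Standard between/within decomposition via [stats::lm()]:
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor), same length.
#' @return A list of class `flim_anova`: `F`, `df1`, `df2`, `p`,
#'   `ms_within`, `group_means`, `group_n`, and `degenerate` (`TRUE` when
#'   the within-group variance is zero while means differ, in which case
#'   `p = 0`).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 values", call. = FALSE)
  fit <- stats::lm(values ~ groups)
  # perfect within-group fits make the F ratio 0/0; handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  ms_within <- an[["Mean Sq"]][2]
  means <- tapply(values, groups, mean)
  degenerate <- FALSE
  Fv <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  tol <- 1e-12 * (mean(values^2) + 1)
  if (!is.finite(ms_within) || ms_within <= tol) {
    if (max(means) - min(means) > 0) {
      Fv <- Inf; p <- 0; degenerate <- TRUE
    } else {
      Fv <- 0; p <- 1
    }
  }
  structure(list(F = Fv, df1 = an$Df[1], df2 = an$Df[2], p = p,
                 ms_within = ms_within, group_means = means,
                 group_n = as.vector(table(groups)),
                 group_levels = levels(groups), degenerate = degenerate),
            class = "flim_anova")
}

#' @export
print.flim_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$degenerate) " [degenerate within-group variance]" else ""))
  invisible(x)
}

#' Fisher's LSD post-hoc pairwise comparisons
#'
#' Unadjusted pairwise t-tests using the pooled within-group variance from
#' the one-way ANOVA: `t = (m_i - m_j) / sqrt(MS_within * (1/n_i + 1/n_j))`
#' on `N - k` degrees of freedom, two-sided. No multiplicity correction is
#' applied beyond the ANOVA-protected design (the definition of least
#' significant difference testing). Significance tiers follow the common
#' figure-legend convention: `*` for p < 0.05, `**` for p < 0.001.
#'
#' @param values,groups As in [one_way_anova()].
#' @param alpha Nominal significance level (recorded; default 0.05).
#' @return A data frame of class `posthoc_table`: `group1`, `group2`,
#'   `mean_diff`, `t`, `df`, `p`, `significance`.
#' @export
lsd_posthoc <- function(values, groups, alpha = 0.05) {
  an <- one_way_anova(values, groups)
  lev <- an$group_levels
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- an$group_means[i1] - an$group_means[i2]
    if (an$degenerate) {
      tv <- if (d == 0) 0 else Inf * sign(d)
      p <- if (d == 0) 1 else 0
    } else {
      se <- sqrt(an$ms_within * (1 / an$group_n[i1] + 1 / an$group_n[i2]))
      tv <- d / se
      p <- 2 * stats::pt(-abs(tv), an$df2)
    }
    data.frame(group1 = lev[i1], group2 = lev[i2], mean_diff = unname(d),
               t = unname(tv), df = an$df2, p = unname(p),
               significance = if (p < 0.001) "**" else if (p < alpha) "*" else "")
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "anova") <- an
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Percent change of a condition mean
#'
#' `100 * (mean_to - mean_from) / mean_from` for one parameter between two
#' conditions of a [summarize_conditions()] table.
#'
#' @param summary A `condition_summary` data frame.
#' @param parameter Parameter name.
#' @param from,to Condition labels (concentrations).
#' @return Signed percent change.
#' @examples
#' # a 2.0 -> 3.2 shift in the amplitude ratio is +60%
#' @export
percent_change <- function(summary, parameter, from, to) {
  pick <- function(cond) {
    r <- summary[summary$concentration == cond & summary$parameter == parameter, ]
    if (nrow(r) != 1) stop("condition/parameter not found: ", cond, "/",
                           parameter, call. = FALSE)
    r$mean
  }
  m0 <- pick(from); m1 <- pick(to)
  if (!is.finite(m0) || m0 == 0)
    stop("reference mean is zero or undefined", call. = FALSE)
  100 * (m1 - m0) / m0
}

#' Dose-response analysis of an experiment table
#'
#' Convenience wrapper: condition summaries, one-way ANOVA and LSD post-hoc
#' per parameter, and control -> highest-dose percent changes.
#'
#' @param table A `flim_experiment` table (single channel).
#' @param parameters Parameter columns to analyse.
#' @param control,treated Conditions compared in the percent-change summary
#'   (defaults: lowest and highest concentration present).
#' @return A list of class `flim_analysis`: `summary`, `anova` (named list),
#'   `posthoc` (named list), `percent_change` (data frame), `control`,
#'   `treated`.
#' @export
analyze_experiment <- function(table,
                               parameters = c("tau1", "tau2", "tau_avg_amp",
                                              "tau_avg_int", "ratio"),
                               control = min(table$concentration),
                               treated = max(table$concentration)) {
  parameters <- intersect(parameters, names(table))
  summ <- summarize_conditions(table, parameters)
  anovas <- list(); posthocs <- list()
  pc <- data.frame(parameter = parameters, percent_change = NA_real_,
                   p_control_vs_treated = NA_real_)
  for (i in seq_along(parameters)) {
    p <- parameters[i]
    anovas[[p]] <- one_way_anova(table[[p]], table$concentration)
    posthocs[[p]] <- lsd_posthoc(table[[p]], table$concentration)
    pc$percent_change[i] <- percent_change(summ, p, control, treated)
    ph <- posthocs[[p]]
    hit <- (ph$group1 == as.character(control) & ph$group2 == as.character(treated)) |
      (ph$group2 == as.character(control) & ph$group1 == as.character(treated))
    pc$p_control_vs_treated[i] <- ph$p[hit][1]
  }
  structure(list(summary = summ, anova = anovas, posthoc = posthocs,
                 percent_change = pc, control = control, treated = treated),
            class = "flim_analysis")
}

#' @export
print.flim_analysis <- function(x, ...) {
  cat(sprintf("Dose-group analysis (control %s vs %s):\n", x$control, x$treated))
  print(x$percent_change, row.names = FALSE)
  invisible(x)
}
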