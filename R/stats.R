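#' Group summary
#'
#' Sample size, mean and standard deviation of one treatment group's
#' effects (in percent-of-pre units). The summary is sufficient for the
#' pooled t-test and Hedges' g, so published summary tables can be
#' re-analyzed without raw values.
#'
#' @param label group label.
#' @param n sample size (>= 2).
#' @param mean,sd group mean and standard deviation (sd >= 0).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2) stop("a group summary needs n >= 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d)\n", x$label, x$mean, x$sd, x$n))
  invisible(x)
}

summarize_values <- function(x, label) {
  group_summary(label, length(x), mean(x), sd(x))
}

#' Exact and approximate small-sample correction for Hedges' g
#'
#' The exact gamma-function form
#' `J(df) = gamma(df / 2) / (sqrt(df / 2) * gamma((df - 1) / 2))`, or the
#' common approximation `1 - 3 / (4 df - 1)`.
#'
#' @param df degrees of freedom (`n_a + n_b - 2`).
#' @param method `"exact"` or `"approx"`.
#' @return The correction factor in (0, 1).
#' @export
hedges_correction <- function(df, method = c("exact", "approx")) {
  method <- match.arg(method)
  if (df < 2) stop("Hedges' correction needs df >= 2")
  if (method == "approx") return(1 - 3 / (4 * df - 1))
  exp(lgamma(df / 2) - 0.5 * log(df / 2) - lgamma((df - 1) / 2))
}

pooled_sd <- function(a, b) {
  df <- a$n + b$n - 2
  sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df)
}

#' Hedges' g effect size from group summaries
#'
#' Bias-corrected standardized mean difference
#' `g = J(df) * (mean_a - mean_b) / s_pooled` with the pooled standard
#' deviation and df = `n_a + n_b - 2`. By convention the first argument is
#' the control group, so a biomarker reduced by treatment yields positive g.
#'
#' @param a,b [group_summary()] objects (control first), or numeric vectors
#'   of raw values.
#' @param correction `"exact"` (gamma-function form, default) or
#'   `"approx"` (`1 - 3 / (4 df - 1)`).
#' @return Hedges' g (scalar).
#' @export
hedges_g <- function(a, b, correction = c("exact", "approx")) {
  correction <- match.arg(correction)
  if (is.numeric(a)) a <- summarize_values(a, "a")
  if (is.numeric(b)) b <- summarize_values(b, "b")
  if (a$n + b$n < 4) stop("Hedges' g needs n_a + n_b >= 4")
  sp <- pooled_sd(a, b)
  if (sp == 0) stop("degenerate input: zero pooled standard deviation")
  df <- a$n + b$n - 2L
  hedges_correction(df, correction) * (a$mean - b$mean) / sp
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Two-sided pooled-variance t-test with `df = n_a + n_b - 2`, computable
#' from raw values or directly from published `(mean, sd, n)` summaries.
#' The returned comparison also carries Hedges' g (exact correction).
#'
#' @param a,b numeric vectors of raw values (each n >= 2) or
#'   [group_summary()] objects, control group first.
#' @return A list of class `group_comparison`: `summary_a`, `summary_b`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value` (two-sided),
#'   `hedges_g`.
#' @export
two_sample_t <- function(a, b) {
  if (is.numeric(a)) a <- summarize_values(a, "a")
  if (is.numeric(b)) b <- summarize_values(b, "b")
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  df <- a$n + b$n - 2L
  sp <- pooled_sd(a, b)
  diff <- a$mean - b$mean
  if (sp == 0) {
    if (diff == 0) {
      t_stat <- 0; p <- 1; g <- 0
    } else {
      stop("degenerate input: zero pooled variance with unequal means")
    }
  } else {
    t_stat <- diff / (sp * sqrt(1 / a$n + 1 / b$n))
    p <- 2 * pt(-abs(t_stat), df)
    g <- hedges_correction(df) * diff / sp
  }
  structure(list(summary_a = a, summary_b = b, t_statistic = t_stat,
                 degrees_of_freedom = df, p_value = p, hedges_g = g),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: t(%d) = %.3f, p = %.3g, Hedges' g = %.3f\n",
              x$summary_a$label, x$summary_b$label, x$degrees_of_freedom,
              x$t_statistic, x$p_value, x$hedges_g))
  invisible(x)
}

#' Unbalanced two-way ANOVA with interaction (Type III)
#'
#' Factorial ANOVA of treatment effects with cell type and treatment as
#' crossed factors, fitted as a linear model with sum-to-zero factor coding
#' and tested with Type III sums of squares, which are well defined for
#' unbalanced designs. On balanced designs the Type III sums of squares
#' coincide with the classical two-way decomposition.
#'
#' @param effects data.frame with columns `value` (numeric), `cell_type`
#'   and `treatment` (each with exactly two levels present).
#' @return A data.frame of class `anova_table` with one row per term
#'   (`cell_type`, `treatment`, `cell_type:treatment`, `Residuals`) and
#'   columns `sum_of_squares`, `df`, `F`, `p`.
#' @export
two_way_anova_unbalanced <- function(effects) {
  req <- c("value", "cell_type", "treatment")
  if (!all(req %in% names(effects)))
    stop("effects must have columns value, cell_type, treatment")
  effects$cell_type <- factor(effects$cell_type)
  effects$treatment <- factor(effects$treatment)
  if (nlevels(effects$cell_type) < 2 || nlevels(effects$treatment) < 2)
    stop("design error: each factor needs two non-empty levels")
  cells <- table(effects$cell_type, effects$treatment)
  if (sum(cells >= 2) < 3)
    stop("design error: need >= 2 observations in at least 3 of the 4 cells")
  fit <- lm(value ~ cell_type * treatment, data = effects,
            contrasts = list(cell_type = "contr.sum",
                             treatment = "contr.sum"))
  a3 <- car::Anova(fit, type = "III")
  terms <- c("cell_type", "treatment", "cell_type:treatment", "Residuals")
  a3 <- a3[terms, ]
  out <- data.frame(term = terms,
                    sum_of_squares = a3[["Sum Sq"]],
                    df = a3[["Df"]],
                    F = a3[["F value"]],
                    p = a3[["Pr(>F)"]],
                    row.names = NULL)
  class(out) <- c("anova_table", class(out))
  out
}

#' Dose-response summary of percent reductions
#'
#' Per-group mean and SD of the percent reduction `100 - percent_of_pre`,
#' with groups ordered by dose (control, single dose, double dose).
#'
#' @param effects data.frame with columns `group` and `percent_of_pre`.
#' @return A data.frame with `group`, `n`, `mean_reduction`,
#'   `sd_reduction`.
#' @export
dose_response_summary <- function(effects) {
  if (!all(c("group", "percent_of_pre") %in% names(effects)))
    stop("effects must have columns group and percent_of_pre")
  present <- intersect(.groups, unique(effects$group))
  if (!length(present)) stop("no recognized dose groups present")
  do.call(rbind, lapply(present, function(g) {
    red <- 100 - effects$percent_of_pre[effects$group == g]
    data.frame(group = g, n = length(red), mean_reduction = mean(red),
               sd_reduction = if (length(red) > 1) sd(red) else 0)
  }))
}

#' Simulate treatment effects at the count level
#'
#' A fast statistical companion to the full image phantom for power and
#' calibration studies: each sample contributes a pre-treatment object
#' count and a post-treatment count obtained by binomial thinning at a
#' per-sample kill fraction drawn around the nominal one (Beta-distributed
#' with concentration `kill_concentration`, capturing inter-construct
#' heterogeneity; a nominal kill of exactly 0 or 1 is applied exactly).
#'
#' @param design data.frame with columns `group`, `cell_type`, `n`
#'   (samples), `kill` (nominal kill fraction), `pre_count` (objects per
#'   sample before treatment).
#' @param kill_concentration Beta concentration of per-sample kill
#'   fractions (default 60).
#' @return data.frame with one row per simulated sample: `sample_id`,
#'   `group`, `cell_type`, `pre_value`, `post_value`, `percent_of_pre`.
#' @export
simulate_treatment_effects <- function(design, kill_concentration = 60) {
  req <- c("group", "cell_type", "n", "kill", "pre_count")
  if (!all(req %in% names(design)))
    stop("design needs columns ", paste(req, collapse = ", "))
  out <- list()
  sid <- 0
  for (i in seq_len(nrow(design))) {
    for (j in seq_len(design$n[i])) {
      sid <- sid + 1
      mu <- design$kill[i]
      k <- if (mu <= 0 || mu >= 1) mu else
        stats::rbeta(1, mu * kill_concentration, (1 - mu) * kill_concentration)
      pre <- design$pre_count[i]
      post <- rbinom(1, pre, 1 - k)
      out[[sid]] <- data.frame(
        sample_id = sprintf("sim%04d", sid), group = design$group[i],
        cell_type = design$cell_type[i], pre_value = pre, post_value = post,
        percent_of_pre = 100 * post / pre)
    }
  }
  do.call(rbind, out)
}
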