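#' Two-way factorial ANOVA on per-trial, per-morph responses
#'
#' Tests for effects of corolla curvature and nectary diameter (and their
#' interaction) on a stage-1 response such as visitation frequency or
#' foraging success rate. Type II sums of squares are the default because
#' trial exclusions leave the design unbalanced; on balanced designs the SS
#' types agree. Rows with missing responses (e.g. morphs excluded for zero
#' visits) are dropped listwise.
#'
#' @param data data.frame holding the response and the two factor columns.
#' @param response Name of the response column.
#' @param factor1,factor2 Names of the factor columns (default `"c"` and
#'   `"diameter"`).
#' @param ss_type `2` (default), `1` or `3`.
#' @return data.frame with one row per term: `term`, `sum_sq`, `df`,
#'   `F`, `p`.
#' @export
two_way_anova <- function(data, response, factor1 = "c",
                          factor2 = "diameter", ss_type = 2) {
  stopifnot(all(c(response, factor1, factor2) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  f1 = factor(data[[factor1]]),
                  f2 = factor(data[[factor2]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$f1)) < 2 || nlevels(droplevels(d$f2)) < 2)
    stop("each factor needs at least 2 observed levels", call. = FALSE)
  d$f1 <- droplevels(d$f1); d$f2 <- droplevels(d$f2)
  if (stats::sd(d$y) == 0) {
    # constant response: all effect and residual SS are zero
    df1 <- nlevels(d$f1) - 1L; df2 <- nlevels(d$f2) - 1L
    return(data.frame(
      term = c(factor1, factor2, paste(factor1, factor2, sep = ":"),
               "Residuals"),
      sum_sq = 0,
      df = c(df1, df2, df1 * df2,
             nrow(d) - (df1 + 1L) * (df2 + 1L)),
      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA)))
  }
  fit <- stats::lm(y ~ f1 * f2, data = d)
  tab <- if (ss_type == 1) {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
               F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    opts <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(opts))
    fit3 <- stats::lm(y ~ f1 * f2, data = d)
    a <- car::Anova(fit3, type = ss_type)
    data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
               F = a$`F value`, p = a$`Pr(>F)`)
  }
  tab$term <- sub("^f1:f2$", paste(factor1, factor2, sep = ":"), tab$term)
  tab$term <- sub("^f1$", factor1, tab$term)
  tab$term <- sub("^f2$", factor2, tab$term)
  # a constant response has zero SS everywhere: report F = 0, p = 1 rather
  # than 0/0
  degen <- !is.na(tab$df) & !grepl("Residual", tab$term) &
    (is.nan(tab$F) | is.na(tab$F)) & tab$sum_sq < 1e-12
  tab$F[degen] <- 0
  tab$p[degen] <- 1
  rownames(tab) <- NULL
  tab
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's pooled-variance t computed directly from group means, SDs and
#' sizes, as when comparing proboscis length between male and female moths
#' from published summaries: `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size (n >= 2).
#' @param mean2,sd2,n2 Second group's mean, SD, size (n >= 2).
#' @return List with `t`, `df`, `p` (two-tailed), and `pooled_mean` (the
#'   size-weighted overall mean).
#' @examples
#' pooled_t_from_summary(82.19, 3.92, 27, 82.77, 2.55, 31)
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       pooled_mean = (n1 * mean1 + n2 * mean2) / (n1 + n2))
}

#' Regress a fitness metric on proboscis length
#'
#' Ordinary least squares of a per-moth fitness value (e.g. mean energy-gain
#' rate, or mean hits per visit) on proboscis length, with the overall
#' F-test of the regression.
#'
#' @param proboscis_mm Predictor: proboscis lengths, mm.
#' @param fitness Response: one fitness value per moth.
#' @return List with `slope`, `intercept`, `p` (F-test), `r_squared` and the
#'   fitted `lm` object.
#' @export
regress_fitness <- function(proboscis_mm, fitness) {
  ok <- is.finite(proboscis_mm) & is.finite(fitness)
  x <- proboscis_mm[ok]; y <- fitness[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("zero variance in proboscis length", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) 0 else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = unname(p), r_squared = sm$r.squared, fit = fit)
}

#' Simulate per-moth profiles with fitness-proboscis relationships
#'
#' Generates moth profiles (sex, proboscis length) matching observed colony
#' summaries, plus pollinator- and plant-fitness values with configurable
#' linear dependence on proboscis length, for exercising
#' [regress_fitness()] and [pooled_t_from_summary()] end to end.
#'
#' @param n_male,n_female Group sizes (defaults 27 and 31).
#' @param mean_male,sd_male,mean_female,sd_female Proboscis length
#'   distributions, mm.
#' @param pollinator_slope,plant_slope True slopes of the two fitness
#'   metrics on proboscis length (per mm); the pollinator slope is positive
#'   and the plant slope negative by default, encoding the opposing
#'   relationships the regressions should recover.
#' @param noise_sd Residual SD of the fitness values.
#' @param seed Integer seed.
#' @return data.frame with `id`, `sex`, `proboscis_mm`,
#'   `pollinator_fitness`, `plant_fitness`.
#' @export
simulate_moth_profiles <- function(n_male = 27, n_female = 31,
                                   mean_male = 82.19, sd_male = 3.92,
                                   mean_female = 82.77, sd_female = 2.55,
                                   pollinator_slope = 0.3,
                                   plant_slope = -0.8, noise_sd = 1,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  sex <- c(rep("M", n_male), rep("F", n_female))
  len <- c(stats::rnorm(n_male, mean_male, sd_male),
           stats::rnorm(n_female, mean_female, sd_female))
  data.frame(
    id = seq_along(sex), sex = sex, proboscis_mm = len,
    pollinator_fitness = 4 + pollinator_slope * (len - 82.5) +
      stats::rnorm(length(len), 0, noise_sd),
    plant_fitness = 22 + plant_slope * (len - 82.5) +
      stats::rnorm(length(len), 0, noise_sd))
}
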