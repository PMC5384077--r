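# Group-level statistics across DR stages. Two granularities, matching
# standard practice for repeated vessel measurements per subject: ANOVA
# compares per-subject mean descriptors; the linear mixed models work on
# vessel-level rows with a random intercept per subject. Estimation is
# REML (lme4) with Wald 95% CIs and two-sided P-values.

descriptor_columns <- c("d_um", "v_mm_s", "q_pl_s", "wsr_s", "wss_dyn_cm2")

default_adjustment_covariates <- function() {
  c("age", "race", "sex", "map", "hr", "hct", "hba1c")
}

merge_vessels_subjects <- function(vessels, subjects) {
  stopifnot("subject_id" %in% names(vessels),
            all(c("subject_id", "group") %in% names(subjects)))
  m <- match(vessels$subject_id, subjects$subject_id)
  if (anyNA(m)) stop("vessels reference subjects missing from subject table")
  cbind(vessels, subjects[m, setdiff(names(subjects), names(vessels)),
                          drop = FALSE])
}

# Factor coding: control group C is the reference; race reference is the
# largest category (a deterministic, documented default).
prepare_factors <- function(df) {
  df$group <- factor(df$group, levels = intersect(dr_groups, unique(df$group)))
  if ("race" %in% names(df)) {
    tab <- sort(table(df$race), decreasing = TRUE)
    df$race <- factor(df$race, levels = names(tab))
  }
  if ("sex" %in% names(df)) df$sex <- factor(df$sex)
  df
}

#' One-way ANOVA of a descriptor across groups
#'
#' Averages the descriptor per subject (one value per subject), runs a
#' one-way ANOVA across groups, and returns the per-group mean +/- SD
#' summary alongside the F-test P-value.
#'
#' @param vessels vessel-level data frame (e.g. from
#'   \code{\link{simulate_cohort}} or \code{\link{hemodynamics_table}}).
#' @param subjects subject table with \code{subject_id} and \code{group}.
#' @param descriptor name of the descriptor column in \code{vessels}.
#' @return list with \code{p_value}, \code{summary} (data frame: group, n
#'   subjects, n vessels, mean, sd, min, max of the per-subject means), and
#'   \code{descriptor}.
#' @export
group_anova <- function(vessels, subjects, descriptor = "v_mm_s") {
  if (!descriptor %in% names(vessels)) {
    stop(sprintf("descriptor '%s' not found", descriptor))
  }
  df <- prepare_factors(merge_vessels_subjects(vessels, subjects))
  y <- df[[descriptor]]
  per_subj <- aggregate(y, by = list(subject_id = df$subject_id), FUN = mean)
  per_subj$group <- df$group[match(per_subj$subject_id, df$subject_id)]
  counts <- table(per_subj$group)
  if (length(counts) < 2) stop("ANOVA needs at least two groups")
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop(sprintf("group %s has fewer than 2 subjects", small[1]))
  }
  fit <- aov(x ~ group, data = per_subj)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  summ <- do.call(rbind, lapply(split(per_subj, per_subj$group), function(s) {
    data.frame(group = s$group[1], n_subjects = nrow(s),
               n_vessels = sum(df$group == s$group[1]),
               mean = mean(s$x), sd = sd(s$x),
               min = min(s$x), max = max(s$x))
  }))
  rownames(summ) <- NULL
  list(descriptor = descriptor, p_value = p, summary = summ)
}

wald_table <- function(est, se, level = 0.95) {
  zc <- qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_lo = unname(est - zc * se), ci_hi = unname(est + zc * se),
    p_value = unname(2 * pnorm(-abs(est / se)))
  )
}

#' Random-intercept linear mixed model of a descriptor on DR stage
#'
#' Fits \eqn{y_{ij} = X\beta + b_i + \epsilon_{ij}} on vessel-level rows,
#' with a Gaussian random intercept per subject, group C as the reference
#' level, REML estimation and Wald 95\% confidence intervals. The
#' unadjusted model has DR stage as the only fixed effect; the adjusted
#' model adds age, race, sex, MAP, HR, HCT and HbA1c. Rows with missing
#' covariates are dropped (count reported). When no subject contributes
#' more than one vessel the random intercept is not identifiable and the
#' fit falls back to ordinary least squares with a warning.
#'
#' @param vessels vessel-level data frame.
#' @param subjects subject table.
#' @param descriptor descriptor column name.
#' @param adjusted logical; include the covariate fixed effects?
#' @param covariates character vector of covariate column names used when
#'   \code{adjusted = TRUE}.
#' @return a \code{conjflow_model} list: \code{descriptor}, \code{model}
#'   ("unadjusted"/"adjusted"), \code{coefficients} (Wald table),
#'   \code{group_effects} (the DR-stage rows of the table),
#'   \code{sigma_b2}, \code{sigma_e2}, \code{n_subjects}, \code{n_vessels},
#'   \code{n_dropped}, \code{ols_fallback}.
#' @export
fit_mixed_model <- function(vessels, subjects, descriptor = "v_mm_s",
                            adjusted = FALSE,
                            covariates = default_adjustment_covariates()) {
  if (!descriptor %in% names(vessels)) {
    stop(sprintf("descriptor '%s' not found", descriptor))
  }
  df <- prepare_factors(merge_vessels_subjects(vessels, subjects))
  df$.y <- df[[descriptor]]
  fixed <- "group"
  if (adjusted) {
    missing_cov <- setdiff(covariates, names(df))
    if (length(missing_cov)) {
      stop(sprintf("missing covariate column(s): %s",
                   paste(missing_cov, collapse = ", ")))
    }
    fixed <- c(fixed, covariates)
  }
  n0 <- nrow(df)
  df <- df[complete.cases(df[, c(".y", fixed, "subject_id")]), , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (nlevels(droplevels(df$group)) < 2) stop("need at least two groups")

  has_repeats <- any(table(df$subject_id) > 1)
  rhs <- paste(fixed, collapse = " + ")
  if (has_repeats) {
    f <- as.formula(paste(".y ~", rhs, "+ (1 | subject_id)"))
    fit <- lme4::lmer(f, data = df, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore", calc.derivs = FALSE))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- lme4::VarCorr(fit)
    sigma_b2 <- as.numeric(vc$subject_id[1, 1])
    sigma_e2 <- attr(vc, "sc")^2
    ols <- FALSE
  } else {
    warning("no subject has repeated vessels; falling back to ordinary regression")
    fit <- lm(as.formula(paste(".y ~", rhs)), data = df)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    sigma_b2 <- 0
    sigma_e2 <- summary(fit)$sigma^2
    ols <- TRUE
  }
  tab <- wald_table(est, se)
  structure(
    list(
      descriptor = descriptor,
      model = if (adjusted) "adjusted" else "unadjusted",
      coefficients = tab,
      group_effects = tab[grepl("^group", tab$term), , drop = FALSE],
      sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
      n_subjects = length(unique(df$subject_id)), n_vessels = nrow(df),
      n_dropped = n_dropped, ols_fallback = ols, fit = fit
    ),
    class = "conjflow_model"
  )
}

#' @export
print.conjflow_model <- function(x, ...) {
  cat(sprintf("%s mixed model for %s (%d vessels, %d subjects)\n",
              x$model, x$descriptor, x$n_vessels, x$n_subjects))
  print(x$coefficients, digits = 3)
  cat(sprintf("random-intercept var %.4g, residual var %.4g%s\n",
              x$sigma_b2, x$sigma_e2,
              if (x$ols_fallback) " [OLS fallback]" else ""))
  invisible(x)
}

#' Per-group velocity-on-diameter slopes with comparison to control
#'
#' Mixed model of V (mm/s) on D (um) with a group-by-diameter interaction
#' and a random intercept per subject. The per-group slope is the base
#' diameter coefficient plus the group's interaction term, scaled by 1000
#' so slopes are reported in 1/s. The P-value against control is the Wald
#' test of the interaction coefficient.
#'
#' @inheritParams fit_mixed_model
#' @return data frame with one row per group: \code{group},
#'   \code{slope_s} (1/s), \code{ci_lo}, \code{ci_hi}, \code{p_slope}
#'   (slope different from zero), \code{p_vs_control} (NA for the
#'   reference group), \code{model}.
#' @export
velocity_diameter_slopes <- function(vessels, subjects, adjusted = FALSE,
                                     covariates = default_adjustment_covariates()) {
  df <- prepare_factors(merge_vessels_subjects(vessels, subjects))
  if (!all(c("v_mm_s", "d_um") %in% names(df))) {
    stop("vessel table must contain v_mm_s and d_um")
  }
  if (sd(df$d_um, na.rm = TRUE) < 1e-9) stop("no diameter variation")
  fixed <- "d_um * group"
  if (adjusted) fixed <- paste(c(fixed, covariates), collapse = " + ")
  keep <- complete.cases(df[, c("v_mm_s", "d_um", "group", "subject_id",
                                if (adjusted) covariates)])
  df <- df[keep, , drop = FALSE]

  f <- as.formula(paste("v_mm_s ~", fixed, "+ (1 | subject_id)"))
  fit <- lme4::lmer(f, data = df, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore", calc.derivs = FALSE))
  est <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  zc <- qnorm(0.975)

  grp <- levels(droplevels(df$group))
  out <- lapply(grp, function(g) {
    sel <- "d_um"
    inter <- paste0("d_um:group", g)
    slope <- est[["d_um"]] + if (inter %in% names(est)) est[[inter]] else 0
    v <- V["d_um", "d_um"]
    p_int <- NA_real_
    if (inter %in% names(est)) {
      v <- v + V[inter, inter] + 2 * V["d_um", inter]
      z_int <- est[[inter]] / sqrt(V[inter, inter])
      p_int <- 2 * pnorm(-abs(z_int))
    }
    se <- sqrt(v)
    data.frame(
      group = g,
      slope_s = 1000 * slope,
      ci_lo = 1000 * (slope - zc * se),
      ci_hi = 1000 * (slope + zc * se),
      p_slope = 2 * pnorm(-abs(slope / se)),
      p_vs_control = p_int,
      model = if (adjusted) "adjusted" else "unadjusted"
    )
  })
  do.call(rbind, out)
}
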