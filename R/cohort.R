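# Synthetic cohort generator for the statistics stage. Vessel-level
# descriptor values follow the random-intercept model the analysis assumes:
# y_ij = mu_g + b_i + e_ij, with per-subject intercepts b_i ~ N(0, sigma_b^2)
# and Gaussian residuals e_ij ~ N(0, sigma_e^2). Default group means, spreads
# and covariate distributions emulate a four-group diabetic-retinopathy
# staging cohort (control C plus NDR / NPDR / PDR).

dr_groups <- c("C", "NDR", "NPDR", "PDR")

default_cohort_covariates <- function() {
  list(
    age = list(mean = c(C = 61, NDR = 55, NPDR = 58, PDR = 53),
               sd = c(C = 11, NDR = 14, NPDR = 10, PDR = 9)),
    female_prob = c(C = 0.76, NDR = 0.66, NPDR = 0.60, PDR = 0.54),
    race_prob = list(
      C = c(AA = 0.12, White = 0.77, Hispanic = 0.11),
      NDR = c(AA = 0.62, White = 0.21, Hispanic = 0.17),
      NPDR = c(AA = 0.51, White = 0.16, Hispanic = 0.33),
      PDR = c(AA = 0.51, White = 0.14, Hispanic = 0.35)
    ),
    map = list(mean = c(C = 89, NDR = 92, NPDR = 91, PDR = 94),
               sd = c(C = 10, NDR = 11, NPDR = 13, PDR = 17)),
    hr = list(mean = c(C = 69, NDR = 73, NPDR = 78, PDR = 78),
              sd = c(C = 9, NDR = 10, NPDR = 12, PDR = 11)),
    hct = list(mean = c(C = 0.44, NDR = 0.42, NPDR = 0.40, PDR = 0.37),
               sd = c(C = 0.05, NDR = 0.05, NPDR = 0.05, PDR = 0.06)),
    hba1c = list(mean = c(C = 5.5, NDR = 7.4, NPDR = 8.4, PDR = 8.2),
                 sd = c(C = 0.5, NDR = 1.5, NPDR = 1.7, PDR = 2.0))
  )
}

#' Specify a synthetic cohort
#'
#' Defines the statistical structure of a simulated vessel-level data set:
#' per-group subject counts, per-descriptor group means, random-intercept
#' and residual standard deviations, vessels per subject, an optional
#' velocity-on-diameter slope per group, and covariate distributions.
#' Defaults emulate the arteriolar measurements of a four-group DR staging
#' cohort (34/47/45/35 subjects; diameters around 18 um; control velocity
#' 0.70 mm/s with an NDR deficit of 0.16 mm/s).
#'
#' @param group_n named integer vector of subjects per group; names must be
#'   a subset of C, NDR, NPDR, PDR.
#' @param mu named list of per-descriptor group means; each element is a
#'   vector with one named entry per group. Descriptors \code{d_um} and
#'   \code{v_mm_s} are required.
#' @param sigma_b named vector of random-intercept standard deviations per
#'   descriptor.
#' @param sigma_e named vector of residual standard deviations per
#'   descriptor.
#' @param vessels_per_subject c(mean, sd) of the per-subject vessel count
#'   (rounded, floored at 3).
#' @param slope_per_group optional named vector (1/s) of true
#'   velocity-on-diameter slopes; when given, v_mm_s is generated as
#'   mu_v + slope/1000 * (d - mu_d) + b_i + e_ij.
#' @param vessel_type label attached to every generated vessel.
#' @param covariates covariate distribution parameters; see
#'   \code{conjflow:::default_cohort_covariates} for the structure.
#' @return a \code{cohort_spec} object.
#' @export
cohort_spec <- function(group_n = c(C = 34, NDR = 47, NPDR = 45, PDR = 35),
                        mu = list(
                          d_um = c(C = 18, NDR = 19, NPDR = 18, PDR = 18),
                          v_mm_s = c(C = 0.70, NDR = 0.54, NPDR = 0.62,
                                     PDR = 0.64)
                        ),
                        sigma_b = c(d_um = 1.5, v_mm_s = 0.08),
                        sigma_e = c(d_um = 4, v_mm_s = 0.20),
                        vessels_per_subject = c(mean = 12, sd = 6),
                        slope_per_group = NULL,
                        vessel_type = "arteriole",
                        covariates = default_cohort_covariates()) {
  if (length(group_n) < 1 || any(group_n <= 0) || anyNA(group_n)) {
    stop("group_n must contain positive subject counts")
  }
  if (is.null(names(group_n)) || !all(names(group_n) %in% dr_groups)) {
    stop("group labels must be drawn from {C, NDR, NPDR, PDR}")
  }
  if (!all(c("d_um", "v_mm_s") %in% names(mu))) {
    stop("mu must include d_um and v_mm_s")
  }
  for (d in names(mu)) {
    if (!all(names(group_n) %in% names(mu[[d]]))) {
      stop(sprintf("mu$%s lacks a mean for some group", d))
    }
  }
  if (any(sigma_b < 0) || any(sigma_e < 0)) {
    stop("standard deviations must be >= 0")
  }
  if (vessels_per_subject[1] <= 0) stop("vessels per subject must be positive")
  if (!is.null(slope_per_group) &&
      !all(names(group_n) %in% names(slope_per_group))) {
    stop("slope_per_group lacks a slope for some group")
  }
  structure(
    list(group_n = group_n, mu = mu, sigma_b = sigma_b, sigma_e = sigma_e,
         vessels_per_subject = vessels_per_subject,
         slope_per_group = slope_per_group, vessel_type = vessel_type,
         covariates = covariates),
    class = "cohort_spec"
  )
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  clamp(rnorm(n, mean, sd), lo, hi)
}

#' Simulate a vessel-level cohort with known group effects
#'
#' Draws subjects (with covariates) and per-subject vessels under the
#' random-intercept Gaussian model of \code{\link{cohort_spec}}, then adds
#' derived descriptors (Q, WSR, eta, WSS) through the hemodynamic formulas.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer seed fixing all randomness.
#' @return list with \code{subjects} (one row per subject: subject_id,
#'   group, age, sex, race, sbp, dbp, map, hr, hct, hba1c) and
#'   \code{vessels} (one row per vessel: subject_id, vessel_id, segment_id,
#'   type, length_um, n_stations, d_um, v_mm_s, vs_mm_s, q_pl_s, wsr_s,
#'   eta_mpas, wss_dyn_cm2).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  cv <- spec$covariates
  with_seed(seed, {
    groups <- rep(names(spec$group_n), times = spec$group_n)
    ns <- length(groups)
    sid <- sprintf("S%03d", seq_len(ns))

    age <- rtrunc_norm(ns, cv$age$mean[groups], cv$age$sd[groups], 21, 90)
    sex <- ifelse(runif(ns) < cv$female_prob[groups], "F", "M")
    race <- vapply(groups, function(g) {
      p <- cv$race_prob[[g]]
      sample(names(p), 1, prob = p)
    }, character(1))
    map <- rtrunc_norm(ns, cv$map$mean[groups], cv$map$sd[groups], 55, 150)
    pp <- rtrunc_norm(ns, 45, 8, 20, 90)  # pulse pressure
    dbp <- map - pp / 3
    sbp <- dbp + pp
    hr <- rtrunc_norm(ns, cv$hr$mean[groups], cv$hr$sd[groups], 40, 130)
    hct <- rtrunc_norm(ns, cv$hct$mean[groups], cv$hct$sd[groups], 0.15, 0.65)
    hba1c <- rtrunc_norm(ns, cv$hba1c$mean[groups], cv$hba1c$sd[groups], 4, 16)

    subjects <- data.frame(
      subject_id = sid, group = groups, age = age, sex = sex, race = race,
      sbp = sbp, dbp = dbp, map = map, hr = hr, hct = hct, hba1c = hba1c,
      row.names = NULL
    )

    nv <- pmax(3L, round(rnorm(ns, spec$vessels_per_subject[1],
                               spec$vessels_per_subject[2])))
    # per-subject random intercepts, one per descriptor
    b_d <- rnorm(ns, 0, spec$sigma_b["d_um"])
    b_v <- rnorm(ns, 0, spec$sigma_b["v_mm_s"])

    si <- rep(seq_len(ns), times = nv)
    n_total <- length(si)
    g_i <- groups[si]
    d <- spec$mu$d_um[g_i] + b_d[si] + rnorm(n_total, 0, spec$sigma_e["d_um"])
    d <- clamp(d, 6.5, 74.5)
    mu_v <- spec$mu$v_mm_s[g_i]
    if (!is.null(spec$slope_per_group)) {
      mu_v <- mu_v + spec$slope_per_group[g_i] / 1000 *
        (d - spec$mu$d_um[g_i])
    }
    v <- mu_v + b_v[si] + rnorm(n_total, 0, spec$sigma_e["v_mm_s"])
    v <- pmax(v, 0.04)

    vessels <- data.frame(
      subject_id = sid[si],
      vessel_id = paste0(sid[si], "_V", unlist(lapply(nv, seq_len))),
      segment_id = seq_len(n_total),
      type = spec$vessel_type,
      length_um = rtrunc_norm(n_total, 180, 60, 55, 600),
      n_stations = NA_integer_,
      d_um = unname(d),
      v_mm_s = unname(v),
      row.names = NULL
    )
    vessels$n_stations <- pmax(3L, round(vessels$length_um / 1.25 / 5))

    vessels <- hemodynamics_table(vessels, subjects)
    list(subjects = subjects, vessels = vessels)
  })
}
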