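# Derived hemodynamic descriptors. Units follow the conventions of the
# clinical literature: D in um, V and Vs in mm/s, Q in pl/s, WSR in 1/s,
# eta in mPa.s, WSS in dyne/cm^2.

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be strictly positive and finite", name))
  }
  invisible(x)
}

check_diameter <- function(d) {
  check_positive(d, "D")
  if (any(d < 6) || any(d > 75)) {
    stop("D must lie within the 6-75 um measurable range")
  }
  invisible(d)
}

#' Cross-sectional mean velocity from axial velocity
#'
#' Converts the measured axial (centerline) velocity to the mean velocity
#' over the vessel cross-section, \eqn{V_s = V / k}. In microvessels the
#' velocity profile is blunted rather than parabolic, so the conversion
#' factor k is below the Poiseuille value of 2; the default k = 1.6 is the
#' conventional value for microvessels of this calibre and is exposed as a
#' parameter.
#'
#' @param v axial velocity (mm/s), positive.
#' @param d vessel diameter (um), in [6, 75].
#' @param k velocity-profile factor (dimensionless).
#' @return cross-sectional velocity Vs (mm/s).
#' @export
cross_section_velocity <- function(v, d, k = 1.6) {
  check_positive(v, "V")
  check_diameter(d)
  check_positive(k, "k")
  v / k
}

#' Blood flow from cross-sectional velocity and diameter
#'
#' \eqn{Q = V_s \pi D^2 / 4}, returned in pl/s
#' (Vs mm/s, D um: Q[pl/s] = Vs*1000 * pi D^2/4 * 1e-3).
#'
#' @param vs cross-sectional velocity (mm/s).
#' @param d diameter (um).
#' @return blood flow Q (pl/s).
#' @export
blood_flow <- function(vs, d) {
  check_positive(vs, "Vs")
  check_positive(d, "D")
  (vs * 1000) * pi * d^2 / 4 * 1e-3
}

#' Wall shear rate
#'
#' \eqn{WSR = 8 V_s / D} in 1/s (Vs converted to um/s).
#'
#' @inheritParams blood_flow
#' @return wall shear rate (1/s).
#' @export
wall_shear_rate <- function(vs, d) {
  check_positive(vs, "Vs")
  check_positive(d, "D")
  8 * (vs * 1000) / d
}

#' Diameter-dependent blood viscosity
#'
#' Apparent dynamic viscosity of blood in a microvessel from the in-vitro
#' diameter-dependent relative-viscosity law (Pries-type), which captures
#' the Fahraeus-Lindqvist effect:
#' \deqn{\eta_{rel} = 1 + (\eta^*_{0.45} - 1)
#'   \frac{(1-HCT)^C - 1}{(1-0.45)^C - 1}}
#' with \eqn{\eta^*_{0.45} = 220 e^{-1.3D} + 3.2 - 2.44 e^{-0.06 D^{0.645}}}
#' and \eqn{C = (0.8 + e^{-0.075D})(-1 + 1/(1+10^{-11}D^{12})) +
#' 1/(1+10^{-11}D^{12})}. The absolute viscosity is
#' \eqn{\eta = \eta_{plasma} \eta_{rel}}.
#'
#' @param hct hematocrit as a fraction in (0, 1).
#' @param d diameter (um), in [6, 75].
#' @param eta_plasma plasma viscosity (mPa.s).
#' @return dynamic viscosity (mPa.s).
#' @export
blood_viscosity <- function(hct, d, eta_plasma = 1.2) {
  if (any(!is.finite(hct)) || any(hct <= 0) || any(hct >= 1)) {
    stop("HCT must be a fraction in (0, 1)")
  }
  check_diameter(d)
  eta_plasma * relative_viscosity(hct, d)
}

#' @rdname blood_viscosity
#' @export
relative_viscosity <- function(hct, d) {
  eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  dampen <- 1 / (1 + 1e-11 * d^12)
  C <- (0.8 + exp(-0.075 * d)) * (-1 + dampen) + dampen
  1 + (eta45 - 1) * ((1 - hct)^C - 1) / ((1 - 0.45)^C - 1)
}

#' Wall shear stress
#'
#' \eqn{WSS = \eta \cdot WSR}, converted from mPa.s x 1/s (= mPa) to
#' dyne/cm^2 (1 mPa = 0.01 dyne/cm^2).
#'
#' @param eta dynamic viscosity (mPa.s).
#' @param wsr wall shear rate (1/s).
#' @return wall shear stress (dyne/cm^2).
#' @export
wall_shear_stress <- function(eta, wsr) {
  check_positive(eta, "eta")
  check_positive(wsr, "WSR")
  eta * wsr * 0.01
}

#' Mean arterial pressure
#'
#' \eqn{MAP = (SBP + 2 DBP) / 3} (mmHg).
#'
#' @param sbp systolic blood pressure (mmHg).
#' @param dbp diastolic blood pressure (mmHg), not exceeding \code{sbp}.
#' @return mean arterial pressure (mmHg).
#' @export
compute_map <- function(sbp, dbp) {
  check_positive(dbp, "DBP")
  if (any(!is.finite(sbp)) || any(dbp > sbp)) {
    stop("SBP must be finite and >= DBP")
  }
  (sbp + 2 * dbp) / 3
}

#' Keep one record per vessel: the longest-centerline segment
#'
#' When several segments are measured along the same vessel, only the
#' segment with the longest centerline is retained. Ties are broken by the
#' larger diametry station count, then by the lowest segment id.
#'
#' @param records data frame with at least \code{vessel_id},
#'   \code{segment_id}, \code{length_um} and \code{n_stations} columns.
#' @return the de-duplicated data frame (row order: by vessel id).
#' @export
dedupe_longest <- function(records) {
  stopifnot(all(c("vessel_id", "segment_id", "length_um", "n_stations") %in%
                  names(records)))
  if (nrow(records) == 0) return(records)
  ord <- order(records$vessel_id, -records$length_um, -records$n_stations,
               records$segment_id)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(records$vessel_id), , drop = FALSE]
}

#' Assemble the vessel-level hemodynamics table
#'
#' Joins per-vessel (D, V) measurements with the subject table (for HCT)
#' and computes Vs, Q, WSR, eta and WSS per vessel.
#'
#' @param vessels data frame with \code{subject_id}, \code{vessel_id},
#'   \code{type}, \code{d_um}, \code{v_mm_s}, and (optionally)
#'   \code{length_um}.
#' @param subjects data frame with \code{subject_id} and \code{hct}
#'   (fraction).
#' @param k velocity-profile factor.
#' @param eta_plasma plasma viscosity (mPa.s).
#' @return data frame with one row per vessel: the inputs plus
#'   \code{vs_mm_s}, \code{q_pl_s}, \code{wsr_s}, \code{eta_mpas},
#'   \code{wss_dyn_cm2}.
#' @export
hemodynamics_table <- function(vessels, subjects, k = 1.6, eta_plasma = 1.2) {
  stopifnot(all(c("subject_id", "vessel_id", "d_um", "v_mm_s") %in%
                  names(vessels)))
  stopifnot(all(c("subject_id", "hct") %in% names(subjects)))
  m <- match(vessels$subject_id, subjects$subject_id)
  if (anyNA(m)) stop("vessels reference subjects missing from the subject table")
  hct <- subjects$hct[m]
  out <- vessels
  out$vs_mm_s <- cross_section_velocity(vessels$v_mm_s, vessels$d_um, k)
  out$q_pl_s <- blood_flow(out$vs_mm_s, vessels$d_um)
  out$wsr_s <- wall_shear_rate(out$vs_mm_s, vessels$d_um)
  out$eta_mpas <- blood_viscosity(hct, vessels$d_um, eta_plasma)
  out$wss_dyn_cm2 <- wall_shear_stress(out$eta_mpas, out$wsr_s)
  out
}
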