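# Noncompartmental analysis of concentration-time profiles.

# Linear trapezoid sum; the workhorse of AUC_0-t and AUMC_0-t.
trapezoid_auc <- function(times, values) {
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Noncompartmental analysis of a concentration-time profile
#'
#' Computes the standard model-free exposure summary: Cmax and tmax from the
#' observed points (ties broken by earliest time), AUC_0-t and AUMC_0-t by
#' the linear trapezoid rule, a terminal log-linear rate constant from the
#' last `n_terminal` positive observations, the extrapolated AUC_0-inf and
#' AUMC_0-inf, mean residence time MRT = AUMC_0-inf / AUC_0-inf, and -- for
#' IV data with a dose -- observed clearance `Dose / AUC_0-inf` and
#' steady-state volume `Vd_ss = CL_obs * MRT`.
#'
#' If the terminal phase is not declining (fitted slope >= 0) the terminal
#' rate constant and every extrapolated quantity are reported as `NA`.
#'
#' @param profile A [conc_profile()] with at least 3 points.
#' @param dose_mg Administered dose (mg); required for clearance/volume.
#' @param route Route tag; `Vd_ss` and `CL_obs` are only reported for
#'   `"IV"` (elsewhere clearance is confounded with bioavailability).
#' @param n_terminal Number of terminal positive points used for the
#'   log-linear terminal fit (default 3, suiting sparse digitized profiles).
#' @return An object of class `nca_result`: `cmax`, `tmax`, `auc_0t`,
#'   `auc_0inf`, `aumc_0t`, `aumc_0inf`, `mrt`, `vdss`, `cl_obs`,
#'   `terminal_lambda`, `n_obs`.
#' @examples
#' prof <- conc_profile(c(0, 1, 2, 4), c(0, 5, 10, 4))
#' run_nca(prof)
#' @export
run_nca <- function(profile, dose_mg = NA_real_, route = NA_character_,
                    n_terminal = 3) {
  if (!inherits(profile, "conc_profile"))
    stop_user("profile must be a conc_profile")
  t <- profile$times; c <- profile$values
  if (length(t) < 3) stop_user("NCA requires at least 3 points")
  if (all(c == 0)) stop_user("degenerate profile: all concentrations are zero")

  i_max <- which.max(c)  # earliest maximum on ties
  cmax <- c[i_max]; tmax <- t[i_max]
  auc_0t <- trapezoid_auc(t, c)
  aumc_0t <- trapezoid_auc(t, t * c)

  pos <- which(c > 0)
  lambda <- NA_real_
  if (length(pos) >= n_terminal) {
    idx <- utils::tail(pos, n_terminal)
    fit <- stats::lm(log(c[idx]) ~ t[idx])
    slope <- unname(stats::coef(fit)[2])
    if (is.finite(slope) && slope < 0) lambda <- -slope
  }

  auc_0inf <- aumc_0inf <- mrt <- NA_real_
  c_last <- c[length(c)]; t_last <- t[length(t)]
  if (!is.na(lambda) && c_last > 0) {
    auc_0inf <- auc_0t + c_last / lambda
    aumc_0inf <- aumc_0t + c_last * t_last / lambda + c_last / lambda^2
    mrt <- aumc_0inf / auc_0inf
  }

  cl_obs <- vdss <- NA_real_
  if (!is.na(dose_mg) && !is.na(route) && toupper(route) == "IV" &&
      !is.na(auc_0inf)) {
    # dose mg / (ug/L * h) -> L/h requires matching mass units: mg -> ug
    cl_obs <- dose_mg * 1000 / auc_0inf
    vdss <- cl_obs * mrt
  }

  structure(list(cmax = cmax, tmax = tmax, auc_0t = auc_0t,
                 auc_0inf = auc_0inf, aumc_0t = aumc_0t,
                 aumc_0inf = aumc_0inf, mrt = mrt, vdss = vdss,
                 cl_obs = cl_obs, terminal_lambda = lambda,
                 n_obs = length(t), units = profile$units),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result> (conc in ", x$units, ")\n", sep = "")
  fm <- function(v) if (is.na(v)) "NA" else sprintf("%.5g", v)
  cat("  Cmax ", fm(x$cmax), " at tmax ", fm(x$tmax), " h\n", sep = "")
  cat("  AUC_0-t ", fm(x$auc_0t), " | AUC_0-inf ", fm(x$auc_0inf),
      " | AUMC_0-t ", fm(x$aumc_0t), "\n", sep = "")
  cat("  MRT ", fm(x$mrt), " h | lambda_z ", fm(x$terminal_lambda),
      " 1/h | Vdss ", fm(x$vdss), " L\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(cmax = x$cmax, tmax = x$tmax, auc_0t = x$auc_0t,
             auc_0inf = x$auc_0inf, aumc_0t = x$aumc_0t,
             aumc_0inf = x$aumc_0inf, mrt = x$mrt, vdss = x$vdss,
             cl_obs = x$cl_obs, terminal_lambda = x$terminal_lambda,
             n_obs = x$n_obs)
}
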