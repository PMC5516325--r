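# Phosphate-release (malachite-green) assay analysis: calibration,
# time-course rates, Hill fits, catalytic efficiency, relative activity,
# and product-activation fits.

#' Fit a malachite-green calibration line
#'
#' Ordinary least squares of absorbance against known phosphate
#' concentration. Standards whose absorbance falls outside the assay's
#' linear range (0.07-0.85 AU) are excluded with a warning.
#'
#' @param standards data.frame with columns `conc_mM` (known Pi) and
#'   `absorbance_AU`.
#' @param linear_range Absorbance range in which the response is linear.
#' @return A `pi_calibration` with `slope` (AU/mM), `intercept` (AU), `r2`,
#'   `linear_range`, and the retained standards.
#' @export
fit_calibration <- function(standards, linear_range = c(0.07, 0.85)) {
  stopifnot(all(c("conc_mM", "absorbance_AU") %in% names(standards)))
  inr <- standards$absorbance_AU >= linear_range[1L] &
         standards$absorbance_AU <= linear_range[2L]
  if (any(!inr))
    warning(sum(!inr), " standard(s) outside the linear range ",
            linear_range[1L], "-", linear_range[2L], " AU excluded")
  kept <- standards[inr, , drop = FALSE]
  if (nrow(kept) < 3L)
    stop("need at least 3 in-range standards, got ", nrow(kept))
  fit <- stats::lm(absorbance_AU ~ conc_mM, data = kept)
  tss <- sum((kept$absorbance_AU - mean(kept$absorbance_AU))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1,
    linear_range = linear_range,
    standards = kept
  ), class = "pi_calibration")
}

#' Convert absorbance to phosphate concentration
#'
#' Inverts the calibration line; readings outside the linear range are
#' converted anyway but flagged with a warning.
#'
#' @param cal A [fit_calibration] result.
#' @param absorbance_AU Absorbance value(s).
#' @return Pi concentration(s) in mM.
#' @export
pi_from_absorbance <- function(cal, absorbance_AU) {
  stopifnot(inherits(cal, "pi_calibration"))
  out_of_range <- absorbance_AU < cal$linear_range[1L] |
                  absorbance_AU > cal$linear_range[2L]
  if (any(out_of_range))
    warning(sum(out_of_range),
            " absorbance value(s) outside the calibrated linear range")
  (absorbance_AU - cal$intercept) / cal$slope
}

#' @rdname pi_from_absorbance
#' @param conc_mM Pi concentration(s) in mM.
#' @export
absorbance_from_pi <- function(cal, conc_mM) {
  stopifnot(inherits(cal, "pi_calibration"))
  cal$intercept + cal$slope * conc_mM
}

#' Initial rate from a phosphate-release time course
#'
#' The enzyme activity is the slope of the least-squares line through
#' released Pi against time.
#'
#' @param tc data.frame with columns `timepoint_min` (strictly increasing)
#'   and `pi` (released Pi, uM).
#' @return Rate in uM/min; a negative fitted slope is reported as 0 with a
#'   warning.
#' @export
rate_from_timecourse <- function(tc) {
  stopifnot(all(c("timepoint_min", "pi") %in% names(tc)),
            nrow(tc) >= 2L)
  slope <- unname(stats::coef(stats::lm(pi ~ timepoint_min, data = tc))[2L])
  if (is.na(slope) || abs(slope) < 1e-12) slope <- 0
  if (slope < 0) {
    warning("negative fitted slope; reporting rate 0")
    slope <- 0
  }
  slope
}

# Multi-start nonlinear least squares helper: tries every start, keeps the
# converged fit with the lowest residual sum of squares.
multistart_nls <- function(formula, data, starts, lower) {
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("nonlinear fit did not converge from any start")
  best
}

#' Fit the Hill equation to saturation rate data
#'
#' Least-squares fit of `v = vmax * S^h / (s50^h + S^h)` (the half-
#' saturation parameterization: the model value at `S = s50` is exactly
#' `vmax / 2`). Multi-start initialization over a log-spaced `s50` grid and
#' a range of Hill coefficients guards against local minima.
#'
#' @param rates data.frame with columns `conc` (uM, >= 5 distinct values)
#'   and `rate` (uM/s, non-negative).
#' @param enzyme_conc Enzyme concentration in uM (for kcat).
#' @return A `hill_fit` with `vmax` (uM/s), `s50` (uM), `h`, `kcat` (1/s),
#'   `efficiency` (1/s/M, `kcat / (s50 * 1e-6)`), standard errors, `rss`
#'   and the fit object.
#' @export
fit_hill <- function(rates, enzyme_conc) {
  stopifnot(all(c("conc", "rate") %in% names(rates)),
            length(unique(rates$conc)) >= 5L, all(rates$rate >= 0),
            enzyme_conc > 0)
  s50_grid <- exp(seq(log(min(rates$conc[rates$conc > 0])),
                      log(max(rates$conc)), length.out = 4L))
  starts <- list()
  for (s50 in s50_grid)
    for (h in c(0.7, 1, 2, 4))
      starts[[length(starts) + 1L]] <-
        list(vmax = max(rates$rate) * 1.2, s50 = s50, h = h)
  fit <- multistart_nls(rate ~ vmax * conc^h / (s50^h + conc^h),
                        data = rates, starts = starts,
                        lower = c(vmax = 1e-12, s50 = 1e-9, h = 0.05))
  co <- summary(fit)$coefficients
  vmax <- co["vmax", "Estimate"]; s50 <- co["s50", "Estimate"]
  h <- co["h", "Estimate"]
  kcat <- vmax / enzyme_conc
  structure(list(
    vmax = vmax, s50 = s50, h = h,
    kcat = kcat,
    efficiency = catalytic_efficiency(kcat, s50),
    se = c(vmax = co["vmax", "Std. Error"], s50 = co["s50", "Std. Error"],
           h = co["h", "Std. Error"]),
    kcat_se = co["vmax", "Std. Error"] / enzyme_conc,
    enzyme_conc = enzyme_conc,
    rss = sum(stats::residuals(fit)^2),
    converged = fit$convInfo$isConv %||% TRUE,
    fit = fit
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> vmax %.4g uM/s, S50 %.4g uM, h %.3g\n",
              x$vmax, x$s50, x$h))
  cat(sprintf("  kcat %.4g 1/s, kcat/Km %.4g 1/s/M\n", x$kcat, x$efficiency))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat Turnover number in 1/s.
#' @param km_uM Half-saturation concentration in uM.
#' @return Efficiency in 1/s/M: `kcat / (km_uM * 1e-6)`.
#' @examples
#' catalytic_efficiency(1.04, 23.6)  # ~4.41e4
#' @export
catalytic_efficiency <- function(kcat, km_uM) {
  if (any(kcat <= 0) || any(km_uM <= 0))
    stop("kcat and Km must be positive")
  kcat / (km_uM * 1e-6)
}

#' Fit a hyperbolic product-activation model
#'
#' Least-squares fit of `v(x) = v0 * (1 + (fold - 1) * x / (k_act + x))`:
#' basal rate `v0`, plateau/basal ratio `fold`, and the effector
#' concentration of half-maximal stimulation `k_act` (the model value at
#' `x = k_act` is `v0 * (1 + fold) / 2`).
#'
#' @param rates data.frame with columns `conc` (effector, mM, including 0,
#'   >= 5 levels) and `rate`.
#' @return An `activation_fit` with `v0`, `fold`, `k_act`, standard errors,
#'   `rss` and `no_activation` (TRUE when the 95% CI of `fold` includes 1).
#' @export
fit_activation <- function(rates) {
  stopifnot(all(c("conc", "rate") %in% names(rates)),
            length(unique(rates$conc)) >= 5L, any(rates$conc == 0))
  v0_start <- mean(rates$rate[rates$conc == 0])
  fold_start <- max(max(rates$rate) / max(v0_start, 1e-12), 1.01)
  pos <- unique(rates$conc[rates$conc > 0])
  k_grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5L))
  starts <- lapply(k_grid, function(k)
    list(v0 = v0_start, fold = fold_start, k_act = k))
  starts <- c(starts, lapply(k_grid[c(1L, 3L)], function(k)
    list(v0 = v0_start, fold = 2, k_act = k)),
    list(list(v0 = v0_start, fold = 1.1, k_act = stats::median(pos))))
  fit <- tryCatch(
    multistart_nls(rate ~ v0 * (1 + (fold - 1) * conc / (k_act + conc)),
                   data = rates, starts = starts,
                   lower = c(v0 = 1e-12, fold = 1, k_act = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # Degenerate (flat) stimulation curves leave k_act unidentifiable at
    # fold = 1; report the constant-rate limit with the flag set.
    v0 <- mean(rates$rate)
    return(structure(list(
      v0 = v0, fold = 1, k_act = NA_real_,
      se = c(v0 = stats::sd(rates$rate) / sqrt(nrow(rates)),
             fold = NA_real_, k_act = NA_real_),
      rss = sum((rates$rate - v0)^2),
      no_activation = TRUE, fit = NULL), class = "activation_fit"))
  }
  co <- summary(fit)$coefficients
  fold <- co["fold", "Estimate"]; fold_se <- co["fold", "Std. Error"]
  structure(list(
    v0 = co["v0", "Estimate"], fold = fold,
    k_act = co["k_act", "Estimate"],
    se = c(v0 = co["v0", "Std. Error"], fold = fold_se,
           k_act = co["k_act", "Std. Error"]),
    rss = sum(stats::residuals(fit)^2),
    no_activation = (fold - 1.96 * fold_se) <= 1,
    fit = fit
  ), class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("<activation_fit> v0 %.4g, fold %.3g, k_act %.4g mM%s\n",
              x$v0, x$fold, x$k_act,
              if (x$no_activation) " [no activation detectable]" else ""))
  invisible(x)
}

#' Relative activity across assay conditions
#'
#' Each condition's rate is expressed as a percentage of the reference
#' condition (e.g. Mg2+ set to 100%). Rates at or below the detection
#' threshold are reported as not detectable (`n.d.`).
#'
#' @param rates Named numeric vector of rates by condition.
#' @param reference Name of the reference condition (rate must be > 0).
#' @param detection_threshold Rates <= this value are flagged `n.d.`.
#' @return data.frame with `condition`, `rate`, `pct` (NA when not
#'   detectable) and `label` (formatted percentage or `"n.d."`).
#' @export
relative_activity <- function(rates, reference, detection_threshold = 0) {
  if (!reference %in% names(rates))
    stop("reference condition '", reference, "' not present")
  ref_rate <- rates[[reference]]
  if (!is.finite(ref_rate) || ref_rate <= 0)
    stop("reference condition rate must be positive")
  pct <- 100 * rates / ref_rate
  nd <- rates <= detection_threshold
  pct[nd] <- NA_real_
  data.frame(condition = names(rates), rate = unname(rates),
             pct = unname(pct),
             label = ifelse(nd, "n.d.", sprintf("%.0f%%", unname(pct))),
             stringsAsFactors = FALSE)
}

#' Molar enzyme concentration from assay amounts
#'
#' @param amount_ug Protein amount in the reaction (ug).
#' @param volume_ul Reaction volume (ul).
#' @param mass_g_mol Monomer molecular mass (g/mol), e.g. from
#'   [average_mass].
#' @return Concentration in uM.
#' @examples
#' enzyme_molar_uM(1, 100, 27893.16)  # ~0.3585 uM
#' @export
enzyme_molar_uM <- function(amount_ug, volume_ul, mass_g_mol) {
  stopifnot(amount_ug > 0, volume_ul > 0, mass_g_mol > 0)
  amount_ug / mass_g_mol / volume_ul * 1e6
}
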