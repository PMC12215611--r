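# Assay models: decreasing-Hill dose-response with IC50/MIC, -ddCt relative
# expression, and growth-curve endpoint / background rules.

#' Fit a decreasing Hill dose-response curve
#'
#' Least-squares fit of \deqn{OD(c) = top / (1 + (c / IC50)^{hill})}
#' with the lower asymptote fixed at 0 (full inhibition at saturating dose).
#' Initial values: \code{top} = maximum OD, \code{ic50} = dose whose mean OD
#' is nearest half-maximum, \code{hill} = 1; all parameters bounded positive.
#' 95\% confidence intervals are Wald intervals from the estimated
#' coefficient covariance. The minimal inhibitory concentration (MIC) is
#' defined as the fitted IC50. A dose series with no decrease in OD (mean OD
#' in the top dose quartile at least that of the bottom quartile) is flagged
#' non-identifiable.
#'
#' @param dose Concentration vector (>= 0).
#' @param od Observed OD values (same length).
#' @return A list of class \code{"hill_fit"}: \code{coefficients} (top, ic50,
#'   hill), \code{ci} (2 x 3 matrix, 95\% Wald), \code{mic},
#'   \code{identifiable}, \code{fitted} (function of dose), \code{model}.
#' @export
#' @examples
#' d <- simulate_dose_response(top = 1, ic50 = 10, hill = 2, seed = 1)
#' fit <- fit_hill(d$dose, d$od)
#' fit$coefficients
fit_hill <- function(dose, od) {
  stopifnot(length(dose) == length(od))
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (any(od < 0)) stop("OD values must be non-negative", call. = FALSE)
  if (length(unique(dose)) < 4L) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  qs <- quantile(dose, c(0.25, 0.75))
  identifiable <- mean(od[dose >= qs[2]]) < mean(od[dose <= qs[1]])
  if (!identifiable) {
    warning("no decrease across the dose range; fit flagged non-identifiable",
            call. = FALSE)
  }
  top0 <- max(od)
  pos <- dose > 0
  half <- abs(od - top0 / 2)
  ic0 <- if (any(pos)) dose[pos][which.min(half[pos])] else 1
  m <- tryCatch(
    minpack.lm::nlsLM(
      od ~ top / (1 + (dose / ic50)^hill),
      start = list(top = top0, ic50 = ic0, hill = 1),
      lower = c(top = 1e-12, ic50 = 1e-12, hill = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      if (identifiable) stop(e)
      NULL
    }
  )
  if (is.null(m)) {
    est <- c(top = NA_real_, ic50 = NA_real_, hill = NA_real_)
    ci <- rbind(lower = est, upper = est)
    return(structure(
      list(coefficients = est, ci = ci, mic = NA_real_,
           identifiable = FALSE, fitted = function(c) rep(NA_real_, length(c)),
           model = NULL),
      class = "hill_fit"
    ))
  }
  est <- coef(m)
  se <- sqrt(diag(vcov(m)))
  z <- qnorm(0.975)
  ci <- rbind(lower = est - z * se, upper = est + z * se)
  structure(
    list(coefficients = est, ci = ci, mic = unname(est["ic50"]),
         identifiable = identifiable,
         fitted = function(c) {
           est["top"] / (1 + (c / est["ic50"])^est["hill"])
         },
         model = m),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Decreasing Hill fit: OD(c) = top / (1 + (c/IC50)^hill)\n")
  print(round(rbind(estimate = x$coefficients, x$ci), 4))
  cat("MIC (= IC50):", signif(x$mic, 4),
      if (!x$identifiable) " [non-identifiable]" else "", "\n")
  invisible(x)
}

#' Relative expression as -ddCt
#'
#' \deqn{-\Delta\Delta C_T = (C_T^{target,ctrl} - C_T^{ref,ctrl}) -
#'   (C_T^{target,trt} - C_T^{ref,trt})}
#' with fold change \eqn{2^{-\Delta\Delta C_T}}. Positive values mean the
#' target is induced in the treated condition relative to the reference gene.
#'
#' @param ct_target_treated,ct_reference_treated Ct of target and reference
#'   gene in the treated condition.
#' @param ct_target_control,ct_reference_control Ct of target and reference
#'   gene in the control condition.
#' @return A list: \code{minus_ddct}, \code{fold_change}.
#' @export
#' @examples
#' ddct(20, 15, 22, 15) # target drops 2 cycles: 4-fold induction
ddct <- function(ct_target_treated, ct_reference_treated,
                 ct_target_control, ct_reference_control) {
  vals <- c(ct_target_treated, ct_reference_treated,
            ct_target_control, ct_reference_control)
  if (!all(is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  mddct <- (ct_target_control - ct_reference_control) -
    (ct_target_treated - ct_reference_treated)
  list(minus_ddct = mddct, fold_change = 2^mddct)
}

#' Growth-curve endpoint time
#'
#' The endpoint of a plate-growth experiment: the first time at which the
#' no-treatment control culture reaches \code{saturation_fraction} of its
#' maximum OD.
#'
#' @param time Strictly increasing time vector.
#' @param od Control OD values (same length).
#' @param saturation_fraction Fraction of the maximum defining saturation.
#' @return The endpoint time.
#' @export
growth_endpoint <- function(time, od, saturation_fraction = 0.9) {
  stopifnot(length(time) == length(od), all(diff(time) > 0))
  if (length(od) > 1L && all(diff(od) < 0)) {
    stop("control curve is monotone decreasing; no growth endpoint",
         call. = FALSE)
  }
  time[which(od >= saturation_fraction * max(od))[1]]
}

#' Background-corrected final OD
#'
#' The OD at the endpoint (the last measured time at or before it) minus the
#' background, defined as the fifth-smallest OD of the series (plant-material
#' absorbance decays over time, so the initial reading can exceed the true
#' background).
#'
#' @param time Strictly increasing time vector (>= 5 points).
#' @param od Sample OD values.
#' @param endpoint Endpoint time from \code{\link{growth_endpoint}}.
#' @return Background-corrected OD at the endpoint.
#' @export
final_od <- function(time, od, endpoint) {
  stopifnot(length(time) == length(od), all(diff(time) > 0))
  if (length(od) < 5L) {
    stop("need at least 5 measurements to define the background", call. = FALSE)
  }
  idx <- which(time <= endpoint)
  if (length(idx) == 0L) {
    stop("endpoint precedes the first measurement", call. = FALSE)
  }
  background <- sort(od)[5]
  od[max(idx)] - background
}
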