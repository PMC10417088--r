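#' Median split of a numeric covariate into high/low groups
#'
#' `"high"` for values strictly above the median, `"low"` otherwise (ties at
#' the median go to the low group).
#'
#' @param values Numeric vector (>= 2 values, not all identical), optionally
#'   named by sample.
#' @return Character vector of `"high"`/`"low"` labels, same names.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop_("need >= 2 values")
  if (length(unique(values)) == 1L)
    stop_("degenerate split: all values identical")
  med <- stats::median(values)
  stats::setNames(ifelse(values > med, "high", "low"), names(values))
}

#' Two-group Kaplan-Meier curves and log-rank test
#'
#' @param time Non-negative survival/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping factor/character, e.g., a [median_split()].
#' @return List with `chisq` (1-df log-rank statistic), `p`, and `fit`
#'   (the `survfit` object with per-group KM curves).
#' @export
km_logrank <- function(time, event, group) {
  check_survival_inputs(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop_("'group' must have exactly 2 non-empty levels")
  if (sum(event) < 1L) stop_("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       fit = survival::survfit(survival::Surv(time, event) ~ group))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling. Non-convergence or an
#' unstable (e.g., separated) fit is flagged rather than raised.
#'
#' @inheritParams km_logrank
#' @param x Numeric covariate (must vary; typically an immune fraction).
#' @return List with `beta`, `se`, `hr`, `ci_lower`, `ci_upper` (Wald 95%),
#'   `p`, `n_events`, and `flagged`.
#' @export
cox_univariate <- function(time, event, x) {
  check_survival_inputs(time, event)
  if (length(unique(x)) == 1L) stop_("covariate is constant")
  if (sum(event) < 2L) stop_("need >= 2 events")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                    control = survival::coxph.control(iter.max = 100L)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || se > 1e3) flagged <- TRUE
  z <- stats::qnorm(0.975)
  list(beta = beta, se = se, hr = exp(beta),
       ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
       p = 2 * stats::pnorm(-abs(beta / se)),
       n_events = sum(event), flagged = flagged)
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-sided, Satterthwaite degrees of freedom. If both groups have zero
#' variance and equal means, `t = 0`, `p = 1` by convention.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_("both groups need >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the point-probability criterion: the
#' p-value sums the probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = exposure
#'   high/low, columns = outcome yes/no).
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(4, 169, 0, 180), 2, byrow = TRUE))
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == 2L))
    stop_("'tab' must be a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab)))
    stop_("counts must be non-negative integers")
  if (sum(tab) == 0) stop_("empty table")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Min-max scaling of survival times to \[0, 1\]
#'
#' @param times Numeric vector with >= 2 distinct values.
#' @return `(t - min) / (max - min)`.
#' @export
minmax_survival_scale <- function(times) {
  if (length(unique(times)) < 2L) stop_("all times identical; scale undefined")
  (times - min(times)) / (max(times) - min(times))
}

#' Assign etiology risk-group labels from clinical flags
#'
#' Deterministic precedence rule for patients with several risk factors:
#' by default HBV > HCV > alcohol; patients with no flag are `"none"`.
#' Missing flags are treated as absent.
#'
#' @param hbv,hcv,alcohol Logical vectors (recycled NA -> FALSE).
#' @param precedence Order in which flags win (default
#'   `c("HBV", "HCV", "alcohol")`).
#' @return Character vector of risk labels.
#' @export
risk_group_assign <- function(hbv, hcv, alcohol,
                              precedence = c("HBV", "HCV", "alcohol")) {
  flags <- list(HBV = isTRUE_vec(hbv), HCV = isTRUE_vec(hcv),
                alcohol = isTRUE_vec(alcohol))
  if (!setequal(precedence, names(flags)))
    stop_("'precedence' must order HBV, HCV, alcohol")
  n <- length(flags$HBV)
  out <- rep("none", n)
  for (lab in rev(precedence)) out[flags[[lab]]] <- lab
  multi <- Reduce(`+`, flags) > 1L
  if (any(multi))
    message(sprintf("%d patient(s) with multiple risk flags assigned by precedence %s",
                    sum(multi), paste(precedence, collapse = " > ")))
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

check_survival_inputs <- function(time, event) {
  if (length(time) != length(event)) stop_("'time' and 'event' lengths differ")
  if (any(time < 0)) stop_("'time' must be non-negative")
  if (!all(event %in% c(0, 1))) stop_("'event' must be 0/1")
  invisible(NULL)
}
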