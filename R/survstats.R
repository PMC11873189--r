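#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with 95% confidence band; the median survival time
#' is the first time at which the survival probability drops to 0.5 or
#' below, `NA` when never reached.
#'
#' @param time,event survival outcome (time in months, event 1 = death).
#' @return list of class `ct_km`: `time`, `surv`, `lower`, `upper`,
#'   `median`, `n`.
#' @export
km_fit <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- s$time[s$surv <= 0.5][1]
  structure(list(time = s$time, surv = s$surv, lower = s$lower,
                 upper = s$upper, median = if (length(med)) med else NA_real_,
                 n = length(time)),
            class = "ct_km")
}

#' @export
print.ct_km <- function(x, ...) {
  cat(sprintf("<ct_km> n = %d, median survival = %s months\n", x$n,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Hazard ratio between two groups
#'
#' Univariate Cox proportional-hazards fit (Efron ties) on a binary group
#' label; reports the hazard ratio of the second factor level versus the
#' first, its 95% confidence interval, and the Wald p-value.
#'
#' @param group two-level factor/vector of group labels.
#' @param time,event survival outcome.
#' @return data.frame coef / hr / ci_lower / ci_upper / p / c_index.
#' @export
hazard_ratio <- function(group, time, event) {
  g <- factor(group)
  if (nlevels(g) != 2L) stopf("hazard_ratio needs exactly two groups (got %d)", nlevels(g))
  if (any(tapply(event, g, sum) == 0)) warnf("a group has no events; fit may be unstable")
  fit <- survival::coxph(survival::Surv(time, event) ~ g, ties = "efron")
  sm <- summary(fit)
  data.frame(coef = unname(stats::coef(fit)),
             hr = unname(sm$conf.int[1, "exp(coef)"]),
             ci_lower = unname(sm$conf.int[1, "lower .95"]),
             ci_upper = unname(sm$conf.int[1, "upper .95"]),
             p = unname(sm$coefficients[1, "Pr(>|z|)"]),
             c_index = unname(sm$concordance["C"]))
}
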