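# Survival arm: Kaplan-Meier curves, two-group log-rank test and Cox
# proportional-hazards fits relating the M2 infiltration group (and other
# covariates) to overall survival. Estimation is delegated to the
# `survival` package (Breslow tie handling for Cox).

#' Assemble a survival table
#'
#' @param patient_id character vector.
#' @param time follow-up times (months), finite and positive.
#' @param event event indicator (1 = death observed, 0 = censored).
#' @param group `"high"`/`"low"` M2 infiltration group.
#' @param ... further covariate vectors (numeric or categorical), recycled
#'   rules as in `data.frame()`.
#' @return `data.frame` of class `hemil_survival`.
#' @export
survival_table <- function(patient_id, time, event, group, ...) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop_invalid("survival times must be finite and positive")
  if (!all(event %in% c(0, 1))) stop_invalid("event must be 0/1")
  if (!all(group %in% c("high", "low")))
    stop_invalid("group must be 'high' or 'low'")
  df <- data.frame(patient_id = as.character(patient_id),
                   time = as.numeric(time), event = as.integer(event),
                   group = as.character(group), ...,
                   stringsAsFactors = FALSE)
  class(df) <- c("hemil_survival", "data.frame")
  df
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator for each level of `group_by`; the curve starts
#' at 1, steps only at event times, and censored subjects leave the risk
#' set after their time.
#'
#' @param records a [survival_table()] (or data frame with `time`, `event`).
#' @param group_by grouping column name (default `"group"`).
#' @return Named list of class `hemil_km`: per group a data frame
#'   `time, n_risk, n_event, survival`.
#' @export
km_curve <- function(records, group_by = "group") {
  if (nrow(records) < 1L) stop_invalid("no records")
  groups <- split(records, records[[group_by]])
  out <- lapply(groups, function(d) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv)
  })
  structure(out, class = "hemil_km")
}

#' Two-group log-rank test
#'
#' @param records a [survival_table()].
#' @param group_by grouping column with exactly two levels.
#' @return List `chi_square`, `p` (1 df chi-square).
#' @export
logrank_test <- function(records, group_by = "group") {
  g <- records[[group_by]]
  if (length(unique(g)) != 2L)
    stop_invalid("log-rank test needs exactly 2 groups, got ",
                 length(unique(g)))
  if (sum(records$event) < 1L) stop_invalid("log-rank test needs >= 1 event")
  d <- records
  d$..g <- g
  fit <- survival::survdiff(survival::Surv(time, event) ~ ..g, data = d)
  chi <- fit$chisq
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling and Wald 95%
#' confidence intervals. One covariate gives the univariate model; several
#' give the multivariate model ("independent risk factor" analysis).
#' Categorical covariates enter treatment-coded with the first level as
#' reference; `group` is coded so the hazard ratio is high-vs-low.
#'
#' @param records a [survival_table()].
#' @param covariates character vector of covariate column names.
#' @return Data frame of class `hemil_cox`: one row per model term with
#'   `covariate, hazard_ratio, ci_low, ci_high, p_value, n, n_events`.
#'   Attribute `fit` carries the underlying `coxph` object.
#' @export
cox_fit <- function(records, covariates = "group") {
  if (sum(records$event) < 1L) stop_invalid("Cox fit needs >= 1 event")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stop_invalid("unknown covariates: ", paste(missing_cov, collapse = ", "))
  d <- as.data.frame(records)
  for (cv in covariates) {
    x <- d[[cv]]
    if (length(unique(x[!is.na(x)])) < 2L)
      stop_invalid("covariate '", cv, "' is constant")
    if (cv == "group") d[[cv]] <- factor(x, levels = c("low", "high"))
    else if (is.character(x)) d[[cv]] <- factor(x)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "breslow"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        warning("possible monotone likelihood (perfect separation); ",
                "estimates clamped at last iteration", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  res <- data.frame(
    covariate = rownames(s$coefficients),
    hazard_ratio = s$coefficients[, "exp(coef)"],
    ci_low  = s$conf.int[, "lower .95"],
    ci_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    n = s$n, n_events = s$nevent,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("hemil_cox", "data.frame")
  attr(res, "fit") <- fit
  res
}

#' Write survival results
#'
#' @param x a `hemil_cox` table or `hemil_km` list.
#' @param path CSV output path.
#' @return `x` invisibly.
#' @export
write_cox <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}

#' @rdname write_cox
#' @export
write_km <- function(x, path) {
  df <- do.call(rbind, lapply(names(x), function(g)
    cbind(group = g, x[[g]])))
  write.csv(df, path, row.names = FALSE)
  invisible(x)
}
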