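# Cox proportional-hazards survival core on the AGE time scale: records enter
# follow-up at 40 (or 75 for the older age window) and exit at death or at
# censoring when a living parent's age was reported. Partial-likelihood
# maximisation is delegated to survival::coxph; the Breslow baseline
# cumulative hazard and Martingale residuals are computed here, since the
# residual-sum identity that downstream scans rely on is exact under the
# Breslow estimator.

#' Fit a Cox proportional-hazards model to parental survival records
#'
#' @param records data.frame with columns `entry`, `observed_age` (exit age),
#'   `event` (1 died, 0 censored alive), plus any covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty for the null model).
#' @param genotype optional numeric vector or matrix of genotype dosages (one
#'   column per variant) fitted simultaneously with the covariates, as in a
#'   verification or multi-variant model.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @return object of class `kin_cox_fit`: `coefficients` (log-HRs), `vcov`,
#'   `basehaz` (Breslow cumulative-hazard step table), `loglik`, `n`,
#'   `nevent`, linear predictor and the survival triplet (kept for residuals).
#'   Covariates that are constant in the data get coefficient 0 and an NA
#'   variance rather than failing the fit.
#' @export
fit_cox <- function(records, covariates = NULL, genotype = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  need <- c("entry", "observed_age", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing column(s): ", paste(miss, collapse = ", "))
  entry <- records$entry
  exit <- records$observed_age
  event <- records$event
  if (anyNA(entry) || anyNA(exit) || anyNA(event))
    stop("survival records contain missing values; run apply_exclusions first")
  if (any(exit <= entry)) stop("every exit age must exceed its entry age")
  if (sum(event) < 1) stop("degenerate data: no events (deaths) in the records")

  X <- NULL
  if (!is.null(covariates) && length(covariates) > 0) {
    missc <- setdiff(covariates, names(records))
    if (length(missc)) stop("unknown covariate column(s): ", paste(missc, collapse = ", "))
    X <- as.matrix(records[, covariates, drop = FALSE])
  }
  if (!is.null(genotype)) {
    G <- as.matrix(genotype)
    if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(ncol(G)))
    X <- if (is.null(X)) G else cbind(X, G)
  }

  nm <- colnames(X)
  coefs <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(X)) {
    keep <- apply(X, 2, function(col) stats::var(col) > 0)
  } else keep <- logical(0)

  if (!is.null(X) && any(keep)) {
    Xf <- X[, keep, drop = FALSE]
    df <- data.frame(.entry = entry, .exit = exit, .event = event, Xf,
                     check.names = FALSE)
    fml <- stats::as.formula(paste(
      "survival::Surv(.entry, .exit, .event) ~",
      paste(sprintf("`%s`", colnames(Xf)), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = ties,
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 50))
    if (any(is.na(stats::coef(fit))))
      stop("Cox fit failed: singular model matrix")
    if (fit$iter >= 50)
      stop("Cox fit did not converge after 50 iterations; max |score| = ",
           format(max(abs(colSums(survival::coxph.detail(fit)$score)))))
    coefs[colnames(Xf)] <- stats::coef(fit)
    vc <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    vc[colnames(Xf), colnames(Xf)] <- stats::vcov(fit)
    lp <- as.numeric(Xf %*% stats::coef(fit))
    loglik <- fit$loglik
    iter <- fit$iter
  } else {
    vc <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    lp <- rep(0, length(exit))
    loglik <- NULL
    iter <- 0L
  }

  bh <- breslow_cumhaz(entry, exit, event, lp)
  structure(list(coefficients = coefs, vcov = vc, ties = ties,
                 basehaz = bh, loglik = loglik, iter = iter,
                 n = length(exit), nevent = sum(event),
                 lp = lp, entry = entry, exit = exit, event = event),
            class = "kin_cox_fit")
}

#' @export
print.kin_cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (age scale): n = %d records, %d events, ties = %s\n",
              x$n, x$nevent, x$ties))
  if (length(x$coefficients)) {
    se <- sqrt(diag(x$vcov))
    tab <- data.frame(coef = x$coefficients, HR = exp(x$coefficients), se = se,
                      z = x$coefficients / se,
                      p = 2 * stats::pnorm(-abs(x$coefficients / se)))
    print(tab, digits = 4)
  } else cat("  (null model, no covariates)\n")
  invisible(x)
}

#' Breslow estimator of the baseline cumulative hazard
#'
#' Step function with increments `d_t / sum(exp(lp))` over the risk set
#' `entry < t <= exit` at each event time `t`. With this baseline the
#' Martingale residuals sum to zero exactly, for any coefficient vector.
#'
#' @param entry,exit,event survival triplet (delayed entry supported).
#' @param lp linear predictor per record (default 0: Nelson-Aalen).
#' @return data.frame with `time` (unique event times), `hazard` (increment)
#'   and `cumhaz` (nondecreasing, zero before the first event).
#' @export
breslow_cumhaz <- function(entry, exit, event, lp = rep(0, length(exit))) {
  w <- exp(lp)
  et <- sort(unique(exit[event == 1]))
  dt <- as.numeric(rowsum(rep(1, sum(event == 1)),
                          factor(exit[event == 1], levels = et)))
  ex_s <- sort(exit)
  wx <- cumsum(exp(lp)[order(exit)])
  en_s <- sort(entry)
  we <- cumsum(w[order(entry)])
  # risk-set weight at t: sum w over entry < t minus sum w over exit < t
  n_en <- findInterval(et, en_s, left.open = TRUE)  # count entry < t
  n_ex <- findInterval(et, ex_s, left.open = TRUE)  # count exit  < t
  risk <- ifelse(n_en > 0, we[pmax(n_en, 1)], 0) -
    ifelse(n_ex > 0, wx[pmax(n_ex, 1)], 0)
  dh <- dt / risk
  data.frame(time = et, hazard = dh, cumhaz = cumsum(dh))
}

# cumulative baseline hazard accrued over (entry, exit] per record
.cumhaz_interval <- function(bh, entry, exit) {
  H <- function(t) {
    i <- findInterval(t, bh$time)  # count of event times <= t
    ifelse(i > 0, bh$cumhaz[pmax(i, 1)], 0)
  }
  H(exit) - H(entry)
}

#' Martingale residuals from a Cox fit
#'
#' `residual_i = event_i - exp(lp_i) * (H0(exit_i) - H0(entry_i))` with the
#' Breslow baseline of the fit: the difference between the observed and the
#' model-expected number of deaths for each record. Residuals are bounded
#' above by 1 and, under the Breslow baseline, sum to zero.
#'
#' @param fit a [fit_cox()] result.
#' @param records optional: the records the fit was computed on, for a
#'   consistency check; a mismatch in size or survival times is an error.
#' @return numeric vector of residuals, one per record.
#' @export
martingale_residuals <- function(fit, records = NULL) {
  if (!inherits(fit, "kin_cox_fit")) stop("fit must be a kin_cox_fit")
  if (!is.null(records)) {
    if (nrow(records) != fit$n ||
        !isTRUE(all.equal(records$observed_age, fit$exit)) ||
        !isTRUE(all.equal(as.numeric(records$event), as.numeric(fit$event))))
      stop("records do not match the fitted model (size or survival times differ)")
  }
  fit$event - exp(fit$lp) * .cumhaz_interval(fit$basehaz, fit$entry, fit$exit)
}

#' @export
residuals.kin_cox_fit <- function(object, ...) martingale_residuals(object)

#' Restricted mean life years by genotype class
#'
#' Area under the Kaplan-Meier survival curve from entry to `horizon`, per
#' genotype class. The difference between adjacent classes is the per-allele
#' life-year effect on the offspring scale; double it (see
#' [rescale_to_parent_scale()]) for the parental scale.
#'
#' @param records survival records as in [fit_cox()].
#' @param group genotype class per record (coercible to factor).
#' @param horizon restriction age in years; defaults to the maximum observed
#'   age in the data.
#' @return data.frame with one row per class: `group`, `n`, `events`,
#'   `life_years` (restricted mean beyond entry).
#' @export
km_life_years <- function(records, group, horizon = NULL) {
  stopifnot(length(group) == nrow(records))
  horizon <- horizon %||% max(records$observed_age)
  entry0 <- min(records$entry)
  g <- factor(group)
  out <- lapply(levels(g), function(lev) {
    r <- records[g == lev, , drop = FALSE]
    if (nrow(r) == 0) stop("empty genotype class: ", lev)
    if (all(r$observed_age <= r$entry))
      stop("undefined estimate: all records censored at entry in class ", lev)
    sf <- survival::survfit(survival::Surv(entry, observed_age, event) ~ 1,
                            data = r)
    tab <- summary(sf, rmean = horizon)$table
    rm_i <- grep("rmean", names(tab))[1]
    data.frame(group = lev, n = nrow(r), events = sum(r$event),
               life_years = unname(tab[rm_i]) - entry0)
  })
  do.call(rbind, out)
}

#' Restrict survival records to an age-at-death window
#'
#' For the younger window (`"40-75"`), exits are capped at 75 and deaths
#' beyond 75 are recoded as survivors at 75. For the older window (`"75+"`),
#' only records with follow-up beyond 75 are kept (survival to 75 is
#' complete by construction) and entry is reset to 75, so the analysis
#' examines survival beyond 75 only.
#'
#' @param records survival records as in [fit_cox()].
#' @param window `"40-75"` or `"75+"` (alias `"75plus"`).
#' @param split the window boundary age (default 75).
#' @return transformed records (possibly fewer rows for the older window).
#' @export
truncate_age_window <- function(records, window = c("40-75", "75+", "75plus"),
                                split = 75) {
  window <- match.arg(window)
  out <- records
  if (window == "40-75") {
    late <- out$observed_age > split
    out$event[late] <- 0L
    out$observed_age[late] <- split
  } else {
    out <- out[out$observed_age > split, , drop = FALSE]
    out$entry <- split
    rownames(out) <- NULL
  }
  out
}

#' Serialize a Cox fit to JSON
#'
#' @param fit a [fit_cox()] result.
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_cox_json <- function(fit, path) {
  obj <- list(coefficients = as.list(fit$coefficients),
              vcov = fit$vcov, ties = fit$ties,
              n = fit$n, nevent = fit$nevent,
              loglik = fit$loglik,
              basehaz = fit$basehaz)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
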