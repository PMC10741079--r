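#' Dichotomize a marker score at the point of highest slope
#'
#' Automatic cutpoint: the location of the maximum absolute derivative of a
#' Gaussian kernel-density estimate (Silverman bandwidth) of the cohort score
#' distribution, searched between the 10th and 90th percentiles. A supplied
#' `override` (the manual, visually-corrected path) wins and is recorded as
#' `method = "manual"`. Patients strictly above the cutpoint are high;
#' a score exactly at the cutpoint is low.
#'
#' @param scores numeric vector of per-patient scores (>= 10 patients,
#'   non-constant).
#' @param override optional manual cutpoint.
#' @param marker optional marker name recorded in the result.
#' @return An object of class `mfihc_cutpoint`: list with `marker`,
#'   `cutpoint`, `method`, and `high`, the logical per-patient flags.
#' @export
highest_slope_threshold <- function(scores, override = NULL, marker = NA) {
  if (length(scores) < 10L)
    stop("need at least 10 patients to place a cutpoint")
  if (diff(range(scores)) == 0)
    stop("scores are constant; no cutpoint exists")
  if (!is.null(override)) {
    cut <- override
    method <- "manual"
  } else {
    d <- stats::density(scores, bw = "nrd0")
    slope <- diff(d$y) / diff(d$x)
    xm <- (d$x[-1] + d$x[-length(d$x)]) / 2
    q <- stats::quantile(scores, c(0.1, 0.9))
    in_win <- xm >= q[1] & xm <= q[2]
    if (!any(in_win)) in_win <- rep(TRUE, length(xm))
    cut <- xm[in_win][which.max(abs(slope[in_win]))]
    method <- "highest_slope_auto"
  }
  structure(list(marker = marker, cutpoint = unname(cut), method = method,
                 high = scores > cut),
            class = "mfihc_cutpoint")
}

#' @export
print.mfihc_cutpoint <- function(x, ...) {
  cat(sprintf("Cutpoint for %s: %.3f (%s); %d high / %d low\n",
              x$marker, x$cutpoint, x$method, sum(x$high), sum(!x$high)))
  invisible(x)
}

#' Five-marker prognosis score
#'
#' Sum over PR, ER, AR, GATA3 and PD-L1 of the per-patient high flags
#' (high = 1 point), giving an integer score from 0 to 5. Missing flags are
#' an error — no imputation.
#'
#' @param flags data.frame or named list of logical vectors; must contain
#'   `<marker>_high` (or bare marker-named) entries for all five markers.
#' @param markers the five markers (default [SCORE_MARKERS]).
#' @return integer vector of scores in 0..5.
#' @export
five_marker_score <- function(flags, markers = SCORE_MARKERS) {
  get_flag <- function(m) {
    v <- flags[[paste0(m, "_high")]]
    if (is.null(v)) v <- flags[[m]]
    if (is.null(v) || anyNA(v))
      stop(sprintf("missing high/low flag for marker '%s'", m))
    as.logical(v)
  }
  cols <- lapply(markers, get_flag)
  n <- unique(lengths(cols))
  if (length(n) != 1L) stop("flag vectors differ in length")
  as.integer(Reduce(`+`, cols))
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate with right censoring, one curve per group
#' (computed via [survival::survfit()]).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators, 0 = censored, 1 = event.
#' @param groups optional grouping vector (single group when omitted).
#' @return named list of per-group step functions, each a data.frame with
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(times, events, groups = NULL) {
  check_surv(times, events)
  if (is.null(groups)) groups <- rep("all", length(times))
  if (any(table(groups) == 0L) || length(unique(groups)) == 0L)
    stop("empty group")
  fits <- lapply(split(seq_along(times), groups), function(i) {
    f <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
    data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
               surv = f$surv)
  })
  fits
}

#' Log-rank test for survival differences between groups
#'
#' Standard k-group log-rank chi-square ([survival::survdiff()]), p-value
#' from a chi-square distribution with k - 1 degrees of freedom.
#'
#' @inheritParams kaplan_meier
#' @param groups grouping vector with >= 2 non-empty groups.
#' @return An object of class `mfihc_test`: list with `test`, `statistic`,
#'   `df`, `p_value`, `group_sizes`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank test needs at least two groups")
  if (sum(events) == 0L) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  structure(list(test = "log-rank", statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 group_sizes = as.integer(sd$n)),
            class = "mfihc_test")
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling
#' ([survival::coxph()]); per-covariate hazard ratios with Wald 95%
#' confidence intervals and p-values.
#'
#' @inheritParams kaplan_meier
#' @param covariates data.frame (or vector) of numeric / 0-1 coded
#'   covariates; no missing values.
#' @return An object of class `mfihc_cox`: list with `coefficients`
#'   (data.frame: term, coef, hr, lower, upper, p), `n`, `n_event`, and the
#'   underlying `fit`.
#' @export
cox_ph <- function(times, events, covariates) {
  check_surv(times, events)
  X <- as.data.frame(covariates)
  if (anyNA(X)) stop("covariates contain missing values")
  if (all(vapply(X, function(v) length(unique(v)) == 1L, logical(1))))
    stop("all covariates are constant; hazard ratios are undefined")
  dat <- cbind(data.frame(.time = times, .event = events), X)
  not_conv <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(.time, .event) ~ ., data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        not_conv <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (not_conv)
    stop(sprintf("Cox model did not converge after %d iterations", fit$iter))
  s <- summary(fit)
  co <- data.frame(term = rownames(s$coefficients),
                   coef = s$coefficients[, "coef"],
                   hr = s$coefficients[, "exp(coef)"],
                   lower = s$conf.int[, "lower .95"],
                   upper = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = co, n = s$n, n_event = s$nevent, fit = fit),
            class = "mfihc_cox")
}

#' @export
print.mfihc_cox <- function(x, ...) {
  cat(sprintf("Cox PH (Breslow ties): n = %d, events = %d\n", x$n,
              x$n_event))
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-20s HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                co$term[i], co$hr[i], co$lower[i], co$upper[i], co$p[i]))
  invisible(x)
}

#' @export
print.mfihc_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, df = %d, p = %.4g\n",
              x$test, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Time-dependent AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at horizon `t`: cases are subjects
#' with an event at or before `t`, controls those still at risk beyond `t`;
#' each subject is weighted by the inverse of the Kaplan-Meier estimate of
#' the censoring survival function (IPCW), evaluated just before the event
#' time for cases and at `t` for controls. Ties in the score count 1/2.
#'
#' @param score numeric risk score (higher = more at risk).
#' @inheritParams kaplan_meier
#' @param horizon evaluation time within the follow-up range.
#' @return list with `auc`, `horizon`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(score, times, events, horizon) {
  check_surv(times, events)
  stopifnot(length(score) == length(times))
  is_case <- times <= horizon & events == 1
  is_ctrl <- times > horizon
  if (!any(is_case)) stop("no cases (events) before the horizon")
  if (!any(is_ctrl)) stop("no controls at risk beyond the horizon")
  # censoring-distribution KM: flip the event indicator
  cfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  eps <- 1e-9
  w_case <- 1 / pmax(G(times[is_case] - eps), eps)
  w_ctrl <- rep(1 / pmax(G(horizon), eps), sum(is_ctrl))
  sc <- score[is_case]
  sk <- score[is_ctrl]
  num <- 0
  for (i in seq_along(sc)) {
    cmpv <- (sc[i] > sk) + 0.5 * (sc[i] == sk)
    num <- num + w_case[i] * sum(w_ctrl * cmpv)
  }
  den <- sum(w_case) * sum(w_ctrl)
  list(auc = num / den, horizon = horizon,
       n_cases = sum(is_case), n_controls = sum(is_ctrl))
}

#' Association between marker status and a clinical category
#'
#' r x c chi-square test (without continuity correction) of high/low status
#' against a clinical category, with a descriptive mean +/- SD table of the
#' continuous score per category alongside; a Kruskal-Wallis rank test on
#' the continuous score is reported as an alternative when `score` is given.
#'
#' @param status factor-like high/low (or any categorical) vector.
#' @param category clinical category vector (pT, pN, M or grade levels).
#' @param score optional continuous per-patient score for the descriptive
#'   table and the rank-based alternative.
#' @return An object of class `mfihc_assoc`: list with `chisq`
#'   (statistic, df, p_value), `table`, optional `descriptives`
#'   (category, n, mean, sd) and `kruskal` (statistic, df, p_value).
#' @export
association_test <- function(status, category, score = NULL) {
  tab <- table(status, category)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("association test needs at least a 2x2 table")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop("expected cell count of zero; category levels are degenerate")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(chisq = list(statistic = unname(ct$statistic),
                           df = unname(ct$parameter),
                           p_value = ct$p.value),
              table = tab)
  if (!is.null(score)) {
    agg <- data.frame(category = levels(factor(category)))
    agg$n <- as.integer(table(factor(category)))
    agg$mean <- as.numeric(tapply(score, factor(category), mean))
    agg$sd <- as.numeric(tapply(score, factor(category), stats::sd))
    kw <- stats::kruskal.test(score, factor(category))
    out$descriptives <- agg
    out$kruskal <- list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter),
                        p_value = kw$p.value)
  }
  class(out) <- "mfihc_assoc"
  out
}

#' @export
print.mfihc_assoc <- function(x, ...) {
  cat(sprintf("chi-square association: X2 = %.4f, df = %d, p = %.4g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  if (!is.null(x$descriptives)) {
    cat("score by category (mean +/- SD):\n")
    d <- x$descriptives
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-8s n=%4d  %5.1f (+/-%.1f)\n", d$category[i], d$n[i],
                  d$mean[i], d$sd[i]))
    cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
                x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  }
  invisible(x)
}

check_surv <- function(times, events) {
  if (length(times) == 0L || length(times) != length(events))
    stop("times and events must be non-empty and aligned")
  if (any(times < 0)) stop("survival times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}
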