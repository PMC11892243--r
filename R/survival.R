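#' Truncate follow-up at five years
#'
#' Patients followed beyond 1825 days have their time set to 1825 days and
#' are censored; everyone else is unchanged. Idempotent.
#'
#' @param table A cohort data frame with `time_days` and `event` columns.
#' @param limit_days Truncation horizon (default 1825).
#' @return The table with five-year truncation applied.
#' @export
censor_at_5_years <- function(table, limit_days = 1825) {
  if (any(!is.finite(table$time_days)) || any(table$time_days <= 0)) {
    bad <- which(!is.finite(table$time_days) | table$time_days <= 0)
    ids <- if (!is.null(table$id)) table$id[bad] else bad
    itil_error("itil_invalid_row",
               paste("nonpositive follow-up time for:",
                     paste(utils::head(ids, 10), collapse = ", ")))
  }
  if (!all(table$event %in% c(0, 1))) {
    itil_error("itil_invalid_row", "event indicator must be 0 or 1")
  }
  over <- table$time_days > limit_days
  table$event[over] <- 0L
  table$time_days[over] <- limit_days
  table
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survival estimates per group and the two-sided log-rank
#' test, via the survival package.
#'
#' @param table Cohort data frame with `time_days` and `event`.
#' @param group Grouping vector (length `nrow(table)`) or the name of a
#'   column in `table`.
#' @return List with `fit` (a [survival::survfit] object), `curves` (step
#'   function data frame: group, time, n_risk, surv), `chisq`, `df`,
#'   `p_value`.
#' @export
km_logrank <- function(table, group) {
  if (is.character(group) && length(group) == 1) group <- table[[group]]
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) {
    itil_error("itil_invalid_argument",
               "log-rank test needs at least two nonempty groups")
  }
  d <- data.frame(time = table$time_days, event = table$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
  sm <- summary(fit)
  curves <- data.frame(
    group = sub("^group=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, surv = sm$surv
  )
  list(fit = fit, curves = curves, chisq = unname(sd$chisq),
       df = length(sd$n) - 1, p_value = unname(p))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood estimation (Efron tie handling) of hazard ratios with
#' 95% confidence intervals and Wald p-values. One covariate gives the
#' univariate analysis; the full roster gives the multivariate one.
#'
#' @param table Cohort data frame with `time_days`, `event` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return List with `fit` (the [survival::coxph] object) and `table`
#'   (data frame: covariate, n, HR, ci_low, ci_high, p).
#' @export
cox_fit <- function(table, covariates) {
  if (length(covariates) == 0) {
    itil_error("itil_invalid_argument", "at least one covariate is required")
  }
  missing_cols <- setdiff(covariates, names(table))
  if (length(missing_cols)) {
    itil_error("itil_invalid_argument",
               paste("unknown covariates:", paste(missing_cols, collapse = ", ")))
  }
  d <- table[stats::complete.cases(table[covariates]), , drop = FALSE]
  for (cv in covariates) {
    if (length(unique(d[[cv]])) < 2) {
      itil_error("itil_invalid_argument",
                 sprintf("covariate '%s' is constant after removing missing rows", cv))
    }
  }
  if (sum(d$event) == 0) {
    itil_error("itil_invalid_argument", "no events present")
  }
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d)
  if (!is.null(fit$info) && any(is.na(stats::coef(fit)))) {
    itil_error("itil_fit_failure", "proportional-hazards fit did not converge")
  }
  s <- summary(fit)
  out <- data.frame(
    covariate = rownames(s$coefficients),
    n = s$n,
    HR = unname(s$conf.int[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    p = unname(s$coefficients[, "Pr(>|z|)"])
  )
  rownames(out) <- NULL
  list(fit = fit, table = out)
}

# log-rank p and approximate log hazard ratio for a binary split
logrank_split <- function(time, event, high) {
  d <- data.frame(time = time, event = event, g = factor(high, c(FALSE, TRUE)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  p <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  # O/E-based approximation, enough for tie-breaking on |log HR|
  loghr <- log((sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1]))
  c(p = unname(p), loghr = unname(loghr))
}

#' Grouped search for the optimal density cut-off
#'
#' Reproduces the discovery procedure for the 17 iTILs/mm^2 threshold:
#' patients are randomly split into `k_groups` equally sized groups
#' (stratified by event status to stabilise per-repeat event counts) and
#' the analysis is repeated `k_groups` times with a different group
#' excluded each time. Within each repeat every grid cut-off is scored by
#' the log-rank p-value of the High-vs-Low split ("most significant
#' stratification"; ties broken by larger absolute log hazard ratio, then
#' by the smaller cut-off); cut-offs emptying either group are skipped.
#' The consensus is the cut-off optimal in every repeat when one exists,
#' otherwise the modal per-repeat optimum, reported as non-unanimous.
#'
#' @param table Cohort data frame with `time_days`, `event` and
#'   `ai_itil_score`.
#' @param grid Candidate cut-offs (default integers 1 to 100 per mm^2).
#' @param k_groups Number of held-out groups (default 5).
#' @param seed Integer seed for the random split.
#' @return A `cutoff_search_result`: list with `per_repeat` (data frame:
#'   repeat index, optimal cut-off, p, log HR), `tables` (per-repeat
#'   per-cutoff data frames), `consensus`, `unanimous`.
#' @export
cutoff_search <- function(table, grid = 1:100, k_groups = 5, seed = 1) {
  if (length(grid) == 0) itil_error("itil_invalid_argument", "empty cut-off grid")
  if (any(!is.finite(table$ai_itil_score))) {
    itil_error("itil_invalid_argument", "scores must be finite")
  }
  n <- nrow(table)
  # key the split to patient identity (fall back to row position) so the
  # search is invariant to table row order
  key <- if (!is.null(table$id)) order(table$id) else seq_len(n)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (ev in sort(unique(table$event))) {
      idx <- key[table$event[key] == ev]
      f[idx] <- sample(rep_len(seq_len(k_groups), length(idx)))
    }
    f
  })
  per_repeat <- list()
  tables <- list()
  for (j in seq_len(k_groups)) {
    d <- table[folds != j, , drop = FALSE]
    rows <- lapply(grid, function(cut) {
      high <- d$ai_itil_score >= cut
      if (all(high) || !any(high)) return(NULL)
      st <- logrank_split(d$time_days, d$event, high)
      data.frame(cutoff = cut, p = st["p"], loghr = st["loghr"])
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    if (is.null(tab) || nrow(tab) == 0) {
      itil_error("itil_invalid_argument",
                 "no grid cut-off yields two nonempty groups")
    }
    ord <- order(tab$p, -abs(tab$loghr), tab$cutoff)
    best <- tab[ord[1], ]
    per_repeat[[j]] <- data.frame(repeat_index = j, cutoff = best$cutoff,
                                  p = best$p, loghr = best$loghr)
    tables[[j]] <- tab
  }
  pr <- do.call(rbind, per_repeat)
  if (length(unique(pr$cutoff)) == 1) {
    consensus <- pr$cutoff[1]; unanimous <- TRUE
  } else {
    cnt <- base::table(pr$cutoff)
    consensus <- as.numeric(names(cnt)[which.max(cnt)])
    unanimous <- FALSE
  }
  structure(list(per_repeat = pr, tables = tables, consensus = consensus,
                 unanimous = unanimous, grid = grid, k_groups = k_groups,
                 seed = seed),
            class = "cutoff_search_result")
}

#' @export
print.cutoff_search_result <- function(x, ...) {
  cat(sprintf("<cutoff_search_result> consensus cut-off %g per mm^2 (%s across %d repeats)\n",
              x$consensus, if (x$unanimous) "unanimous" else "modal", x$k_groups))
  print(x$per_repeat, row.names = FALSE)
  invisible(x)
}

#' Stage II clinical risk classification
#'
#' Clinical high risk in Stage II colorectal cancer: any of T4 stage, high
#' grade, extramural venous invasion, lymphovascular invasion, or fewer
#' than 12 lymph nodes examined; low risk means none of the five. Patients
#' missing any of the five features are `"unclassified"`.
#'
#' @param covariates Data frame with logical columns `t4`, `grade_high`,
#'   `emvi`, `lvi`, `nodes_lt12`.
#' @return Character vector: `"high"`, `"low"` or `"unclassified"`.
#' @export
clinical_risk <- function(covariates) {
  feats <- c("t4", "grade_high", "emvi", "lvi", "nodes_lt12")
  missing_cols <- setdiff(feats, names(covariates))
  if (length(missing_cols)) {
    itil_error("itil_invalid_argument",
               paste("missing risk features:", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(covariates[feats])
  out <- ifelse(rowSums(is.na(m)) > 0, "unclassified",
                ifelse(rowSums(m, na.rm = TRUE) > 0, "high", "low"))
  unname(out)
}
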