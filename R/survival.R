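#' Pull one survival endpoint out of a clinical table
#'
#' Endpoints live as `<name>_time` / `<name>_event` column pairs. The
#' alias map translates alternative endpoint vocabularies (for example
#' the curated-resource names `DFI` and `PFI`) onto the package's
#' canonical OS/DSS/DFS/PFS names. Rows with missing time or event, or
#' nonpositive time, are dropped and counted.
#'
#' @param clinical Clinical tibble with `sample_id`.
#' @param endpoint Endpoint name, e.g. `"OS"`.
#' @param aliases Named character vector mapping alternative stored names
#'   to canonical ones (default maps `DFI -> DFS`, `PFI -> PFS`).
#' @return Tibble `sample_id`, `time`, `event`; attribute `n_dropped`
#'   counts removed rows.
#' @export
extract_endpoint <- function(clinical, endpoint,
                             aliases = c(DFI = "DFS", PFI = "PFS")) {
  stems <- sub("_time$", "", grep("_time$", names(clinical), value = TRUE))
  available <- stems[paste0(stems, "_event") %in% names(clinical)]
  stem <- if (endpoint %in% available) {
    endpoint
  } else {
    # the requested canonical name may be stored under an alias
    alt <- names(aliases)[aliases == endpoint]
    alt <- alt[alt %in% available]
    # or the stored name may itself be an alias key
    if (!length(alt) && endpoint %in% names(aliases) &&
        aliases[[endpoint]] %in% available) {
      alt <- aliases[[endpoint]]
    }
    if (!length(alt)) {
      abort(sprintf("endpoint '%s' not found; available: %s",
                    endpoint, paste(available, collapse = ", ")))
    }
    alt[[1]]
  }
  time <- clinical[[paste0(stem, "_time")]]
  event <- clinical[[paste0(stem, "_event")]]
  keep <- !is.na(time) & !is.na(event) & time > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("endpoint %s: dropped %d sample(s) with missing or nonpositive time/event.",
                   endpoint, n_dropped))
  }
  if (!sum(keep)) abort(sprintf("endpoint '%s' has no usable samples.", endpoint))
  if (!all(event[keep] %in% c(0, 1))) abort("event indicators must be 0/1.")
  out <- tibble(sample_id = clinical$sample_id[keep],
                time = time[keep], event = as.integer(event[keep]))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' First-principles implementation: at each distinct event time `t_j` with
#' `d_j` events among `n_j` at risk, survival multiplies by
#' `1 - d_j / n_j`. Censoring at an event time is processed after the
#' events at that time (the censored subject counts as at risk there).
#' Greenwood standard errors and log-scale confidence bands are included.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = event, 0 = censored).
#' @param conf_level Confidence level for the Greenwood bands.
#' @return An object of class `"km_curve"`; `tidy()` returns the
#'   step-curve table, `glance()` the one-row summary.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) == 0) abort("empty input.")
  if (length(time) != length(event)) abort("`time` and `event` lengths differ.")
  if (any(!is.finite(time)) || any(time <= 0)) abort("times must be positive and finite.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")

  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), integer(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), integer(1))
  survival <- cumprod(1 - n_event / n_risk)

  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  std_err <- survival * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # log-scale bands, clipped to [0, 1]
  with_log <- survival > 0
  lower <- upper <- rep(NA_real_, length(survival))
  lower[with_log] <- pmax(0, exp(log(survival[with_log]) - z * sqrt(gw[with_log])))
  upper[with_log] <- pmin(1, exp(log(survival[with_log]) + z * sqrt(gw[with_log])))
  lower[!with_log] <- 0
  upper[!with_log] <- 0

  structure(list(
    table = tibble(time = ut, n_risk = n_risk, n_event = n_event,
                   n_censor = n_censor, survival = survival,
                   std_err = std_err, lower = lower, upper = upper),
    censor_times = sort(time[event == 0]),
    n = n, n_events = sum(event), conf_level = conf_level
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, %d distinct event times\n",
              x$n, x$n_events, nrow(x$table)))
  print(head(x$table, 10))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.km_curve <- function(x, ...) {
  med <- km_median(x)
  tibble(n = x$n, n_events = x$n_events,
         n_censored = x$n - x$n_events, median_survival = med)
}

# first time at which the estimate drops to <= 0.5 (NA if it never does)
km_median <- function(curve) {
  tab <- curve$table
  i <- which(tab$survival <= 0.5)
  if (length(i)) tab$time[min(i)] else NA_real_
}

# survival probability at an arbitrary time (right-continuous step)
km_survival_at <- function(curve, at) {
  tab <- curve$table
  vapply(at, function(t) {
    i <- which(tab$time <= t)
    if (length(i)) tab$survival[max(i)] else 1
  }, numeric(1))
}

#' Two-group logrank test
#'
#' Standard (Mantel-Cox) logrank, implemented from first principles: at
#' each distinct event time the observed events in group 1 are compared
#' with the hypergeometric expectation given the risk sets, tied events
#' pooled into one draw; the statistic is `(O - E)^2 / V` on 1 df.
#'
#' @param time,event As in [km_estimate()].
#' @param group A vector with exactly two distinct non-missing values.
#' @return Object of class `"logrank_test"` with chi-square statistic,
#'   p-value and per-group observed/expected event counts; supports
#'   `tidy()` and `glance()`.
#' @export
logrank_test <- function(time, event, group) {
  if (!(length(time) == length(event) && length(time) == length(group))) {
    abort("`time`, `event`, `group` must have equal length.")
  }
  keep <- !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- as.character(group[keep])
  lev <- sort(unique(group))
  if (length(lev) != 2) abort("`group` must have exactly two distinct values.")
  if (!all(lev %in% group)) abort("one group is empty.")
  if (any(time <= 0)) abort("times must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")

  g1 <- group == lev[1]
  n_per_group <- c(sum(g1), sum(!g1))
  names(n_per_group) <- lev
  observed <- c(sum(event[g1]), sum(event[!g1]))
  names(observed) <- lev

  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) {
    warn("no events in either group; logrank p reported as 1.")
    res <- list(chi2 = 0, df = 1L, p = 1,
                observed = observed, expected = observed * 0,
                variance = 0, n_per_group = n_per_group, groups = lev)
    return(structure(res, class = "logrank_test"))
  }

  e1 <- v <- numeric(length(ut))
  o1 <- numeric(length(ut))
  for (j in seq_along(ut)) {
    t <- ut[j]
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & g1)
    dj <- sum(time == t & event == 1)
    o1[j] <- sum(time == t & event == 1 & g1)
    e1[j] <- dj * n1j / nj
    v[j] <- if (nj > 1) dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1) else 0
  }
  E1 <- sum(e1)
  V <- sum(v)
  expected <- c(E1, sum(event) - E1)
  names(expected) <- lev
  chi2 <- if (V > 0) (sum(o1) - E1)^2 / V else 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)

  structure(list(chi2 = chi2, df = 1L, p = p,
                 observed = observed, expected = expected,
                 variance = V, n_per_group = n_per_group, groups = lev),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Logrank test\n")
  print(tibble(group = x$groups, n = unname(x$n_per_group),
               observed = unname(x$observed), expected = unname(x$expected)))
  cat(sprintf("chi2 = %.4f on %d df, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logrank_test <- function(x, ...) {
  tibble(group = x$groups, n = unname(x$n_per_group),
         observed = unname(x$observed), expected = unname(x$expected))
}

#' @exportS3Method generics::glance
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' Survival analysis per endpoint and stratum for the ratio groups
#'
#' For every requested endpoint (optionally within every level of a
#' stratification column, e.g. PAM50 subtype) this computes Kaplan-Meier
#' curves for the `COL1_HIGH`, `COL3_HIGH` and `OTHER` groups and the
#' two-group logrank test comparing `COL1_HIGH` against `COL3_HIGH`
#' (`OTHER` is plotted but never tested). Comparison groups with fewer
#' than 2 usable samples cause that block's test to be skipped with a
#' warning.
#'
#' @param clinical Clinical tibble.
#' @param labels Output of [classify_patients()] (or any tibble with
#'   `sample_id` and `label`).
#' @param endpoints Character vector of endpoint names.
#' @param strata Optional name of a clinical column to stratify on.
#' @param aliases Endpoint alias map, see [extract_endpoint()].
#' @return Tibble with one row per endpoint x stratum: group sizes and
#'   event counts, `chi2`, `p`, and list-columns `curves` (named list of
#'   `km_curve` objects) and `test` (the `logrank_test`, or NULL).
#' @export
survival_by_group <- function(clinical, labels,
                              endpoints = c("OS", "DSS", "DFS", "PFS"),
                              strata = NULL,
                              aliases = c(DFI = "DFS", PFI = "PFS")) {
  if (!all(c("sample_id", "label") %in% names(labels))) {
    abort("`labels` must have sample_id and label columns.")
  }
  if (!is.null(strata) && !strata %in% names(clinical)) {
    abort(sprintf("stratum column '%s' not in clinical table.", strata))
  }
  strata_levels <- if (is.null(strata)) {
    "all"
  } else {
    sort(unique(stats::na.omit(clinical[[strata]])))
  }

  rows <- list()
  for (ep in endpoints) {
    surv <- extract_endpoint(clinical, ep, aliases = aliases)
    surv <- dplyr::inner_join(surv, labels[, c("sample_id", "label")],
                              by = "sample_id")
    for (st in strata_levels) {
      block <- if (is.null(strata)) {
        surv
      } else {
        ids <- clinical$sample_id[!is.na(clinical[[strata]]) &
                                    clinical[[strata]] == st]
        dplyr::filter(surv, .data$sample_id %in% ids)
      }
      grp <- function(g) dplyr::filter(block, .data$label == g)
      counts <- vapply(c("COL1_HIGH", "COL3_HIGH", "OTHER"),
                       function(g) nrow(grp(g)), integer(1))
      curves <- list()
      for (g in c("COL1_HIGH", "COL3_HIGH", "OTHER")) {
        b <- grp(g)
        if (nrow(b) >= 2) curves[[g]] <- km_estimate(b$time, b$event)
      }
      test <- NULL
      if (counts[["COL1_HIGH"]] >= 2 && counts[["COL3_HIGH"]] >= 2) {
        two <- dplyr::filter(block, .data$label %in% c("COL1_HIGH", "COL3_HIGH"))
        test <- logrank_test(two$time, two$event, droplevels(factor(two$label)))
      } else {
        warn(sprintf("endpoint %s, stratum %s: a comparison group has < 2 samples; logrank skipped.",
                     ep, st))
      }
      events <- vapply(c("COL1_HIGH", "COL3_HIGH", "OTHER"), function(g) {
        b <- grp(g); if (nrow(b)) sum(b$event) else 0L
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble(
        endpoint = ep, stratum = as.character(st),
        n_col1_high = counts[["COL1_HIGH"]],
        n_col3_high = counts[["COL3_HIGH"]],
        n_other = counts[["OTHER"]],
        events_col1_high = events[["COL1_HIGH"]],
        events_col3_high = events[["COL3_HIGH"]],
        events_other = events[["OTHER"]],
        chi2 = if (is.null(test)) NA_real_ else test$chi2,
        p = if (is.null(test)) NA_real_ else test$p,
        curves = list(curves),
        test = list(test)
      )
    }
  }
  list_rbind(rows)
}

#' Fisher exact tests of subtype composition between the ratio groups
#'
#' For each molecular subtype, a 2x2 table (this subtype vs all others,
#' by `COL1_HIGH` vs `COL3_HIGH`) is tested with a two-sided Fisher exact
#' test (point-probability rule), BH-adjusted across subtypes. Under the
#' stromal-ratio hypothesis no subtype should be enriched: tumors of any
#' intrinsic subtype are equally likely to fall in either ratio group.
#'
#' @param labels Output of [classify_patients()].
#' @param clinical Clinical tibble with `sample_id` and `subtype`.
#' @return Tibble per subtype: the 2x2 counts, odds ratio, `p`, `q`.
#' @export
subtype_association <- function(labels, clinical) {
  dat <- dplyr::inner_join(labels[, c("sample_id", "label")],
                           clinical[, c("sample_id", "subtype")],
                           by = "sample_id")
  dat <- dplyr::filter(dat, .data$label %in% c("COL1_HIGH", "COL3_HIGH"))
  for (g in c("COL1_HIGH", "COL3_HIGH")) {
    sub <- dat$subtype[dat$label == g]
    if (!length(sub) || all(is.na(sub))) {
      abort(sprintf("group %s has no subtype calls.", g))
    }
  }
  dat <- dplyr::filter(dat, !is.na(.data$subtype))
  subtypes <- sort(unique(dat$subtype))
  rows <- map(subtypes, function(s) {
    tab <- matrix(c(
      sum(dat$subtype == s & dat$label == "COL1_HIGH"),
      sum(dat$subtype == s & dat$label == "COL3_HIGH"),
      sum(dat$subtype != s & dat$label == "COL1_HIGH"),
      sum(dat$subtype != s & dat$label == "COL3_HIGH")
    ), nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    tibble(subtype = s,
           n_col1_high = tab[1, 1], n_col3_high = tab[1, 2],
           rest_col1_high = tab[2, 1], rest_col3_high = tab[2, 2],
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- list_rbind(rows)
  out$q <- bh_adjust(out$p)
  out
}
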