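test_that("endpoint extraction selects, aliases and cleans columns", {
  clin <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    OS_time = c(5, 3, NA, 2, -1), OS_event = c(1, 0, 1, NA, 1),
    DFI_time = 1:5, DFI_event = c(1, 1, 0, 0, 1))
  out <- suppressMessages(extract_endpoint(clin, "OS"))
  expect_equal(out$sample_id, c("s1", "s2"))
  expect_equal(attr(out, "n_dropped"), 3)
  # canonical name resolves through the alias map to the stored DFI pair
  dfs <- extract_endpoint(clin, "DFS")
  expect_equal(nrow(dfs), 5)
  err <- tryCatch(extract_endpoint(clin, "PFS"), error = conditionMessage)
  expect_match(err, "OS")
})

test_that("product-limit estimate matches hand-computed curves", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$table$n_risk, c(3L, 2L, 1L))
  # all censored: flat at 1, no event rows
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km2$table), 0)
  expect_equal(collagenkit:::km_survival_at(km2, 10), 1)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  with_seed_local(3, {
    t <- sample(rexp(40, 0.2))
    km <- km_estimate(t, rep(1, 40))
    ecdf_surv <- vapply(km$table$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$table$survival, ecdf_surv, tolerance = 1e-12)
  })
})

test_that("KM curve matches the survival package on random censored data", {
  skip_if_not_installed("survival")
  with_seed_local(17, {
    for (rep in 1:10) {
      n <- 30
      t <- rexp(n, 0.3)
      e <- rbinom(n, 1, 0.6)
      if (!sum(e)) e[1] <- 1
      km <- km_estimate(t, e)
      sf <- survival::survfit(survival::Surv(t, e) ~ 1)
      oracle <- summary(sf, times = km$table$time)$surv
      expect_lt(max(abs(km$table$survival - oracle)), 1e-10)
    }
  })
})

test_that("logrank handles degenerate inputs per contract", {
  t <- c(1, 2, 3, 1, 2, 3)
  e <- c(1, 0, 1, 1, 0, 1)
  g <- rep(c("A", "B"), each = 3)
  # identical data in both groups: no separation
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-10)
  expect_warning(logrank_test(t, rep(0, 6), g), "no events")
  expect_error(logrank_test(t, e, rep("A", 6)), "two distinct")
})

test_that("logrank equals the survival package and is label-symmetric", {
  skip_if_not_installed("survival")
  # the small worked dataset: group A events at 1,2,3; B at 4,5,6
  t <- c(1, 2, 3, 4, 5, 6)
  e <- rep(1, 6)
  g <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_lt(abs(lr$chi2 - sd$chisq), 1e-8)
  expect_lt(abs(lr$p - stats::pchisq(sd$chisq, 1, lower.tail = FALSE)), 1e-8)
  # relabeling leaves the statistic unchanged
  swapped <- logrank_test(t, e, ifelse(g == "A", "B", "A"))
  expect_equal(lr$chi2, swapped$chi2, tolerance = 1e-12)
  # random censored datasets
  with_seed_local(23, {
    for (rep in 1:10) {
      n <- 40
      tt <- rexp(n, 0.2)
      ee <- rbinom(n, 1, 0.7)
      gg <- sample(rep(c("A", "B"), n / 2))
      if (sum(ee[gg == "A"]) == 0) ee[which(gg == "A")[1]] <- 1
      if (sum(ee[gg == "B"]) == 0) ee[which(gg == "B")[1]] <- 1
      lr2 <- logrank_test(tt, ee, gg)
      sd2 <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
      expect_lt(abs(lr2$chi2 - sd2$chisq), 1e-8)
    }
  })
})

test_that("logrank agrees with a permutation reference on small data", {
  with_seed_local(5, {
    t <- rexp(12, 0.3)
    e <- rbinom(12, 1, 0.8)
    if (sum(e) < 2) e[1:2] <- 1
    g <- rep(c("A", "B"), 6)
  })
  p_perm <- logrank_perm_p(t, e, g, n_perm = 4000, seed = 99)
  p_asym <- logrank_test(t, e, g)$p
  expect_lt(abs(p_perm - p_asym), 0.1)
})

test_that("tidy and glance summarize the survival objects", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 0, 1, 1, 1)
  g <- rep(c("A", "B"), 3)
  km <- km_estimate(t, e)
  expect_named(generics::glance(km),
               c("n", "n_events", "n_censored", "median_survival"))
  expect_identical(generics::tidy(km), km$table)
  lr <- logrank_test(t, e, g)
  expect_equal(generics::glance(lr)$p.value, lr$p)
  expect_equal(nrow(generics::tidy(lr)), 2)
})

test_that("survival_by_group iterates endpoints and strata and tests the two ratio groups", {
  co <- fixture_cohort
  labels <- classify_patients(compute_ratio_features(co$expression))
  res <- suppressMessages(suppressWarnings(
    survival_by_group(co$clinical, labels, endpoints = c("OS", "DFS"),
                      strata = "subtype")))
  expect_equal(sort(unique(res$endpoint)), c("DFS", "OS"))
  expect_true(all(res$stratum %in% co$clinical$subtype))
  # unstratified: one block per endpoint with all three groups present
  res2 <- suppressMessages(
    survival_by_group(co$clinical, labels, endpoints = c("OS", "DSS",
                                                         "DFS", "PFS")))
  expect_equal(nrow(res2), 4)
  expect_true(all(res2$n_col1_high + res2$n_col3_high + res2$n_other <=
                    nrow(co$clinical)))
  expect_true(all(!is.na(res2$p)))
  expect_named(res2$curves[[1]], c("COL1_HIGH", "COL3_HIGH", "OTHER"))
  # OTHER never enters the test: expected counts only cover two groups
  expect_setequal(res2$test[[1]]$groups, c("COL1_HIGH", "COL3_HIGH"))
})

test_that("groups with fewer than two samples skip the logrank with a warning", {
  clin <- tibble::tibble(sample_id = paste0("s", 1:6),
                         OS_time = c(1, 2, 3, 4, 5, 6),
                         OS_event = c(1, 1, 1, 1, 0, 1))
  labels <- tibble::tibble(sample_id = paste0("s", 1:6),
                           label = factor(c("COL1_HIGH", rep("COL3_HIGH", 4),
                                            "OTHER"),
                                          levels = collagenkit:::ratio_group_levels))
  expect_warning(res <- survival_by_group(clin, labels, endpoints = "OS"),
                 "< 2 samples")
  expect_true(is.na(res$p))
})

test_that("Fisher subtype tests match known 2x2 results and are transpose-invariant", {
  expect_equal(stats::fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  p_diag <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value
  expect_equal(p_diag, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(p_diag, 1.083e-5, tolerance = 1e-3)
  m <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(stats::fisher.test(m)$p.value,
               stats::fisher.test(t(m))$p.value, tolerance = 1e-12)

  co <- fixture_cohort
  labels <- classify_patients(compute_ratio_features(co$expression))
  res <- subtype_association(labels, co$clinical)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_setequal(res$subtype, sort(unique(co$clinical$subtype)))
})

test_that("subtype composition shows no association when drawn independently", {
  clean <- 0
  n_rep <- 20
  for (s in 1:n_rep) {
    co <- generate_cohort(cohort_params(n_samples = 400,
                                        n_background_genes = 0,
                                        seed = 700 + s))
    labels <- classify_patients(compute_ratio_features(co$expression))
    res <- subtype_association(labels, co$clinical)
    clean <- clean + all(res$q >= 0.05)
  }
  expect_gte(clean / n_rep, 0.9)
})
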