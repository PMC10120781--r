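test_that("log2(x+1) transform maps known values and guards its scale", {
  mat <- matrix(c(0, 1, 7, 3), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expr <- make_expr(mat, scale = "raw")
  out <- log2p1_transform(expr)
  expect_equal(unname(expr_matrix(out)), matrix(c(0, 1, 3, 2), nrow = 2))
  expect_identical(expr_scale(out), "log2p1")
  expect_error(log2p1_transform(out), "twice")
  neg <- make_expr(matrix(c(-1, 2), 1, 2,
                          dimnames = list("g", c("a", "b"))), scale = "raw")
  expect_error(log2p1_transform(neg), "nonnegative")
})

test_that("purity screen recovers perfect and degenerate correlations", {
  purity <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mat <- rbind(exact = purity, flat = rep(2, 5), anti = 1 - purity)
  colnames(mat) <- paste0("s", 1:5)
  expr <- make_expr(mat)
  clin <- tibble::tibble(sample_id = paste0("s", 1:5), purity = purity)
  res <- purity_correlation_screen(expr, clin)
  expect_equal(res$r[res$gene_id == "exact"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$gene_id == "anti"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$gene_id == "flat"]))
  expect_true(is.na(res$q[res$gene_id == "flat"]))
  # missing purity dropped pairwise
  clin2 <- clin
  clin2$purity[2] <- NA
  res2 <- purity_correlation_screen(expr, clin2)
  expect_equal(unique(res2$n_used), 4)
  expect_error(purity_correlation_screen(expr,
                                         dplyr::mutate(clin, purity = NA)),
               "at least 3")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.05, 1.0)), c(0.10, 1.0))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # NA p-values pass through without affecting the number of tests
  expect_equal(bh_adjust(c(0.05, NA, 1.0)), c(0.10, NA, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is invariant under permutation of input order", {
  with_seed_local(42, {
    p <- runif(50)^2
    q <- bh_adjust(p)
    for (i in 1:5) {
      perm <- sample(50)
      expect_equal(bh_adjust(p[perm])[order(perm)], q, tolerance = 1e-12)
    }
  })
})

test_that("ratio features divide the configured scale and flag zeros", {
  mat <- rbind(COL1A1 = c(5, 10, 4), COL1A2 = c(5, 8, 2),
               COL3A1 = c(5, 5, 0))
  colnames(mat) <- paste0("s", 1:3)
  expr <- make_expr(mat)
  f <- compute_ratio_features(expr)
  expect_equal(f$r1[1], 1)
  expect_equal(f$r1[2], 2)
  expect_false(f$valid[3])
  expect_true(is.na(f$r1[3]))
  # linear mode divides 2^v - 1
  flin <- compute_ratio_features(expr, ratio_scale = "linear")
  expect_equal(flin$r1[1], 1)
  expect_equal(flin$r1[2], (2^10 - 1) / (2^5 - 1))
  # absent gene is a hard error
  expr2 <- make_expr(mat[1:2, ])
  expect_error(compute_ratio_features(expr2), "COL3A1")
})

test_that("quartile classification reproduces the worked 1..8 example", {
  f <- tibble::tibble(sample_id = paste0("s", 1:8),
                      r1 = 1:8, r2 = 1:8, valid = TRUE)
  lab <- classify_patients(f)
  expect_setequal(lab$sample_id[lab$label == "COL1_HIGH"], c("s7", "s8"))
  expect_setequal(lab$sample_id[lab$label == "COL3_HIGH"], c("s1", "s2"))
  expect_setequal(lab$sample_id[lab$label == "OTHER"],
                  paste0("s", 3:6))
  expect_equal(sum(lab$label == "EXCLUDED"), 0)
})

test_that("conflicting quartiles exclude and ties degenerate to OTHER", {
  # sample in top quartile of r1 and bottom quartile of r2 -> EXCLUDED
  f <- tibble::tibble(sample_id = paste0("s", 1:9),
                      r1 = c(1:8, 9), r2 = c(1:8, 0.5), valid = TRUE)
  lab <- classify_patients(f)
  expect_equal(as.character(lab$label[9]), "EXCLUDED")
  # all-identical ratios: no quartile separation, everyone OTHER
  f2 <- tibble::tibble(sample_id = paste0("s", 1:10),
                       r1 = rep(2, 10), r2 = rep(2, 10), valid = TRUE)
  expect_true(all(classify_patients(f2)$label == "OTHER"))
  expect_error(classify_patients(f2[1:5, ]), "at least 8")
})

test_that("classification partitions valid samples; concordant ratios never conflict", {
  with_seed_local(13, {
    for (rep in 1:5) {
      r1 <- rlnorm(60)
      f <- tibble::tibble(sample_id = as.character(1:60),
                          r1 = r1, r2 = 2 * r1^1.3, valid = TRUE)
      lab <- classify_patients(f)
      expect_false(any(is.na(lab$label)))
      expect_equal(sum(lab$label == "EXCLUDED"), 0)
      # rank-concordant dual rule reduces to the single-ratio rule
      single_top <- r1 > quantile(r1, 0.75)
      expect_setequal(which(lab$label == "COL1_HIGH"), which(single_top))
      counts <- table(lab$label)
      expect_equal(sum(counts), 60)
      expect_equal(unname(counts["COL1_HIGH"]), 15)
      expect_equal(unname(counts["COL3_HIGH"]), 15)
    }
  })
})

test_that("hypergeometric enrichment matches exact tail values", {
  universe <- paste0("g", 1:10)
  sets <- list(inside = paste0("g", 1:5), outside = paste0("g", 6:10))
  hits <- paste0("g", 1:5)
  res <- enrichment_test(hits, sets, universe)
  expect_equal(res$p[res$set == "inside"], 1 / choose(10, 5),
               tolerance = 1e-12)
  # overlap 0 is the minimum possible here, so upper tail covers everything
  expect_equal(res$p[res$set == "outside"], 1, tolerance = 1e-12)
  expect_error(enrichment_test("x", sets, character(0)), "empty")
  expect_error(enrichment_test("absent", sets, universe), "contained")
})

test_that("enrichment p-values are uniform under uniform hit draws", {
  universe <- paste0("g", 1:2000)
  set <- list(s = paste0("g", 1:400))
  ps <- with_seed_local(7, replicate(200, {
    enrichment_test(sample(universe, 300), set, universe)$p
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
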