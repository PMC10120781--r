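# Shared fixtures, built once per test run.

# mid-sized default-parameter cohort used by several files
fixture_cohort <- generate_cohort(cohort_params(n_samples = 300, seed = 101))

# one clean straight fiber at a known angle
fixture_single_fiber <- render_fiber_field(fiber_field_params(
  image_size = 256, n_fibers = 1, kappa = 1e6, mean_angle_deg = 30,
  length_mean = 200, length_sd = 0, width_mean = 6, width_sd = 0,
  waviness_amp = 0, noise_sd = 0.005, seed = 3))

# tiny expression tibble builder
make_expr <- function(mat, scale = "log2p1") {
  expr <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(expr) <- colnames(mat)
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)), expr)
  expr_scale(expr) <- scale
  expr
}

# two-sided Fisher p by direct enumeration of hypergeometric point
# probabilities (independent of stats::fisher.test)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# logrank chi-square for a label permutation (reference for the
# permutation test; reuses the package statistic on permuted labels)
logrank_perm_p <- function(time, event, group, n_perm = 2000, seed = 1) {
  obs <- logrank_test(time, event, group)$chi2
  stats <- with_seed_local(seed, replicate(n_perm, {
    logrank_test(time, event, sample(group))$chi2
  }))
  mean(stats >= obs - 1e-12)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

tmp_dir <- function() {
  d <- tempfile("ckit")
  dir.create(d)
  d
}
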