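#' Parameters for the synthetic bulk-tumor cohort generator
#'
#' Bulk tumor RNA-seq expression of stromal collagens is confounded with
#' tumor purity: the collagen transcripts (COL1A1, COL1A2, COL3A1) come
#' almost entirely from the stromal compartment, so samples with more
#' cancer cells show less collagen signal regardless of the biology of
#' their stroma. The generator builds a cohort with exactly this
#' structure, plus a latent per-sample Col1-vs-Col3 balance phenotype that
#' (a) shifts COL1A1/COL1A2 up and COL3A1 down symmetrically on the log2
#' scale and (b) drives an exponential proportional hazard on every
#' survival endpoint. Because the ratio features cancel the shared
#' stromal/purity factor, the generated data let the de-biasing and
#' survival-stratification claims be tested end-to-end.
#'
#' @param n_samples Number of patients (>= 8).
#' @param purity_alpha,purity_beta Beta shape parameters for tumor purity
#'   (fraction of cancer cells, in (0,1)).
#' @param stromal_mean Baseline log2 expression of the collagen genes in
#'   the stromal compartment.
#' @param stromal_sd Per-sample, per-gene Gaussian noise (log2 scale) on
#'   the stromal collagen level.
#' @param cancer_mean Log2 expression of the collagen genes in the cancer
#'   compartment (low: carcinoma cells transcribe little fibrillar
#'   collagen).
#' @param ratio_effect_sd Standard deviation of the latent Col1-vs-Col3
#'   balance phenotype `r_latent` (log2 units).
#' @param hazard_beta Log-hazard coefficient on `r_latent`; positive means
#'   Col1-skewed (high Col1:Col3) patients die faster.
#' @param baseline_hazard Events per time unit at `r_latent = 0`.
#' @param censor_rate Rate of the independent exponential censoring time.
#' @param admin_cutoff Optional administrative follow-up cutoff (time
#'   units); observations beyond it are censored at the cutoff.
#' @param n_background_genes Number of purity-independent filler genes
#'   (true nulls for the correlation screen).
#' @param subtype_probs Named multinomial probabilities for PAM50 labels;
#'   drawn independently of `r_latent`.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#'
#' @return A list of class `"cohort_params"`.
#' @export
#' @examples
#' p <- cohort_params(n_samples = 100, seed = 7)
#' cohort <- generate_cohort(p)
#' dim(expr_matrix(cohort$expression))
cohort_params <- function(n_samples = 1000,
                          purity_alpha = 5, purity_beta = 2,
                          stromal_mean = 10, stromal_sd = 0.5,
                          cancer_mean = 4,
                          ratio_effect_sd = 1,
                          hazard_beta = 1,
                          baseline_hazard = 0.1,
                          censor_rate = 0.06,
                          admin_cutoff = NULL,
                          n_background_genes = 100,
                          subtype_probs = c(LumA = 0.50, LumB = 0.20,
                                            Her2 = 0.10, Basal = 0.15,
                                            `Normal-like` = 0.05),
                          seed = 1L) {
  stopifnot_scalar_number(n_samples, "n_samples", positive = TRUE)
  if (n_samples < 8) abort("`n_samples` must be at least 8.")
  for (nm in c("purity_alpha", "purity_beta", "baseline_hazard", "censor_rate")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  for (nm in c("stromal_mean", "stromal_sd", "cancer_mean",
               "ratio_effect_sd", "hazard_beta")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (stromal_sd < 0 || ratio_effect_sd < 0) abort("standard deviations must be >= 0.")
  stopifnot_scalar_number(n_background_genes, "n_background_genes")
  if (n_background_genes < 0) abort("`n_background_genes` must be >= 0.")
  if (!is.null(admin_cutoff)) stopifnot_scalar_number(admin_cutoff, "admin_cutoff", positive = TRUE)
  if (is.null(names(subtype_probs)) || any(subtype_probs < 0) || sum(subtype_probs) <= 0) {
    abort("`subtype_probs` must be a named nonnegative vector.")
  }
  stopifnot_scalar_number(seed, "seed")
  structure(list(
    n_samples = as.integer(n_samples),
    purity_alpha = purity_alpha, purity_beta = purity_beta,
    stromal_mean = stromal_mean, stromal_sd = stromal_sd,
    cancer_mean = cancer_mean,
    ratio_effect_sd = ratio_effect_sd,
    hazard_beta = hazard_beta,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    admin_cutoff = admin_cutoff,
    n_background_genes = as.integer(n_background_genes),
    subtype_probs = subtype_probs / sum(subtype_probs),
    seed = as.integer(seed)
  ), class = "cohort_params")
}

collagen_genes <- c("COL1A1", "COL1A2", "COL3A1")
cohort_endpoints <- c("OS", "DSS", "DFS", "PFS")

#' Generate a synthetic purity-confounded bulk-expression cohort
#'
#' Expression is mixed on the linear scale — each collagen gene's bulk
#' value is `(1 - purity) * 2^stromal + purity * 2^cancer` — because bulk
#' RNA-seq admixture is physically linear in transcript counts; the
#' log2(x+1) transform is applied afterwards. Survival times for each of
#' the OS/DSS/DFS/PFS endpoints are exponential with hazard
#' `baseline_hazard * exp(hazard_beta * r_latent)`, independently
#' right-censored. Draw order under the root seed is fixed (purity, latent
#' phenotype, collagen noise, background genes, subtypes, then per-endpoint
#' event and censoring times), so a fixed seed reproduces the cohort
#' exactly.
#'
#' @param params A [cohort_params()] object.
#' @return A list with elements `expression` (tibble: `gene_id` plus one
#'   column per sample, log2(x+1) scale), `clinical` (tibble: `sample_id`,
#'   `purity`, `subtype`, `<endpoint>_time`/`<endpoint>_event` for
#'   OS/DSS/DFS/PFS), and `truth` (tibble: `sample_id`, `purity`,
#'   `r_latent`).
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) {
    abort("`params` must come from cohort_params().")
  }
  p <- params
  n <- p$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  with_seed(p$seed, {
    purity <- rbeta(n, p$purity_alpha, p$purity_beta)
    r_latent <- rnorm(n, 0, p$ratio_effect_sd)

    # collagen genes: latent phenotype shifts Col1 up / Col3 down symmetrically
    sign_by_gene <- c(COL1A1 = +0.5, COL1A2 = +0.5, COL3A1 = -0.5)
    collagen <- vapply(collagen_genes, function(g) {
      stromal_log2 <- p$stromal_mean + sign_by_gene[[g]] * r_latent +
        rnorm(n, 0, p$stromal_sd)
      bulk_linear <- (1 - purity) * 2^stromal_log2 + purity * 2^p$cancer_mean
      log2(bulk_linear + 1)
    }, numeric(n))
    collagen <- t(collagen) # genes x samples

    background <- NULL
    if (p$n_background_genes > 0) {
      base_mean <- runif(p$n_background_genes, 2, 12)
      background <- matrix(
        pmax(0, rnorm(p$n_background_genes * n, mean = rep(base_mean, times = n), sd = 1)),
        nrow = p$n_background_genes, ncol = n
      )
      rownames(background) <- sprintf("GENE%05d", seq_len(p$n_background_genes))
    }

    subtype <- sample(names(p$subtype_probs), n, replace = TRUE,
                      prob = p$subtype_probs)

    hazard <- p$baseline_hazard * exp(p$hazard_beta * r_latent)
    surv_cols <- list()
    for (ep in cohort_endpoints) {
      t_event <- rexp(n, rate = hazard)
      t_censor <- rexp(n, rate = p$censor_rate)
      if (!is.null(p$admin_cutoff)) t_censor <- pmin(t_censor, p$admin_cutoff)
      time <- pmin(t_event, t_censor)
      event <- as.integer(t_event <= t_censor)
      surv_cols[[paste0(ep, "_time")]] <- time
      surv_cols[[paste0(ep, "_event")]] <- event
    }

    mat <- rbind(collagen, background)
    expression <- tibble::as_tibble(mat, .name_repair = "minimal")
    names(expression) <- sample_ids
    expression <- dplyr::bind_cols(tibble(gene_id = rownames(mat)), expression)
    expr_scale(expression) <- "log2p1"

    clinical <- tibble(
      sample_id = sample_ids,
      purity = purity,
      subtype = subtype
    )
    clinical <- dplyr::bind_cols(clinical, tibble::as_tibble(surv_cols))

    truth <- tibble(sample_id = sample_ids, purity = purity, r_latent = r_latent)

    list(expression = expression, clinical = clinical, truth = truth,
         params = p)
  })
}

#' Write a cohort to tab-separated files
#'
#' Writes `expression.tsv` (first column `gene_id`, header row of sample
#' ids), `clinical.tsv` and `truth.tsv` into `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(cohort$expression, paths[["expression"]])
  readr::write_tsv(cohort$clinical, paths[["clinical"]])
  readr::write_tsv(cohort$truth, paths[["truth"]])
  invisible(paths)
}

#' Read expression and clinical tables written by [write_cohort()]
#'
#' @param expression_file Gene-by-sample TSV (first column `gene_id`).
#' @param clinical_file Clinical TSV with a `sample_id` column.
#' @param scale Scale of the stored expression values.
#' @return A list with `expression` (scale attribute set) and `clinical`.
#' @export
read_cohort <- function(expression_file, clinical_file,
                        scale = c("log2p1", "raw")) {
  scale <- match.arg(scale)
  expression <- readr::read_tsv(expression_file, show_col_types = FALSE)
  names(expression)[1] <- "gene_id"
  check_expr(expression)
  expr_scale(expression) <- scale
  clinical <- readr::read_tsv(clinical_file, show_col_types = FALSE)
  if (!"sample_id" %in% names(clinical)) {
    abort("clinical table must have a `sample_id` column.")
  }
  list(expression = expression, clinical = clinical)
}
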