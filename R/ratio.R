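#' Apply the log2(x+1) transform to a raw expression table
#'
#' @param expr Expression tibble on the raw (linear, nonnegative) scale.
#' @return The tibble with every value replaced by `log2(value + 1)` and
#'   the scale flag set to `"log2p1"`. Transforming an already-transformed
#'   table is an error, not a silent double transform.
#' @export
log2p1_transform <- function(expr) {
  check_expr(expr)
  if (identical(expr_scale(expr), "log2p1")) {
    abort("expression is already on the log2(x+1) scale; refusing to transform twice.")
  }
  m <- expr_matrix(expr)
  if (any(m < 0)) abort("raw expression values must be nonnegative.")
  out <- expr
  out[, -1] <- as.data.frame(log2(m + 1))
  expr_scale(out) <- "log2p1"
  out
}

#' Transcriptome-wide Pearson screen of expression against tumor purity
#'
#' For every gene, the Pearson correlation between its log2(x+1)
#' expression and tumor purity across samples, with the usual t-based
#' two-sided p-value and Benjamini-Hochberg q-values over all defined
#' p-values. Stromal transcripts (collagens prominent among them) come out
#' strongly negative: the more cancer cells in the sample, the less
#' stromal message.
#'
#' Samples with missing purity are dropped pairwise. Genes with zero
#' variance over the used samples (or fewer than 3 usable samples) get
#' `NA` for r/p and are excluded from the BH adjustment.
#'
#' @param expr Expression tibble on the log2p1 scale.
#' @param clinical Clinical tibble with `sample_id` and `purity` columns.
#' @return A tibble with columns `gene_id`, `r`, `p`, `q`, `n_used`.
#' @export
purity_correlation_screen <- function(expr, clinical) {
  check_expr(expr)
  if (!identical(expr_scale(expr), "log2p1")) {
    abort("expression must be on the log2(x+1) scale (see log2p1_transform()).")
  }
  if (!all(c("sample_id", "purity") %in% names(clinical))) {
    abort("`clinical` must have `sample_id` and `purity` columns.")
  }
  m <- expr_matrix(expr)
  purity <- clinical$purity[match(colnames(m), clinical$sample_id)]
  use <- !is.na(purity)
  if (sum(use) < 3) abort("need at least 3 samples with non-missing purity.")
  m <- m[, use, drop = FALSE]
  purity <- purity[use]
  n <- length(purity)

  # vectorized Pearson r of every gene row against the purity vector
  mc <- m - rowMeans(m)
  pc <- purity - mean(purity)
  gene_ss <- rowSums(mc^2)
  r <- as.vector(mc %*% pc) / sqrt(gene_ss * sum(pc^2))
  r[gene_ss == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))

  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0

  tibble(
    gene_id = rownames(m),
    r = r,
    p = p,
    q = bh_adjust(p),
    n_used = n
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH with monotonicity enforcement, input order
#' preserved. `NA` p-values (e.g. zero-variance genes) stay `NA` and do
#' not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

default_ratio_genes <- c(col1a1 = "COL1A1", col1a2 = "COL1A2", col3a1 = "COL3A1")

#' Stromal-normalizing collagen expression ratios
#'
#' Computes the two de-biasing features per sample: `r1` =
#' COL1A1/COL3A1 and `r2` = COL1A2/COL3A1. Because numerator and
#' denominator are both stromal transcripts, the shared stromal-fraction
#' factor cancels, removing most of the tumor-purity confounding that
#' single collagen genes carry.
#'
#' @param expr Expression tibble on the log2p1 scale.
#' @param genes Named aliases for the three collagen transcripts, in case
#'   the matrix uses Ensembl ids or other symbols
#'   (names `col1a1`, `col1a2`, `col3a1`).
#' @param ratio_scale `"log"` divides the log2(x+1) values directly
#'   (the literal order of operations: transform, then ratio);
#'   `"linear"` divides the linear values `2^v - 1` instead, i.e. a
#'   fold-ratio. Both are offered because the two orderings differ.
#' @return Tibble with `sample_id`, `r1`, `r2`, `valid`. A sample is
#'   invalid when its denominator is zero on the chosen scale.
#' @export
compute_ratio_features <- function(expr, genes = default_ratio_genes,
                                   ratio_scale = c("log", "linear")) {
  ratio_scale <- match.arg(ratio_scale)
  check_expr(expr)
  if (!identical(expr_scale(expr), "log2p1")) {
    abort("expression must be on the log2(x+1) scale.")
  }
  if (!all(c("col1a1", "col1a2", "col3a1") %in% names(genes))) {
    abort("`genes` must name col1a1, col1a2 and col3a1 aliases.")
  }
  m <- expr_matrix(expr)
  missing <- setdiff(unname(genes[c("col1a1", "col1a2", "col3a1")]), rownames(m))
  if (length(missing)) {
    abort(paste0("required gene(s) absent from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  v1 <- m[genes[["col1a1"]], ]
  v2 <- m[genes[["col1a2"]], ]
  v3 <- m[genes[["col3a1"]], ]
  if (ratio_scale == "linear") {
    v1 <- 2^v1 - 1
    v2 <- 2^v2 - 1
    v3 <- 2^v3 - 1
  }
  valid <- v3 != 0
  tibble(
    sample_id = colnames(m),
    r1 = unname(ifelse(valid, v1 / v3, NA_real_)),
    r2 = unname(ifelse(valid, v2 / v3, NA_real_)),
    valid = unname(valid)
  )
}

ratio_group_levels <- c("COL1_HIGH", "COL3_HIGH", "OTHER", "EXCLUDED")

#' Dual-ratio quartile classification of patients
#'
#' Patients in the uppermost quartile of either ratio distribution (and
#' not in the bottommost quartile of the other) are Col1:Col3 high
#' (`COL1_HIGH`); bottommost-quartile patients are Col3:Col1 high
#' (`COL3_HIGH`) symmetrically; patients in the middle two quartiles of
#' both ratios are `OTHER`; the rare patient in the top quartile of one
#' ratio and the bottom quartile of the other is `EXCLUDED` as
#' conflicting. The union rule (rather than requiring both ratios) is what
#' makes group sizes larger than n/4 possible.
#'
#' Quartile cutpoints use the linear-interpolation percentile convention
#' (`stats::quantile` type 7) over valid samples; "uppermost quartile"
#' means strictly greater than Q3 and "bottommost" strictly less than Q1,
#' so values tied exactly at a cutpoint fall to the middle. If all ratios
#' are identical there is no quartile separation and everyone is `OTHER`.
#'
#' @param features Output of [compute_ratio_features()].
#' @return The features tibble with a `label` factor column added
#'   (levels `COL1_HIGH`, `COL3_HIGH`, `OTHER`, `EXCLUDED`); invalid
#'   samples get `NA` label.
#' @export
classify_patients <- function(features) {
  req <- c("sample_id", "r1", "r2", "valid")
  if (!all(req %in% names(features))) {
    abort("`features` must come from compute_ratio_features().")
  }
  valid <- features$valid & !is.na(features$r1) & !is.na(features$r2)
  if (sum(valid) < 8) abort("need at least 8 valid samples to form quartiles.")

  zone <- function(x) {
    qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    dplyr::case_when(x > qs[2] ~ "top", x < qs[1] ~ "bottom", TRUE ~ "mid")
  }
  z1 <- zone(features$r1[valid])
  z2 <- zone(features$r2[valid])

  lab <- dplyr::case_when(
    (z1 == "top" & z2 == "bottom") | (z1 == "bottom" & z2 == "top") ~ "EXCLUDED",
    z1 == "top" | z2 == "top" ~ "COL1_HIGH",
    z1 == "bottom" | z2 == "bottom" ~ "COL3_HIGH",
    TRUE ~ "OTHER"
  )

  label <- rep(NA_character_, nrow(features))
  label[valid] <- lab
  dplyr::mutate(features,
                label = factor(label, levels = ratio_group_levels))
}

#' Hypergeometric over-representation test for user-supplied gene sets
#'
#' One-sided (upper tail) hypergeometric p-value per set for the overlap
#' between `hit_genes` and the set, both intersected with `universe`,
#' BH-adjusted across sets.
#'
#' @param hit_genes Character vector of hits (must lie in `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector, the tested gene universe.
#' @return Tibble: `set`, `set_size`, `n_hits`, `overlap`, `p`, `q`.
#' @export
enrichment_test <- function(hit_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` is empty.")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe)) {
    abort("all `hit_genes` must be contained in `universe`.")
  }
  if (is.null(names(gene_sets))) abort("`gene_sets` must be a named list.")
  N <- length(universe)
  n_hits <- length(hit_genes)
  rows <- imap(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(set, hit_genes))
    # P(overlap >= k) drawing n_hits from N with length(set) marked
    p <- phyper(k - 1, length(set), N - length(set), n_hits, lower.tail = FALSE)
    tibble(set = nm, set_size = length(set), n_hits = n_hits,
           overlap = k, p = p)
  })
  out <- list_rbind(rows)
  out$q <- bh_adjust(out$p)
  out
}
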