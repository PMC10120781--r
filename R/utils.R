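# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

#' Extract the numeric gene-by-sample matrix from an expression tibble
#'
#' Expression data travel as a tibble whose first column is `gene_id` and
#' whose remaining columns are one numeric column per sample. This returns
#' the plain numeric matrix (genes in rows, samples in columns) with
#' dimnames set, for internal linear algebra.
#'
#' @param expr An expression tibble (`gene_id` column plus sample columns).
#' @return A numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
expr_matrix <- function(expr) {
  check_expr(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' Get or set the expression scale flag
#'
#' An expression tibble carries a `"expr_scale"` attribute, either
#' `"raw"` (linear values, nonnegative) or `"log2p1"` (log2(x+1)
#' transformed). dplyr verbs can drop attributes, so the flag can also be
#' re-asserted with the setter.
#'
#' @param expr An expression tibble.
#' @param value `"raw"` or `"log2p1"`.
#' @return The scale string, or the tibble with the attribute set.
#' @export
expr_scale <- function(expr) {
  attr(expr, "expr_scale") %||% "log2p1"
}

#' @rdname expr_scale
#' @export
`expr_scale<-` <- function(expr, value) {
  value <- match.arg(value, c("raw", "log2p1"))
  attr(expr, "expr_scale") <- value
  expr
}

check_expr <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2L || names(expr)[1] != "gene_id") {
    abort("expression data must be a data frame with a `gene_id` first column and one column per sample.")
  }
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene ids in expression data.")
  if (anyDuplicated(names(expr)[-1])) abort("duplicate sample ids in expression data.")
  invisible(expr)
}

# map angles (degrees) into [-90, 90)
wrap_angle_deg <- function(a) {
  ((a + 90) %% 180) - 90
}

as_image_matrix <- function(image, name = "image") {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix (or EBImage Image).", name))
  }
  if (!all(is.finite(image))) abort(sprintf("`%s` contains non-finite pixels.", name))
  image
}
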