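#' Construct a gene-expression matrix
#'
#' @param values numeric matrix, rows = genes, columns = samples/time points.
#' @param gene_ids,sample_ids identifiers; taken from `dimnames(values)` when
#'   omitted.
#' @return numeric matrix of class `expression_matrix` with gene identifiers
#'   as rownames and sample identifiers as colnames.
#' @details Missing values are rejected: expression is expected to be
#'   pre-treated and normalized upstream, and any imputation policy would be
#'   a modelling choice this package does not make.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (ncol(values) < 1L) stop("expression matrix needs at least one sample")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (any(!is.finite(values))) stop("expression values must be finite (no NAs)")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read a gene-expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (a flat series-matrix-like export). Rows sharing a gene
#' identifier are collapsed by their arithmetic mean, with a warning.
#'
#' @param path path to the TSV file.
#' @return an [expression_matrix].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed expression matrix in ", path)
  genes <- raw[[1L]]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, colnames(raw)[-1L]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at row %d, column '%s' of %s",
                 bad[["row"]], colnames(vals)[bad[["col"]]], path))
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    warning(sprintf("read_expression: averaged %d duplicated gene row(s)",
                    n_dup))
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  expression_matrix(vals, gene_ids = genes, sample_ids = colnames(vals))
}

#' Write an expression matrix as TSV
#'
#' Values are emitted with round-trip precision (`%.17g`), so a write/read
#' cycle reproduces the matrix bit-exactly.
#'
#' @param expr an [expression_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  fmt <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  out <- cbind(gene_id = rownames(expr), fmt)
  colnames(out) <- c("gene_id", colnames(expr))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Per-gene dynamic binarization thresholds
#'
#' For each gene with expression values \eqn{E_t} over \eqn{n} samples the
#' threshold is
#' \deqn{G = U + 2 \sigma V, \quad U = \frac{1}{n}\sum_t E_t, \quad
#'       \sigma^2 = \frac{1}{n}\sum_t (U - E_t)^2, \quad
#'       V = \frac{1}{1 + \sigma^2}.}
#' The volatility factor \eqn{V} pulls the threshold back towards the mean
#' for noisy genes, so that highly fluctuating profiles are not binarized
#' against an unreachably high cut-off. The variance uses divisor \eqn{n}
#' (population form).
#'
#' @param expr an [expression_matrix] (or numeric matrix with rownames).
#' @return data frame with one row per gene: `gene_id`, `mean`, `sigma2`,
#'   `sigma`, `volatility`, `threshold`.
#' @export
gene_thresholds <- function(expr) {
  x <- unclass(expr)
  n <- ncol(x)
  u <- rowMeans(x)
  sigma2 <- rowMeans((x - u)^2)
  sigma <- sqrt(sigma2)
  v <- 1 / (1 + sigma2)
  data.frame(gene_id = rownames(x), mean = u, sigma2 = sigma2, sigma = sigma,
             volatility = v, threshold = u + 2 * sigma * v,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binarize expression into "active"/"inactive" states
#'
#' An entry becomes 1 ("active") iff it is strictly greater than its gene's
#' dynamic threshold from [gene_thresholds()]; ties and lower values are 0
#' ("inactive"). A constant gene therefore binarizes to all zeros.
#'
#' @param expr an [expression_matrix].
#' @return 0/1 integer matrix of class `boolean_expression`, same shape and
#'   dimnames as `expr`.
#' @export
binarize <- function(expr) {
  x <- unclass(expr)
  g <- gene_thresholds(expr)$threshold
  b <- (x > g) * 1L
  dimnames(b) <- dimnames(x)
  class(b) <- c("boolean_expression", class(b))
  b
}
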