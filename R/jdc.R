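#' Edge clustering coefficient of an interacting pair
#'
#' For an edge \eqn{\{i,j\}} with endpoint degrees \eqn{k_i, k_j} and
#' \eqn{z_{ij}} triangles through the edge,
#' \deqn{ECC(i,j) = \frac{z_{ij}}{\min(k_i - 1, k_j - 1)},}
#' the ratio of actual to maximum possible triangles. When an endpoint has
#' degree 1 the denominator vanishes and no triangle is possible; the value
#' is 0 by convention (which also preserves \eqn{JDC \le DC}).
#'
#' @param net a [ppi_network].
#' @param i,j protein identifiers forming an edge of `net`.
#' @return ECC value in \[0, 1\].
#' @export
ecc <- function(net, i, j) {
  ni <- ppi_neighbors(net, i)
  if (!(j %in% ni)) stop("ecc is defined only for interacting pairs: ",
                         i, " -- ", j)
  denom <- min(length(ni) - 1L, ppi_degree(net, j) - 1L)
  if (denom == 0L) return(0)
  length(intersect(ni, ppi_neighbors(net, j))) / denom
}

#' Jaccard similarity of two Boolean activity vectors
#'
#' `|intersection| / |union|` of the "active" sample sets. Two genes that are
#' never active share no co-expression evidence, so an empty union yields 0.
#'
#' @param si,sj 0/1 vectors of equal length.
#' @return value in \[0, 1\].
#' @export
jaccard_similarity <- function(si, sj) {
  if (length(si) != length(sj))
    stop("Boolean vectors must have equal length")
  u <- sum(si | sj)
  if (u == 0) return(0)
  sum(si & sj) / u
}

# Boolean rows aligned to the network's node order; proteins without an
# expression row get an all-zero vector (minimal-information default).
.aligned_boolean <- function(net, boolexpr) {
  b <- unclass(boolexpr)
  m <- matrix(0L, nrow = length(net$nodes), ncol = ncol(b),
              dimnames = list(net$nodes, colnames(b)))
  hit <- intersect(net$nodes, rownames(b))
  if (length(hit) < length(net$nodes)) {
    message(sprintf("%d network protein(s) lack an expression row; treated as never active",
                    length(net$nodes) - length(hit)))
  }
  m[hit, ] <- b[hit, , drop = FALSE]
  m
}

# ECC for every edge of the network, vectorized over the edge table.
.edge_ecc <- function(net) {
  edf <- net$edges
  if (nrow(edf) == 0L) return(numeric())
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  deg <- rowSums(adj)
  ia <- match(edf$a, net$nodes)
  ib <- match(edf$b, net$nodes)
  z <- (adj %*% adj)[cbind(ia, ib)]
  denom <- pmin(deg[ia], deg[ib]) - 1
  ifelse(denom > 0, z / denom, 0)
}

#' Per-edge ECC, Jaccard and combined clustering weights
#'
#' Computes, for every edge of the network, the edge clustering coefficient,
#' the Jaccard similarity of the endpoints' Boolean expression vectors, and
#' their product `jc` — the co-expressed-cluster weight summed by
#' [jdc_scores()]. Network proteins without an expression row are treated as
#' never active, so all their edges get Jaccard 0.
#'
#' @param net a [ppi_network].
#' @param boolexpr a `boolean_expression` matrix from [binarize()].
#' @return data frame with columns `a`, `b`, `ecc`, `jaccard`, `jc`, one row
#'   per edge in the network's canonical edge order.
#' @export
edge_weights <- function(net, boolexpr) {
  edf <- net$edges
  b <- .aligned_boolean(net, boolexpr)
  e <- .edge_ecc(net)
  if (nrow(edf) == 0L) {
    return(data.frame(a = character(), b = character(), ecc = numeric(),
                      jaccard = numeric(), jc = numeric()))
  }
  ia <- match(edf$a, net$nodes)
  ib <- match(edf$b, net$nodes)
  rs <- rowSums(b)
  inter <- rowSums(b[ia, , drop = FALSE] * b[ib, , drop = FALSE])
  un <- rs[ia] + rs[ib] - inter
  jac <- ifelse(un > 0, inter / un, 0)
  data.frame(a = edf$a, b = edf$b, ecc = e, jaccard = jac, jc = jac * e,
             stringsAsFactors = FALSE)
}

#' Rank table of per-protein scores
#'
#' @param scores named numeric vector, one entry per network protein.
#' @param method method label (e.g. `"JDC"`).
#' @return data frame of class `score_table` with columns `protein`, `score`,
#'   `rank`, ordered by descending score with ties broken by ascending
#'   protein identifier; the method label is kept in attribute `method`.
#' @export
score_table <- function(scores, method) {
  ord <- order(-scores, names(scores))
  out <- data.frame(protein = names(scores)[ord], score = unname(scores[ord]),
                    rank = seq_along(scores), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("score_table", class(out))
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table (%s): %d proteins\n", attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' JDC essentiality scores
#'
#' The JDC score of protein \eqn{i} sums, over its neighbours \eqn{j}, the
#' evidence that \eqn{i} and \eqn{j} sit in the same densely connected,
#' co-expressed cluster:
#' \deqn{JDC(i) = \sum_{j \in D_i} Jaccard(i,j) \cdot ECC(i,j).}
#' Isolated proteins score 0.
#'
#' @param net a [ppi_network].
#' @param boolexpr a `boolean_expression` matrix from [binarize()].
#' @return a [score_table] with method `"JDC"`.
#' @export
jdc_scores <- function(net, boolexpr) {
  w <- edge_weights(net, boolexpr)
  s <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(w) > 0L) {
    add <- tapply(c(w$jc, w$jc), c(w$a, w$b), sum)
    s[names(add)] <- add
  }
  score_table(s, "JDC")
}

# Pearson correlation of raw expression rows for each edge; proteins without
# an expression row, zero-variance rows (NaN) and negative correlations all
# contribute 0, the convention shared by the PeC and WDC baselines.
.edge_pcc <- function(net, expr) {
  edf <- net$edges
  if (nrow(edf) == 0L) return(numeric())
  x <- unclass(expr)
  ia <- match(edf$a, rownames(x))
  ib <- match(edf$b, rownames(x))
  pcc <- numeric(nrow(edf))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) {
    xi <- x[ia[ok], , drop = FALSE]
    xj <- x[ib[ok], , drop = FALSE]
    ci <- xi - rowMeans(xi)
    cj <- xj - rowMeans(xj)
    num <- rowSums(ci * cj)
    den <- sqrt(rowSums(ci^2) * rowSums(cj^2))
    r <- ifelse(den > 0, num / den, 0)
    pcc[ok] <- pmax(r, 0)
  }
  pcc
}

.sum_over_edges <- function(net, w) {
  s <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    add <- tapply(c(w, w), c(net$edges$a, net$edges$b), sum)
    s[names(add)] <- add
  }
  s
}

#' Baseline centrality scores
#'
#' The comparison centralities computed on the same inputs as JDC:
#' * `DC` — degree centrality, \eqn{k_i};
#' * `NC` — sum of ECC over incident edges;
#' * `PeC` — sum of \eqn{ECC \cdot PCC} over incident edges, where PCC is the
#'   Pearson correlation of the raw expression rows clamped to \[0, 1\]
#'   (negative or undefined correlations count as 0);
#' * `WDC` — sum of \eqn{\lambda \cdot ECC + (1-\lambda) \cdot PCC} over
#'   incident edges.
#'
#' @param net a [ppi_network].
#' @param expr an [expression_matrix] (unused by `DC`/`NC`).
#' @param method one of `"DC"`, `"NC"`, `"PeC"`, `"WDC"`.
#' @param lambda mixing weight for `WDC`, in \[0, 1\].
#' @return a [score_table] labelled with `method`.
#' @export
baseline_scores <- function(net, expr = NULL,
                            method = c("DC", "NC", "PeC", "WDC"),
                            lambda = 0.5) {
  method <- match.arg(method)
  if (method %in% c("PeC", "WDC") && is.null(expr))
    stop(method, " requires an expression matrix")
  s <- switch(method,
    DC  = ppi_degree(net),
    NC  = .sum_over_edges(net, .edge_ecc(net)),
    PeC = .sum_over_edges(net, .edge_ecc(net) * .edge_pcc(net, expr)),
    WDC = .sum_over_edges(net, lambda * .edge_ecc(net) +
                                 (1 - lambda) * .edge_pcc(net, expr)))
  score_table(stats::setNames(as.numeric(s), net$nodes), method)
}

#' Write a score table as TSV
#'
#' Emits `protein_id`, `score`, `rank` sorted by rank, with the method name
#' in a leading `#` comment line. Scores use round-trip precision.
#'
#' @param st a [score_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(st, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", attr(st, "method")), con)
  writeLines("protein_id\tscore\trank", con)
  writeLines(sprintf("%s\t%.17g\t%d", st$protein, st$score, st$rank), con)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path path to the TSV file.
#' @return a [score_table].
#' @export
read_score_table <- function(path) {
  first <- readLines(path, n = 1L)
  method <- sub("^# method: ", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  score_table(stats::setNames(df$score, df$protein_id), method)
}
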