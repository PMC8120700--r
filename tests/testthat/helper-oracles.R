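# Independent brute-force references the fast implementations are checked
# against. These deliberately use naive loops/set operations only.

# Erdos-Renyi edge table over nodes P01..Pn.
rand_edges <- function(n, p) {
  ids <- sprintf("P%02d", seq_len(n))
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on <- stats::runif(nrow(pair)) < p
  data.frame(a = ids[pair[on, 1L]], b = ids[pair[on, 2L]],
             stringsAsFactors = FALSE)
}

# Adjacency list straight from an edge table.
adj_list <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

naive_ecc <- function(adj, i, j) {
  z <- length(intersect(adj[[i]], adj[[j]]))
  denom <- min(length(adj[[i]]), length(adj[[j]])) - 1L
  if (denom <= 0L) 0 else z / denom
}

naive_jaccard <- function(si, sj) {
  u <- sum(si == 1L | sj == 1L)
  if (u == 0L) 0 else sum(si == 1L & sj == 1L) / u
}

# Naive double loop over neighbours; B is a 0/1 matrix with node rownames
# (nodes missing a row count as never active).
naive_jdc <- function(adj, B) {
  row_of <- function(v) {
    if (v %in% rownames(B)) B[v, ] else rep(0L, ncol(B))
  }
  vapply(names(adj), function(i) {
    s <- 0
    for (j in adj[[i]])
      s <- s + naive_jaccard(row_of(i), row_of(j)) * naive_ecc(adj, i, j)
    s
  }, numeric(1L))
}

# Tie-corrected Mann-Whitney AUC by explicit pair comparison.
mw_auc <- function(scores, labels) {
  a <- scores[labels == 1L]
  b <- scores[labels == 0L]
  mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
}

# Hand evaluation of the confusion-derived metrics.
naive_metrics <- function(tp, fp, tn, fn) {
  c(SN = tp / (tp + fn), SP = tn / (tn + fp), FPR = fp / (tn + fp),
    PPV = tp / (tp + fp), NPV = tn / (tn + fn),
    F = 2 * tp / (2 * tp + fp + fn),
    ACC = (tp + tn) / (tp + fp + tn + fn),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}
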