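#' Specification of a synthetic benchmark instance
#'
#' Describes a planted-partition PPI network with matched expression data:
#' `n_clusters` dense clusters of `cluster_size` proteins (within-cluster
#' edge probability `p_in`) plus `n_background` loosely attached proteins
#' (all other pairs edged with probability `p_out`). Expression over
#' `n_samples` samples follows cluster-level on/off states: in each sample a
#' cluster is "on" with probability `p_active_in`; a member gene's state is
#' its cluster's state flipped independently with probability
#' `activation_noise`; background genes are always off. An "on" gene draws
#' `expr_high + N(0, noise_sd)`, otherwise `expr_low + N(0, noise_sd)`. A
#' fixed `essential_fraction_in_clusters` of each cluster is labelled
#' essential, mirroring the enrichment of essential proteins in dense
#' co-expressed PPI clusters.
#'
#' @param n_clusters,cluster_size,n_background network composition.
#' @param p_in,p_out edge probabilities; `p_in > p_out` is required so the
#'   planted structure is detectable.
#' @param n_samples number of expression samples/time points.
#' @param p_active_in per-sample probability that a cluster is "on".
#' @param activation_noise per-gene, per-sample state flip rate in \[0, 1).
#' @param expr_high,expr_low mean expression in the on/off state
#'   (`expr_high > expr_low` required).
#' @param noise_sd Gaussian noise s.d. added to every expression value.
#' @param essential_fraction_in_clusters fraction of each cluster labelled
#'   essential, in (0, 1\].
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 3L, cluster_size = 10L,
                           n_background = 30L, p_in = 0.8, p_out = 0.02,
                           n_samples = 40L, p_active_in = 0.5,
                           activation_noise = 0.1, expr_high = 8,
                           expr_low = 2, noise_sd = 1,
                           essential_fraction_in_clusters = 0.6,
                           seed = 42L) {
  spec <- list(n_clusters = as.integer(n_clusters),
               cluster_size = as.integer(cluster_size),
               n_background = as.integer(n_background),
               p_in = p_in, p_out = p_out,
               n_samples = as.integer(n_samples),
               p_active_in = p_active_in,
               activation_noise = activation_noise,
               expr_high = expr_high, expr_low = expr_low,
               noise_sd = noise_sd,
               essential_fraction_in_clusters = essential_fraction_in_clusters,
               seed = as.integer(seed))
  if (spec$p_in <= spec$p_out)
    stop("p_in must exceed p_out (planted structure must be detectable)")
  if (spec$expr_high <= spec$expr_low)
    stop("expr_high must exceed expr_low")
  if (spec$activation_noise < 0 || spec$activation_noise >= 1)
    stop("activation_noise must lie in [0, 1)")
  if (spec$essential_fraction_in_clusters <= 0 ||
      spec$essential_fraction_in_clusters > 1)
    stop("essential_fraction_in_clusters must lie in (0, 1]")
  class(spec) <- "synthetic_spec"
  spec
}

# Run expr with the RNG seeded from `seed`, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a synthetic PPI network, expression matrix and essential labels
#'
#' Identical specs (including the seed) produce bit-identical outputs.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_bundle`: `network` ([ppi_network] over
#'   all generated proteins, isolated ones included), `expr`
#'   ([expression_matrix]), `essential` (character vector),
#'   `clusters` (named integer vector; `NA` for background proteins) and
#'   `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    k <- spec$n_clusters
    cs <- spec$cluster_size
    cluster_ids <- unlist(lapply(seq_len(k), function(cl)
      sprintf("C%d_%02d", cl, seq_len(cs))))
    bg_ids <- if (spec$n_background > 0L)
      sprintf("B_%02d", seq_len(spec$n_background)) else character()
    ids <- c(cluster_ids, bg_ids)
    n <- length(ids)
    membership <- c(rep(seq_len(k), each = cs),
                    rep(NA_integer_, spec$n_background))
    names(membership) <- ids

    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- !is.na(membership[pair[, 1L]]) &
      !is.na(membership[pair[, 2L]]) &
      membership[pair[, 1L]] == membership[pair[, 2L]]
    p <- ifelse(same, spec$p_in, spec$p_out)
    on <- stats::runif(nrow(pair)) < p
    net <- ppi_network(data.frame(a = ids[pair[on, 1L]],
                                  b = ids[pair[on, 2L]],
                                  stringsAsFactors = FALSE),
                       nodes = ids)

    m <- spec$n_samples
    cluster_on <- matrix(stats::runif(k * m) < spec$p_active_in, k, m)
    state <- matrix(0L, n, m, dimnames = list(ids, sprintf("S%03d", seq_len(m))))
    in_cluster <- !is.na(membership)
    state[in_cluster, ] <- cluster_on[membership[in_cluster], ] * 1L
    flip <- matrix(stats::runif(sum(in_cluster) * m) < spec$activation_noise,
                   sum(in_cluster), m)
    state[in_cluster, ] <- (state[in_cluster, ] + flip) %% 2L
    vals <- ifelse(state == 1L, spec$expr_high, spec$expr_low) +
      matrix(stats::rnorm(n * m, sd = spec$noise_sd), n, m)
    dimnames(vals) <- dimnames(state)
    expr <- expression_matrix(vals)

    n_ess <- max(1L, round(spec$essential_fraction_in_clusters * cs))
    essential <- unlist(lapply(seq_len(k), function(cl) {
      members <- cluster_ids[membership[cluster_ids] == cl]
      sort(sample(members, n_ess))
    }))

    structure(list(network = net, expr = expr, essential = essential,
                   clusters = membership, spec = spec),
              class = "synthetic_bundle")
  })
}

#' Write a synthetic bundle as fixture files
#'
#' Writes the edge list (`network.tsv`), expression matrix
#' (`expression.tsv`) and essential list (`essential.txt`, one identifier
#' per line) in the dialects the package readers consume, plus a JSON
#' sidecar (`spec.json`) recording the generating spec and the ground-truth
#' cluster assignment.
#'
#' @param bundle a `synthetic_bundle` from [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             essential = file.path(dir, "essential.txt"),
             spec = file.path(dir, "spec.json"))
  write_ppi(bundle$network, paths[["network"]])
  write_expression(bundle$expr, paths[["expression"]])
  writeLines(bundle$essential, paths[["essential"]])
  sidecar <- c(unclass(bundle$spec),
               list(clusters = as.list(bundle$clusters)))
  jsonlite::write_json(sidecar, paths[["spec"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an essential-protein list file
#'
#' One identifier per line; `#` comment lines and blank lines are skipped.
#'
#' @param path path to the list file.
#' @return character vector of identifiers.
#' @export
read_essential <- function(path) {
  if (!file.exists(path)) stop("cannot read essential list: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}
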