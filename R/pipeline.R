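#' Configuration of a scoring/evaluation run
#'
#' @param ppi_path,expr_path,essential_path input files: edge-list TSV,
#'   expression TSV, essential-protein list.
#' @param methods methods to score; subset of `"JDC"`, `"DC"`, `"NC"`,
#'   `"PeC"`, `"WDC"`.
#' @param wdc_lambda mixing weight for WDC.
#' @param top_percents percentages for the top-slice analysis.
#' @param overlap_top_n top-N size for the cross-method overlap table.
#' @param top_fraction fraction of the ranking for the restricted ROC.
#' @param output_dir directory all outputs are written into.
#' @return list of class `run_config`.
#' @export
run_config <- function(ppi_path, expr_path, essential_path,
                       methods = c("JDC", "DC", "NC", "PeC", "WDC"),
                       wdc_lambda = 0.5,
                       top_percents = c(1, 5, 10, 15, 20, 25),
                       overlap_top_n = 100L, top_fraction = 0.2,
                       output_dir = ".") {
  methods <- match.arg(methods, c("JDC", "DC", "NC", "PeC", "WDC"),
                       several.ok = TRUE)
  if (length(methods) == 0L) stop("at least one method is required")
  structure(list(ppi_path = ppi_path, expr_path = expr_path,
                 essential_path = essential_path, methods = methods,
                 wdc_lambda = wdc_lambda, top_percents = top_percents,
                 overlap_top_n = as.integer(overlap_top_n),
                 top_fraction = top_fraction, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML (or flat key: value) file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path path to the config file.
#' @param ... overrides applied on top of the file's values.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.score_one <- function(method, net, expr, boolexpr, lambda) {
  if (method == "JDC") jdc_scores(net, boolexpr)
  else baseline_scores(net, expr, method, lambda = lambda)
}

#' Score a PPI network with the configured methods
#'
#' Reads the network and expression inputs, computes one score table per
#' requested method, and writes each as `scores_<METHOD>.tsv` in
#' `output_dir` together with a `manifest.json` echoing the config and the
#' MD5 checksums of the inputs. Reruns with identical inputs produce
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return named list of [score_table]s, invisibly.
#' @export
run_score <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  net <- read_ppi(cfg$ppi_path)
  expr <- read_expression(cfg$expr_path)
  boolexpr <- binarize(expr)
  tables <- lapply(cfg$methods, .score_one, net = net, expr = expr,
                   boolexpr = boolexpr, lambda = cfg$wdc_lambda)
  names(tables) <- cfg$methods
  for (m in cfg$methods)
    write_score_table(tables[[m]], file.path(cfg$output_dir,
                                             sprintf("scores_%s.tsv", m)))
  manifest <- list(
    config = unclass(cfg),
    inputs = as.list(tools::md5sum(c(cfg$ppi_path, cfg$expr_path,
                                     cfg$essential_path))))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tables)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Evaluate score tables against an essential-protein list
#'
#' For each scored method, writes into `output_dir`: `metrics_<M>.tsv`
#' (confusion counts plus the derived metrics at the number-of-essentials
#' cutoff), `roc_<M>.tsv` and `roc_top_<M>.tsv` (FPR/TPR points, AUC in a
#' `#` header), `jackknife_<M>.tsv` and `topk_<M>.tsv`; plus
#' `overlap_<M>.tsv` comparing every other method's top-N set against the
#' first configured method's.
#'
#' @param cfg a [run_config()].
#' @param tables named list of [score_table]s; read back from
#'   `scores_<METHOD>.tsv` files in `output_dir` when omitted.
#' @return named list of `eval_report`s, invisibly.
#' @export
run_evaluate <- function(cfg, tables = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(tables)) {
    tables <- lapply(cfg$methods, function(m)
      read_score_table(file.path(cfg$output_dir,
                                 sprintf("scores_%s.tsv", m))))
    names(tables) <- cfg$methods
  }
  essential <- read_essential(cfg$essential_path)
  if (length(intersect(essential, tables[[1L]]$protein)) == 0L)
    stop("no essential protein is present in the scored universe")
  reports <- lapply(tables, evaluate_ranking, essential = essential,
                    top_fraction = cfg$top_fraction,
                    percents = cfg$top_percents)
  for (m in names(reports)) {
    r <- reports[[m]]
    metr <- data.frame(
      metric = c("TP", "FP", "TN", "FN", names(r$metrics), "AUC", "AUC_top"),
      value = c(r$counts$TP, r$counts$FP, r$counts$TN, r$counts$FN,
                unname(r$metrics), r$auc, r$auc_top))
    .write_tsv(metr, file.path(cfg$output_dir, sprintf("metrics_%s.tsv", m)))
    .write_roc <- function(roc, auc, path) {
      con <- file(path, "wt"); on.exit(close(con))
      writeLines(sprintf("# AUC: %.17g", auc), con)
      writeLines("FPR\tTPR", con)
      if (!is.null(roc))
        writeLines(sprintf("%.17g\t%.17g", roc$FPR, roc$TPR), con)
    }
    .write_roc(r$roc, r$auc, file.path(cfg$output_dir,
                                       sprintf("roc_%s.tsv", m)))
    .write_roc(r$roc_top, r$auc_top,
               file.path(cfg$output_dir, sprintf("roc_top_%s.tsv", m)))
    .write_tsv(data.frame(rank = seq_along(r$jackknife),
                          cumulative_essential = r$jackknife),
               file.path(cfg$output_dir, sprintf("jackknife_%s.tsv", m)))
    .write_tsv(data.frame(percent = cfg$top_percents,
                          essential_count = unname(r$topk)),
               file.path(cfg$output_dir, sprintf("topk_%s.tsv", m)))
  }
  ref <- names(tables)[1L]
  for (m in setdiff(names(tables), ref)) {
    ov <- overlap_analysis(tables[[ref]], tables[[m]], essential,
                           top_n = min(cfg$overlap_top_n, nrow(tables[[ref]])))
    .write_tsv(data.frame(
      reference = ref, method = m, top_n = ov$top_n,
      intersection = ov$intersection,
      ref_only = ov$a_only$size, ref_only_essential = ov$a_only$essential,
      ref_only_essential_pct = ov$a_only$essential_pct,
      method_only = ov$b_only$size,
      method_only_essential = ov$b_only$essential,
      method_only_essential_pct = ov$b_only$essential_pct),
      file.path(cfg$output_dir, sprintf("overlap_%s.tsv", m)))
  }
  invisible(reports)
}

#' Concatenate per-method evaluation outputs into one summary table
#'
#' @param cfg a [run_config()].
#' @return data frame (method x metric, long form), also written to
#'   `summary.tsv` in `output_dir`.
#' @export
run_report <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rows <- lapply(cfg$methods, function(m) {
    df <- utils::read.delim(file.path(cfg$output_dir,
                                      sprintf("metrics_%s.tsv", m)))
    cbind(method = m, df)
  })
  out <- do.call(rbind, rows)
  .write_tsv(out, file.path(cfg$output_dir, "summary.tsv"))
  out
}
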