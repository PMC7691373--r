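#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run — input, projection side,
#' predictor, PE/MI parameters, evaluation settings, seed, output directory
#' — into one validated object. A configuration round-trips through a flat
#' `key = value` text file, so runs are fully reproducible from a file plus
#' nothing else.
#'
#' @param input path to a bipartite edge list (see
#'   [read_bipartite_edgelist()]).
#' @param out_dir output directory (created if missing).
#' @param method predictor, as in [score_candidates()].
#' @param side projection side, as in [pmil()].
#' @param evaluate if `TRUE` run the cross-validated evaluation as well.
#' @param k,repeats,auc_samples,L,precision_at evaluation settings, as in
#'   [evaluate_predictor()].
#' @param no_cn_constant,log_base,eps model parameters, as in [pmil()].
#' @param seed root RNG seed for the whole run.
#' @param delimiter input field separator (`NULL` auto-detects).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, out_dir = ".", method = "pmil", side = "auto",
                       evaluate = FALSE, k = 10, repeats = 1,
                       auc_samples = 10000, L = NULL,
                       precision_at = c(10, 20, 50), no_cn_constant = 0.1,
                       log_base = 2, eps = 1e-10, seed = 1,
                       delimiter = NULL) {
  method <- match.arg(method, c("pmil", "cn", "jc", "pa", "cs"))
  side <- match.arg(side, c("auto", "u", "v"))
  if (k < 2) stop_arg("`k` must be at least 2")
  if (repeats < 1) stop_arg("`repeats` must be at least 1")
  if (auc_samples < 1) stop_arg("`auc_samples` must be at least 1")
  structure(list(input = input, out_dir = out_dir, method = method,
                 side = side, evaluate = isTRUE(evaluate), k = k,
                 repeats = repeats, auc_samples = auc_samples, L = L,
                 precision_at = precision_at,
                 no_cn_constant = no_cn_constant, log_base = log_base,
                 eps = eps, seed = seed, delimiter = delimiter),
            class = "run_config")
}

#' Read / write a run configuration file
#'
#' Flat `key = value` text, one setting per line, `#` comments allowed;
#' `precision_at` is comma-separated. Keys missing from the file keep the
#' [run_config()] defaults.
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_run_config()`: a `run_config`;
#'   `write_run_config()`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  if (any(lengths(kv) != 3L))
    stop_arg("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  args <- list()
  for (s in seq_along(keys)) {
    key <- keys[s]; val <- vals[s]
    args[[key]] <- switch(key,
      input = , out_dir = , method = , side = , delimiter = val,
      evaluate = as.logical(val),
      precision_at = as.numeric(strsplit(val, ",")[[1L]]),
      L = if (toupper(val) == "NULL") NULL else as.numeric(val),
      as.numeric(val))
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  fmt <- function(key) {
    v <- config[[key]]
    if (is.null(v)) return(NULL)
    paste0(key, " = ", paste(v, collapse = ","))
  }
  keys <- c("input", "out_dir", "method", "side", "evaluate", "k",
            "repeats", "auc_samples", "L", "precision_at",
            "no_cn_constant", "log_base", "eps", "seed", "delimiter")
  writeLines(unlist(lapply(keys, fmt)), path)
  invisible(path)
}

#' Run the full prediction pipeline
#'
#' Executes projection, pattern weighting and candidate ranking on an input
#' edge list, writing each artifact to the output directory:
#' `projected.tsv` (the weighted projection), `pattern_weights.tsv`
#' (per-pattern PE, MI, WP and total), `ranking.tsv` (the ranked score
#' table) and, when evaluation is requested, `evaluation.tsv` (per-fold
#' metrics) and `evaluation.json` (per-fold plus means). Identical
#' configuration and seed produce identical artifacts. For baseline methods
#' the pattern-weight table is skipped (they do not use it).
#'
#' @param config a [run_config()] (or path to a config file).
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the fitted objects, the ranking, the
#'   evaluation report (or `NULL`) and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop_arg("`config` must be a run_config")
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  g <- read_bipartite_edgelist(config$input, config$delimiter)
  say("input: |U| = ", length(g$u), ", |V| = ", length(g$v),
      ", |E| = ", n_edges(g))
  side <- config$side
  if (side == "auto") side <- if (length(g$v) < length(g$u)) "v" else "u"

  paths <- list()
  pg <- project_weighted(g, side)
  say("projection (side ", side, "): ", nrow(pg$edges), " patterns")
  paths$projected <- file.path(config$out_dir, "projected.tsv")
  write_projected_edgelist(pg, paths$projected)

  fit <- NULL
  if (config$method == "pmil") {
    fit <- pmil(g, side = side, no_cn_constant = config$no_cn_constant,
                log_base = config$log_base, eps = config$eps)
    paths$weights <- file.path(config$out_dir, "pattern_weights.tsv")
    utils::write.table(as.data.frame(fit$weights), paths$weights,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ranking <- predict(fit)
    say("ranked ", nrow(ranking), " candidate pairs (PMIS)")
  } else {
    ranking <- score_candidates(g, config$method, side)
    say("ranked ", nrow(ranking), " candidate pairs (",
        toupper(config$method), ")")
  }
  paths$ranking <- file.path(config$out_dir, "ranking.tsv")
  utils::write.table(ranking, paths$ranking, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  report <- NULL
  if (config$evaluate) {
    report <- evaluate_predictor(
      g, method = config$method, k = config$k, repeats = config$repeats,
      n_comparisons = config$auc_samples, L = config$L,
      precision_at = config$precision_at, seed = config$seed, side = side,
      no_cn_constant = config$no_cn_constant, log_base = config$log_base,
      eps = config$eps)
    say("evaluation: mean AUC = ", round(report$mean[["auc"]], 4),
        ", mean precision = ", round(report$mean[["precision"]], 4))
    paths$eval_tsv <- file.path(config$out_dir, "evaluation.tsv")
    utils::write.table(report$folds, paths$eval_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$eval_json <- file.path(config$out_dir, "evaluation.json")
    mean_list <- as.list(report$mean)
    mean_list <- lapply(mean_list, function(x)
      if (is.finite(x)) x else as.character(x))
    jsonlite::write_json(
      list(method = config$method, k = config$k, repeats = config$repeats,
           seed = config$seed, mean = mean_list, folds = report$folds),
      paths$eval_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(graph = g, projection = pg, fit = fit, ranking = ranking,
                 report = report, paths = paths))
}
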