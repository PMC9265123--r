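#' Run the full classification pipeline
#'
#' Executes, in order: input acquisition (a breakpoint table, an in-memory
#' record data frame, or the synthetic generator), per-sample graph
#' construction, connectivity profiling on the integrated graphs,
#' threshold filtering, a stratified train/test split, attention-network
#' training, and evaluation — writing every artifact plus a run manifest
#' into `out_dir`. The evaluation artifacts are a pure function of the
#' configuration and seed, so reruns with one seed are byte-identical.
#'
#' @param config A list with any of:
#'   \describe{
#'     \item{input}{Path to a TSV/CSV breakpoint table.}
#'     \item{records}{Record data frame (alternative to `input`).}
#'     \item{synthetic}{List `(preset = "separable", n_per_class, seed)` to
#'       generate the input instead.}
#'     \item{mode}{`"integrated"` (default), `"inter"` or `"intra"`: which
#'       aberrations feed the classifier. Connectivity filtering always
#'       uses the integrated graph.}
#'     \item{tau, tau_high}{Connectivity thresholds; see [filter_config()].}
#'     \item{test_fraction}{Held-out fraction (default 0.2).}
#'     \item{gnn}{Named overrides for [gnn_config()] (e.g. `max_epochs`).}
#'     \item{seed}{Global seed (default 0); the split and, unless
#'       overridden, the network seed derive from it.}
#'     \item{out_dir}{Output directory (required).}
#'   }
#' @return Invisibly, a list with `model`, `report`, `dataset` (per-sample
#'   table with kept/split status), `history` and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(!is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mode <- config$mode %||% "integrated"
  tau <- config$tau %||% 0.3
  seed <- as.integer(config$seed %||% 0L)
  test_fraction <- config$test_fraction %||% 0.2
  paths <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input ---------------------------------------------------------------
  input_checksum <- NULL
  records <- stage("input", {
    if (!is.null(config$records)) {
      config$records
    } else if (!is.null(config$input)) {
      input_checksum <- unname(tools::md5sum(config$input))
      read_breakpoints(config$input)
    } else if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      rec <- make_separable_cohort(n_per_class = syn$n_per_class %||% 200L,
                                   seed = syn$seed %||% seed)
      paths$cohort <- file.path(out_dir, "cohort.tsv")
      write_breakpoints(rec, paths$cohort)
      rec
    } else {
      stop("config needs one of 'input', 'records' or 'synthetic'")
    }
  })

  # --- graphs and connectivity (always on the integrated graph) ------------
  samples <- stage("grouping", group_by_sample(records))
  graphs_int <- stage("graphs", build_cohort_graphs(samples,
                                                    mode = "integrated"))
  message("built ", length(graphs_int), " graphs from ",
          nrow(records), " records")
  profiles <- stage("connectivity", cohort_connectivity(graphs_int))
  conn <- connectivity_report(graphs_int, profiles)
  paths$connectivity <- file.path(out_dir, "connectivity.tsv")
  utils::write.table(conn, paths$connectivity, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- filtering -----------------------------------------------------------
  fc <- filter_config(tau_low = tau, tau_high = config$tau_high)
  parts <- stage("filtering", filter_graphs(graphs_int, profiles, fc))
  message(length(parts$kept), " of ", length(graphs_int),
          " graphs kept at tau = ", tau)
  kept_ids <- vapply(parts$kept, function(g) g$sample_id, character(1))

  # --- mode restriction + split --------------------------------------------
  graphs_mode <- stage("mode", {
    if (mode == "integrated") {
      parts$kept
    } else {
      lapply(kept_ids, function(id) {
        s <- samples[[id]]
        build_graph(s$sample_id, s$cancer_type, s$records, mode = mode)
      })
    }
  })
  split <- stage("split", split_dataset(graphs_mode,
                                        test_fraction = test_fraction,
                                        seed = seed))
  test_ids <- vapply(split$test, function(g) g$sample_id, character(1))
  dataset <- conn
  dataset$kept <- dataset$sample_id %in% kept_ids
  dataset$split <- ifelse(!dataset$kept, "dropped",
                          ifelse(dataset$sample_id %in% test_ids,
                                 "test", "train"))
  paths$dataset <- file.path(out_dir, "dataset.tsv")
  utils::write.table(dataset, paths$dataset, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- training ------------------------------------------------------------
  gnn_overrides <- config$gnn %||% list()
  if (is.null(gnn_overrides$seed)) gnn_overrides$seed <- seed
  cfg <- do.call(gnn_config, gnn_overrides)
  model <- stage("training", gnn_train(split, cfg))
  paths$model <- file.path(out_dir, "model.json")
  write_model(model, paths$model)
  paths$training_log <- file.path(out_dir, "training_log.tsv")
  utils::write.table(model$history, paths$training_log, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- evaluation ----------------------------------------------------------
  pred <- stage("evaluation", stats::predict(model, split$test))
  truth <- vapply(split$test, function(g) g$label, character(1))
  report <- classification_report(true_labels = truth,
                                  predicted_labels = pred$labels,
                                  class_order = model$classes,
                                  unit = "graphs")
  paths$report <- file.path(out_dir, "eval_report.json")
  write_report_json(report, paths$report)
  paths$confusion <- file.path(out_dir, "confusion_counts.tsv")
  paths$confusion_norm <- file.path(out_dir, "confusion_normalized.tsv")
  write_confusion_tsv(report, paths$confusion, paths$confusion_norm)
  predictions <- data.frame(sample_id = test_ids, true = truth,
                            predicted = pred$labels,
                            round(pred$prob, 6),
                            stringsAsFactors = FALSE)
  paths$predictions <- file.path(out_dir, "predictions.tsv")
  utils::write.table(predictions, paths$predictions, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    tool = "chromgraph",
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    mode = mode,
    tau = tau,
    test_fraction = test_fraction,
    gnn_config = unclass(cfg),
    input_checksum = input_checksum,
    n_records = nrow(records),
    n_graphs = length(graphs_int),
    n_kept = length(parts$kept),
    artifacts = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  message(sprintf("test accuracy: %.3f (%d graphs)", report$accuracy,
                  length(split$test)))
  invisible(list(model = model, report = report, dataset = dataset,
                 history = model$history, split = split, paths = paths))
}
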