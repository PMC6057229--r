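#' Run one analysis end to end
#'
#' Single programmatic entry point behind the command-line tool: loads (or
#' simulates) epochs, extracts the analysis target, runs the requested
#' analysis for every comparison, applies the requested correction, and
#' writes result tables, plots and a manifest under the output directory.
#' Identical configuration and seed produce byte-identical result tables,
#' independent of `workers`.
#'
#' @param config a list (or JSON path) with elements:
#'   `analysis` (`"simulate"`, `"sensors"`, `"gfp"`, `"tanova"`,
#'   `"classify"`), `out_dir`, `seed`, and per analysis:
#'   `spec` (simulation spec, for simulate) or `epochs` (HDF5 path) +
#'   `target` (JSON path or target list); optional `window_ms`, `alpha`,
#'   `strategy`, `n_shuffles`, `test_size`, `folds`, `n_permutations`,
#'   `correct` (`"cluster"` or `"fdr_bh"`), `min_duration_ms`, `fdr`,
#'   `stat`, `average_reference`, `workers`, `plots`.
#' @return invisibly, the manifest: a list of files written.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  analysis <- config$analysis %||% stopf("config is missing 'analysis'")
  out_dir <- config$out_dir %||% stopf("config is missing 'out_dir'")
  seed <- config$seed %||% stopf("config is missing 'seed'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  workers <- config$workers %||% 1L
  alpha <- config$alpha %||% 0.05
  files <- character(0)

  log_line <- sprintf("topostat %s | analysis=%s seed=%s | %s",
                      as.character(utils::packageVersion("topostat")),
                      analysis, seed,
                      paste(names(config), vapply(config, function(v)
                        paste(format(unlist(v)), collapse = ","), ""),
                        sep = "=", collapse = " "))

  if (analysis == "simulate") {
    spec <- config$spec
    if (is.character(spec)) spec <- read_simulation_spec(spec)
    if (!inherits(spec, "simulation_spec")) stopf("'spec' must be a simulation spec")
    spec$seed <- as.integer(seed)
    out_file <- file.path(out_dir, config$out_file %||% "epochs.h5")
    save_epochs(simulate_epochs(spec), out_file)
    files <- out_file
  } else {
    x <- if (inherits(config$epochs, "eeg_epochs")) config$epochs
         else load_epochs(config$epochs)
    target <- config$target
    if (is.character(target)) target <- read_target(target)
    if (!inherits(target, "analysis_target"))
      target <- analysis_target(target$conditions, target$comparisons %||% list(),
                                target$time_range, target$window_ms)
    view <- extract_epochs(x, target,
                           average_reference = config$average_reference %||% TRUE)
    window_ms <- config$window_ms %||% target$window_ms %||%
      stopf("no 'window_ms' in config or target")
    if (length(target$comparisons) == 0L)
      stopf("target defines no comparisons")
    cseeds <- derive_seeds(as.integer(seed), length(target$comparisons))
    series <- if (analysis == "gfp") gfp_series(view)
    for (ci in seq_along(target$comparisons)) {
      cmp <- target$comparisons[[ci]]
      tag <- paste0(analysis, "_", cmp[1], "_vs_", cmp[2])
      res <- switch(analysis,
        sensors = sensor_tests(view, cmp, window_ms, alpha = alpha,
                               fdr = isTRUE(config$fdr)),
        gfp = gfp_compare(series, cmp, window_ms,
                          stat = config$stat %||% "mean",
                          fdr = isTRUE(config$fdr), alpha = alpha),
        tanova = tanova(view, cmp, window_ms,
                        strategy = config$strategy %||% 3,
                        n_shuffles = config$n_shuffles %||% 1000,
                        seed = cseeds[ci], alpha = alpha, workers = workers),
        classify = classify(view, cmp,
                            classification_config(
                              window_ms = window_ms,
                              test_size = config$test_size %||% 0.3,
                              folds = config$folds %||% 25,
                              seed = cseeds[ci]),
                            n_permutations = config$n_permutations %||% 10000,
                            alpha = alpha, workers = workers),
        stopf("unknown analysis '%s'", analysis))
      if (!is.null(config$correct))
        res <- correct(res, config$correct, alpha = alpha,
                       min_duration_ms = config$min_duration_ms %||% 20)
      files <- c(files, save_result(res, file.path(out_dir, tag)))
      if (isTRUE(config$plots))
        files <- c(files, plot(res, file = file.path(out_dir,
                                                     paste0(tag, ".png"))))
    }
    if (analysis == "gfp")
      files <- c(files, save_result(series, file.path(out_dir, "gfp_series")))
  }

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(analysis = analysis, seed = seed, log = log_line,
                            files = basename(files)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  message(log_line)
  invisible(c(files, manifest))
}
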