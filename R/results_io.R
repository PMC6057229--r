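# Uniform result envelope: every analysis result is a list with
# analysis_name, a primary `table`, optional extra tables, and an
# `annotation` echoing the parameters (including the seed for permutation
# analyses). Serialization is TSV per table + one JSON metadata sidecar.

result_tables <- function(x) {
  out <- list(table = x$table)
  if (!is.null(x$counts)) out$counts <- x$counts
  if (!is.null(x$scores))
    out$scores <- data.frame(subject = rownames(x$scores),
                             as.data.frame(x$scores, optional = TRUE),
                             check.names = FALSE)
  if (!is.null(x$summary)) out$summary <- x$summary
  out
}

#' @export
print.topostat_result <- function(x, ...) {
  cat(sprintf("<%s result> comparison: %s\n", x$analysis_name,
              paste(x$annotation$comparison, collapse = " vs ")))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...", nrow(x$table), "windows\n")
  invisible(x)
}

#' @export
summary.topostat_result <- function(object, ...) {
  tab <- object$table
  sig <- if ("significant_corrected" %in% names(tab))
    tab$significant_corrected else tab$significant
  cat(sprintf("%s: %d windows, %d significant%s\n", object$analysis_name,
              nrow(tab), sum(sig, na.rm = TRUE),
              if ("significant_corrected" %in% names(tab))
                " (corrected)" else " (uncorrected)"))
  if (any(sig, na.rm = TRUE))
    cat(sprintf("  first significant window: [%g, %g) ms\n",
                tab$window_start[which(sig)[1]], tab$window_end[which(sig)[1]]))
  invisible(object)
}

#' Save an analysis result to disk
#'
#' Writes every table of the result as a TSV file (`<prefix>_<table>.tsv`,
#' tab-separated, header row, UTF-8, '.' decimal) plus a JSON metadata
#' sidecar `<prefix>.json` holding the analysis name, the annotation
#' (parameters and seed, echoed verbatim) and the table manifest. The round
#' trip through [load_result()] is lossless.
#'
#' @param x a result object (`tanova_result`, `gfp_test`, `sensor_sig_map`,
#'   `classification_result`, or a `gfp_series`).
#' @param prefix output path prefix (directories are created).
#' @return character vector of files written, invisibly.
#' @export
save_result <- function(x, prefix) {
  if (inherits(x, "gfp_series")) x <- gfp_series_envelope(x)
  stopifnot(inherits(x, "topostat_result"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  tabs <- result_tables(x)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- paste0(prefix, "_", nm, ".tsv")
    utils::write.table(tabs[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  meta <- list(analysis_name = x$analysis_name,
               class = class(x)[1],
               annotation = x$annotation,
               tables = as.list(stats::setNames(basename(files), names(tabs))))
  json <- paste0(prefix, ".json")
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(files, json))
}

gfp_series_envelope <- function(x) {
  long <- do.call(rbind, lapply(names(x$series), function(cn) {
    g <- x$series[[cn]]
    data.frame(condition = cn,
               subject = rep(rownames(g), times = ncol(g)),
               time_ms = rep(x$times, each = nrow(g)),
               gfp_uV = as.vector(g))
  }))
  structure(list(analysis_name = "gfp_series", table = long,
                 summary = x$summary,
                 annotation = list(conditions = names(x$series),
                                   n_subjects = length(x$subjects),
                                   sampling_rate = x$sampling_rate,
                                   seed = NA)),
            class = c("gfp_series_envelope", "topostat_result"))
}

#' Load an analysis result saved by [save_result()]
#'
#' @param prefix the prefix passed to [save_result()] (or the path of the
#'   JSON sidecar without extension).
#' @return the result object, with its original class, tables and
#'   annotation. Permutation results must carry their seed: a sidecar
#'   without a `seed` entry in the annotation of a permutation analysis is
#'   rejected as malformed.
#' @export
load_result <- function(prefix) {
  json <- if (endsWith(prefix, ".json")) prefix else paste0(prefix, ".json")
  if (!file.exists(json)) stopf("result sidecar not found: %s", json)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  for (f in c("analysis_name", "class", "annotation", "tables"))
    if (is.null(meta[[f]])) stopf("result sidecar %s is missing '%s'", json, f)
  if (meta$analysis_name %in% c("tanova", "classification") &&
      is.null(meta$annotation$seed))
    stopf("result sidecar %s is missing 'seed' in its annotation", json)
  dir <- dirname(json)
  tabs <- lapply(meta$tables, function(f)
    utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE))
  out <- list(analysis_name = meta$analysis_name, table = tabs$table,
              annotation = meta$annotation)
  if (!is.null(tabs$counts)) out$counts <- tabs$counts
  if (!is.null(tabs$summary)) out$summary <- tabs$summary
  if (!is.null(tabs$scores)) {
    m <- as.matrix(tabs$scores[, -1, drop = FALSE])
    rownames(m) <- tabs$scores[[1]]
    colnames(m) <- NULL
    out$scores <- m
  }
  structure(out, class = c(meta$class, "topostat_result"))
}

#' Plot a GFP series
#'
#' Group-mean GFP per condition with a standard-error band.
#'
#' @param x a [gfp_series()] object.
#' @param file optional PNG path; when given, the plot is written there and
#'   the path returned invisibly.
#' @param ... ignored.
#' @export
plot.gfp_series <- function(x, file = NULL, ...) {
  draw <- function() {
    conds <- names(x$series)
    cols <- grDevices::hcl.colors(max(3L, length(conds)), "Dark 3")
    ylim <- range(x$summary$mean + x$summary$sem,
                  x$summary$mean - x$summary$sem, 0)
    graphics::plot(NA, xlim = range(x$times), ylim = ylim,
                   xlab = "time (ms)", ylab = "GFP (µV)",
                   main = "Global field power (group mean ± SEM)")
    for (i in seq_along(conds)) {
      s <- x$summary[x$summary$condition == conds[i], ]
      graphics::polygon(c(s$time_ms, rev(s$time_ms)),
                        c(s$mean + s$sem, rev(s$mean - s$sem)),
                        col = grDevices::adjustcolor(cols[i], 0.25),
                        border = NA)
      graphics::lines(s$time_ms, s$mean, col = cols[i], lwd = 2)
    }
    graphics::legend("topright", legend = conds, col = cols[seq_along(conds)],
                     lwd = 2, bty = "n")
  }
  render_png(draw, file)
}

#' Plot a windowed p-value series
#'
#' p-values across window start times on a -log10 scale, with the alpha
#' threshold line and corrected-significant windows (if present) marked.
#'
#' @param x a `tanova_result`, `classification_result` or `gfp_test`.
#' @param file optional PNG path.
#' @param ... ignored.
#' @export
plot.topostat_result <- function(x, file = NULL, ...) {
  tab <- x$table
  if (is.null(tab$p) || all(is.na(tab$p)))
    stopf("result has no p-value series to plot")
  alpha <- x$annotation$alpha %||% 0.05
  draw <- function() {
    lp <- -log10(pmax(tab$p, 1e-12))
    graphics::plot(tab$window_start, lp, type = "b", pch = 16,
                   xlab = "window start (ms)", ylab = "-log10 p",
                   main = sprintf("%s: %s", x$analysis_name,
                                  paste(x$annotation$comparison,
                                        collapse = " vs ")))
    graphics::abline(h = -log10(alpha), lty = 2)
    if (!is.null(tab$significant_corrected) && any(tab$significant_corrected))
      graphics::points(tab$window_start[tab$significant_corrected],
                       lp[tab$significant_corrected], pch = 16, cex = 1.4,
                       col = "red3")
  }
  render_png(draw, file)
}

#' Plot a significant-sensor count strip
#'
#' @param x a [sensor_tests()] result.
#' @param file optional PNG path.
#' @param ... ignored.
#' @export
plot.sensor_sig_map <- function(x, file = NULL, ...) {
  cnt <- x$counts
  draw <- function() {
    graphics::image(x = c(cnt$window_start, cnt$window_end[nrow(cnt)]),
                    y = c(0, 1),
                    z = matrix(cnt$sig_count, ncol = 1),
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                    xlab = "time (ms)", yaxt = "n", ylab = "",
                    main = sprintf("Significant sensors: %s",
                                   paste(x$annotation$comparison,
                                         collapse = " vs ")))
    graphics::text(x = (cnt$window_start + cnt$window_end) / 2, y = 0.5,
                   labels = cnt$sig_count)
  }
  render_png(draw, file)
}

render_png <- function(draw, file) {
  if (is.null(file)) {
    draw()
    return(invisible(NULL))
  }
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(file, width = 900, height = 500, res = 110)
  ok <- FALSE
  tryCatch({ draw(); ok <- TRUE }, finally = {
    grDevices::dev.off()
    if (!ok && file.exists(file)) unlink(file)
  })
  invisible(file)
}
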