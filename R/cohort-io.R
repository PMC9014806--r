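#' Read ROI control points from CSV or JSON
#'
#' CSV files need `z_mm`/`x_mm` columns (or two unnamed numeric columns);
#' JSON files either an array of `[z, x]` pairs or an object with `z_mm`
#' and `x_mm` arrays.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return Numeric matrix of control points, ready for
#'   [roi_from_control_points()].
#' @export
read_roi_control_points <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- if (is.list(j) && !is.null(j$z_mm)) cbind(j$z_mm, j$x_mm)
           else as.matrix(j)
  } else {
    df <- utils::read.csv(path)
    pts <- if (all(c("z_mm", "x_mm") %in% names(df)))
      cbind(df$z_mm, df$x_mm) else as.matrix(df[, 1:2])
  }
  storage.mode(pts) <- "double"
  colnames(pts) <- c("z_mm", "x_mm")
  pts
}

#' Append a per-tumor metrics record to a cohort CSV
#'
#' Writes the scalar read-outs of a reconstruction as long-format rows
#' (`tumor_id`, `cell_line`, `arm`, `timepoint`, `metric`, `value`),
#' creating the file with a header when absent. The long format feeds
#' [anova_tukey()] / [ancova_longitudinal()] directly after reshaping by
#' metric.
#'
#' @param metrics named list of scalar metrics (e.g. `ulm_run$metrics`).
#' @param tumor_id,cell_line,arm,timepoint cohort annotations; `arm` is one
#'   of control / sorafenib / folfox / combination, `timepoint` baseline or
#'   endpoint.
#' @param path cohort CSV path.
#' @return The rows appended, invisibly.
#' @export
append_metrics_csv <- function(metrics, tumor_id, cell_line, arm,
                               timepoint = c("baseline", "endpoint"),
                               path = "cohort.csv") {
  timepoint <- match.arg(timepoint)
  arm <- match.arg(arm, c("control", "sorafenib", "folfox", "combination"))
  scalars <- metrics[vapply(metrics, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  rows <- data.frame(tumor_id = tumor_id, cell_line = cell_line, arm = arm,
                     timepoint = timepoint, metric = names(scalars),
                     value = unlist(scalars, use.names = FALSE))
  utils::write.table(rows, path, append = file.exists(path), sep = ",",
                     row.names = FALSE, col.names = !file.exists(path))
  invisible(rows)
}

#' Reshape a long cohort CSV for one metric into test-ready vectors
#'
#' @param cohort data.frame as written by [append_metrics_csv()] (or the
#'   path of one).
#' @param metric metric name to extract.
#' @return data.frame with one row per tumor: `tumor_id`, `cell_line`,
#'   `arm`, `baseline`, `endpoint`; tumors missing an endpoint are kept
#'   (with `NA`) so callers can report attrition before dropping them.
#' @export
cohort_metric_table <- function(cohort, metric) {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  sub <- cohort[cohort$metric == metric, , drop = FALSE]
  stop_if(nrow(sub) == 0, sprintf("metric '%s' absent from cohort", metric))
  ids <- unique(sub$tumor_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- sub[sub$tumor_id == id, ]
    pick <- function(tp) {
      v <- rows$value[rows$timepoint == tp]
      if (length(v)) v[1] else NA_real_
    }
    data.frame(tumor_id = id, cell_line = rows$cell_line[1],
               arm = rows$arm[1], baseline = pick("baseline"),
               endpoint = pick("endpoint"))
  }))
  rownames(out) <- NULL
  out
}
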