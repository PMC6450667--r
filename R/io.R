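#' Write / read a trial table as CSV
#'
#' Fixed column layout so tables round-trip exactly; all downstream stages
#' accept the reloaded table.
#'
#' @param trials Trial table data.frame.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an ROI time-series set as TSV companions
#'
#' `ts.tsv` (time x ROI, header = ROI labels), `run.tsv`, and
#' `nuisance.tsv` under the given prefix.
#'
#' @param ts_set A `roi_timeseries`.
#' @param prefix Path prefix (files get `_ts.tsv`, `_run.tsv`,
#'   `_nuisance.tsv` suffixes).
#' @export
write_timeseries <- function(ts_set, prefix) {
  utils::write.table(ts_set$ts, paste0(prefix, "_ts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(run = ts_set$run), paste0(prefix, "_run.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ts_set$nuisance, paste0(prefix, "_nuisance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read an ROI time-series set written by [write_timeseries()]
#'
#' @param prefix Path prefix used when writing.
#' @param design The `study_design` the series were generated under.
#' @param trials Trial table for the subject.
#' @return A `roi_timeseries` list.
#' @export
read_timeseries <- function(prefix, design, trials) {
  ts <- as.matrix(utils::read.table(paste0(prefix, "_ts.tsv"), sep = "\t",
                                    header = TRUE, check.names = FALSE))
  run <- utils::read.table(paste0(prefix, "_run.tsv"), sep = "\t",
                           header = TRUE)$run
  nuis <- as.matrix(utils::read.table(paste0(prefix, "_nuisance.tsv"),
                                      sep = "\t", header = TRUE))
  structure(list(ts = ts, run = run, nuisance = nuis, design = design,
                 trials = trials),
            class = "roi_timeseries")
}

#' Read one-column error samples (layout of a feature-errors table)
#'
#' Accepts either a one-column CSV of wrapped errors in degrees or a trial
#' table with an `err_<feature>_deg` column.
#'
#' @param path CSV path.
#' @param feature `"color"` or `"scene"` (used when the file is a trial
#'   table).
#' @return Numeric vector of errors in degrees.
#' @export
read_errors <- function(path, feature = "color") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- paste0("err_", feature, "_deg")
  if (col %in% names(d)) return(d[[col]])
  if (ncol(d) == 1L) return(d[[1L]])
  stop("cannot find an error column in ", path)
}
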