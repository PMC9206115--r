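#' Write analysis records with a provenance manifest
#'
#' Serializes a metrics record, defect log, regime diagram or feature
#' histogram to CSV/JSON files in `dir` and writes a `manifest.json`
#' listing every file with its MD5 hash, the package version, the seed and
#' a full parameter echo -- any output can be traced back to
#' `(config, seed, version)` from the manifest alone.
#'
#' @param record a `cw_metrics`, `cw_defect_log`, `cw_regime_diagram`,
#'   feature-histogram matrix, or plain data frame.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param seed seed to record.
#' @param params optional [cw_params()] echoed into the manifest.
#' @return Character vector of written file paths (the manifest last),
#'   invisibly.
#' @export
write_outputs <- function(record, dir, prefix = "cortexwave", seed = NA,
                          params = NULL) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory ", dir)
  files <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (inherits(record, "cw_metrics")) {
    put_csv(record$per_box, "per_box")
    s <- record$summary
    put_csv(data.frame(metric = c("period_s", "width_s", "rel_amplitude",
                                  "shift_s"),
                       mean = vapply(s[1:4], `[[`, 0, "mean"),
                       sd = vapply(s[1:4], `[[`, 0, "sd"),
                       n = vapply(s[1:4], `[[`, 0, "n")), "summary")
  } else if (inherits(record, "cw_defect_log")) {
    put_csv(record$tracks, "tracks")
    if (!is.null(record$events)) put_csv(record$events, "events")
  } else if (inherits(record, "cw_regime_diagram")) {
    put_csv(as.data.frame(record), "regimes")
    if (!is.null(attr(record, "boundaries")))
      put_csv(attr(record, "boundaries"), "boundaries")
  } else if (is.matrix(record)) {
    put_csv(data.frame(group = rownames(record), record,
                       check.names = FALSE), "histogram")
  } else if (is.data.frame(record)) {
    put_csv(record, "table")
  } else stop("unsupported record type: ", paste(class(record), collapse = "/"))
  manifest <- list(
    package = "cortexwave",
    version = as.character(utils::packageVersion("cortexwave")),
    seed = seed,
    params = if (!is.null(params)) unclass(params),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mpath))
}
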