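# CSV/JSON writers for trajectories, scans, datasets and fits, plus the
# provenance manifest that accompanies every command-line artifact.

#' Write a trajectory to CSV
#'
#' @param traj A `tgf_trajectory`.
#' @param path Output CSV path.
#' @param format `"tidy"` (time, species, value) or `"wide"` (one column per
#'   species).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "tgf_trajectory"))
  df <- if (format == "tidy") as.data.frame(traj)
        else data.frame(time = traj$time, traj$mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a scan result to CSV
#'
#' @param scan A `tgf_scan`.
#' @param path Output CSV path for the summary table.
#' @param curves_path Optional CSV path for the full readout curves (if the
#'   scan kept them).
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path, curves_path = NULL) {
  stopifnot(inherits(scan, "tgf_scan"))
  utils::write.csv(scan$summary, path, row.names = FALSE)
  if (!is.null(curves_path) && !is.null(scan$curves))
    utils::write.csv(scan$curves, curves_path, row.names = FALSE)
  invisible(path)
}

#' Read / write a fold-change-versus-ratio dataset
#'
#' CSV dialect with header `ratio, fold_change, sd, gene, n`.
#'
#' @param path CSV path.
#' @return `read_ratio_dataset`: the dataset data.frame.
#' @export
read_ratio_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ratio", "fold_change")
  if (!all(need %in% names(df)))
    stop("ratio dataset needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$ratio < 0) || any(df$fold_change < 0))
    stop("ratios and fold changes must be >= 0", call. = FALSE)
  df
}

#' @rdname read_ratio_dataset
#' @param data Dataset data.frame.
#' @export
write_ratio_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' @param fit A `tgf_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "tgf_fit"))
  jsonlite::write_json(list(a = fit$a, b = fit$b, rss = fit$rss,
                            residuals = fit$residuals, n = fit$n,
                            form = fit$form, weighted = fit$weighted,
                            singular = fit$singular),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a provenance manifest next to an artifact
#'
#' Records the configuration (with an md5 hash), seed, package version and
#' timestamp so any artifact can be re-run from its manifest.
#'
#' @param path Output JSON path.
#' @param config Named list describing the run configuration.
#' @param seed Seed used (or `NA`).
#' @param command Command label.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NA, command = "run") {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  jsonlite::write_json(list(
    command = command,
    config = config,
    config_md5 = hash,
    seed = seed,
    package = "tgfsmad",
    version = as.character(utils::packageVersion("tgfsmad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
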