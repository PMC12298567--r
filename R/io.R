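# Readers/writers for the delimited-text record and pattern formats, plus
# run-configuration round-tripping. All formats are plain text.

#' Write an acceleration record to CSV (with a JSON sidecar)
#'
#' One file per record, columns `t,ax_g,ay_g,az_g` with a header row; the
#' metadata (label, case id, geometry, sampling rate) goes to a JSON sidecar
#' at `<path>.meta.json`.
#'
#' @param record an `accel_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  meta <- list(label = attr(record, "label"), case_id = attr(record, "case_id"),
               fs = attr(record, "fs"), H1 = attr(record, "H1"),
               H2 = attr(record, "H2"), record_id = attr(record, "record_id"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an acceleration record from delimited text
#'
#' Validates the time grid (strictly increasing, sampling interval constant
#' to within 1%) and the sample values (no missing/non-finite entries,
#' reported with their line numbers). Units are auto-detected from the
#' median acceleration norm: about 1 means g, about 9.81 means m/s^2
#' (converted to g); `units` overrides the detection. A JSON sidecar written
#' by [write_record()] is picked up automatically; `col_map` adapts foreign
#' column names.
#'
#' @param path CSV path.
#' @param units `"auto"` (default), `"g"` or `"ms2"`.
#' @param col_map optional named character vector mapping the canonical
#'   names `t`, `ax_g`, `ay_g`, `az_g` to the file's column names,
#'   e.g. `c(t = "time", ax_g = "Ax", ay_g = "Ay", az_g = "Az")`.
#' @return An `accel_record`.
#' @export
read_record <- function(path, units = c("auto", "g", "ms2"),
                        col_map = NULL) {
  units <- match.arg(units)
  stop_if_not(file.exists(path), paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      stop_if_not(col_map[[canon]] %in% names(d),
                  paste("mapped column not found:", col_map[[canon]]))
      names(d)[names(d) == col_map[[canon]]] <- canon
    }
  }
  need <- c("t", "ax_g", "ay_g", "az_g")
  missing_cols <- setdiff(need, names(d))
  stop_if_not(length(missing_cols) == 0,
              paste("missing columns:", paste(missing_cols, collapse = ", ")))
  d <- d[, need]
  fin <- vapply(d, function(x) is.numeric(x) & is.finite(x),
                logical(nrow(d)))
  if (is.null(dim(fin))) fin <- matrix(fin, nrow = nrow(d))
  bad <- which(!stats::complete.cases(d) | rowSums(fin) < ncol(d))
  if (length(bad))
    stop("non-finite or missing values at data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  dt <- diff(d$t)
  if (any(dt <= 0))
    stop("time must be strictly increasing; violation at data line ",
         which(dt <= 0)[1] + 2L, call. = FALSE)
  if (length(dt) > 1 && (max(dt) - min(dt)) > 0.01 * stats::median(dt))
    stop("sampling interval varies by more than 1%", call. = FALSE)

  norm <- sqrt(d$ax_g^2 + d$ay_g^2 + d$az_g^2)
  med <- stats::median(norm)
  if (units == "auto") units <- if (med > 4) "ms2" else "g"
  if (units == "ms2") {
    d$ax_g <- d$ax_g / 9.80665
    d$ay_g <- d$ay_g / 9.80665
    d$az_g <- d$az_g / 9.80665
  }

  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(d,
            label = meta$label, case_id = meta$case_id,
            fs = meta$fs %||% (1 / stats::median(dt)),
            H1 = meta$H1, H2 = meta$H2,
            record_id = meta$record_id %||%
              sub("\\.csv$", "", basename(path)),
            class = c("accel_record", "data.frame"))
}

#' Write / read a pattern dataset as CSV
#'
#' Column layout: `record_id,case_id,window_start,dapmax_m,dmlmax_m,cea_m2,
#' rms_m,label,split` (plus `noise_pct` when present).
#'
#' @param dataset a `pattern_dataset`.
#' @param path CSV path.
#' @return `path` invisibly ([write_patterns()]); a `pattern_dataset`
#'   ([read_patterns()]).
#' @export
write_patterns <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dapmax_m", "dmlmax_m", "cea_m2", "rms_m", "label")
  stop_if_not(all(need %in% names(d)),
              paste("pattern file lacks columns:",
                    paste(setdiff(need, names(d)), collapse = ", ")))
  structure(d, class = c("pattern_dataset", "data.frame"))
}

#' Write / read a run configuration
#'
#' A run configuration is a plain named list (paths, geometry, window and
#' noise settings, seeds...). It round-trips losslessly through JSON so
#' every run can store the fully resolved configuration next to its outputs.
#'
#' @param config named list.
#' @param path JSON path.
#' @return `path` invisibly ([write_config()]); the list ([read_config()]).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
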