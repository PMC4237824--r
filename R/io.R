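# File interfaces: cohort/roster/contour CSVs, NIfTI series with a JSON
# protocol sidecar, JSON study reports, YAML pipeline configuration.

cohort_columns <- c("subject_id", "vendor", "y1", "y2", "area1", "area2")

#' Read / write paired cohort tables as CSV
#'
#' Schema: one row per subject with columns `subject_id`, `vendor`, `y1`,
#' `y2`, `area1`, `area2`. Violations are reported naming the offending
#' column.
#'
#' @param table A cohort data.frame.
#' @param path CSV path.
#' @return `read_cohort_csv` returns the validated data.frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  miss <- setdiff(cohort_columns, names(table))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(table[, cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_columns, names(tab))
  if (length(miss))
    stop("cohort CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("y1", "y2", "area1", "area2")) {
    if (!is.numeric(tab[[col]]))
      stop("cohort CSV column '", col, "' is not numeric")
  }
  check_cohort(tab)
  tab
}

#' Read / write scan rosters as CSV
#' @param roster A roster data.frame (see [generate_roster()]).
#' @param path CSV path.
#' @return The roster data.frame (read) or `path` invisibly (write).
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a DCE series as NIfTI with a JSON protocol sidecar
#'
#' The 4D signal array is stored as NIfTI (x = rows, y = cols, z = slices,
#' t = frames) and the acquisition metadata as a JSON sidecar next to it
#' (same path with extension `.json`).
#'
#' @param series A `dce_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `read_series` returns the reconstructed `dce_series`;
#'   `write_series` returns `path` invisibly.
#' @export
write_series <- function(series, path) {
  validate_series(series)
  d <- dim(series$data)
  # slices x rows x cols x frames -> rows x cols x slices x frames
  arr <- aperm(series$data, c(2, 3, 1, 4))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_size, series$pixel_size,
                           series$protocol$slice_thickness,
                           series$protocol$frame_interval)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  pr <- unclass(series$protocol)
  jsonlite::write_json(list(protocol = pr, frame_times = series$frame_times),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop("protocol sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pr <- meta$protocol
  protocol <- do.call(acq_protocol, c(list(vendor = pr$vendor),
    pr[setdiff(names(pr), c("vendor", "pixel_size"))]))
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 1, 2, 4))
  structure(list(
    data = arr,
    protocol = protocol,
    frame_times = as.numeric(meta$frame_times),
    motion_true = NULL,
    pixel_size = protocol$pixel_size
  ), class = "dce_series")
}

#' Write / read contour polygons as CSV
#'
#' Long format with columns `contour` (e.g. "lumen", "outer"), `x_mm`,
#' `y_mm`; vertex order is preserved.
#'
#' @param contours Named list of two-column vertex matrices (mm).
#' @param path CSV path.
#' @return `read_contours_csv` returns the named list of matrices.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(names(contours), function(nm) {
    data.frame(contour = nm, x_mm = contours[[nm]][, 1],
               y_mm = contours[[nm]][, 2], stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("contour", "x_mm", "y_mm"), names(tab))
  if (length(miss))
    stop("contour CSV is missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(tab, tab$contour), function(s) cbind(x = s$x_mm, y = s$y_mm))
}

#' Write a study report as JSON (with optional text summary)
#'
#' @param report A `study_report` from [run_study()].
#' @param path Output JSON path.
#' @param text_path Optional path for the human-readable summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, text_path = NULL) {
  jsonlite::write_json(unclass_report(report), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  if (!is.null(text_path)) {
    writeLines(utils::capture.output(print(report)), text_path)
  }
  invisible(path)
}

# Strip classes so jsonlite serializes plainly; calls/functions become
# their deparsed text.
unclass_report <- function(x) {
  if (is.call(x) || is.function(x) || inherits(x, "formula")) {
    return(paste(deparse(x), collapse = " "))
  }
  if (is.atomic(x) && !is.null(names(x)) && is.null(base::dim(x))) {
    return(as.list(stats::setNames(as.vector(x), names(x))))
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_report)
  } else if (!is.data.frame(x)) {
    dims <- base::dim(x)
    attributes(x) <- attributes(x)["names"]
    base::dim(x) <- dims
  }
  if (!is.data.frame(x)) class(x) <- NULL
  x
}

#' Read a pipeline configuration from YAML
#'
#' Values in the YAML file override the defaults of [study_config()].
#'
#' @param path YAML path.
#' @return A `study_config` list.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}
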