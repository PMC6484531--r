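#' Per-cell morphological feature tables
#'
#' A `cell_table` is a data frame with one row per segmented cell and the
#' canonical role columns `plate`, `well`, `treatment` (plus optional `moa`
#' and `concentration`), followed by numeric feature columns. A designated
#' negative-control treatment (vehicle, `"DMSO"` by default) anchors every
#' per-plate statistic downstream: percentile scaling, bin edges, bin-z
#' baselines and the stability test all condition on it.
#'
#' @param data a data frame holding the raw per-cell measurements.
#' @param plate,well,treatment names of the columns carrying the plate
#'   identifier, the plate-unique well identifier, and the treatment
#'   (compound) label.
#' @param moa,concentration optional column names for the mode-of-action
#'   annotation and the treatment concentration.
#' @param features character vector of feature column names. When `NULL`
#'   (default) every remaining numeric column is used and non-numeric
#'   leftovers are excluded with a message; when given explicitly, a
#'   non-numeric entry is an error.
#' @param control treatment label of the negative-control wells.
#' @param validate run [validate_cell_table()] on the result.
#'
#' @return An object of class `cell_table` (a data frame with canonical
#'   column names and attributes `features` and `control`).
#' @seealso [read_cell_table()], [normalize_linear_percentile()],
#'   [bin_profile()]
#' @export
cell_table <- function(data, plate = "plate", well = "well",
                       treatment = "treatment", moa = NULL,
                       concentration = NULL, features = NULL,
                       control = "DMSO", validate = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c(plate, well, treatment)
  absent <- setdiff(need, names(data))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  out <- data.frame(plate = as.character(data[[plate]]),
                    well = as.character(data[[well]]),
                    treatment = as.character(data[[treatment]]),
                    stringsAsFactors = FALSE)
  reserved <- c(plate, well, treatment)
  if (!is.null(moa)) {
    if (!moa %in% names(data)) stop("MoA column not found: ", moa)
    out$moa <- as.character(data[[moa]])
    reserved <- c(reserved, moa)
  }
  if (!is.null(concentration)) {
    if (!concentration %in% names(data))
      stop("concentration column not found: ", concentration)
    out$concentration <- as.numeric(data[[concentration]])
    reserved <- c(reserved, concentration)
  }
  if (is.null(features)) {
    cand <- setdiff(names(data), reserved)
    numeric_ok <- vapply(data[cand], is.numeric, logical(1))
    if (any(!numeric_ok))
      message("excluding non-numeric column(s): ",
              paste(cand[!numeric_ok], collapse = ", "))
    features <- cand[numeric_ok]
  } else {
    miss <- setdiff(features, names(data))
    if (length(miss))
      stop("feature column(s) not found: ", paste(miss, collapse = ", "))
    bad <- features[!vapply(data[features], is.numeric, logical(1))]
    if (length(bad))
      stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  }
  if (!length(features)) stop("no numeric feature columns found")
  for (f in features) out[[f]] <- as.numeric(data[[f]])
  out <- structure(out, class = c("cell_table", "data.frame"),
                   features = features, control = control)
  if (validate) validate_cell_table(out)
  out
}

#' Validate a cell table
#'
#' Checks the structural invariants: mandatory role columns present, feature
#' values finite or missing, and at least one negative-control well on every
#' plate (an error names the offending plate). A plate with a single control
#' well triggers a warning because control dispersion statistics need two.
#'
#' @param x a [cell_table()].
#' @return `x`, invisibly.
#' @export
validate_cell_table <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  if (!all(c("plate", "well", "treatment") %in% names(x)))
    stop("cell_table lost its mandatory columns")
  feats <- attr(x, "features")
  for (f in feats) {
    v <- x[[f]]
    if (any(!is.finite(v) & !is.na(v)))
      stop("non-finite values in feature ", f)
  }
  ctl <- attr(x, "control")
  n_ctrl_wells <- vapply(split(x, x$plate), function(d)
    length(unique(d$well[d$treatment == ctl])), integer(1))
  if (any(n_ctrl_wells == 0L))
    stop("plate(s) without any '", ctl, "' control well: ",
         paste(names(n_ctrl_wells)[n_ctrl_wells == 0L], collapse = ", "))
  if (any(n_ctrl_wells == 1L))
    warning("plate(s) with a single '", ctl, "' control well: ",
            paste(names(n_ctrl_wells)[n_ctrl_wells == 1L], collapse = ", "),
            " (two or more are needed for control dispersion statistics)")
  invisible(x)
}

#' Read a per-cell feature table from CSV, TSV or Parquet
#'
#' @param path path to the input file; the format is inferred from the
#'   extension unless `format` is given. Parquet requires the \pkg{arrow}
#'   package.
#' @param schema named list mapping column roles to column names; recognised
#'   roles are `plate`, `well`, `treatment`, `moa`, `concentration` and
#'   `features` (see [cell_table()]).
#' @param control negative-control treatment label.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"parquet"`.
#' @param validate run validation after construction.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path,
                            schema = list(plate = "plate", well = "well",
                                          treatment = "treatment"),
                            control = "DMSO",
                            format = c("auto", "csv", "tsv", "parquet"),
                            validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     parquet = "parquet",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  raw <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("reading parquet requires the 'arrow' package")
      as.data.frame(arrow::read_parquet(path))
    })
  cell_table(raw,
             plate = schema$plate %||% "plate",
             well = schema$well %||% "well",
             treatment = schema$treatment %||% "treatment",
             moa = schema$moa, concentration = schema$concentration,
             features = schema$features, control = control,
             validate = validate)
}

#' Write a cell table or profile table to CSV or Parquet
#'
#' @param x a data frame (e.g. a [cell_table()] or [well_average()] output).
#' @param path output path; format inferred from extension unless given.
#' @param format one of `"auto"`, `"csv"`, `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", parquet = "parquet",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("writing parquet requires the 'arrow' package")
    arrow::write_parquet(as.data.frame(x), path)
  }
  invisible(path)
}

#' @export
`[.cell_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("plate", "well", "treatment") %in% names(out))) {
    attr(out, "features") <- intersect(attr(x, "features"), names(out))
    attr(out, "control") <- attr(x, "control")
    class(out) <- c("cell_table", "data.frame")
  }
  out
}

#' @export
print.cell_table <- function(x, ...) {
  feats <- attr(x, "features")
  cat(sprintf("<cell_table> %d cells, %d features\n", nrow(x), length(feats)))
  cat(sprintf("  plates:    %s\n",
              paste(unique(x$plate), collapse = ", ")))
  cat(sprintf("  wells:     %d  (control '%s': %d)\n",
              length(unique(paste(x$plate, x$well))), attr(x, "control"),
              length(unique(paste(x$plate, x$well)[
                x$treatment == attr(x, "control")]))))
  cat(sprintf("  features:  %s%s\n",
              paste(utils::head(feats, 6), collapse = ", "),
              if (length(feats) > 6) ", ..." else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild a cell_table after row subsetting by logical/integer index
subset_cells <- function(x, i) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cell_table", "data.frame"),
            features = attr(x, "features"), control = attr(x, "control"))
}

well_key <- function(x) paste(x$plate, x$well, sep = ":")
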