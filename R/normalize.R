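#' Linear percentile scaling against the plate's DMSO distribution
#'
#' Per plate and per parameter, the low and high percentiles (defaults 1 and
#' 99) of the negative-control cell values define a linear map sending the
#' low percentile to 0 and the high percentile to 1; the map is applied to
#' every cell on the plate. Values outside \[0, 1\] are kept (no clipping or
#' winsorizing). A parameter whose two control percentiles coincide on a
#' plate carries no scale there: its values are set to missing plate-wide
#' and a warning is raised.
#'
#' The operation is idempotent: after one application the control
#' percentiles are exactly 0 and 1 (quantiles are equivariant under linear
#' maps), so a second application is the identity.
#'
#' @param x a [cell_table()].
#' @param low,high percentiles in (0, 100), `low < high`.
#' @param type quantile type passed to [stats::quantile()] (default 7,
#'   linear interpolation between order statistics).
#' @return the rescaled `cell_table`.
#' @export
normalize_linear_percentile <- function(x, low = 1, high = 99, type = 7) {
  stopifnot(inherits(x, "cell_table"))
  if (!(low > 0 && high < 100 && low < high))
    stop("percentiles must satisfy 0 < low < high < 100")
  feats <- attr(x, "features")
  ctl <- attr(x, "control")
  for (p in unique(x$plate)) {
    pi <- x$plate == p
    ci <- pi & x$treatment == ctl
    if (!any(ci)) stop("plate ", p, " has no '", ctl, "' cells")
    dropped <- character()
    for (f in feats) {
      v <- x[[f]][ci]
      if (all(is.na(v))) { dropped <- c(dropped, f); x[[f]][pi] <- NA_real_; next }
      q <- stats::quantile(v, c(low, high) / 100, na.rm = TRUE,
                           names = FALSE, type = type)
      if (q[2] == q[1]) {
        x[[f]][pi] <- NA_real_
        dropped <- c(dropped, f)
      } else {
        x[[f]][pi] <- (x[[f]][pi] - q[1]) / (q[2] - q[1])
      }
    }
    if (length(dropped) == length(feats))
      stop("all parameters degenerate on plate ", p)
    if (length(dropped))
      warning("plate ", p, ": control percentiles coincide; values set ",
              "missing for: ", paste(dropped, collapse = ", "))
  }
  x
}

#' Per-well arithmetic means of single-cell data
#'
#' The simplest fingerprint: one profile per well, each feature the
#' arithmetic mean over that well's cells, skipping missing cell values.
#' Wells with fewer cells than `min_cells` are flagged (`low_n`), not
#' removed, so the caller decides whether they enter later statistics.
#'
#' @param x a [cell_table()].
#' @param min_cells wells with fewer cells are flagged.
#' @return a `well_profiles` data frame: role columns, `n_cells`, `low_n`,
#'   then one column per feature.
#' @export
well_average <- function(x, min_cells = 50) {
  stopifnot(inherits(x, "cell_table"), nrow(x) > 0)
  feats <- attr(x, "features")
  key <- well_key(x)
  first <- !duplicated(key)
  meta_cols <- intersect(c("plate", "well", "treatment", "moa",
                           "concentration"), names(x))
  meta <- as.data.frame(x)[first, meta_cols, drop = FALSE]
  ukey <- key[first]
  rownames(meta) <- ukey

  vals <- as.matrix(as.data.frame(x)[feats])
  present <- 1 - is.na(vals)
  vals[is.na(vals)] <- 0
  sums <- rowsum(vals, key)
  nobs <- rowsum(present, key)
  avg <- sums / nobs           # 0/0 -> NaN for all-missing wells
  avg[nobs == 0] <- NA_real_
  avg <- avg[ukey, , drop = FALSE]

  n_cells <- as.integer(table(key)[ukey])
  out <- data.frame(meta, n_cells = n_cells, low_n = n_cells < min_cells,
                    avg, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("well_profiles", "data.frame"),
            features = feats, control = attr(x, "control"))
}

#' Z-normalize well averages per plate against the DMSO wells
#'
#' Per plate and parameter, each well-average value `x` becomes
#' `(x - mean_DMSO) / sd_DMSO`, where the mean and the sample standard
#' deviation (denominator n - 1) are taken over that plate's control well
#' averages. After the transform the control wells of every plate have mean
#' 0 and sample sd 1 in every retained parameter. Parameters with zero
#' control sd on a plate are set to missing plate-wide with a warning.
#'
#' @param p a `well_profiles` data frame from [well_average()].
#' @return the z-scored `well_profiles`.
#' @export
zscore_well_averages <- function(p) {
  stopifnot(inherits(p, "well_profiles"))
  feats <- attr(p, "features")
  ctl <- attr(p, "control")
  for (pl in unique(p$plate)) {
    pi <- p$plate == pl
    ci <- pi & p$treatment == ctl
    if (sum(ci) < 2)
      stop("plate ", pl, " has fewer than 2 '", ctl, "' wells")
    dropped <- character()
    for (f in feats) {
      m <- mean(p[[f]][ci], na.rm = TRUE)
      s <- stats::sd(p[[f]][ci], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        p[[f]][pi] <- NA_real_
        dropped <- c(dropped, f)
      } else {
        p[[f]][pi] <- (p[[f]][pi] - m) / s
      }
    }
    if (length(dropped))
      warning("plate ", pl, ": zero control sd; values set missing for: ",
              paste(dropped, collapse = ", "))
  }
  p
}
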