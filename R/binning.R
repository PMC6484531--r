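#' Quantile bin edges from the pooled per-plate control population
#'
#' For k bins, the interior cutoffs are the i*(100/k)-th percentiles
#' (i = 1..k-1) of the pooled control cell values of the plate — for the
#' default k = 5, the 20th/40th/60th/80th percentiles, creating five bins
#' that each hold approximately 20% of the control population. Duplicated
#' cutoffs arise for discrete or near-constant parameters (e.g. a nuclei
#' count that is almost always 1) and mark zero-width bins. A bin is
#' *instantiated* when at least one pooled control cell falls into it; for a
#' constant parameter only a single bin is instantiated.
#'
#' @param x a [cell_table()].
#' @param k number of bins (>= 2).
#' @param type quantile type for [stats::quantile()] (default 7).
#' @return an object of class `bin_edges`: arrays `edges`
#'   (plate x parameter x k-1) and `instantiated` (plate x parameter x k),
#'   plus `k`, `control`, `plates`, `parameters`.
#' @export
compute_bin_edges <- function(x, k = 5, type = 7) {
  stopifnot(inherits(x, "cell_table"), k >= 2)
  feats <- attr(x, "features")
  ctl <- attr(x, "control")
  plates <- unique(x$plate)
  probs <- seq_len(k - 1) / k
  edges <- array(NA_real_, dim = c(length(plates), length(feats), k - 1),
                 dimnames = list(plates, feats, NULL))
  inst <- array(FALSE, dim = c(length(plates), length(feats), k),
                dimnames = list(plates, feats, NULL))
  skipped <- character()
  for (p in plates) {
    ci <- x$plate == p & x$treatment == ctl
    for (f in feats) {
      v <- x[[f]][ci]
      v <- v[!is.na(v)]
      if (!length(v)) {
        skipped <- c(skipped, paste0(p, "/", f))
        next
      }
      e <- stats::quantile(v, probs, names = FALSE, type = type)
      edges[p, f, ] <- e
      b <- findInterval(v, e) + 1L
      inst[p, f, ] <- tabulate(b, nbins = k) > 0L
    }
  }
  if (length(skipped))
    warning("no control values; (plate, parameter) omitted: ",
            paste(skipped, collapse = ", "))
  structure(list(edges = edges, instantiated = inst, k = k, control = ctl,
                 plates = plates, parameters = feats, type = type),
            class = "bin_edges")
}

#' Assign cell values to quantile bins and count them
#'
#' Bins are half-open intervals `[e_(i-1), e_i)` with the last bin closed
#' above at +Inf; a value exactly on a cutoff goes to the upper bin.
#' Zero-width bins (duplicated cutoffs) therefore receive no cells. Missing
#' values are skipped; their number is attached as attribute `"missing"`.
#'
#' @param values numeric vector of per-cell values.
#' @param edges ascending interior cutoffs (length k - 1) for one plate and
#'   parameter.
#' @return integer vector of k per-bin counts, attribute `missing`.
#' @export
assign_bins <- function(values, edges) {
  if (is.unsorted(edges)) stop("edges must be nondecreasing")
  k <- length(edges) + 1L
  ok <- !is.na(values)
  b <- findInterval(values[ok], edges) + 1L
  structure(tabulate(b, nbins = k), missing = sum(!ok))
}

#' Bin every well against the pooled plate control distribution
#'
#' The central fitting function of the subpopulation analysis. Per plate and
#' parameter, quantile cutoffs are determined from the pooled control cells
#' ([compute_bin_edges()]); every well's cells are counted into the bins
#' ([assign_bins()]); counts are converted to percentages of the well's
#' non-missing cells; and each (parameter, bin) percentage is standardized
#' into a z-score against the mean and sample sd of the plate's control well
#' percentages. Bins whose control sd is zero (including bins never
#' instantiated by the pooled controls) yield missing z-scores, later
#' removed by the missing-column filter of [assemble_fingerprints()].
#'
#' Because the edges are quantiles of the same plate's data, the whole
#' analysis is invariant under any strictly increasing per-plate transform
#' of a parameter, and no prior normalization of the cell data is required.
#'
#' @param x a [cell_table()].
#' @param k number of bins.
#' @param type quantile type for the cutoffs.
#' @return an object of class `bin_profile` with elements
#'   \describe{
#'     \item{wells}{data frame of well metadata (plate, well, treatment,
#'       optional moa/concentration, n_cells), rownames `plate:well`.}
#'     \item{counts, percent, z}{arrays well x parameter x bin.}
#'     \item{baseline}{list of `mean` and `sd` arrays
#'       (plate x parameter x bin) over control wells.}
#'     \item{edges}{the [compute_bin_edges()] result.}
#'   }
#' @seealso [stability()], [assemble_fingerprints()], [dmso_baseline()],
#'   [bin_z_scores()]
#' @export
bin_profile <- function(x, k = 5, type = 7) {
  stopifnot(inherits(x, "cell_table"))
  be <- compute_bin_edges(x, k = k, type = type)
  feats <- be$parameters
  plates <- be$plates
  ctl <- be$control

  key <- well_key(x)
  first <- !duplicated(key)
  meta_cols <- intersect(c("plate", "well", "treatment", "moa",
                           "concentration"), names(x))
  wells <- as.data.frame(x)[first, meta_cols, drop = FALSE]
  ukey <- key[first]
  rownames(wells) <- ukey
  wells$n_cells <- as.integer(table(key)[ukey])
  nw <- nrow(wells)

  counts <- array(0L, dim = c(nw, length(feats), k),
                  dimnames = list(ukey, feats, NULL))
  for (p in plates) {
    pi <- which(x$plate == p)
    pkeys <- ukey[wells$plate == p]
    nwp <- length(pkeys)
    wi <- match(key[pi], pkeys)
    for (f in feats) {
      e <- be$edges[p, f, ]
      if (anyNA(e)) next
      v <- x[[f]][pi]
      ok <- !is.na(v)
      b <- findInterval(v[ok], e) + 1L
      cnt <- tabulate(wi[ok] + (b - 1L) * nwp, nbins = nwp * k)
      counts[pkeys, f, ] <- matrix(cnt, nwp, k)
    }
  }

  ntot <- apply(counts, c(1, 2), sum)            # non-missing cells per well/param
  den <- array(ntot, dim = dim(counts))          # recycle over the bin dim
  den[den == 0] <- NA_real_
  percent <- counts / den * 100

  bmean <- array(NA_real_, dim = c(length(plates), length(feats), k),
                 dimnames = list(plates, feats, NULL))
  bsd <- bmean
  z <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  for (p in plates) {
    wp <- which(wells$plate == p)
    cw <- wp[wells$treatment[wp] == ctl]
    if (length(cw) < 2)
      stop("plate ", p, " has fewer than 2 '", ctl, "' wells")
    pc <- percent[cw, , , drop = FALSE]
    bmean[p, , ] <- apply(pc, c(2, 3), mean)
    bsd[p, , ] <- apply(pc, c(2, 3), stats::sd)
    s <- bsd[p, , ]
    s[s == 0] <- NA_real_
    for (w in wp)
      z[w, , ] <- (percent[w, , ] - bmean[p, , ]) / s
  }

  structure(list(wells = wells, counts = counts, percent = percent, z = z,
                 baseline = list(mean = bmean, sd = bsd),
                 edges = be, k = k, control = ctl),
            class = "bin_profile")
}

#' Control baseline of bin occupancies
#'
#' Mean and sample standard deviation of the per-bin percentages across a
#' plate's control wells — the reference against which every well's bin
#' occupancy is z-scored. For a 5-bin analysis the means are close to 20
#' when the pooled population and the wells are exchangeable; a zero sd
#' flags a degenerate bin.
#'
#' @param bp a [bin_profile()].
#' @return long data frame: plate, parameter, bin, mean_percent, sd_percent,
#'   instantiated.
#' @export
dmso_baseline <- function(bp) {
  stopifnot(inherits(bp, "bin_profile"))
  be <- bp$edges
  out <- expand.grid(bin = seq_len(bp$k), parameter = be$parameters,
                     plate = be$plates, stringsAsFactors = FALSE)
  out <- out[c("plate", "parameter", "bin")]
  idx <- cbind(match(out$plate, be$plates),
               match(out$parameter, be$parameters), out$bin)
  out$mean_percent <- bp$baseline$mean[idx]
  out$sd_percent <- bp$baseline$sd[idx]
  out$instantiated <- be$instantiated[idx]
  out
}

#' Per-well bin z-scores in long format
#'
#' @param bp a [bin_profile()].
#' @return long data frame: plate, well, treatment, parameter, bin, count,
#'   percent, z.
#' @export
bin_z_scores <- function(bp) {
  stopifnot(inherits(bp, "bin_profile"))
  as.data.frame(bp)
}

#' @export
as.data.frame.bin_profile <- function(x, ...) {
  w <- x$wells
  feats <- x$edges$parameters
  nw <- nrow(w)
  nf <- length(feats)
  k <- x$k
  out <- data.frame(
    plate = rep(w$plate, times = nf * k),
    well = rep(w$well, times = nf * k),
    treatment = rep(w$treatment, times = nf * k),
    parameter = rep(rep(feats, each = nw), times = k),
    bin = rep(seq_len(k), each = nw * nf),
    count = as.integer(x$counts),
    percent = as.numeric(x$percent),
    z = as.numeric(x$z),
    stringsAsFactors = FALSE)
  out[order(out$plate, out$well, out$parameter, out$bin), , drop = FALSE]
}

#' @export
print.bin_profile <- function(x, ...) {
  inst <- apply(x$edges$instantiated, 2, function(m) sum(m) / nrow(x$edges$instantiated))
  cat(sprintf("<bin_profile> k = %d bins, %d wells, %d parameters, %d plate(s)\n",
              x$k, nrow(x$wells), length(x$edges$parameters),
              length(x$edges$plates)))
  cat(sprintf("  control '%s' wells: %d\n", x$control,
              sum(x$wells$treatment == x$control)))
  cat(sprintf("  fully instantiated parameters: %d of %d\n",
              sum(inst == x$k), length(inst)))
  invisible(x)
}

#' Compare a well's bin occupancy with the control baseline
#'
#' Draws side-by-side bars of the per-bin percentages of one well against
#' the control baseline (mean +/- sd) for one parameter — the standard
#' picture of a subpopulation shift, where a unimodal-to-bimodal change
#' fills the extreme bins at the expense of the middle ones.
#'
#' @param x a [bin_profile()].
#' @param parameter parameter name.
#' @param well well identifier `"plate:well"` (a rowname of `x$wells`).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bin_profile <- function(x, parameter, well, ...) {
  stopifnot(parameter %in% x$edges$parameters, well %in% rownames(x$wells))
  p <- x$wells[well, "plate"]
  base <- x$baseline$mean[p, parameter, ]
  sds <- x$baseline$sd[p, parameter, ]
  obs <- x$percent[well, parameter, ]
  m <- rbind(control = base, well = obs)
  bx <- graphics::barplot(m, beside = TRUE, names.arg = seq_len(x$k),
                          xlab = "bin", ylab = "% of cells",
                          legend.text = c(paste0(x$control, " baseline"), well),
                          main = parameter, ...)
  graphics::arrows(bx[1, ], base - sds, bx[1, ], base + sds,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}
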