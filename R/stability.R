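#' Multinomial goodness-of-fit chi-square test for bin counts
#'
#' The cells of a well fall into the k quantile bins like draws from an urn
#' with replacement, so the per-bin counts follow a multinomial
#' distribution. The test compares observed counts with expected counts
#' `E_i = n * p_i` via `chi2 = sum((O_i - E_i)^2 / E_i)` on
#' `df = length(observed) - 1` degrees of freedom, with the upper-tail
#' chi-square probability as p-value. By default the expected proportions
#' are uniform — each bin should hold 1/k of the well — restricted to the
#' bins actually passed in (callers supply only instantiated bins for
#' discrete parameters).
#'
#' @param observed nonnegative integer counts per bin (length >= 2).
#' @param expected expected proportions, positive, summing to 1; default
#'   uniform over the supplied bins.
#' @return list with `chi2`, `df`, `p`.
#' @export
multinomial_chisq <- function(observed, expected = NULL) {
  if (any(observed < 0)) stop("negative counts")
  n <- sum(observed)
  if (n == 0) stop("all counts zero")
  if (length(observed) < 2)
    stop("test undefined for a single bin")
  if (is.null(expected)) {
    expected <- rep(1 / length(observed), length(observed))
  } else {
    if (length(expected) != length(observed))
      stop("observed and expected lengths differ")
    if (any(expected <= 0)) stop("expected proportions must be positive")
    expected <- expected / sum(expected)
  }
  E <- n * expected
  chi2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Bonferroni multiple-testing adjustment
#'
#' `p_adj = min(1, p * family_size)`, elementwise. The family size may
#' exceed the number of p-values supplied (e.g. when untestable cases are
#' still counted in the family).
#'
#' @param p numeric vector of p-values.
#' @param family_size number of tests in the family (>= `length(p)`).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, family_size = length(p)) {
  if (family_size < 1) stop("family_size must be >= 1")
  if (family_size < length(p))
    stop("family_size smaller than the number of p-values")
  pmin(1, p * family_size)
}

#' Stable-parameter analysis of negative-control wells
#'
#' For every control well and every testable parameter, the observed bin
#' counts are tested against the equal-occupancy multinomial expectation
#' with [multinomial_chisq()], restricted to the plate's instantiated bins
#' (renormalized uniform expectation), and Bonferroni-adjusted within the
#' plate's family of (well x parameter) tests. A parameter is then scored
#' by the fraction of tested control wells whose adjusted p-value exceeds
#' the cutoff — i.e. wells consistent with the expected distribution.
#' Parameters where nearly all wells agree are *stable*; parameters whose
#' wells frequently deviate (well-to-well distributional drift) are
#' *noisy*.
#'
#' Only control wells enter, so the selection is blind to treatment labels:
#' removing or relabeling any treated class leaves the result identical.
#' Parameters with fewer than 2 instantiated bins on a plate are untestable
#' there and excluded; wells with fewer than `min_cells` cells are excluded
#' from the denominator.
#'
#' @param bp a [bin_profile()].
#' @param cutoff significance cutoff on the adjusted p-value (default 0.05).
#' @param min_cells minimum non-missing cells for a well to be tested.
#' @param family scope of the Bonferroni family: `"plate"` (all tests
#'   computed within the plate, the default) or `"none"` (no adjustment).
#' @return an object of class `stability_report`: `$tests` (one row per
#'   well x parameter test: plate, well, parameter, n, chi2, df, p, p_adj)
#'   and `$report` (per parameter: wells_tested, wells_passing,
#'   fraction_passing, untestable flag).
#' @seealso [stability_ladder()], [select_best_threshold()]
#' @export
stability <- function(bp, cutoff = 0.05, min_cells = 50,
                      family = c("plate", "none")) {
  stopifnot(inherits(bp, "bin_profile"))
  family <- match.arg(family)
  be <- bp$edges
  ctl <- bp$control
  rows <- list()
  for (p in be$plates) {
    wp <- which(bp$wells$plate == p & bp$wells$treatment == ctl)
    for (f in be$parameters) {
      inst <- which(be$instantiated[p, f, ])
      if (length(inst) < 2) next
      for (w in wp) {
        obs <- bp$counts[w, f, inst]
        n <- sum(bp$counts[w, f, ])
        if (n < min_cells) next
        E <- n / length(inst)
        chi2 <- sum((obs - E)^2 / E)
        rows[[length(rows) + 1L]] <- data.frame(
          plate = p, well = bp$wells$well[w], parameter = f,
          n = n, chi2 = chi2, df = length(inst) - 1L,
          p = stats::pchisq(chi2, length(inst) - 1L, lower.tail = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no testable (well, parameter) combinations")
  tests <- do.call(rbind, rows)
  if (family == "plate") {
    fam <- table(tests$plate)
    tests$p_adj <- pmin(1, tests$p * as.numeric(fam[tests$plate]))
  } else {
    tests$p_adj <- tests$p
  }
  report <- stability_fractions(tests, cutoff = cutoff,
                                parameters = be$parameters)
  structure(list(tests = tests, report = report, cutoff = cutoff,
                 min_cells = min_cells, family = family, control = ctl),
            class = "stability_report")
}

#' Per-parameter stability fractions
#'
#' Aggregates a table of per-well chi-square tests into the fraction of
#' control wells per parameter whose adjusted p-value exceeds the cutoff.
#' Parameters with zero testable wells are reported with
#' `wells_tested = 0` and flagged `untestable`.
#'
#' @param tests data frame with columns `parameter` and `p_adj`
#'   (e.g. `stability(...)$tests`).
#' @param cutoff cutoff on the adjusted p-value.
#' @param parameters optional full parameter set, so untestable parameters
#'   appear in the report.
#' @return data frame: parameter, wells_tested, wells_passing,
#'   fraction_passing, untestable.
#' @export
stability_fractions <- function(tests, cutoff = 0.05, parameters = NULL) {
  stopifnot(all(c("parameter", "p_adj") %in% names(tests)))
  if (is.null(parameters)) parameters <- unique(tests$parameter)
  tested <- table(factor(tests$parameter, levels = parameters))
  passing <- table(factor(tests$parameter[tests$p_adj > cutoff],
                          levels = parameters))
  out <- data.frame(parameter = parameters,
                    wells_tested = as.integer(tested),
                    wells_passing = as.integer(passing),
                    stringsAsFactors = FALSE)
  out$fraction_passing <- ifelse(out$wells_tested > 0,
                                 out$wells_passing / out$wells_tested,
                                 NA_real_)
  out$untestable <- out$wells_tested == 0L
  rownames(out) <- NULL
  out
}

#' Stability-threshold fingerprint ladder
#'
#' Builds the nested family of parameter sets obtained by removing noisy
#' parameters stepwise: at threshold t, a parameter is retained when at
#' least a fraction t of its tested control wells passed the stability
#' test. The default thresholds run from 0.01 to 0.96 in steps of 0.05 —
#' 20 values, hence 20 nested fingerprints, each a subset of the previous.
#' Untestable parameters are treated as unstable and never retained.
#'
#' @param x a `stability_report` (from [stability()]) or its `$report`
#'   data frame.
#' @param thresholds ascending retention thresholds.
#' @return object of class `stability_ladder`: `$thresholds` and
#'   `$retained` (list of parameter character vectors).
#' @export
stability_ladder <- function(x, thresholds = seq(0.01, 0.96, by = 0.05)) {
  rep <- if (inherits(x, "stability_report")) x$report else x
  stopifnot(is.data.frame(rep), nrow(rep) > 0)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  rep <- rep[!rep$untestable, , drop = FALSE]
  retained <- lapply(thresholds, function(t)
    rep$parameter[rep$fraction_passing >= t])
  structure(list(thresholds = thresholds, retained = retained),
            class = "stability_ladder")
}

#' Pick the stability threshold with the best leave-one-out accuracy
#'
#' Runs the classification task ([nn_loo_classify()]) once per ladder rung
#' on the fingerprint restricted to the retained parameters and returns the
#' threshold with the highest accuracy; ties are broken toward the larger
#' threshold, i.e. the sparser fingerprint. Rungs with an empty retained
#' set, or whose fingerprint loses every column to the missing-value
#' filter, are skipped.
#'
#' @param ladder a [stability_ladder()].
#' @param source profile source passed to [assemble_fingerprints()]
#'   (a [bin_profile()] for the bin modes, [well_average()] output for
#'   `well_average`).
#' @param mode fingerprint mode, see [assemble_fingerprints()].
#' @param exclude leave-one-out exclusion policy, see [nn_loo_classify()].
#' @param replicate_median collapse replicates with [median_replicates()]
#'   before classification.
#' @return list of class `threshold_selection`: `threshold`, `accuracy`,
#'   and a per-rung `details` data frame.
#' @export
select_best_threshold <- function(ladder, source, mode = "all_bins",
                                  exclude = "same_treatment",
                                  replicate_median = FALSE) {
  stopifnot(inherits(ladder, "stability_ladder"))
  nt <- length(ladder$thresholds)
  acc <- rep(NA_real_, nt)
  nfeat <- integer(nt)
  for (i in seq_len(nt)) {
    params <- ladder$retained[[i]]
    nfeat[i] <- length(params)
    if (!length(params)) next
    fm <- tryCatch(
      suppressMessages(assemble_fingerprints(source, mode = mode,
                                             parameters = params)),
      error = function(e) NULL)
    if (is.null(fm)) next
    if (replicate_median) fm <- median_replicates(fm)
    rep <- tryCatch(suppressMessages(nn_loo_classify(fm, exclude = exclude)),
                    error = function(e) NULL)
    if (is.null(rep)) next
    acc[i] <- rep$accuracy
  }
  if (all(is.na(acc))) stop("no usable threshold in the ladder")
  best <- max(which(acc == max(acc, na.rm = TRUE)))  # ties -> larger threshold
  structure(list(threshold = ladder$thresholds[best],
                 accuracy = acc[best],
                 retained = ladder$retained[[best]],
                 details = data.frame(threshold = ladder$thresholds,
                                      n_parameters = nfeat,
                                      accuracy = acc)),
            class = "threshold_selection")
}

#' @export
print.stability_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<stability_report> %d parameters, %d well-level tests, cutoff %.3g\n",
              nrow(r), nrow(x$tests), x$cutoff))
  ok <- !r$untestable
  cat(sprintf("  untestable: %d | fraction_passing median %.2f [%.2f, %.2f]\n",
              sum(!ok), stats::median(r$fraction_passing[ok]),
              min(r$fraction_passing[ok]), max(r$fraction_passing[ok])))
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  r <- object$report[!object$report$untestable, ]
  r[order(r$fraction_passing), ]
}

#' @export
plot.stability_report <- function(x, breaks = 20, ...) {
  r <- x$report[!x$report$untestable, ]
  graphics::hist(r$fraction_passing, breaks = breaks,
                 xlab = "fraction of control wells passing",
                 main = "Parameter stability", ...)
  invisible(x)
}

#' @export
print.stability_ladder <- function(x, ...) {
  cat(sprintf("<stability_ladder> %d thresholds (%.2f .. %.2f)\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds)))
  sizes <- vapply(x$retained, length, integer(1))
  cat("  retained sizes: ", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold_selection> threshold %.2f, accuracy %.3f, %d parameters\n",
              x$threshold, x$accuracy, length(x$retained)))
  invisible(x)
}
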