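#' Assemble a fingerprint matrix from well averages or binned profiles
#'
#' Builds the profiles-by-features matrix used for cosine-distance
#' classification:
#' \describe{
#'   \item{`well_average`}{one feature per parameter, taken from a
#'     [well_average()] (optionally [zscore_well_averages()]-normalized)
#'     profile table.}
#'   \item{`all_bins`}{one feature per (parameter, bin) z-score from a
#'     [bin_profile()], named `<parameter>__bin<i>__z`.}
#'   \item{`extreme_bins`}{only the lowest and highest bins (the 20% and
#'     100% bins for k = 5) — the bins most sensitive to phenotype shifts,
#'     since parameters move either down or up.}
#' }
#' An optional parameter filter (a stability-retained set, or any subset)
#' restricts the columns first. Columns containing any missing value —
#' uninstantiated bins, degenerate baselines, plate-dropped parameters —
#' are then removed (with a message), because the cosine distance requires
#' complete vectors.
#'
#' @param x a [bin_profile()] (bin modes) or `well_profiles` data frame
#'   (`well_average` mode).
#' @param mode `"well_average"`, `"all_bins"` or `"extreme_bins"`.
#' @param parameters optional character vector restricting the parameters.
#' @param drop_unlabelled drop profiles without an MoA annotation (control
#'   wells stay out of the classification task by default).
#' @return object of class `fingerprint_matrix`: `$values` (numeric matrix,
#'   rownames are profile ids), `$meta` (id, plate, well, treatment, moa,
#'   optional concentration), `$mode`, `$filter`.
#' @export
assemble_fingerprints <- function(x, mode = c("all_bins", "extreme_bins",
                                              "well_average"),
                                  parameters = NULL,
                                  drop_unlabelled = FALSE) {
  mode <- match.arg(mode)
  if (mode == "well_average") {
    stopifnot(inherits(x, "well_profiles"))
    feats <- attr(x, "features")
    if (!is.null(parameters)) {
      miss <- setdiff(parameters, feats)
      if (length(miss))
        stop("unknown parameter(s): ", paste(miss, collapse = ", "))
      feats <- intersect(feats, parameters)
    }
    values <- as.matrix(as.data.frame(x)[feats])
    meta <- data.frame(id = paste(x$plate, x$well, sep = ":"),
                       x[intersect(c("plate", "well", "treatment", "moa",
                                     "concentration"), names(x))],
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(x, "bin_profile"))
    feats <- x$edges$parameters
    if (!is.null(parameters)) {
      miss <- setdiff(parameters, feats)
      if (length(miss))
        stop("unknown parameter(s): ", paste(miss, collapse = ", "))
      feats <- intersect(feats, parameters)
    }
    bins <- if (mode == "extreme_bins") c(1L, x$k) else seq_len(x$k)
    zz <- x$z[, feats, bins, drop = FALSE]
    zz <- aperm(zz, c(1, 3, 2))                  # well, bin, parameter
    values <- matrix(zz, nrow = nrow(x$wells),
                     ncol = length(bins) * length(feats))
    colnames(values) <- sprintf("%s__bin%d__z",
                                rep(feats, each = length(bins)),
                                rep(bins, times = length(feats)))
    w <- x$wells
    meta <- data.frame(id = rownames(w),
                       w[intersect(c("plate", "well", "treatment", "moa",
                                     "concentration"), names(w))],
                       stringsAsFactors = FALSE)
  }
  rownames(meta) <- NULL
  if (drop_unlabelled && "moa" %in% names(meta)) {
    keep <- !is.na(meta$moa)
    values <- values[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  bad <- colSums(is.na(values)) > 0
  if (any(bad))
    message("dropping ", sum(bad), " column(s) with missing values")
  values <- values[, !bad, drop = FALSE]
  if (!ncol(values))
    stop("no columns left after removing missing-value columns")
  rownames(values) <- meta$id
  structure(list(values = values, meta = meta, mode = mode,
                 filter = if (!is.null(parameters)) parameters),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d profiles x %d features (mode %s%s)\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (!is.null(x$filter)) ", filtered" else ""))
  if ("moa" %in% names(x$meta))
    cat(sprintf("  labelled profiles: %d in %d class(es)\n",
                sum(!is.na(x$meta$moa)),
                length(unique(stats::na.omit(x$meta$moa)))))
  invisible(x)
}

#' Componentwise median over replicate profiles
#'
#' Collapses replicate rows of a fingerprint matrix to one profile per
#' group — by default per (treatment, concentration) — taking the
#' componentwise median (even replicate counts average the two middle
#' values). The MoA label must agree within a group and is carried through.
#'
#' @param fm a `fingerprint_matrix`.
#' @param by grouping columns present in `fm$meta`.
#' @return a `fingerprint_matrix` with one row per replicate group; ids are
#'   the group keys.
#' @export
median_replicates <- function(fm, by = c("treatment", "concentration")) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  by <- intersect(by, names(fm$meta))
  if (!length(by)) stop("no grouping columns found in the profile metadata")
  key <- do.call(paste, c(fm$meta[by], sep = "|"))
  if ("moa" %in% names(fm$meta)) {
    n_moa <- vapply(split(fm$meta$moa, key),
                    function(v) length(unique(v)), integer(1))
    if (any(n_moa > 1))
      stop("conflicting MoA labels within replicate group(s): ",
           paste(names(n_moa)[n_moa > 1], collapse = ", "))
  }
  groups <- split(seq_len(nrow(fm$values)), key)
  med <- t(vapply(groups, function(i)
    apply(fm$values[i, , drop = FALSE], 2, stats::median, na.rm = TRUE),
    numeric(ncol(fm$values))))
  colnames(med) <- colnames(fm$values)
  firsts <- vapply(groups, `[`, integer(1), 1L)
  meta <- fm$meta[firsts, intersect(c(by, "moa"), names(fm$meta)),
                  drop = FALSE]
  meta <- data.frame(id = names(groups), meta, row.names = NULL,
                     stringsAsFactors = FALSE)
  meta$n_replicates <- lengths(groups)
  rownames(med) <- meta$id
  structure(list(values = med, meta = meta, mode = fm$mode,
                 filter = fm$filter),
            class = "fingerprint_matrix")
}

#' Cosine distance between two feature vectors
#'
#' `1 - (u . v) / (|u| |v|)`, in \[0, 2\]: 0 for parallel, 1 for
#' orthogonal, 2 for antiparallel vectors. Invariant to positive rescaling
#' of either argument. A zero vector has no direction and is an error.
#'
#' @param u,v numeric vectors of equal length.
#' @return the cosine distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero vector")
  1 - sum(u * v) / (nu * nv)
}

#' All-pairs cosine distance matrix of a fingerprint matrix
#'
#' @param fm a `fingerprint_matrix` or a plain numeric matrix (rows are
#'   profiles).
#' @return symmetric distance matrix with zero diagonal.
#' @export
cosine_distances <- function(fm) {
  M <- if (inherits(fm, "fingerprint_matrix")) fm$values else fm
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0))
    stop("zero-vector profile(s): ",
         paste(rownames(M)[nrm == 0], collapse = ", "))
  D <- 1 - tcrossprod(M / nrm)
  D[D < 0] <- 0
  D[D > 2] <- 2
  diag(D) <- 0
  D
}

#' Leave-one-out nearest-neighbor mode-of-action classification
#'
#' Each profile is classified with the MoA label of its nearest neighbor
#' by cosine distance among the candidate profiles. The default exclusion
#' policy removes all profiles of the query's own treatment (the
#' not-same-compound protocol, so replicates of the same compound cannot
#' vote for themselves); `"self"` excludes only the query profile. Exact
#' distance ties are broken deterministically by the lexicographically
#' smaller candidate id. Profiles without any candidate are reported as
#' unclassifiable and excluded from the accuracy denominator. Unlabelled
#' profiles (missing MoA, e.g. control wells) are dropped with a message.
#'
#' @param fm a `fingerprint_matrix` whose metadata carries `moa`.
#' @param exclude `"same_treatment"` or `"self"`.
#' @return object of class `moa_classification`: `$results` (per profile:
#'   id, treatment, actual, nn_id, nn_distance, predicted, correct),
#'   `$n_profiles`, `$n_classified`, `$n_correct`, `$accuracy`,
#'   `$confusion`.
#' @export
nn_loo_classify <- function(fm, exclude = c("same_treatment", "self")) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  exclude <- match.arg(exclude)
  if (!"moa" %in% names(fm$meta))
    stop("profiles carry no MoA annotation")
  keep <- !is.na(fm$meta$moa)
  if (any(!keep))
    message("dropping ", sum(!keep), " unlabelled profile(s)")
  meta <- fm$meta[keep, , drop = FALSE]
  M <- fm$values[keep, , drop = FALSE]
  n <- nrow(M)
  if (n < 2) stop("need at least 2 labelled profiles")
  if (length(unique(meta$moa)) < 2)
    stop("need at least 2 distinct MoA classes")
  D <- cosine_distances(M)
  ids <- meta$id
  res <- data.frame(id = ids, treatment = meta$treatment, actual = meta$moa,
                    nn_id = NA_character_, nn_distance = NA_real_,
                    predicted = NA_character_, correct = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    if (exclude == "same_treatment")
      cand <- cand[meta$treatment[cand] != meta$treatment[i]]
    if (!length(cand)) next                       # unclassifiable
    j <- cand[order(D[i, cand], ids[cand])][1]
    res$nn_id[i] <- ids[j]
    res$nn_distance[i] <- D[i, j]
    res$predicted[i] <- meta$moa[j]
    res$correct[i] <- meta$moa[j] == meta$moa[i]
  }
  classified <- !is.na(res$predicted)
  n_correct <- sum(res$correct[classified])
  conf <- table(actual = res$actual[classified],
                predicted = res$predicted[classified])
  structure(list(results = res, n_profiles = n,
                 n_classified = sum(classified), n_correct = n_correct,
                 accuracy = n_correct / sum(classified),
                 confusion = conf, exclude = exclude),
            class = "moa_classification")
}

#' @export
print.moa_classification <- function(x, ...) {
  cat(sprintf("<moa_classification> %d/%d correct (%.1f%%), %d profiles, exclusion: %s\n",
              x$n_correct, x$n_classified, 100 * x$accuracy,
              x$n_profiles, x$exclude))
  if (x$n_classified < x$n_profiles)
    cat("  unclassifiable profiles:", x$n_profiles - x$n_classified, "\n")
  invisible(x)
}

#' @export
summary.moa_classification <- function(object, ...) {
  object$confusion
}

#' Held-out-class generalization experiment
#'
#' Measures how well a feature-selection method generalizes to a mode of
#' action it has never seen. Parameter selection — the stability ladder
#' with its best threshold, or the L1 scan with its best alpha — is
#' performed with every profile of the held-out class removed; the selected
#' feature set is then applied to the full profile set, the held-out class
#' restored, and the leave-one-out classification rerun. Because the
#' stability selection uses control wells only, its held-in selection is
#' identical to the full-data selection; the L1 selection, trained on the
#' remaining labels, may discard features that were informative only for
#' the held-out class.
#'
#' @param x a [cell_table()].
#' @param holdout MoA label to hold out of the selection step.
#' @param method `"stability"` or `"l1"`.
#' @param mode fingerprint mode (see [assemble_fingerprints()]).
#' @param k number of bins.
#' @param cutoff,min_cells stability-test settings (see [stability()]).
#' @param thresholds ladder thresholds (see [stability_ladder()]).
#' @param alphas L1 penalty ladder (see [l1_scan()]).
#' @param exclude leave-one-out exclusion policy.
#' @return object of class `holdout_experiment`: the selection object, the
#'   selected `features`, the full-data `report` ([nn_loo_classify()]),
#'   `holdout_n` and `holdout_misclassified` (held-out profiles not
#'   correctly classified, unclassifiable ones included).
#' @export
holdout_class_experiment <- function(x, holdout,
                                     method = c("stability", "l1"),
                                     mode = "extreme_bins", k = 5,
                                     cutoff = 0.05, min_cells = 50,
                                     thresholds = seq(0.01, 0.96, by = 0.05),
                                     alphas = c(0.01, 0.05, 0.1, 0.5, 1, 2,
                                                4, 6, 8, 10),
                                     exclude = "same_treatment") {
  stopifnot(inherits(x, "cell_table"))
  method <- match.arg(method)
  if (!"moa" %in% names(x)) stop("cell table carries no MoA annotation")
  if (!holdout %in% x$moa) stop("holdout class not found: ", holdout)
  in_rows <- is.na(x$moa) | x$moa != holdout
  held_in <- subset_cells(x, in_rows)
  if (length(unique(stats::na.omit(held_in$moa))) < 2)
    stop("fewer than 2 classes remain after holding out ", holdout)

  bp_full <- bin_profile(x, k = k)
  bp_in <- bin_profile(held_in, k = k)

  if (method == "stability") {
    st <- stability(bp_in, cutoff = cutoff, min_cells = min_cells)
    lad <- stability_ladder(st, thresholds = thresholds)
    sel <- select_best_threshold(lad, bp_in, mode = mode, exclude = exclude)
    fm_full <- suppressMessages(
      assemble_fingerprints(bp_full, mode = mode,
                            parameters = sel$retained))
  } else {
    fm_in <- suppressMessages(assemble_fingerprints(bp_in, mode = mode))
    scan <- l1_scan(fm_in, alphas = alphas)
    sel <- best_alpha(scan, fm_in, exclude = exclude)
    fm_full <- suppressMessages(assemble_fingerprints(bp_full, mode = mode))
    cols <- intersect(sel$retained, colnames(fm_full$values))
    if (!length(cols)) stop("selection yields an empty feature set")
    fm_full$values <- fm_full$values[, cols, drop = FALSE]
    fm_full$filter <- cols
  }
  report <- suppressMessages(nn_loo_classify(fm_full, exclude = exclude))
  hr <- report$results[report$results$actual == holdout, , drop = FALSE]
  mis <- sum(is.na(hr$correct) | !hr$correct)
  structure(list(method = method, holdout = holdout, selection = sel,
                 features = colnames(fm_full$values), report = report,
                 holdout_n = nrow(hr), holdout_misclassified = mis),
            class = "holdout_experiment")
}

#' @export
print.holdout_experiment <- function(x, ...) {
  cat(sprintf("<holdout_experiment> method %s, held-out class '%s'\n",
              x$method, x$holdout))
  cat(sprintf("  features selected: %d | overall accuracy %.3f\n",
              length(x$features), x$report$accuracy))
  cat(sprintf("  held-out profiles misclassified: %d of %d\n",
              x$holdout_misclassified, x$holdout_n))
  invisible(x)
}
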