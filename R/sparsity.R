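#' L1-penalized multinomial logistic scan over a penalty ladder
#'
#' The supervised feature-selection baseline: for each penalty strength
#' alpha, an L1-penalized logistic regression of the MoA labels on the
#' (standardized) profile features is fitted, and the features with any
#' nonzero coefficient across classes form the retained set. Alpha
#' multiplies the L1 term of the per-sample-averaged loss (so larger alpha
#' means stronger shrinkage; the inverse-regularization convention of
#' common solvers is `C = 1/alpha`). Features are centred and scaled to
#' unit sd before fitting; intercepts are unpenalized. Zero-variance
#' columns cannot be standardized and are dropped with a warning. The
#' default ladder spans 0.01 to 10 in 10 steps; on standardized features
#' the largest alphas typically shrink every coefficient to zero, and such
#' rungs are skipped downstream with a warning.
#'
#' Fitting is delegated to \pkg{glmnet} (`lambda = alpha`), one-vs-rest by
#' default with a symmetric multinomial (softmax) option.
#'
#' @param fm a `fingerprint_matrix` with MoA labels (>= 2 classes).
#' @param alphas penalty strengths.
#' @param scheme `"ovr"` (one binomial fit per class) or `"multinomial"`.
#' @param zero_tol coefficients with absolute value below this (on the
#'   standardized scale) count as zero.
#' @param thresh,maxit convergence tolerance and iteration cap for glmnet.
#' @return object of class `l1_scan`: a list with one element per alpha in
#'   the given order, each holding `alpha`, `retained` (feature names) and
#'   `coefficients` (classes x features).
#' @export
l1_scan <- function(fm, alphas = c(0.01, 0.05, 0.1, 0.5, 1, 2, 4, 6, 8, 10),
                    scheme = c("ovr", "multinomial"),
                    zero_tol = 1e-8, thresh = 1e-9, maxit = 1e5) {
  stopifnot(inherits(fm, "fingerprint_matrix"), length(alphas) >= 1)
  if (any(alphas <= 0)) stop("alphas must be positive")
  scheme <- match.arg(scheme)
  if (!"moa" %in% names(fm$meta))
    stop("profiles carry no MoA annotation")
  keep <- !is.na(fm$meta$moa)
  y <- fm$meta$moa[keep]
  X <- fm$values[keep, , drop = FALSE]
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  bad <- colnames(X)[colSums(!is.finite(X)) > 0]
  if (length(bad))
    stop("non-finite feature column(s): ", paste(bad, collapse = ", "))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xs <- scale(X)
  lam <- sort(unique(alphas), decreasing = TRUE)
  # glmnet dislikes a single-value lambda path; pad and index into it
  lam_fit <- if (length(lam) == 1) c(lam * 10, lam) else lam
  jmap <- match(lam, lam_fit)

  coefs <- vector("list", length(lam))           # per lambda: classes x feats
  if (scheme == "ovr") {
    B <- lapply(classes, function(cl) {
      fit <- glmnet::glmnet(Xs, factor(y == cl, levels = c(FALSE, TRUE)),
                            family = "binomial", alpha = 1, lambda = lam_fit,
                            standardize = FALSE, thresh = thresh,
                            maxit = maxit)
      as.matrix(fit$beta)                        # features x lambdas
    })
    for (j in seq_along(lam))
      coefs[[j]] <- t(vapply(B, function(b) b[, jmap[j]], numeric(ncol(Xs))))
  } else {
    fit <- glmnet::glmnet(Xs, factor(y), family = "multinomial", alpha = 1,
                          lambda = lam_fit, standardize = FALSE,
                          thresh = thresh, maxit = maxit)
    for (j in seq_along(lam))
      coefs[[j]] <- t(vapply(fit$beta, function(b) as.matrix(b)[, jmap[j]],
                             numeric(ncol(Xs))))
  }
  for (j in seq_along(lam)) {
    rownames(coefs[[j]]) <- classes
    colnames(coefs[[j]]) <- colnames(Xs)
  }

  out <- lapply(alphas, function(a) {
    j <- match(a, lam)
    cf <- coefs[[j]]
    list(alpha = a,
         retained = colnames(cf)[apply(abs(cf) > zero_tol, 2, any)],
         coefficients = cf)
  })
  structure(out, class = "l1_scan", scheme = scheme, classes = classes)
}

#' @export
print.l1_scan <- function(x, ...) {
  cat(sprintf("<l1_scan> %d alphas (%s)\n", length(x), attr(x, "scheme")))
  for (r in x)
    cat(sprintf("  alpha %-6g retained %d\n", r$alpha, length(r$retained)))
  invisible(x)
}

#' Restrict a fingerprint matrix to an L1-retained feature set
#'
#' Column-filters the matrix to the retained features; row order, ids and
#' labels are untouched. An empty retained set is an error (callers skip
#' such alphas), as is a retained name absent from the matrix.
#'
#' @param fm a `fingerprint_matrix`.
#' @param result one element of an [l1_scan()] (or a character vector of
#'   feature names).
#' @return the filtered `fingerprint_matrix`.
#' @export
apply_l1_selection <- function(fm, result) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  retained <- if (is.character(result)) result else result$retained
  if (!length(retained)) stop("empty retained feature set")
  absent <- setdiff(retained, colnames(fm$values))
  if (length(absent))
    stop("retained feature(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  fm$values <- fm$values[, retained, drop = FALSE]
  fm$filter <- retained
  fm
}

#' Pick the L1 penalty with the best leave-one-out accuracy
#'
#' Runs the classification task on the fingerprint restricted to each
#' alpha's retained set and returns the alpha with the highest accuracy;
#' ties are broken toward the larger alpha (the sparser fingerprint).
#' Alphas with an empty retained set are skipped with a warning.
#'
#' @param scan an [l1_scan()].
#' @param fm the `fingerprint_matrix` the scan was fitted on.
#' @param exclude leave-one-out exclusion policy ([nn_loo_classify()]).
#' @param replicate_median collapse replicates before classification.
#' @return list of class `alpha_selection`: `alpha`, `accuracy`,
#'   `retained`, and a per-alpha `details` data frame.
#' @export
best_alpha <- function(scan, fm, exclude = "same_treatment",
                       replicate_median = FALSE) {
  stopifnot(inherits(scan, "l1_scan"))
  alphas <- vapply(scan, `[[`, numeric(1), "alpha")
  ord <- order(alphas)
  acc <- rep(NA_real_, length(scan))
  for (i in ord) {
    r <- scan[[i]]
    if (!length(r$retained)) {
      warning("alpha ", r$alpha, ": empty retained set, skipped")
      next
    }
    fma <- apply_l1_selection(fm, r)
    if (replicate_median) fma <- median_replicates(fma)
    rep <- tryCatch(suppressMessages(nn_loo_classify(fma, exclude = exclude)),
                    error = function(e) NULL)
    if (is.null(rep)) next
    acc[i] <- rep$accuracy
  }
  if (all(is.na(acc))) stop("no usable alpha in the scan")
  usable <- which(!is.na(acc))
  best <- usable[acc[usable] == max(acc[usable])]
  best <- best[which.max(alphas[best])]          # ties -> larger alpha
  structure(list(alpha = alphas[best], accuracy = acc[best],
                 retained = scan[[best]]$retained,
                 details = data.frame(alpha = alphas,
                                      n_features = vapply(scan, function(r)
                                        length(r$retained), integer(1)),
                                      accuracy = acc)),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("<alpha_selection> alpha %g, accuracy %.3f, %d features\n",
              x$alpha, x$accuracy, length(x$retained)))
  invisible(x)
}
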