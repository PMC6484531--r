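# Independent reference computations used to check the pipeline.

# explicit interval counting: [lo, hi) with the last interval closed above
ref_count_bins <- function(v, edges) {
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  vapply(seq_along(lo), function(i) sum(v >= lo[i] & v < hi[i]), numeric(1))
}

# type-7 quantile by hand (linear interpolation of order statistics)
ref_q7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# chi-square upper tail for even df via the closed-form finite sum
ref_chisq_upper_even <- function(x, df) {
  stopifnot(df %% 2 == 0)
  j <- 0:(df / 2 - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

ref_cosine <- function(u, v) {
  1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

# brute-force 1-NN LOO with explicit pairwise loops and the documented
# (distance, id) tie rule
ref_nn_loo <- function(values, meta, exclude = "same_treatment") {
  n <- nrow(values)
  pred <- character(n)
  for (i in seq_len(n)) {
    best_d <- Inf
    best_id <- NULL
    best_moa <- NA_character_
    for (j in seq_len(n)) {
      if (j == i) next
      if (exclude == "same_treatment" &&
          meta$treatment[j] == meta$treatment[i]) next
      d <- ref_cosine(values[i, ], values[j, ])
      if (d < best_d || (d == best_d && meta$id[j] < best_id)) {
        best_d <- d
        best_id <- meta$id[j]
        best_moa <- meta$moa[j]
      }
    }
    pred[i] <- best_moa
  }
  pred
}

# directly assembled fingerprint matrix fixture
make_fm <- function(values, moa, treatment = NULL, mode = "well_average") {
  n <- nrow(values)
  if (is.null(treatment)) treatment <- sprintf("t%02d", seq_len(n))
  meta <- data.frame(id = sprintf("pr%02d", seq_len(n)), plate = "P1",
                     well = sprintf("w%02d", seq_len(n)),
                     treatment = treatment, moa = moa,
                     stringsAsFactors = FALSE)
  rownames(values) <- meta$id
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%d", seq_len(ncol(values)))
  structure(list(values = values, meta = meta, mode = mode, filter = NULL),
            class = "fingerprint_matrix")
}

# small hand-built cell table: 1 plate, DMSO + treated wells, given cells
make_cells <- function(well_values, treatment = NULL, plate = "P1",
                       feature = "f1") {
  wells <- names(well_values)
  if (is.null(treatment))
    treatment <- ifelse(grepl("^D", wells), "DMSO", wells)
  df <- do.call(rbind, lapply(seq_along(wells), function(i)
    data.frame(plate = plate, well = wells[i], treatment = treatment[i],
               v = well_values[[i]], stringsAsFactors = FALSE)))
  names(df)[names(df) == "v"] <- feature
  cell_table(df, plate = "plate", well = "well", treatment = "treatment",
             features = feature, validate = FALSE)
}

small_screen_config <- function(seed = 1, ...) {
  args <- list(seed = seed, plates = 2, wells_per_plate = 16,
               dmso_wells_per_plate = 8, cells_per_well = 200,
               n_parameters = 30, n_noisy = 5, n_degenerate = 1,
               moa_classes = 3, compounds_per_class = 2, replicates = 2,
               signature_size = 4, effect_size = 2, bimodal_fraction = 0.5,
               noise_drift_sd = 0.5)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}
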