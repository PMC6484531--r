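test_that("cosine distance hits its anchor values and properties", {
  u <- c(1, 2, 3)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(u, -u), 2)
  expect_error(cosine_distance(u, c(0, 0, 0)), "zero vector")
  expect_error(cosine_distance(u, c(1, 2)), "length")
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6)
    expect_equal(cosine_distance(a, b), cosine_distance(b, a))
    expect_equal(cosine_distance(a * runif(1, 0.1, 10), b),
                 cosine_distance(a, b), tolerance = 1e-12)
  }
})

test_that("the distance matrix agrees with pairwise evaluation", {
  set.seed(42)
  M <- matrix(rnorm(60), 10)
  rownames(M) <- sprintf("r%02d", 1:10)
  D <- cosine_distances(M)
  for (i in 1:10) for (j in 1:10)
    expect_equal(D[i, j],
                 if (i == j) 0 else ref_cosine(M[i, ], M[j, ]),
                 tolerance = 1e-12)
})

test_that("fingerprint assembly produces the expected columns per mode", {
  scr <- generate_screen(small_screen_config(seed = 43, n_parameters = 10,
                                             n_noisy = 0, n_degenerate = 0,
                                             signature_size = 2))
  bp <- bin_profile(scr$cells)
  fm_all <- suppressMessages(assemble_fingerprints(bp, "all_bins"))
  fm_ext <- suppressMessages(assemble_fingerprints(bp, "extreme_bins"))
  expect_lte(ncol(fm_ext$values), 20)  # 2 bins x 10 parameters at most
  expect_true(all(grepl("__bin[15]__z$", colnames(fm_ext$values))))
  expect_true(all(colnames(fm_ext$values) %in% colnames(fm_all$values)))
  expect_false(anyNA(fm_all$values))
  # well-average mode carries one column per parameter
  wa <- zscore_well_averages(well_average(scr$cells, min_cells = 1))
  fm_wa <- suppressMessages(assemble_fingerprints(wa, "well_average"))
  expect_lte(ncol(fm_wa$values), 10)
  # a parameter filter restricts columns
  keep <- attr(scr$cells, "features")[1:3]
  fm_f <- suppressMessages(assemble_fingerprints(bp, "extreme_bins",
                                                 parameters = keep))
  expect_true(all(sub("__bin.*", "", colnames(fm_f$values)) %in% keep))
  expect_error(assemble_fingerprints(bp, "all_bins", parameters = "nope"),
               "unknown parameter")
})

test_that("columns touched by missing values are dropped everywhere", {
  df <- data.frame(plate = "P1",
                   well = rep(c("D1", "D2", "D3", "T1"), each = 20),
                   treatment = rep(c("DMSO", "DMSO", "DMSO", "x"), each = 20),
                   f1 = rnorm(80), f2 = rnorm(80))
  df$f2[df$well == "T1"] <- NA  # parameter missing in one well
  ct <- cell_table(df)
  bp <- bin_profile(ct)
  fm <- suppressMessages(assemble_fingerprints(bp, "all_bins"))
  expect_false(any(grepl("^f2__", colnames(fm$values))))
})

test_that("nearest-neighbor LOO matches hand-built cases", {
  # two classes, within-class identical, between-class orthogonal
  V <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  fm <- make_fm(V, moa = c("A", "A", "B", "B"))
  r <- nn_loo_classify(fm, exclude = "self")
  expect_equal(r$n_correct, 4)
  expect_equal(r$accuracy, 1)

  # nearest candidate has the wrong label for one query
  V3 <- rbind(c(1, 0), c(0.9, 0.1), c(0.8, 0.25))
  fm3 <- make_fm(V3, moa = c("A", "B", "B"))
  r3 <- nn_loo_classify(fm3, exclude = "self")
  D <- cosine_distances(V3)
  pred <- sapply(1:3, function(i) {
    j <- setdiff(1:3, i)[which.min(D[i, setdiff(1:3, i)])]
    fm3$meta$moa[j]
  })
  expect_equal(r3$results$predicted, pred)
  expect_equal(r3$n_correct, sum(pred == fm3$meta$moa))

  # exact tie -> lexicographically smaller candidate id
  Vt <- rbind(c(1, 0), c(0, 1), c(0, 1))
  fmt <- make_fm(Vt, moa = c("q", "A", "B"))
  rt <- nn_loo_classify(fmt, exclude = "self")
  expect_equal(rt$results$nn_id[1], "pr02")
  expect_equal(rt$results$predicted[1], "A")
})

test_that("LOO classification is invariant to profile order and rescaling", {
  set.seed(44)
  V <- matrix(rnorm(30 * 6), 30)
  moa <- rep(c("A", "B", "C"), 10)
  fm <- make_fm(V, moa)
  r1 <- nn_loo_classify(fm, exclude = "self")
  perm <- sample(30)
  fm2 <- make_fm(V[perm, ] * 7, moa[perm])
  fm2$meta <- fm$meta[perm, ]
  rownames(fm2$values) <- fm2$meta$id
  r2 <- nn_loo_classify(fm2, exclude = "self")
  m <- match(r1$results$id, r2$results$id)
  expect_equal(r1$results$predicted, r2$results$predicted[m])
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("same-treatment exclusion removes replicate self-matches", {
  V <- rbind(c(1, 0), c(1, 0), c(0.7, 0.7), c(0, 1))
  fm <- make_fm(V, moa = c("A", "A", "B", "B"),
                treatment = c("c1", "c1", "c2", "c3"))
  r_self <- nn_loo_classify(fm, exclude = "self")
  r_nsc <- nn_loo_classify(fm, exclude = "same_treatment")
  # with replicates allowed, the identical replicate wins for rows 1-2
  expect_equal(r_self$results$nn_id[1], "pr02")
  # with the compound excluded, the nearest other compound wins
  expect_equal(r_nsc$results$nn_id[1], "pr03")
  # zero-candidate queries are unclassifiable but reported
  fm2 <- make_fm(rbind(c(1, 0), c(0, 1)), moa = c("A", "B"),
                 treatment = c("c1", "c1"))
  r2 <- nn_loo_classify(fm2, exclude = "same_treatment")
  expect_equal(r2$n_classified, 0)
  expect_equal(r2$n_profiles, 2)
})

test_that("replicate-median classification equals per-replicate when replicates are identical", {
  V <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  fm <- make_fm(V, moa = c("A", "A", "B", "B"),
                treatment = c("c1", "c1", "c2", "c2"))
  med <- median_replicates(fm, by = "treatment")
  expect_equal(nrow(med$values), 2)
  r_med <- nn_loo_classify(med, exclude = "self")
  r_rep <- nn_loo_classify(fm, exclude = "same_treatment")
  expect_equal(r_med$accuracy, r_rep$accuracy)
})

test_that("holding out a singleton class still counts its profile", {
  scr <- generate_screen(small_screen_config(seed = 45))
  ct <- scr$cells
  # shrink MoA03 to a single profile
  k3 <- which(!is.na(ct$moa) & ct$moa == "MoA03")
  keep_well <- unique(paste(ct$plate, ct$well)[k3])[1]
  drop <- k3[paste(ct$plate, ct$well)[k3] != keep_well]
  ct2 <- ct[-drop, ]
  ex <- suppressWarnings(
    holdout_class_experiment(ct2, "MoA03", method = "stability"))
  expect_equal(ex$holdout_n, 1L)
  expect_true(ex$holdout_misclassified %in% c(0L, 1L))
})
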