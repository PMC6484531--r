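test_that("linear percentile scaling maps control percentiles to 0/1 without clipping", {
  set.seed(11)
  dmso <- rnorm(500, 50, 20)
  q <- quantile(dmso, c(0.01, 0.99), names = FALSE, type = 7)
  probe <- c(q[1], q[2], mean(q), q[1] - 50)
  ct <- make_cells(list(D1 = dmso[1:250], D2 = dmso[251:500], T1 = probe))
  out <- normalize_linear_percentile(ct)
  expect_equal(out$f1[ct$well == "T1"],
               c(0, 1, 0.5, -50 / (q[2] - q[1])), tolerance = 1e-12)
})

test_that("linear percentile scaling is idempotent", {
  set.seed(12)
  ct <- make_cells(list(D1 = rnorm(200), D2 = rnorm(200), T1 = rnorm(50, 2)))
  once <- normalize_linear_percentile(ct)
  twice <- normalize_linear_percentile(once)
  expect_equal(twice$f1, once$f1, tolerance = 1e-12)
})

test_that("a constant control parameter is dropped plate-wide with a warning", {
  df <- data.frame(plate = "P1", well = rep(c("D1", "D2", "T1"), each = 5),
                   treatment = rep(c("DMSO", "DMSO", "x"), each = 5),
                   flat = 7, ok = rnorm(15))
  ct <- cell_table(df)
  expect_warning(out <- normalize_linear_percentile(ct), "flat")
  expect_true(all(is.na(out$flat)))
  expect_false(anyNA(out$ok))
  df$ok <- 3
  expect_error(suppressWarnings(
    normalize_linear_percentile(cell_table(df))), "degenerate")
})

test_that("well averages are per-well means skipping missing values", {
  df <- data.frame(plate = "P1",
                   well = c("D1", "D1", "D1", "D2", "D2", "T1", "T1"),
                   treatment = c(rep("DMSO", 5), "x", "x"),
                   f1 = c(1, 2, 3, 4, 6, 1, NA),
                   f2 = c(0, 0, 0, 1, 1, 10, 20))
  wa <- well_average(cell_table(df), min_cells = 2)
  expect_equal(wa$f1, c(2, 5, 1))
  expect_equal(wa$f2, c(0, 1, 15))
  expect_equal(wa$n_cells, c(3L, 2L, 2L))
  expect_equal(wa$low_n, c(FALSE, FALSE, FALSE))
})

test_that("well averaging commutes with row permutation of the input", {
  scr <- generate_screen(small_screen_config(seed = 3, n_parameters = 6,
                                             n_noisy = 1, n_degenerate = 0,
                                             signature_size = 1,
                                             cells_per_well = 30))
  ct <- scr$cells
  set.seed(99)
  shuffled <- ct[sample(nrow(ct)), ]
  a <- well_average(ct)
  b <- well_average(shuffled)
  b <- b[match(paste(a$plate, a$well), paste(b$plate, b$well)), ]
  rownames(b) <- NULL
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("z-scoring well averages matches the hand-computed sample-sd form", {
  df <- data.frame(plate = "P1", well = c("D1", "D2", "D3", "T1"),
                   treatment = c("DMSO", "DMSO", "DMSO", "x"),
                   f1 = c(1, 2, 3, 5))
  wa <- well_average(cell_table(df), min_cells = 1)
  z <- zscore_well_averages(wa)
  expect_equal(z$f1, c(-1, 0, 1, 3))  # sd over {1,2,3} with n-1 is 1
})

test_that("z-scored control wells have mean 0 and sample sd 1 per plate", {
  scr <- generate_screen(small_screen_config(seed = 4, n_parameters = 8,
                                             n_noisy = 2, n_degenerate = 0,
                                             signature_size = 2,
                                             cells_per_well = 40))
  z <- zscore_well_averages(well_average(scr$cells, min_cells = 1))
  for (pl in unique(z$plate)) {
    ctl <- z[z$plate == pl & z$treatment == "DMSO", ]
    for (f in attr(z, "features")) {
      expect_equal(mean(ctl[[f]]), 0, tolerance = 1e-12)
      expect_equal(sd(ctl[[f]]), 1, tolerance = 1e-12)
    }
  }
})

test_that("fewer than two control wells on a plate is an error naming it", {
  df <- data.frame(plate = "P9", well = c("D1", "T1"),
                   treatment = c("DMSO", "x"), f1 = c(1, 2))
  wa <- well_average(suppressWarnings(cell_table(df)), min_cells = 1)
  expect_error(zscore_well_averages(wa), "P9")
})

test_that("zero control sd drops the parameter with a warning", {
  df <- data.frame(plate = "P1", well = rep(c("D1", "D2", "T1"), each = 2),
                   treatment = rep(c("DMSO", "DMSO", "x"), each = 2),
                   flat = rep(c(2, 2, 9), each = 2),
                   ok = c(1, 1, 4, 4, 9, 9))
  wa <- well_average(cell_table(df), min_cells = 1)
  expect_warning(z <- zscore_well_averages(wa), "flat")
  expect_true(all(is.na(z$flat)))
  expect_false(anyNA(z$ok))
})

test_that("replicate medians use the stated conventions and carry MoA through", {
  fm <- make_fm(matrix(c(0.1, 0.2, 0.9,
                         1, 3, 5), ncol = 2),
                moa = rep("A", 3), treatment = rep("cmpd1", 3))
  fm$meta$concentration <- 1
  med <- median_replicates(fm)
  expect_equal(unname(med$values[1, ]), c(0.2, 3))
  expect_equal(med$meta$moa, "A")

  one <- make_fm(matrix(c(0.4, 0.7), nrow = 1), moa = "A",
                 treatment = "solo")
  expect_equal(unname(median_replicates(one)$values[1, ]), c(0.4, 0.7))

  even <- make_fm(matrix(c(1, 3), ncol = 1), moa = c("A", "A"),
                  treatment = rep("c", 2))
  expect_equal(unname(median_replicates(even)$values[1, 1]), 2)

  bad <- make_fm(matrix(1:4, ncol = 2), moa = c("A", "B"),
                 treatment = rep("c", 2))
  expect_error(median_replicates(bad), "conflicting MoA")
})
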