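#' Configuration for the synthetic screen generator
#'
#' Fixes the layout and the planted ground truth of a simulated
#' high-content screen: plates carrying many vehicle (DMSO) wells and
#' treated wells, hundreds of cells per well, and parameters of four
#' kinds — stable and uninformative, stable and phenotype-shifted by some
#' class, noisy (per-well distributional drift) and degenerate (a discrete
#' value for almost every cell, like a nuclei count of 1).
#'
#' Defaults describe a two-plate screen with 20 DMSO wells per plate,
#' 500 cells per well (Poisson-dispersed), 100 parameters of which 20 are
#' noisy with a per-well location drift of 0.5 baseline sd, and 3 MoA
#' classes whose signatures shift 5 parameters each by 2 baseline sd —
#' half translated, half split into a bimodal population.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param plates number of plates.
#' @param wells_per_plate total wells per plate (controls + treated
#'   capacity).
#' @param dmso_wells_per_plate negative-control wells per plate (>= 2).
#' @param cells_per_well mean cells per well (Poisson-dispersed, floor 1).
#' @param n_parameters total parameters.
#' @param n_noisy parameters with independent per-well location drift.
#' @param n_degenerate parameters taking a single value for >= 99% of
#'   cells.
#' @param moa_classes number of MoA classes (0 for a control-only screen).
#' @param compounds_per_class compounds per class.
#' @param replicates replicate wells per compound.
#' @param effect_size phenotype shift in units of the baseline sd.
#' @param bimodal_fraction fraction of each signature's parameters whose
#'   shift splits the population (half up, half down) instead of
#'   translating it.
#' @param noise_drift_sd sd of the per-well random offset of noisy
#'   parameters, in baseline sd units.
#' @param signature_size shifted parameters per class; signatures are
#'   drawn disjointly from the stable pool, so every class owns private
#'   informative parameters.
#' @param baseline `"normal"` or `"lognormal"` cell-level baseline.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, plates = 2L, wells_per_plate = 40L,
                             dmso_wells_per_plate = 20L,
                             cells_per_well = 500L, n_parameters = 100L,
                             n_noisy = 20L, n_degenerate = 5L,
                             moa_classes = 3L, compounds_per_class = 2L,
                             replicates = 3L, effect_size = 2,
                             bimodal_fraction = 0.5, noise_drift_sd = 0.5,
                             signature_size = 5L,
                             baseline = c("normal", "lognormal")) {
  baseline <- match.arg(baseline)
  cfg <- list(seed = as.integer(seed), plates = as.integer(plates),
              wells_per_plate = as.integer(wells_per_plate),
              dmso_wells_per_plate = as.integer(dmso_wells_per_plate),
              cells_per_well = as.integer(cells_per_well),
              n_parameters = as.integer(n_parameters),
              n_noisy = as.integer(n_noisy),
              n_degenerate = as.integer(n_degenerate),
              moa_classes = as.integer(moa_classes),
              compounds_per_class = as.integer(compounds_per_class),
              replicates = as.integer(replicates),
              effect_size = effect_size,
              bimodal_fraction = bimodal_fraction,
              noise_drift_sd = noise_drift_sd,
              signature_size = as.integer(signature_size),
              baseline = baseline)
  with(cfg, {
    if (plates < 1 || wells_per_plate < 1 || cells_per_well < 1)
      stop("plates, wells and cells must be positive")
    if (dmso_wells_per_plate < 2)
      stop("need at least 2 DMSO wells per plate")
    if (dmso_wells_per_plate > wells_per_plate)
      stop("more DMSO wells than wells per plate")
    if (n_noisy + n_degenerate > n_parameters)
      stop("n_noisy + n_degenerate exceeds n_parameters")
    if (bimodal_fraction < 0 || bimodal_fraction > 1)
      stop("bimodal_fraction must be in [0, 1]")
    if (effect_size < 0 || noise_drift_sd < 0)
      stop("effect_size and noise_drift_sd must be nonnegative")
    n_treated <- moa_classes * compounds_per_class * replicates
    if (n_treated > plates * (wells_per_plate - dmso_wells_per_plate))
      stop("treated wells (", n_treated, ") exceed the plates' capacity")
    if (moa_classes > 0 &&
        moa_classes * signature_size > n_parameters - n_noisy - n_degenerate)
      stop("not enough stable parameters for disjoint class signatures")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multi-plate single-cell screen
#'
#' Draws a [cell_table()] with known ground truth. DMSO cells of parameter
#' j on plate p are i.i.d. Normal(loc\[p, j\], scale\[p, j\]) (location and
#' scale chosen once per plate and parameter, so plates differ and
#' per-plate statistics matter); with the lognormal baseline the same
#' values are exponentiated. Noisy parameters additionally receive an
#' independent per-well offset ~ Normal(0, `noise_drift_sd` * scale).
#' Degenerate parameters take the value 1 for >= 99% of cells (2
#' otherwise). Treated wells apply their class signature: *translate*
#' shifts the well's mean by `effect_size` sd in the signature direction;
#' *bimodal* moves exactly half the cells up and half down by
#' `effect_size` sd, leaving the well average in place while filling the
#' extreme bins — the subpopulation phenotype a well mean cannot see.
#'
#' The output is byte-identical for identical configurations.
#'
#' @param config a [synthetic_config()].
#' @return list with `cells` (a [cell_table()]; control wells carry
#'   `moa = NA`) and `truth` (parameter roles and per-class signatures).
#' @export
generate_screen <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  c0 <- config
  set.seed(c0$seed)
  params <- sprintf("p%03d", seq_len(c0$n_parameters))

  ord <- sample(c0$n_parameters)
  noisy <- params[ord[seq_len(c0$n_noisy)]]
  degenerate <- if (c0$n_degenerate > 0)
    params[ord[c0$n_noisy + seq_len(c0$n_degenerate)]] else character()
  stable_pool <- setdiff(params, c(noisy, degenerate))
  roles <- stats::setNames(rep("stable_uninformative", c0$n_parameters),
                           params)
  roles[noisy] <- "noisy"
  roles[degenerate] <- "degenerate"

  plates <- sprintf("P%02d", seq_len(c0$plates))
  loc <- matrix(stats::rnorm(c0$plates * c0$n_parameters, 0, 1),
                c0$plates, c0$n_parameters,
                dimnames = list(plates, params))
  scl <- matrix(exp(stats::rnorm(c0$plates * c0$n_parameters, 0, 0.2)),
                c0$plates, c0$n_parameters,
                dimnames = list(plates, params))

  classes <- if (c0$moa_classes > 0)
    sprintf("MoA%02d", seq_len(c0$moa_classes)) else character()
  signatures <- list()
  if (length(classes)) {
    sig_params <- sample(stable_pool,
                         c0$moa_classes * c0$signature_size)
    for (i in seq_along(classes)) {
      ps <- sig_params[(i - 1) * c0$signature_size + seq_len(c0$signature_size)]
      n_bi <- round(c0$bimodal_fraction * c0$signature_size)
      type <- rep("translate", c0$signature_size)
      type[sample(c0$signature_size, n_bi)] <- "bimodal"
      signatures[[classes[i]]] <- data.frame(
        parameter = ps,
        direction = sample(c(-1, 1), c0$signature_size, replace = TRUE),
        type = type, stringsAsFactors = FALSE)
      roles[ps] <- "stable_informative"
    }
  }

  # compound list laid out round-robin across plates
  compounds <- character()
  comp_moa <- character()
  if (length(classes)) {
    for (cl in classes)
      for (j in seq_len(c0$compounds_per_class)) {
        id <- sprintf("%s_c%d", cl, j)
        compounds <- c(compounds, rep(id, c0$replicates))
        comp_moa <- c(comp_moa, rep(cl, c0$replicates))
      }
  }
  trt_plate <- if (length(compounds))
    plates[(seq_along(compounds) - 1) %% c0$plates + 1] else character()

  blocks <- list()
  meta <- list()
  for (pi in seq_along(plates)) {
    p <- plates[pi]
    trt_idx <- which(trt_plate == p)
    wells <- c(sprintf("D%02d", seq_len(c0$dmso_wells_per_plate)),
               sprintf("T%02d", seq_along(trt_idx)))
    treatments <- c(rep("DMSO", c0$dmso_wells_per_plate),
                    compounds[trt_idx])
    moas <- c(rep(NA_character_, c0$dmso_wells_per_plate),
              comp_moa[trt_idx])
    for (wi in seq_along(wells)) {
      n <- max(1L, stats::rpois(1, c0$cells_per_well))
      M <- matrix(stats::rnorm(n * c0$n_parameters), n, c0$n_parameters)
      M <- sweep(M, 2, scl[p, ], `*`)
      M <- sweep(M, 2, loc[p, ], `+`)
      colnames(M) <- params
      if (length(noisy)) {
        drift <- stats::rnorm(length(noisy), 0, c0$noise_drift_sd)
        M[, noisy] <- M[, noisy] +
          rep(drift * scl[p, noisy], each = n)
      }
      if (!is.na(moas[wi])) {
        sig <- signatures[[moas[wi]]]
        for (si in seq_len(nrow(sig))) {
          j <- sig$parameter[si]
          delta <- c0$effect_size * scl[p, j]
          if (sig$type[si] == "translate") {
            M[, j] <- M[, j] + sig$direction[si] * delta
          } else {
            up <- sample(n, n %/% 2)
            M[up, j] <- M[up, j] + delta
            M[-up, j] <- M[-up, j] - delta
          }
        }
      }
      if (c0$baseline == "lognormal") {
        cont <- setdiff(params, degenerate)
        M[, cont] <- exp(M[, cont])
      }
      if (length(degenerate)) {
        D <- matrix(1, n, length(degenerate))
        D[stats::runif(n * length(degenerate)) < 0.005] <- 2
        M[, degenerate] <- D
      }
      blocks[[length(blocks) + 1L]] <- M
      meta[[length(meta) + 1L]] <- data.frame(
        plate = p, well = wells[wi], treatment = treatments[wi],
        moa = moas[wi], concentration = 1, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, Map(function(m, b) data.frame(m, b,
                                                        check.names = FALSE,
                                                        stringsAsFactors = FALSE),
                              meta, blocks))
  rownames(cells) <- NULL
  ct <- cell_table(cells, plate = "plate", well = "well",
                   treatment = "treatment", moa = "moa",
                   concentration = "concentration", features = params,
                   control = "DMSO", validate = FALSE)
  list(cells = ct,
       truth = list(parameter_roles = roles, class_signatures = signatures))
}

#' A tiny deterministic worked example for the binning pipeline
#'
#' Builds a fixed 2-plate, 8-well, 100-cells-per-well table with six
#' parameters whose binning outcome is known by construction, with no
#' random number generation involved:
#' \describe{
#'   \item{u_uniform}{every well holds a permutation of 1..100, so each
#'     bin of every well captures exactly 20 cells and the stability
#'     chi-square is 0.}
#'   \item{g_stable}{every well holds the same normal quantile grid, plus
#'     a tiny deterministic per-well offset (0.01 per well index) so the
#'     control baseline has nonzero dispersion and z-scores are defined.}
#'   \item{g_drift}{as `g_stable`, but control well D6 is shifted by
#'     +1 — a planted well-level drift the stability test must flag.}
#'   \item{g_shift}{treated well T1 is translated by +1.}
#'   \item{g_bimodal}{treated well T2 is split by +/-2 (bimodal).}
#'   \item{c_const}{constant 1 — only one bin instantiated, untestable.}
#' }
#' Wells D1..D6 are DMSO, T1 and T2 are treated; plate P2 repeats the
#' layout with all continuous values offset by +5 to exercise per-plate
#' edges.
#'
#' @return list with `cells` (a [cell_table()]) and `layout` notes.
#' @export
generate_worked_example <- function() {
  grid <- stats::qnorm((seq_len(100) - 0.5) / 100)
  wells <- c(paste0("D", 1:6), "T1", "T2")
  treatments <- c(rep("DMSO", 6), "cmpdA", "cmpdB")
  moas <- c(rep(NA_character_, 6), "shift", "bimodal")
  rows <- list()
  for (pl in 1:2) {
    off <- if (pl == 2) 5 else 0
    for (wi in seq_along(wells)) {
      u <- ((seq_len(100) + 7 * wi) %% 100) + 1
      woff <- 0.01 * wi                # deterministic well-to-well jitter
      g_drift <- grid + woff + if (wells[wi] == "D6") 1 else 0
      g_shift <- grid + woff + if (wells[wi] == "T1") 1 else 0
      g_bimodal <- grid + woff + if (wells[wi] == "T2")
        rep(c(2, -2), 50) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        plate = paste0("P", pl), well = wells[wi],
        treatment = treatments[wi], moa = moas[wi],
        u_uniform = u + off, g_stable = grid + woff + off,
        g_drift = g_drift + off, g_shift = g_shift + off,
        g_bimodal = g_bimodal + off, c_const = 1,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  ct <- cell_table(cells, plate = "plate", well = "well",
                   treatment = "treatment", moa = "moa",
                   control = "DMSO", validate = FALSE)
  list(cells = ct,
       layout = list(control_wells = paste0("D", 1:6),
                     drift_well = "D6", shift_well = "T1",
                     bimodal_well = "T2"))
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed %d: %d plate(s) x %d wells (%d DMSO), ~%d cells/well\n",
              x$seed, x$plates, x$wells_per_plate, x$dmso_wells_per_plate,
              x$cells_per_well))
  cat(sprintf("  parameters: %d (%d noisy, %d degenerate) | classes: %d x %d compounds x %d replicates\n",
              x$n_parameters, x$n_noisy, x$n_degenerate, x$moa_classes,
              x$compounds_per_class, x$replicates))
  cat(sprintf("  effect %.2g sd, bimodal fraction %.2g, drift sd %.2g, baseline %s\n",
              x$effect_size, x$bimodal_fraction, x$noise_drift_sd,
              x$baseline))
  invisible(x)
}
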