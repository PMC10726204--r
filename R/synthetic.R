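#' @section Synthetic field trials:
#' Real plot-level trial data of this design are rarely shareable, so the
#' package ships a phenomenological generator that emulates a four-level
#' water-stress trial: 4 irrigation treatments x 10 cultivars x 3
#' replications = 120 plots, with treatment-level yield means and standard
#' deviations matching the descriptive statistics of the motivating trial.
#' A latent canopy-vigor variable couples yield to the spectral bands: the
#' red band decreases and the NIR band increases with vigor such that the
#' NDVI response is linear in vigor; blue, green and red edge carry only
#' noise. The planted (informative-by-construction) index set defaults to
#' the exact-duplicate family of that response: NDVI itself, MRVI (which
#' is algebraically identical to NDVI) and the as-printed TVI (NDVI + 0.5).
#' Signal enters through the bands, not through individual indices, so
#' whole correlated index families become informative together — as they do
#' in real canopies.
#' @name synthetic
NULL

#' Configuration of a synthetic water-stress trial
#'
#' Defaults encode the reference trial design: four irrigation treatments
#' (W1 = severe drought ... W4 = extreme surplus), 10 cultivars x 3 reps
#' per treatment, and treatment-level yield moments (t/ha) from its
#' descriptive statistics.
#'
#' @param treatments Treatment labels.
#' @param yield_mean,yield_sd Per-treatment yield mean and SD (t/ha).
#' @param cultivars Number of cultivars (default 10).
#' @param reps Replications per cultivar (default 3).
#' @param planted Index names made informative by construction.
#' @param signal Signal strength in \[0, 1\]: the share of within-treatment
#'   yield variation carried by latent vigor (default 0.9, a strong but not
#'   noise-free canopy-yield coupling).
#' @param band_noise_sd SD of additive per-band reflectance noise
#'   (default 0.005).
#' @param cultivar_sd SD of cultivar random intercepts, t/ha (default 0.3).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(treatments = c("W1", "W2", "W3", "W4"),
                       yield_mean = c(7.77, 8.32, 8.97, 8.19),
                       yield_sd = c(1.56, 1.39, 1.19, 1.26),
                       cultivars = 10, reps = 3,
                       planted = c("NDVI", "TVI", "MRVI"),
                       signal = 0.9, band_noise_sd = 0.005,
                       cultivar_sd = 0.3, seed = 1) {
  if (length(yield_mean) != length(treatments) || length(yield_sd) != length(treatments)) {
    vi_stop("yield_mean / yield_sd must match the number of treatments",
            "viselect_config_error")
  }
  if (any(yield_mean <= 0) || any(yield_sd <= 0)) {
    vi_stop("yield means and SDs must be positive", "viselect_config_error")
  }
  if (signal < 0 || signal > 1) vi_stop("signal must be in [0, 1]", "viselect_config_error")
  unknown <- setdiff(planted, vi_names())
  if (length(unknown)) {
    vi_stop(sprintf("planted indices not in the library: %s",
                    paste(unknown, collapse = ", ")), "viselect_config_error")
  }
  structure(list(treatments = treatments, yield_mean = yield_mean,
                 yield_sd = yield_sd, cultivars = as.integer(cultivars),
                 reps = as.integer(reps), planted = planted, signal = signal,
                 band_noise_sd = band_noise_sd, cultivar_sd = cultivar_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Band model constants: baseline reflectances of a wheat canopy, the slope
# tying the NDVI response to latent vigor, and the amplitudes of three
# independent latent axes (soil-background brightness in red, greenness,
# red-edge chlorophyll) that vary between plots without tracking yield —
# these spread the index-yield correlations the way real trials do.
.band_pars <- list(red0 = 0.06, red_slope = 0.004, soil_amp = 0.010,
                   ndvi0 = 0.50, ndvi_slope = 0.08,
                   red_edge0 = 0.25, red_edge_amp = 0.03,
                   green0 = 0.10, green_amp = 0.015, blue0 = 0.05)

#' Simulate a water-stress field trial
#'
#' Generates one plot record per treatment x cultivar x rep. Per plot a
#' latent vigor value is drawn from a treatment-shifted standard normal;
#' yield is the treatment mean plus a vigor term and residual noise scaled
#' so the treatment SD matches the configuration (cultivar intercepts
#' included), truncated below at 0.1 t/ha. Bands follow the vigor coupling
#' described in the package overview. Each plot consumes its own
#' counter-based random substream derived from the global seed, so results
#' do not depend on record order.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_trial` with `$plots` (the standard
#'   plot CSV schema: `plot_id, treatment, cultivar, rep, blue, green, red,
#'   red_edge, nir, yield_t_ha`) and `$truth` (latent vigor, planted index
#'   names, config echo).
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) vi_stop("config must be a sim_config", "viselect_config_error")
  tr <- config$treatments
  n_per <- config$cultivars * config$reps
  design <- expand.grid(rep = seq_len(config$reps),
                        cultivar = seq_len(config$cultivars),
                        treatment = seq_along(tr))
  design <- design[order(design$treatment, design$cultivar, design$rep), ]
  n <- nrow(design)

  # treatment shift of latent vigor, aligned with the yield means
  mu <- config$yield_mean; sdv <- config$yield_sd
  delta <- (mu - mean(mu)) / mean(sdv)
  cult_eff <- with_seed(mix_seed(config$seed, 999983L),
                        stats::rnorm(config$cultivars, 0, config$cultivar_sd))
  s <- config$signal
  bp <- .band_pars
  sigma_resid <- sqrt(pmax(sdv^2 - config$cultivar_sd^2, 1e-12))

  rows <- vector("list", n)
  vigor <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- design$treatment[i]
    draws <- with_seed(mix_seed(config$seed, i), stats::rnorm(10))
    z <- draws[1]; e <- draws[2]
    soil <- draws[3]; chl <- draws[4]; redge <- draws[5]
    bnoise <- draws[6:10] * config$band_noise_sd
    v <- delta[t_i] + z
    vigor[i] <- v
    yield <- mu[t_i] + sigma_resid[t_i] * (s * z + sqrt(1 - s^2) * e) +
      cult_eff[design$cultivar[i]]
    yield <- max(0.1, yield)
    red <- clamp(bp$red0 - bp$red_slope * s * v + bp$soil_amp * soil + bnoise[1],
                 0.001, 0.999)
    tgt <- clamp(bp$ndvi0 + bp$ndvi_slope * s * v, -0.97, 0.97)
    nir <- clamp(red * (1 + tgt) / (1 - tgt) + bnoise[2], 0.001, 0.999)
    red_edge <- clamp(bp$red_edge0 + bp$red_edge_amp * redge + bnoise[3], 0.001, 0.999)
    green <- clamp(bp$green0 + bp$green_amp * chl + bnoise[4], 0.001, 0.999)
    blue <- clamp(bp$blue0 + bnoise[5], 0.001, 0.999)
    rows[[i]] <- data.frame(
      plot_id = sprintf("%s_c%02d_r%d", tr[t_i], design$cultivar[i], design$rep[i]),
      treatment = tr[t_i],
      cultivar = sprintf("cv%02d", design$cultivar[i]),
      rep = design$rep[i],
      blue = blue, green = green, red = red, red_edge = red_edge, nir = nir,
      yield_t_ha = yield, stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, rows)
  rownames(plots) <- NULL
  structure(list(plots = plots,
                 truth = list(vigor = vigor, planted = config$planted,
                              signal = s, config = config)),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic water-stress trial: %d plots (%s)\n", nrow(x$plots),
              paste(unique(x$plots$treatment), collapse = ", ")))
  cat(sprintf("  planted indices: %s (signal %.2f)\n",
              paste(x$truth$planted, collapse = ", "), x$truth$signal))
  invisible(x)
}

#' Ground-truth informative indices of a synthetic trial
#'
#' @param trial A `synthetic_trial` (or the result of
#'   [simulate_planted_vitable()]).
#' @return A `vi_subset` of the configured planted index names (possibly
#'   empty for a pure-null trial).
#' @export
planted_truth <- function(trial) {
  planted <- if (!is.null(trial$truth)) trial$truth$planted else trial$planted
  vi_subset(planted %||% character(),
            provenance = list(list(step = "planted_truth")))
}

#' Recovery rate of a selected subset against the planted truth
#'
#' @param selected A `vi_subset` (or character vector) of selected features.
#' @param truth A `vi_subset` (or character vector) of planted features.
#' @return `|selected intersect planted| / |planted|`, or `NA` for an empty
#'   planted set.
#' @export
recovery_rate <- function(selected, truth) {
  sel <- if (inherits(selected, "vi_subset")) selected$features else as.character(selected)
  pl <- if (inherits(truth, "vi_subset")) truth$features else as.character(truth)
  if (!length(pl)) return(NA_real_)
  length(intersect(sel, pl)) / length(pl)
}

#' Simulate an index table with directly planted informative features
#'
#' A simpler, index-level companion to [simulate_experiment()] for
#' benchmarking selectors in isolation: the planted columns load on a
#' shared latent factor that drives yield, all other index columns are
#' independent noise. This bypasses the band model entirely (useful when a
#' controlled number of informative columns is required) and is labelled
#' synthetic in its output.
#'
#' @param n Number of plots (default 150).
#' @param planted Names of informative columns (default NDVI, NDRE, GNDVI).
#' @param rho Squared loading of planted columns on the latent factor
#'   (default 0.7).
#' @param signal Correlation of yield with the latent factor (default 0.9).
#' @param yield_mean,yield_sd Yield scale (t/ha), defaults 8.31 and 1.40.
#' @param seed Integer seed.
#' @return A list with `$vitable` (data.frame, all 35 index names),
#'   `$yield`, `$planted`.
#' @export
simulate_planted_vitable <- function(n = 150, planted = c("NDVI", "NDRE", "GNDVI"),
                                     rho = 0.7, signal = 0.9,
                                     yield_mean = 8.31, yield_sd = 1.40,
                                     seed = 1) {
  unknown <- setdiff(planted, vi_names())
  if (length(unknown)) {
    vi_stop(sprintf("planted indices not in the library: %s",
                    paste(unknown, collapse = ", ")), "viselect_config_error")
  }
  with_seed(seed, {
    v <- stats::rnorm(n)
    cols <- lapply(vi_names(), function(nm) {
      if (nm %in% planted) {
        sqrt(rho) * v + sqrt(1 - rho) * stats::rnorm(n)
      } else {
        stats::rnorm(n)
      }
    })
    names(cols) <- vi_names()
    yield <- pmax(0.1, yield_mean +
                    yield_sd * (signal * v + sqrt(1 - signal^2) * stats::rnorm(n)))
    list(vitable = data.frame(cols, check.names = FALSE),
         yield = yield, planted = planted)
  })
}
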