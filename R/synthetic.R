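# Synthetic-data generators: every input the pipeline consumes can be built
# in code, with a truth record sufficient to score the downstream estimator.

# Evaluate expr with a local RNG state; the caller's RNG is untouched and a
# fixed seed gives bit-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Per-stream substreams from one global seed, kept inside 32-bit range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Simulate an imaging-flow-cytometry event table
#'
#' Draws per-cell internalized-bead counts from the mechanics model: count ~
#' Poisson(`lambda_scale * A(xi) * a(xi, R) * g(xi)`), for every rigidity x
#' replicate x bead-size condition. Bead fluorescence is the count times a
#' lognormal per-bead intensity (zero iff the count is zero). Focus scores and
#' singlet morphology are drawn so that configured fractions of events fail
#' the focus (gradient RMS < 50) and singlet gates.
#'
#' @param panel Substrate rigidities, kPa. Default the commercial panel
#'   `c(0.5, 2, 8, 16, 32, 64)`.
#' @param radii Bead radii, um. Default `c(0.4, 1.2)` (0.8 and 2.4 um beads).
#' @param n_cells Cells per rigidity x replicate x size condition. Default
#'   1000.
#' @param n_replicates Replicates (wells) per condition. Default 3.
#' @param params [mechanics_params()] used as generative truth.
#' @param lambda_scale Calibration constant mapping propensity to expected
#'   beads per cell. Default 2.
#' @param out_of_focus_frac Fraction of events drawn below the focus gate.
#'   Default 0.1.
#' @param doublet_frac Fraction of events drawn as doublets (low aspect ratio,
#'   high area). Default 0.05.
#' @param bead_intensity_mean Mean fluorescence per bead, arbitrary units.
#'   Default 100.
#' @param bead_intensity_sigma Lognormal sigma of per-event intensity noise.
#'   Default 0.3.
#' @param seed RNG seed.
#' @return List with `events` (data.frame: `focus_rms`, `aspect_ratio`,
#'   `area_px`, `bead_count`, `bead_intensity`, `rigidity_kpa`, `radius_um`,
#'   `replicate`) and `truth` (per-condition Poisson rate and expected uptake
#'   fraction `1 - exp(-rate)`, plus all generator settings).
#' @export
sim_uptake_events <- function(panel = c(0.5, 2, 8, 16, 32, 64),
                              radii = c(0.4, 1.2),
                              n_cells = 1000, n_replicates = 3,
                              params = mechanics_params(),
                              lambda_scale = 2,
                              out_of_focus_frac = 0.1, doublet_frac = 0.05,
                              bead_intensity_mean = 100,
                              bead_intensity_sigma = 0.3,
                              seed = 1) {
  params <- as_mechanics_params(params)
  stopifnot(n_cells >= 1, n_replicates >= 1, lambda_scale >= 0)
  cond <- expand.grid(replicate = paste0("rep", seq_len(n_replicates)),
                      rigidity_kpa = panel, radius_um = radii,
                      stringsAsFactors = FALSE)
  cond$rate <- lambda_scale *
    mapply(function(xi, r) uptake_propensity(xi, r, params,
                                             include_functionality = TRUE),
           cond$rigidity_kpa, cond$radius_um)
  events <- with_seed(derive_seed(seed, 1L), {
    do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
      n <- n_cells
      count <- stats::rpois(n, cond$rate[i])
      oof <- stats::runif(n) < out_of_focus_frac
      dbl <- stats::runif(n) < doublet_frac
      intensity <- ifelse(
        count > 0,
        count * bead_intensity_mean *
          stats::rlnorm(n, -bead_intensity_sigma^2 / 2, bead_intensity_sigma),
        0)
      data.frame(
        focus_rms = ifelse(oof, stats::runif(n, 10, 49.5),
                           stats::runif(n, 55, 95)),
        aspect_ratio = ifelse(dbl, stats::runif(n, 0.25, 0.55),
                              stats::runif(n, 0.65, 1.0)),
        area_px = ifelse(dbl, stats::rnorm(n, 220, 15),
                         stats::rnorm(n, 100, 8)),
        bead_count = count,
        bead_intensity = intensity,
        rigidity_kpa = cond$rigidity_kpa[i],
        radius_um = cond$radius_um[i],
        replicate = cond$replicate[i])
    }))
  })
  truth <- cond
  truth$expected_fraction <- 1 - exp(-truth$rate)
  list(events = events,
       truth = list(conditions = truth, lambda_scale = lambda_scale,
                    params = params, n_cells = n_cells,
                    out_of_focus_frac = out_of_focus_frac,
                    doublet_frac = doublet_frac, seed = seed))
}

#' Simulate gel-cube compression traces
#'
#' Linear-elastic force-displacement curves for cubic gel samples compressed
#' to 90% of their edge length, with multiplicative force noise and optional
#' mild strain-stiffening beyond 10% strain (to exercise the elastic-window
#' choice in the modulus fit).
#'
#' @param E_true True Young's modulus, kPa.
#' @param side_pre Pre-compression cube edge length, um. Default 1000 (a 1
#'   mm^3 cube).
#' @param n_samples Number of cubes. Default 10.
#' @param noise_pct Multiplicative force noise, percent. Default 5.
#' @param n_points Points per trace, spanning strain (0, 0.9]. Default 50.
#' @param stiffening Strain-stiffening coefficient: the tangent modulus grows
#'   by `stiffening * (strain - 0.1)` relative beyond 10% strain. Default 0
#'   (purely linear).
#' @param seed RNG seed.
#' @return List with `records` (list of [compression_record()]) and `truth`.
#' @export
sim_compression_curves <- function(E_true, side_pre = 1000, n_samples = 10,
                                   noise_pct = 5, n_points = 50,
                                   stiffening = 0, seed = 1) {
  stopifnot(E_true > 0, side_pre > 0, n_samples >= 1, n_points >= 3)
  strain <- seq(0.9 / n_points, 0.9, length.out = n_points)
  records <- with_seed(derive_seed(seed, 3L), {
    lapply(seq_len(n_samples), function(s) {
      stress <- E_true * strain * (1 + stiffening * pmax(0, strain - 0.10))
      force <- stress * side_pre^2 / UN_PER_UM2_TO_KPA *
        (1 + stats::rnorm(n_points, 0, noise_pct / 100))
      compression_record(strain * side_pre, force, side_pre,
                         sample_id = sprintf("cube_%02d", s))
    })
  })
  list(records = records,
       truth = list(E_true = E_true, side_pre = side_pre,
                    noise_pct = noise_pct, stiffening = stiffening,
                    seed = seed))
}

# Rasterize non-overlapping ellipses; returns label matrix (0 = background).
rasterize_ellipses <- function(dim_px, centers, a, b, phi) {
  lab <- matrix(0L, dim_px, dim_px)
  if (length(a) == 0L) return(lab)
  xs <- seq_len(dim_px) - 0.5
  for (i in seq_along(a)) {
    r <- ceiling(a[i]) + 1L
    ix <- which(xs >= centers[i, 1] - r & xs <= centers[i, 1] + r)
    iy <- which(xs >= centers[i, 2] - r & xs <= centers[i, 2] + r)
    dx <- outer(xs[ix] - centers[i, 1], rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), xs[iy] - centers[i, 2])
    u <- dx * cos(phi[i]) + dy * sin(phi[i])
    v <- -dx * sin(phi[i]) + dy * cos(phi[i])
    inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
    lab[cbind(as.vector(row(inside))[inside] + ix[1] - 1L,
              as.vector(col(inside))[inside] + iy[1] - 1L)] <- i
  }
  lab
}

#' Simulate a two-channel fluorescence image with ground truth
#'
#' Places `n_cells` non-overlapping elliptical cells (rejection sampling on
#' bounding circles) with per-cell areas around `mean_area_um2`, one
#' concentric nucleus per cell covering `nucleus_fraction` of the cell area,
#' unit foreground intensity and Gaussian background noise of standard
#' deviation `1/snr` (clipped at zero).
#'
#' @param n_cells Number of cells; 0 gives blank channels.
#' @param mean_area_um2 Mean per-cell area, um^2.
#' @param nucleus_fraction Nucleus area as a fraction of cell area. Default
#'   0.16.
#' @param pixel_size Pixel edge, um/pixel. Default 0.5.
#' @param snr Foreground amplitude over noise standard deviation. Default 10.
#' @param seed RNG seed.
#' @param fill_max Maximum fraction of the frame covered by cells, used to
#'   size the frame. Default 0.2.
#' @param max_attempts Placement attempts per cell before a density error.
#' @return An [image_pair()] whose `ground_truth` holds `n_cells`, per-cell
#'   analytic `areas_um2`, the label matrices of both channels and the
#'   generator settings.
#' @export
sim_image <- function(n_cells, mean_area_um2, nucleus_fraction = 0.16,
                      pixel_size = 0.5, snr = 10, seed = 1, fill_max = 0.2,
                      max_attempts = 400) {
  stopifnot(n_cells >= 0, mean_area_um2 > 0, nucleus_fraction > 0,
            nucleus_fraction < 1, snr > 0)
  with_seed(derive_seed(seed, 2L), {
    area_px_mean <- mean_area_um2 / pixel_size^2
    dim_px <- max(96L, ceiling(sqrt(max(n_cells, 1) * area_px_mean / fill_max)))
    if (n_cells > 0) {
      areas_um2 <- mean_area_um2 *
        pmax(0.4, stats::rnorm(n_cells, 1, 0.1))
      areas_px <- areas_um2 / pixel_size^2
      q <- stats::runif(n_cells, 0.6, 1)      # axis ratio b/a
      a <- sqrt(areas_px / (pi * q))
      b <- a * q
      phi <- stats::runif(n_cells, 0, pi)
      centers <- matrix(NA_real_, n_cells, 2)
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          cand <- stats::runif(2, a[i] + 2, dim_px - a[i] - 2)
          prev <- seq_len(i - 1L)
          if (i == 1L ||
              all(sqrt((centers[prev, 1] - cand[1])^2 +
                         (centers[prev, 2] - cand[2])^2) >
                    a[prev] + a[i] + 2)) {
            centers[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("cell packing failed: requested density too high", call. = FALSE)
      }
      cell_lab <- rasterize_ellipses(dim_px, centers, a, b, phi)
      s <- sqrt(nucleus_fraction)
      nuc_lab <- rasterize_ellipses(dim_px, centers, a * s, b * s, phi)
    } else {
      areas_um2 <- numeric(0)
      cell_lab <- nuc_lab <- matrix(0L, 96L, 96L)
      dim_px <- 96L
    }
    noise_sd <- 1 / snr
    cell <- pmax((cell_lab > 0) * 1 +
                   matrix(stats::rnorm(length(cell_lab), 0, noise_sd),
                          nrow(cell_lab)), 0)
    nuc <- pmax((nuc_lab > 0) * 1 +
                  matrix(stats::rnorm(length(nuc_lab), 0, noise_sd),
                         nrow(nuc_lab)), 0)
    image_pair(cell, nuc, pixel_size,
               ground_truth = list(
                 n_cells = n_cells, areas_um2 = areas_um2,
                 mean_area_um2 = mean_area_um2,
                 nucleus_fraction = nucleus_fraction,
                 cell_labels = cell_lab, nuclei_labels = nuc_lab,
                 snr = snr, seed = seed))
  })
}

#' Simulate a rigidity panel of spreading-area images
#'
#' One image per rigidity, with the generative mean per-cell area following
#' the saturating spreading law `area_max * tanh(alpha_A * xi)`: area grows
#' with rigidity and saturates above roughly 16 kPa.
#'
#' @param panel Substrate rigidities, kPa. Default `c(0.5, 2, 8, 16, 32, 64)`.
#' @param n_cells Cells per image. Default 15.
#' @param area_max Saturating mean per-cell area, um^2. Default 1200.
#' @param alpha_A Spreading tanh rate, 1/kPa. Default 0.2.
#' @param seed RNG seed (one substream per image).
#' @param ... Passed to [sim_image()] (`nucleus_fraction`, `pixel_size`,
#'   `snr`, ...).
#' @return List with `images` (named list of [image_pair()]) and `truth`
#'   (data.frame of rigidity and generative mean area).
#' @export
sim_rigidity_panel_images <- function(panel = c(0.5, 2, 8, 16, 32, 64),
                                      n_cells = 15, area_max = 1200,
                                      alpha_A = 0.2, seed = 1, ...) {
  mean_areas <- area_max * tanh(alpha_A * panel)
  images <- lapply(seq_along(panel), function(i) {
    sim_image(n_cells, mean_areas[i], seed = derive_seed(seed, 100L + i), ...)
  })
  names(images) <- sprintf("xi_%g_kpa", panel)
  list(images = images,
       truth = data.frame(rigidity_kpa = panel, mean_area_um2 = mean_areas,
                          n_cells = n_cells))
}
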