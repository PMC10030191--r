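#' Force-displacement record of a gel-cube compression test
#'
#' One parallel-plate compression trace of a (nominally cubic) polyacrylamide
#' sample, as produced by a micro-scale compression tester. Displacement is
#' platen travel from first contact; samples are compressed by at most 90% of
#' their pre-compression edge length.
#'
#' @param displacement Platen travel, um; strictly increasing, starting >= 0.
#' @param force Measured force, uN; same length as `displacement`.
#' @param side_pre Pre-compression cube edge length, um.
#' @param sample_id Optional label.
#' @return An object of class `compression_record`.
#' @export
compression_record <- function(displacement, force, side_pre,
                               sample_id = "sample") {
  if (!is.numeric(side_pre) || length(side_pre) != 1L || !is.finite(side_pre) ||
      side_pre <= 0)
    stop("'side_pre' must be a single positive edge length (um)",
         call. = FALSE)
  if (length(displacement) != length(force))
    stop("'displacement' and 'force' must have the same length", call. = FALSE)
  if (any(!is.finite(displacement)) || any(!is.finite(force)))
    stop("displacement and force must be finite", call. = FALSE)
  if (any(displacement < 0) || is.unsorted(displacement, strictly = TRUE))
    stop("'displacement' must be nonnegative and strictly increasing",
         call. = FALSE)
  if (max(displacement) > 0.9 * side_pre)
    stop("maximum displacement exceeds 90% of the pre-compression edge length",
         call. = FALSE)
  structure(list(displacement = displacement, force = force,
                 side_pre = side_pre, sample_id = sample_id),
            class = "compression_record")
}

# uN / um^2 = MPa; 1 MPa = 1000 kPa
UN_PER_UM2_TO_KPA <- 1000

#' Convert a compression trace to an engineering stress-strain curve
#'
#' Engineering conventions: strain is displacement over the pre-compression
#' edge length and stress is force over the pre-compression cross-section
#' (edge length squared), converted to kPa.
#'
#' @param rec A [compression_record()].
#' @return A data.frame of class `stress_strain_curve` with columns `strain`
#'   (dimensionless, in `[0, 0.9]`) and `stress` (kPa), plus a `side_pre`
#'   attribute.
#' @export
to_stress_strain <- function(rec) {
  if (!inherits(rec, "compression_record"))
    rec <- do.call(compression_record, rec)
  structure(
    data.frame(strain = rec$displacement / rec$side_pre,
               stress = rec$force / rec$side_pre^2 * UN_PER_UM2_TO_KPA),
    side_pre = rec$side_pre, sample_id = rec$sample_id,
    class = c("stress_strain_curve", "data.frame")
  )
}

#' Young's modulus from the low-strain region of a stress-strain curve
#'
#' Least-squares line through the points with strain in the elastic window,
#' intercept fixed at zero (stress vanishes at zero strain by construction),
#' so the slope is the Young's modulus. The default window `(0, 0.10]` targets
#' the linear-elastic regime up to 10% strain.
#'
#' @param curve A `stress_strain_curve` (or data.frame with `strain`,
#'   `stress`).
#' @param strain_window Length-2 numeric `(low, high]`; points with
#'   `low < strain <= high` enter the fit. Default `c(0, 0.10)`.
#' @param strain_offset Optional toe-region strain offset subtracted before
#'   fitting (contact artifacts); default 0.
#' @return An object of class `modulus_estimate`: list with `E_hat` (kPa),
#'   `stderr` (kPa), `n_points`, `strain_window`, `sample_id`.
#' @export
fit_young_modulus <- function(curve, strain_window = c(0, 0.10),
                              strain_offset = 0) {
  if (!all(c("strain", "stress") %in% names(curve)))
    stop("'curve' needs columns 'strain' and 'stress'", call. = FALSE)
  if (length(strain_window) != 2L || strain_window[1] >= strain_window[2])
    stop("'strain_window' must be (low, high) with low < high", call. = FALSE)
  strain <- curve$strain - strain_offset
  keep <- strain > strain_window[1] & strain <= strain_window[2]
  if (sum(keep) < 3L)
    stop("insufficient data: fewer than 3 points with strain in (",
         strain_window[1], ", ", strain_window[2], "]", call. = FALSE)
  fit <- stats::lm(stress ~ 0 + strain,
                   data = data.frame(strain = strain[keep],
                                     stress = curve$stress[keep]))
  # slope SE computed directly: summary.lm warns on noise-free fixtures
  rss <- sum(stats::residuals(fit)^2)
  se <- sqrt(rss / stats::df.residual(fit) / sum(strain[keep]^2))
  structure(list(E_hat = unname(stats::coef(fit)[1]), stderr = se,
                 n_points = sum(keep), strain_window = strain_window,
                 sample_id = attr(curve, "sample_id")),
            class = "modulus_estimate")
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf("Young's modulus: %.3f kPa (SE %.3f, %d points, strain (%g, %g])\n",
              x$E_hat, x$stderr, x$n_points,
              x$strain_window[1], x$strain_window[2]))
  invisible(x)
}

#' Replicate summary of per-sample Young's moduli
#'
#' @param estimates List of `modulus_estimate` objects (or a numeric vector of
#'   moduli in kPa).
#' @return List with `mean` (kPa), `sd` (kPa; 0 when a single estimate, with
#'   `n = 1` marking it undefined), and `n`.
#' @export
summarize_moduli <- function(estimates) {
  if (is.numeric(estimates)) {
    e <- estimates
  } else {
    if (length(estimates) == 0L)
      stop("no modulus estimates supplied", call. = FALSE)
    e <- vapply(estimates, function(x) x$E_hat, numeric(1))
  }
  if (length(e) == 0L) stop("no modulus estimates supplied", call. = FALSE)
  list(mean = mean(e), sd = if (length(e) > 1L) stats::sd(e) else 0,
       n = length(e))
}

#' Read a compression trace from CSV
#'
#' Expects columns `displacement_um` and `force_un`; the pre-compression edge
#' length is taken from a `side_pre_um` column (constant) or passed
#' explicitly.
#'
#' @param path CSV file path.
#' @param side_pre Pre-compression edge length, um; overrides any
#'   `side_pre_um` column.
#' @return A [compression_record()].
#' @export
read_compression_csv <- function(path, side_pre = NULL) {
  df <- utils::read.csv(path)
  if (is.null(side_pre)) {
    if (!"side_pre_um" %in% names(df))
      stop("no 'side_pre_um' column and no 'side_pre' argument", call. = FALSE)
    side_pre <- df$side_pre_um[1]
  }
  compression_record(df$displacement_um, df$force_un, side_pre,
                     sample_id = sub("\\.csv$", "", basename(path)))
}
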