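#' Two-channel fluorescence image of adherent cells
#'
#' Pairs a cell-body channel (e.g. phalloidin-stained actin) with a nuclear
#' channel (e.g. DAPI) over the same field of view. Channel-to-role mapping is
#' explicit: nothing is inferred from colour.
#'
#' @param cell_channel Numeric matrix of cell-body intensities, >= 0.
#' @param nuclei_channel Numeric matrix of nuclear intensities, same shape.
#' @param pixel_size Pixel edge length, um/pixel.
#' @param ground_truth Optional list attached by the synthetic generator
#'   (per-cell areas in um^2, masks, nucleus count).
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(cell_channel, nuclei_channel, pixel_size,
                       ground_truth = NULL) {
  if (!is.matrix(cell_channel) || !is.matrix(nuclei_channel))
    stop("channels must be matrices", call. = FALSE)
  if (!identical(dim(cell_channel), dim(nuclei_channel)))
    stop("channel shapes differ", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive um/pixel value", call. = FALSE)
  if (min(cell_channel) < 0 || min(nuclei_channel) < 0)
    stop("intensities must be nonnegative", call. = FALSE)
  structure(list(cell_channel = cell_channel,
                 nuclei_channel = nuclei_channel,
                 pixel_size = pixel_size, ground_truth = ground_truth),
            class = "image_pair")
}

#' Fraction of pixels above an intensity threshold
#'
#' The stained-area readout: the share of the image occupied by pixels
#' brighter than the threshold, i.e. the complement of the intensity-histogram
#' mass from zero up to the threshold.
#'
#' @param channel Numeric matrix of intensities.
#' @param threshold Intensity threshold; pixels strictly above it count.
#' @return Fraction in `[0, 1]`.
#' @export
pixel_fraction_above <- function(channel, threshold) {
  if (length(channel) == 0L) stop("empty raster", call. = FALSE)
  mean(channel > threshold)
}

#' Otsu threshold for one channel
#'
#' Histogram-based automatic threshold separating background from stain;
#' the default when no manual threshold is given, since manual per-image
#' choices are not reproducible.
#'
#' @param channel Numeric matrix of intensities.
#' @param levels Histogram bins used by the search. Default 256.
#' @return Threshold on the intensity scale of `channel`.
#' @export
otsu_threshold <- function(channel, levels = 256) {
  if (length(channel) == 0L) stop("empty raster", call. = FALSE)
  hi <- max(channel)
  if (hi <= 0) return(0)
  EBImage::otsu(EBImage::Image(channel / hi), range = c(0, 1),
                levels = levels) * hi
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]      # \ diagonal
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]     # / diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Count nuclei in the nuclear channel
#'
#' Number of 8-connected components of the above-threshold mask with at least
#' `min_size` pixels. Touching nuclei merge into one component (no watershed
#' splitting): counts are conservative on crowded fields.
#'
#' @param nuclei_channel Numeric matrix of nuclear-stain intensities.
#' @param threshold Intensity threshold; `NULL` (default) uses
#'   [otsu_threshold()].
#' @param min_size Minimum component size in pixels; default 20.
#' @return Integer count of nuclei.
#' @export
count_nuclei <- function(nuclei_channel, threshold = NULL, min_size = 20) {
  if (min_size < 1) stop("'min_size' must be >= 1", call. = FALSE)
  if (length(nuclei_channel) == 0L) stop("empty raster", call. = FALSE)
  if (is.null(threshold)) threshold <- otsu_threshold(nuclei_channel)
  mask <- nuclei_channel > threshold
  if (!any(mask)) return(0L)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_size)
}

#' Per-image cell-area report
#'
#' Threshold-based spreading-area quantification: cell and nuclear pixel
#' fractions, nucleus count, and mean exposed area per cell both including the
#' nucleus footprint and excluding it (cell mask minus nuclear mask).
#'
#' @param img An [image_pair()].
#' @param cell_threshold,nuclei_threshold Manual intensity thresholds; `NULL`
#'   (default) selects each per channel with [otsu_threshold()].
#' @param min_size Minimum nucleus size in pixels for counting; default 20.
#' @return A one-row data.frame of class `area_report`: `n_cells`,
#'   `cell_pixel_fraction`, `nuclei_pixel_fraction`, `area_per_cell_incl`
#'   (um^2), `area_per_cell_excl` (um^2).
#' @export
area_report <- function(img, cell_threshold = NULL, nuclei_threshold = NULL,
                        min_size = 20) {
  if (!inherits(img, "image_pair"))
    stop("'img' must be an image_pair", call. = FALSE)
  if (is.null(cell_threshold)) cell_threshold <- otsu_threshold(img$cell_channel)
  if (is.null(nuclei_threshold))
    nuclei_threshold <- otsu_threshold(img$nuclei_channel)
  cell_mask <- img$cell_channel > cell_threshold
  nuc_mask <- img$nuclei_channel > nuclei_threshold
  cell_frac <- mean(cell_mask)
  nuc_frac <- mean(nuc_mask)
  n_cells <- count_nuclei(img$nuclei_channel, nuclei_threshold, min_size)
  if (n_cells == 0L) {
    if (cell_frac > 0)
      stop("degenerate image: stained cell area but no countable nuclei",
           call. = FALSE)
    incl <- excl <- 0
  } else {
    px_area <- img$pixel_size^2
    incl <- sum(cell_mask) * px_area / n_cells
    excl <- sum(cell_mask & !nuc_mask) * px_area / n_cells
  }
  structure(
    data.frame(n_cells = n_cells, cell_pixel_fraction = cell_frac,
               nuclei_pixel_fraction = nuc_frac,
               area_per_cell_incl = incl, area_per_cell_excl = excl),
    thresholds = c(cell = cell_threshold, nuclei = nuclei_threshold),
    class = c("area_report", "data.frame")
  )
}

#' Read an image pair from TIFF files
#'
#' Accepts either two single-plane grayscale TIFFs or one two-plane TIFF with
#' an explicit channel-to-role mapping.
#'
#' @param cell_path TIFF with the cell-body channel (or a 2-plane TIFF).
#' @param nuclei_path TIFF with the nuclear channel; `NULL` if `cell_path` has
#'   two planes.
#' @param pixel_size Pixel edge length, um/pixel.
#' @param channels Integer pair giving (cell, nuclei) plane indices when a
#'   single multi-plane file is used. Default `c(1, 2)`.
#' @return An [image_pair()].
#' @export
read_image_pair <- function(cell_path, nuclei_path = NULL, pixel_size,
                            channels = c(1, 2)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF input", call. = FALSE)
  as_plane <- function(x) if (is.list(x)) x else list(x)
  cimg <- as_plane(tiff::readTIFF(cell_path, all = TRUE))
  if (is.null(nuclei_path)) {
    planes <- if (length(cimg) >= 2) cimg else {
      a <- cimg[[1]]
      if (length(dim(a)) == 3) lapply(seq_len(dim(a)[3]), function(i) a[, , i])
      else stop("single-plane TIFF but no 'nuclei_path' given", call. = FALSE)
    }
    cell <- planes[[channels[1]]]; nuc <- planes[[channels[2]]]
  } else {
    cell <- cimg[[1]]
    if (length(dim(cell)) == 3) cell <- cell[, , 1]
    nuc <- as_plane(tiff::readTIFF(nuclei_path, all = TRUE))[[1]]
    if (length(dim(nuc)) == 3) nuc <- nuc[, , 1]
  }
  image_pair(cell, nuc, pixel_size)
}
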