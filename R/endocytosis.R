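#' Generate a synthetic two-channel fluorescence image pair
#'
#' Emulates a wide-field field of view of macrophages: the nuclear channel
#' contains non-overlapping bright disks (Hoechst-stained nuclei) on a dim
#' background; the green channel contains a constant background plus, for
#' each cell, a uniform probe intensity deposited over the nucleus expanded
#' by `halo_px` pixels (the perinuclear compartment where endocytosed Hb:Hp
#' accumulates), plus Gaussian read noise. Complete ground truth is
#' returned.
#'
#' @param n_cells Number of cells to place.
#' @param width,height Image size in pixels.
#' @param radius_range Nuclear radius range in pixels (uniform).
#' @param min_gap_px Minimum edge-to-edge gap between nuclei.
#' @param nuclear_intensity,nuclear_bg Nuclear-channel levels (AU).
#' @param green_intensity_mean,green_intensity_cv Per-cell probe intensity:
#'   lognormal with this mean and CV (CV 0 gives identical cells).
#' @param background_AU Green-channel background level.
#' @param noise_sd Gaussian noise sd added to both channels.
#' @param halo_px Perinuclear halo width (pixels) over which probe signal
#'   extends beyond the nucleus.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param max_tries Placement retries per cell before giving up.
#' @return List with `nuclear`, `green` (matrices) and `truth` (centers,
#'   radii, per-cell intensity, background, seed).
#' @export
generate_image_pair <- function(n_cells = 25, width = 256, height = 256,
                                radius_range = c(5, 7), min_gap_px = 20,
                                nuclear_intensity = 200, nuclear_bg = 10,
                                green_intensity_mean = 50,
                                green_intensity_cv = 0,
                                background_AU = 5, noise_sd = 2,
                                halo_px = 8, seed = 1L, max_tries = 5000) {
  stopifnot(n_cells >= 0, width > 0, height > 0)
  set.seed(as.integer(seed))
  margin <- max(radius_range) + halo_px + 2
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      x <- stats::runif(1, margin, width - margin)
      y <- stats::runif(1, margin, height - margin)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) >=
              radii + r + min_gap_px)) {
        centers <- rbind(centers, c(x, y))
        radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n_cells, " non-overlapping cells; ",
           "reduce n_cells or min_gap_px")
    }
  }
  if (green_intensity_cv > 0 && n_cells > 0) {
    sdlog <- sqrt(log(1 + green_intensity_cv^2))
    intensities <- stats::rlnorm(n_cells,
                                 log(green_intensity_mean) - sdlog^2 / 2,
                                 sdlog)
  } else {
    intensities <- rep(green_intensity_mean, n_cells)
  }
  xs <- matrix(seq_len(width), nrow = width, ncol = height)
  ys <- matrix(seq_len(height), nrow = width, ncol = height, byrow = TRUE)
  nuclear <- matrix(nuclear_bg, width, height)
  green <- matrix(background_AU, width, height)
  for (i in seq_len(n_cells)) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    nuclear[d2 <= radii[i]^2] <- nuclear_intensity
    green[d2 <= (radii[i] + halo_px)^2] <- background_AU + intensities[i]
  }
  if (noise_sd > 0) {
    nuclear <- nuclear + matrix(stats::rnorm(width * height, 0, noise_sd),
                                width, height)
    green <- green + matrix(stats::rnorm(width * height, 0, noise_sd),
                            width, height)
  }
  nuclear[nuclear < 0] <- 0
  green[green < 0] <- 0
  list(nuclear = nuclear, green = green,
       truth = list(centers = centers, radii = radii,
                    intensity_AU = intensities,
                    background_AU = background_AU, halo_px = halo_px,
                    seed = seed))
}

#' Segment and count nuclei
#'
#' Global Otsu threshold on the (max-normalized) nuclear channel, connected
#' components, and an area filter. A constant image yields zero cells.
#'
#' @param nuclear_channel 2-D intensity matrix.
#' @param min_area_px,max_area_px Retained object area bounds in pixels.
#' @return List with `labels` (integer matrix, 0 = background, objects
#'   relabeled 1..count) and `count`.
#' @export
segment_nuclei <- function(nuclear_channel, min_area_px = 20,
                           max_area_px = Inf) {
  stopifnot(is.matrix(nuclear_channel), length(nuclear_channel) > 0,
            all(nuclear_channel >= 0))
  mx <- max(nuclear_channel)
  if (mx <= min(nuclear_channel)) {
    return(list(labels = matrix(0L, nrow(nuclear_channel),
                                ncol(nuclear_channel)), count = 0L))
  }
  norm <- nuclear_channel / mx
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  bw <- EBImage::Image(norm > th)
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  list(labels = out, count = length(keep))
}

# Expand each labeled nucleus by a disc of the given radius (grayscale
# dilation of the label map; generated images keep nuclei far enough apart
# that expanded regions do not collide).
dilate_labels <- function(labels, radius_px) {
  if (radius_px <= 0) return(labels)
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, shape = "disc")
  d <- EBImage::imageData(EBImage::dilate(EBImage::Image(labels), brush))
  matrix(as.integer(round(d)), nrow(labels), ncol(labels))
}

#' Per-cell green-channel intensity measurements
#'
#' Each cell's region is its nucleus label dilated by `dilation_radius_px`
#' (capturing the perinuclear probe signal); the measurement is the mean
#' green intensity over that region minus the scalar experiment background,
#' floored at 0.
#'
#' @param pair List with `nuclear` and `green` matrices (same shape).
#' @param labels Label matrix from [segment_nuclei()] on `pair$nuclear`.
#' @param dilation_radius_px Region expansion radius (default 8 px).
#' @param background_AU Scalar background from [estimate_background()].
#' @return List of class `hemopk_cells`: `cell_count`, `per_cell` (data
#'   frame with `cell`, `mean_AU`, `corrected_AU`), `mean_corrected_AU`.
#' @export
measure_cells <- function(pair, labels, dilation_radius_px = 8,
                          background_AU = 0) {
  stopifnot(identical(dim(pair$nuclear), dim(pair$green)))
  if (!identical(dim(labels), dim(pair$green))) {
    stop("label matrix shape does not match the image")
  }
  regions <- dilate_labels(labels, dilation_radius_px)
  n <- max(regions)
  if (n == 0) {
    per_cell <- data.frame(cell = integer(0), mean_AU = numeric(0),
                           corrected_AU = numeric(0))
  } else {
    means <- vapply(seq_len(n), function(i) mean(pair$green[regions == i]),
                    numeric(1))
    per_cell <- data.frame(cell = seq_len(n), mean_AU = means,
                           corrected_AU = pmax(means - background_AU, 0))
  }
  structure(list(cell_count = n, per_cell = per_cell,
                 mean_corrected_AU = if (n) mean(per_cell$corrected_AU)
                                     else NA_real_),
            class = "hemopk_cells")
}

#' Estimate the experiment background from no-probe controls
#'
#' Mean green intensity over the (dilated) cell regions of control image
#' pairs acquired without any fluorescent protein; averaged across control
#' images. If no cells are found in any control the whole-image mean is
#' used instead, flagged via attribute `fallback`.
#'
#' @param control_pairs List of image pairs (each with `nuclear`, `green`).
#' @param dilation_radius_px Region expansion radius, as in
#'   [measure_cells()].
#' @param ... Passed to [segment_nuclei()].
#' @return Scalar background in AU.
#' @export
estimate_background <- function(control_pairs, dilation_radius_px = 8, ...) {
  stopifnot(length(control_pairs) >= 1)
  vals <- vapply(control_pairs, function(pair) {
    seg <- segment_nuclei(pair$nuclear, ...)
    if (seg$count == 0) return(NA_real_)
    regions <- dilate_labels(seg$labels, dilation_radius_px)
    mean(pair$green[regions > 0])
  }, numeric(1))
  if (all(is.na(vals))) {
    warning("no cells found in any control image; using whole-image mean")
    bg <- mean(vapply(control_pairs, function(p) mean(p$green), numeric(1)))
    return(structure(bg, fallback = TRUE))
  }
  mean(vals, na.rm = TRUE)
}

#' Summarize per-cell uptake over a sample's images
#'
#' Segments and measures every image pair of one sample (cover slip), pools
#' all cells, and reports the cell count, mean background-corrected per-cell
#' intensity, and its SEM.
#'
#' @param pairs List of image pairs.
#' @param background_AU Scalar background, from [estimate_background()].
#' @param dilation_radius_px Region expansion radius.
#' @param ... Passed to [segment_nuclei()].
#' @return List of class `hemopk_sample`: `n_images`, `n_cells`,
#'   `mean_corrected_AU`, `sem_corrected_AU`, `per_cell` (pooled data frame
#'   with an `image` column). Zero cells across all images yields `NA`
#'   summaries with a warning.
#' @export
summarize_sample <- function(pairs, background_AU, dilation_radius_px = 8,
                             ...) {
  stopifnot(length(pairs) >= 1)
  per_image <- lapply(seq_along(pairs), function(i) {
    seg <- segment_nuclei(pairs[[i]]$nuclear, ...)
    m <- measure_cells(pairs[[i]], seg$labels, dilation_radius_px,
                       background_AU)
    if (m$cell_count == 0) return(NULL)
    cbind(image = i, m$per_cell)
  })
  pooled <- do.call(rbind, per_image)
  if (is.null(pooled) || nrow(pooled) == 0) {
    warning("no cells found in any image of the sample")
    return(structure(list(n_images = length(pairs), n_cells = 0L,
                          mean_corrected_AU = NA_real_,
                          sem_corrected_AU = NA_real_,
                          per_cell = NULL), class = "hemopk_sample"))
  }
  v <- pooled$corrected_AU
  structure(list(n_images = length(pairs), n_cells = nrow(pooled),
                 mean_corrected_AU = mean(v),
                 sem_corrected_AU = if (length(v) > 1)
                   stats::sd(v) / sqrt(length(v)) else NA_real_,
                 per_cell = pooled),
            class = "hemopk_sample")
}
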