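#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence frame by grayscale
#' morphological opening with a disc element of the given radius (the
#' rolling-ball construction) and subtracts it. For large radii the
#' estimate is computed on a downscaled copy of the frame and resampled
#' back, the standard acceleration for well-scale images; the radius is in
#' pixels and therefore depends on pixel size. Output is non-negative and
#' the operation is idempotent up to interpolation tolerance.
#'
#' @param frame numeric matrix (AU).
#' @param radius ball radius in pixels (default 150, the whole-well
#'   screening setting); must be positive and smaller than the smallest
#'   image dimension.
#' @return background-subtracted matrix; the estimated background is
#'   attached as attribute `background`.
#' @export
subtract_background <- function(frame, radius = 150) {
  check_frame(frame)
  if (radius <= 0) stop("radius must be positive")
  if (radius >= min(dim(frame)))
    stop("radius must be smaller than the smallest image dimension")
  bg <- rolling_ball_background(frame, radius)
  out <- pmax(frame - bg, 0)
  attr(out, "background") <- bg
  out
}

rolling_ball_background <- function(frame, radius) {
  top <- max(frame, 65535)
  img <- frame / top                       # EBImage grayscale wants [0,1]
  shrink <- if (radius <= 20) 1L else as.integer(min(8, floor(radius / 20)))
  if (shrink > 1L) {
    small <- EBImage::resize(EBImage::Image(img),
                             w = ceiling(nrow(img) / shrink),
                             h = ceiling(ncol(img) / shrink))
    r_small <- max(1, round(radius / shrink))
    op <- EBImage::opening(small, EBImage::makeBrush(2L * r_small + 1L, "disc"))
    bg <- as.matrix(EBImage::resize(op, w = nrow(img), h = ncol(img)))
  } else {
    bg <- as.matrix(EBImage::opening(EBImage::Image(img),
                                     EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                                        "disc")))
  }
  pmin(bg, img) * top                      # background never exceeds signal
}

check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame) || !length(frame))
    stop("frame must be a non-empty numeric matrix")
  if (any(frame < 0, na.rm = TRUE) || any(frame > 65535, na.rm = TRUE))
    stop("frame intensities must lie within the 16-bit range")
  invisible(frame)
}

#' Whole-well mean intensity
#'
#' Arithmetic mean over all pixels of a background-subtracted frame — the
#' primary-screen readout is computed on a whole-well basis rather than per
#' cell.
#'
#' @param frame numeric matrix.
#' @return mean intensity (AU).
#' @export
measure_well_intensity <- function(frame) {
  check_frame(frame)
  mean(frame)
}

#' Cell-occupied area fraction
#'
#' Fraction of pixels above an adaptive (Otsu) threshold on a
#' background-subtracted frame; the toxicity metric. A frame with no
#' dynamic range (blank well) scores 0.
#'
#' @param frame background-subtracted numeric matrix.
#' @param threshold_method `"otsu"` (adaptive) or a numeric cutoff in AU.
#' @return occupied fraction in `[0, 1]`.
#' @export
measure_cell_area <- function(frame, threshold_method = "otsu") {
  check_frame(frame)
  if (diff(range(frame)) == 0) return(0)
  # Otsu on log intensities of positive pixels: the log compresses the
  # bright nucleus/puncta tail so the dominant split is background vs cell,
  # and dropping clipped zeros keeps the histogram bimodal
  th <- if (is.numeric(threshold_method)) threshold_method
        else log_otsu(frame)
  mean(frame > th)
}

# Otsu threshold computed on the log of the positive intensities
log_otsu <- function(x) {
  v <- as.numeric(x)
  v <- v[v > 0]
  if (!length(v) || diff(range(v)) == 0) return(max(x))
  exp(vec_otsu(log(v)))
}

# Otsu threshold on a numeric vector (256-bin histogram)
vec_otsu <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / nbins * diff(r)
}

#' Segment a field into nuclear and cytoplasmic compartments
#'
#' Two-threshold segmentation on the summed, smoothed channels: an Otsu
#' threshold separates cells from background, a second Otsu pass within the
#' cell mask separates bright nuclei from cytoplasm; nuclei seed a
#' Voronoi-style propagation that splits touching cells. Saturated or blank
#' fields return an empty, low-confidence result rather than an error.
#'
#' @param green,red registered numeric matrices.
#' @param smooth_sigma Gaussian presmoothing sigma (px).
#' @return list of class `opl_segmentation`: `nuclear_mask` and
#'   `cytoplasm_mask` (integer label matrices with matching cell labels,
#'   disjoint per cell), `cell_count`, `low_confidence` flag.
#' @export
segment_cells <- function(green, red, smooth_sigma = 2) {
  check_frame(green); check_frame(red)
  stopifnot(all(dim(green) == dim(red)))
  img <- (green + red) / 2
  degenerate <- diff(range(img)) < 1 || mean(img >= 65534) > 0.5
  if (degenerate) {
    z <- matrix(0L, nrow(img), ncol(img))
    return(structure(list(nuclear_mask = z, cytoplasm_mask = z,
                          cell_count = 0L, low_confidence = TRUE),
                     class = "opl_segmentation"))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img / 65535), smooth_sigma))
  th_cell <- log_otsu(sm)
  cellmask <- sm > th_cell
  th_nuc <- vec_otsu(sm[cellmask])
  nucmask <- sm > th_nuc & cellmask
  # the opening element must exceed the puncta footprint so bright puncta
  # cannot seed spurious nuclei, while staying below the nuclear diameter
  nucmask <- as.matrix(EBImage::opening(EBImage::Image(nucmask * 1),
                                        EBImage::makeBrush(11, "disc"))) > 0
  seeds <- EBImage::bwlabel(EBImage::Image(nucmask * 1))
  cells <- EBImage::propagate(EBImage::Image(sm), seeds,
                              mask = EBImage::Image(cellmask))
  nuclear_mask <- matrix(as.integer(as.matrix(seeds)), nrow(img))
  cell_labels <- matrix(as.integer(as.matrix(cells)), nrow(img))
  cytoplasm_mask <- cell_labels
  cytoplasm_mask[nuclear_mask > 0] <- 0L
  n <- max(nuclear_mask)
  structure(list(nuclear_mask = nuclear_mask,
                 cytoplasm_mask = cytoplasm_mask,
                 cell_count = as.integer(n),
                 low_confidence = n == 0L),
            class = "opl_segmentation")
}

#' @export
print.opl_segmentation <- function(x, ...) {
  cat("Segmentation:", x$cell_count, "cells",
      if (x$low_confidence) "(low confidence)" else "", "\n")
  invisible(x)
}

#' Detect LC3-like puncta in one channel
#'
#' Enhances puncta against the cytoplasmic background with a white top-hat
#' transform, thresholds at `median + c * MAD` of the enhanced signal within
#' the cytoplasm, labels connected components and applies an area gate.
#' Each punctum is assigned to the nuclear or cytoplasmic compartment of
#' its centroid.
#'
#' @param frame numeric matrix (background-subtracted or raw; the top-hat
#'   removes smooth structure either way).
#' @param segmentation an [segment_cells()] result.
#' @param params list: `scale` (top-hat element radius, px), `c` (MAD
#'   multiplier), `min_area`, `max_area` (px).
#' @param channel channel label recorded on the detected objects.
#' @return list of class `opl_puncta`: `puncta` data.frame (`x, y, area,
#'   mean_intensity, compartment, channel`; 0-based centroid coordinates),
#'   `label_image`, `channel`.
#' @export
detect_puncta <- function(frame, segmentation,
                          params = list(scale = 3, c = 5,
                                        min_area = 3, max_area = 120),
                          channel = NA_character_) {
  check_frame(frame)
  p <- modifyList(list(scale = 3, c = 5, min_area = 3, max_area = 120),
                  params)
  if (p$min_area > p$max_area)
    stop("degenerate size gate: min_area exceeds max_area")
  inside <- segmentation$cytoplasm_mask > 0 | segmentation$nuclear_mask > 0
  th_img <- as.matrix(EBImage::whiteTopHat(
    EBImage::Image(frame / 65535),
    EBImage::makeBrush(2L * as.integer(p$scale) + 1L, "disc"))) * 65535
  cyt <- th_img[segmentation$cytoplasm_mask > 0]
  if (!length(cyt)) {
    return(structure(list(puncta = empty_puncta(), channel = channel,
                          label_image = matrix(0L, nrow(frame), ncol(frame))),
                     class = "opl_puncta"))
  }
  cutoff <- median(cyt) + p$c * mad(cyt)
  mask <- th_img > cutoff & inside
  labels <- matrix(as.integer(as.matrix(
    EBImage::bwlabel(EBImage::Image(mask * 1)))), nrow(frame))
  if (max(labels) == 0) {
    return(structure(list(puncta = empty_puncta(), channel = channel,
                          label_image = labels), class = "opl_puncta"))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(frame)) + 1
  cols <- ((idx - 1) %/% nrow(frame)) + 1
  area <- tabulate(lab)
  keep <- which(area >= p$min_area & area <= p$max_area)
  if (!length(keep)) {
    labels[] <- 0L
    return(structure(list(puncta = empty_puncta(), channel = channel,
                          label_image = labels), class = "opl_puncta"))
  }
  cy <- tapply(rows, lab, mean)[as.character(keep)] - 1   # 0-based y
  cx <- tapply(cols, lab, mean)[as.character(keep)] - 1   # 0-based x
  mi <- tapply(frame[idx], lab, mean)[as.character(keep)]
  cen_r <- pmin(pmax(round(cy) + 1, 1), nrow(frame))
  cen_c <- pmin(pmax(round(cx) + 1, 1), ncol(frame))
  comp <- ifelse(segmentation$nuclear_mask[cbind(cen_r, cen_c)] > 0,
                 "nuclear", "cytoplasmic")
  relab <- labels
  relab[!(labels %in% keep)] <- 0L
  new_id <- match(relab, keep, nomatch = 0L)
  relab <- matrix(as.integer(new_id), nrow(frame))
  puncta <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                       area = area[keep], mean_intensity = as.numeric(mi),
                       compartment = comp, channel = channel,
                       stringsAsFactors = FALSE)
  rownames(puncta) <- NULL
  structure(list(puncta = puncta, channel = channel, label_image = relab),
            class = "opl_puncta")
}

empty_puncta <- function() {
  data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
             mean_intensity = numeric(0), compartment = character(0),
             channel = character(0), stringsAsFactors = FALSE)
}

#' @export
print.opl_puncta <- function(x, ...) {
  cat("Puncta set:", nrow(x$puncta), "objects (",
      sum(x$puncta$compartment == "cytoplasmic"), "cytoplasmic )\n")
  if (!is.null(x$colocalized_count))
    cat("  colocalized:", x$colocalized_count, "fraction:",
        signif(x$colocalized_fraction, 3), "\n")
  invisible(x)
}

#' Object colocalization of red and green puncta
#'
#' A cytoplasmic red punctum counts as colocalized ("yellow") when its pixel
#' overlap with any green punctum covers at least `overlap` of its own
#' area. The fraction is colocalized count over cytoplasmic red count, and
#' is undefined (NA, flagged) when there are no cytoplasmic red puncta.
#'
#' @param red_puncta,green_puncta [detect_puncta()] results from the same
#'   registered field.
#' @param overlap required fractional overlap of the red object (default
#'   0.5).
#' @return `red_puncta` with a logical `colocalized` column on `$puncta`
#'   plus `colocalized_count`, `colocalized_fraction` and
#'   `fraction_undefined` fields.
#' @export
colocalize_puncta <- function(red_puncta, green_puncta, overlap = 0.5) {
  stopifnot(inherits(red_puncta, "opl_puncta"),
            inherits(green_puncta, "opl_puncta"))
  rl <- red_puncta$label_image
  gl <- green_puncta$label_image
  stopifnot(all(dim(rl) == dim(gl)))
  n <- nrow(red_puncta$puncta)
  coloc <- logical(n)
  if (n > 0) {
    green_bin <- gl > 0
    idx <- which(rl > 0)
    if (length(idx)) {
      ov <- tapply(green_bin[idx], rl[idx], mean)
      got <- as.integer(names(ov))
      coloc[got] <- ov >= overlap
    }
  }
  red_puncta$puncta$colocalized <- coloc
  cyto <- red_puncta$puncta$compartment == "cytoplasmic"
  count <- sum(coloc & cyto)
  red_puncta$colocalized_count <- count
  red_puncta$fraction_undefined <- sum(cyto) == 0
  red_puncta$colocalized_fraction <-
    if (sum(cyto) == 0) NA_real_ else count / sum(cyto)
  red_puncta
}

#' Write a puncta object table to CSV
#'
#' One row per punctum: `field, channel, compartment, x, y, area,
#' mean_intensity, colocalized`.
#'
#' @param puncta an `opl_puncta` (after [colocalize_puncta()] if
#'   colocalization is wanted).
#' @param path output CSV.
#' @param field field identifier stored in the first column.
#' @param metadata optional `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(puncta, path, field = "field01",
                             metadata = NULL) {
  df <- puncta$puncta
  df$colocalized <- df$colocalized %||% NA
  out <- data.frame(field = field, channel = df$channel,
                    compartment = df$compartment, x = df$x, y = df$y,
                    area = df$area, mean_intensity = df$mean_intensity,
                    colocalized = df$colocalized)
  write_csv_with_header(out, path, metadata)
}
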