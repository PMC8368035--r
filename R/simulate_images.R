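#' Default synthetic field configuration
#'
#' Parameters for [generate_images()]: field geometry, cell and nucleus
#' sizes, channel intensity levels (16-bit AU), puncta counts and profile,
#' background gradient and additive noise.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
field_config <- function(...) {
  cfg <- list(
    width = 400L, height = 400L,
    n_cells = 25L,
    cell_radius = 24, nucleus_radius = 10,
    bg_level = 300, gradient_amp = 400,     # smooth background plane
    cyto_level = 1200, nuc_level = 3000,    # added above background
    puncta_amplitude = 6000, puncta_sigma = 1.5,
    n_red_puncta = 50L, n_green_extra = 20L, n_nuclear_red = 0L,
    min_puncta_sep = 7,                     # px between distinct puncta
    noise_sd = 40
  )
  modifyList(cfg, list(...))
}

#' Generate a registered two-channel synthetic microscopy field
#'
#' Draws a 16-bit green/red image pair containing cells (bright nuclei
#' inside dimmer cytoplasmic disks), a smooth background gradient,
#' Gaussian-profile LC3-like puncta and additive noise, together with a
#' ground-truth object table. A fraction `planted_colocalization` of the
#' cytoplasmic red puncta is co-drawn in the green channel (the
#' "yellow", unacidified-autophagosome population); remaining red puncta
#' have no green partner and extra green-only puncta are placed away from
#' all red puncta.
#'
#' @param config a [field_config()] list.
#' @param planted_colocalization fraction in `[0, 1]` of cytoplasmic red
#'   puncta that are also green; the planted count is
#'   `round(frac * n_red_puncta)`.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return list of class `opl_field`: `green` and `red` (numeric matrices,
#'   AU in `[0, 65535]`, row = y, column = x), `puncta` (truth table:
#'   `channel, x, y, cell, compartment, colocalized` with 0-based
#'   upper-left-origin pixel coordinates), `cells` (centers and radii),
#'   `cell_area_fraction` (planted), and `config`.
#' @examples
#' fld <- generate_images(field_config(n_cells = 4L, n_red_puncta = 8L),
#'                        planted_colocalization = 0.5, seed = 1)
#' @export
generate_images <- function(config = field_config(),
                            planted_colocalization = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (planted_colocalization < 0 || planted_colocalization > 1)
    stop("planted_colocalization must lie in [0, 1]")
  cfg <- config
  stopifnot(cfg$width > 0, cfg$height > 0, cfg$n_cells >= 0,
            cfg$n_red_puncta >= 0)
  set.seed(derive_seed(seed, "field"))

  # jittered-grid cell placement keeps cells non-touching
  gdim <- ceiling(sqrt(cfg$n_cells))
  pitch <- min(cfg$width, cfg$height) / max(gdim, 1)
  if (cfg$n_cells > 0 && pitch < 2 * cfg$cell_radius + 4)
    stop("too many cells for the field size at this cell radius")
  centers <- NULL
  if (cfg$n_cells > 0) {
    slots <- expand.grid(gx = seq_len(gdim), gy = seq_len(gdim))
    slots <- slots[sample.int(nrow(slots), cfg$n_cells), , drop = FALSE]
    jit <- pitch / 2 - cfg$cell_radius - 2
    centers <- data.frame(
      cell = seq_len(cfg$n_cells),
      cx = (slots$gx - 0.5) * pitch + runif(cfg$n_cells, -jit, jit),
      cy = (slots$gy - 0.5) * pitch + runif(cfg$n_cells, -jit, jit))
  }

  xs <- matrix(rep(seq_len(cfg$width) - 1, each = cfg$height),
               nrow = cfg$height)
  ys <- matrix(rep(seq_len(cfg$height) - 1, times = cfg$width),
               nrow = cfg$height)
  base <- cfg$bg_level + cfg$gradient_amp *
    (xs / cfg$width + 0.5 * ys / cfg$height)

  cellmat <- matrix(0, cfg$height, cfg$width)
  nucmat <- matrix(0, cfg$height, cfg$width)
  if (!is.null(centers)) {
    for (i in seq_len(nrow(centers))) {
      d2 <- (xs - centers$cx[i])^2 + (ys - centers$cy[i])^2
      cellmat[d2 <= cfg$cell_radius^2] <- cfg$cyto_level
      nucmat[d2 <= cfg$nucleus_radius^2] <- cfg$nuc_level
    }
  }

  place_puncta <- function(n, existing, compartment = "cytoplasmic") {
    if (n == 0 || is.null(centers)) return(existing[0, , drop = FALSE])
    placed <- existing
    out <- NULL
    tries <- 0
    while (is.null(out) || nrow(out) < n) {
      if ((tries <- tries + 1) > 200 * n)
        stop("could not place puncta with the requested separation")
      ci <- sample.int(nrow(centers), 1)
      if (compartment == "cytoplasmic") {
        rr <- runif(1, cfg$nucleus_radius + 3, cfg$cell_radius - 3)
      } else {
        rr <- runif(1, 0, max(cfg$nucleus_radius - 3, 1))
      }
      th <- runif(1, 0, 2 * pi)
      px <- centers$cx[ci] + rr * cos(th)
      py <- centers$cy[ci] + rr * sin(th)
      if (px < 3 || py < 3 || px > cfg$width - 4 || py > cfg$height - 4) next
      if (nrow(placed) &&
          min((placed$x - px)^2 + (placed$y - py)^2) < cfg$min_puncta_sep^2)
        next
      row <- data.frame(x = px, y = py, cell = ci, compartment = compartment)
      placed <- rbind(placed[, c("x", "y", "cell", "compartment")], row)
      out <- rbind(out, row)
    }
    out
  }

  empty <- data.frame(x = numeric(0), y = numeric(0), cell = integer(0),
                      compartment = character(0))
  red_cyto <- place_puncta(cfg$n_red_puncta, empty)
  red_nuc <- place_puncta(cfg$n_nuclear_red,
                          rbind(empty, red_cyto), "nuclear")
  n_coloc <- round(planted_colocalization * nrow(red_cyto))
  coloc_idx <- if (nrow(red_cyto)) sample.int(nrow(red_cyto), n_coloc) else integer(0)
  green_extra <- place_puncta(cfg$n_green_extra, rbind(red_cyto, red_nuc))

  draw <- function(img, pts) {
    for (i in seq_len(nrow(pts))) {
      w <- ceiling(4 * cfg$puncta_sigma)
      x0 <- round(pts$x[i]); y0 <- round(pts$y[i])
      cx <- max(1, x0 - w + 1):min(cfg$width, x0 + w + 1)
      cy <- max(1, y0 - w + 1):min(cfg$height, y0 + w + 1)
      d2 <- outer((cy - 1) - pts$y[i], (cx - 1) - pts$x[i],
                  function(a, b) a^2 + b^2)
      img[cy, cx] <- img[cy, cx] +
        cfg$puncta_amplitude * exp(-d2 / (2 * cfg$puncta_sigma^2))
    }
    img
  }

  red <- base + cellmat + nucmat
  red <- draw(red, rbind(red_cyto, red_nuc))
  green <- base + cellmat + nucmat
  if (length(coloc_idx)) green <- draw(green, red_cyto[coloc_idx, ])
  green <- draw(green, green_extra)

  clip16 <- function(img)
    pmin(pmax(round(img + rnorm(length(img), 0, cfg$noise_sd)), 0), 65535)
  red <- clip16(red); green <- clip16(green)

  truth <- rbind(
    if (nrow(red_cyto)) data.frame(channel = "red", red_cyto,
      colocalized = seq_len(nrow(red_cyto)) %in% coloc_idx),
    if (nrow(red_nuc)) data.frame(channel = "red", red_nuc,
      colocalized = FALSE),
    if (length(coloc_idx)) data.frame(channel = "green",
      red_cyto[coloc_idx, ], colocalized = TRUE),
    if (nrow(green_extra)) data.frame(channel = "green", green_extra,
      colocalized = FALSE))
  cell_px <- if (is.null(centers)) 0 else sum(cellmat > 0 | nucmat > 0)
  out <- list(green = green, red = red,
              puncta = truth[, c("channel", "x", "y", "cell",
                                 "compartment", "colocalized")],
              cells = centers,
              cell_area_fraction = cell_px / (cfg$width * cfg$height),
              config = cfg, seed = seed)
  class(out) <- "opl_field"
  out
}

#' @export
print.opl_field <- function(x, ...) {
  cat("Synthetic field:", x$config$width, "x", x$config$height, "px,",
      if (is.null(x$cells)) 0 else nrow(x$cells), "cells,",
      nrow(x$puncta), "planted puncta\n")
  invisible(x)
}

#' Write a single-channel frame as 16-bit grayscale TIFF
#'
#' @param frame numeric matrix in AU (0-65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  tiff::writeTIFF(pmin(pmax(frame, 0), 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF into an AU matrix
#'
#' @param path TIFF path.
#' @return numeric matrix scaled back to 0-65535.
#' @export
read_frame_tiff <- function(path) {
  tiff::readTIFF(path) * 65535
}
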