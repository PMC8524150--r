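## Immediate-early-gene quantification: synthetic sections, threshold
## calibration, particle detection with size/roundness filters, densities.

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# Points and polygon share the 0-based pixel coordinate system.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# TRUE when any two non-adjacent edges of the closed polygon cross.
polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (segmentsIntersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                            poly[idx[j, 1], ], poly[idx[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Construct a section image
#'
#' @param pixels Numeric/integer matrix of 8-bit gray values (rows = y).
#' @param pixel_size Pixel edge length in mm (default 0.001, the synthetic
#'   stand-in for the 100x imaging setup).
#' @param roi n x 2 polygon of (x, y) pixel coordinates; defaults to the
#'   full image frame.
#' @param area_label,hemisphere,slice_position,subject_id Annotations.
#' @param ground_truth Planted-cell table for synthetic sections.
#' @return A [SectionImage-class].
#' @export
sectionImage <- function(pixels, pixel_size = 0.001, roi = NULL,
                         area_label = "CPi", hemisphere = "left",
                         slice_position = NA_real_, subject_id = "S01",
                         ground_truth = data.frame()) {
  pixels <- round(pixels)
  storage.mode(pixels) <- "integer"
  if (is.null(roi)) {
    w <- ncol(pixels); h <- nrow(pixels)
    roi <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  }
  new("SectionImage", pixels = pixels, pixel_size = pixel_size,
      roi = roi, area_label = area_label, hemisphere = hemisphere,
      slice_position = slice_position, subject_id = subject_id,
      ground_truth = ground_truth)
}

setMethod("show", "SectionImage", function(object) {
  cat(sprintf("SectionImage %s/%s/%s: %d x %d px @ %g mm/px, ROI %.4f mm^2",
              object@subject_id, object@area_label, object@hemisphere,
              ncol(object@pixels), nrow(object@pixels), object@pixel_size,
              roiAreaPx(object) * object@pixel_size^2))
  if (nrow(object@ground_truth))
    cat(sprintf(", %d planted cells", nrow(object@ground_truth)))
  cat("\n")
})

setMethod("show", "ThresholdBand", function(object) {
  cat(sprintf("ThresholdBand: stain intensity [%g, %g]\n",
              object@lower, object@upper))
})

#' Number of raster pixels inside the ROI
#'
#' Counts pixels whose center lies inside the ROI polygon (even-odd rule).
#'
#' @param image A [SectionImage-class].
#' @return Integer pixel count.
#' @export
roiAreaPx <- function(image) {
  h <- nrow(image@pixels); w <- ncol(image@pixels)
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  sum(pointInPolygon(cx, cy, image@roi))
}

#' Generate a synthetic stained section with ground truth
#'
#' Plants `n_cells` non-overlapping elliptical "nuclei" of known size,
#' elongation, orientation and stain intensity inside the ROI of a light
#' background image with Gaussian background noise (dark cells on light
#' background, as in DAB-stained material). Cell pixels carry the exact
#' planted stain intensity so that a threshold band calibrated from the
#' ground truth captures them; the noise models background stain
#' variability. Deterministic given the seed.
#'
#' @param n_cells Number of cells to plant.
#' @param width,height Image size in px.
#' @param pixel_size Pixel edge in mm.
#' @param roi Polygon; defaults to the frame inset by `margin` px.
#' @param margin Frame inset for the default ROI.
#' @param radius_mean,radius_sd Semi-major axis distribution (px); the
#'   defaults keep planted cells safely above the 15-px size filter.
#' @param elongation_mean,elongation_sd Axis-ratio (a/b) distribution.
#' @param intensity_mean,intensity_sd Stain peak distribution (8-bit).
#' @param background_mean,noise_sd Background stain level and noise SD.
#' @param seed Integer seed.
#' @param area_label,hemisphere,slice_position,subject_id Annotations.
#' @param max_attempts Placement attempts before a generation error.
#' @return A [SectionImage-class] with exact `ground_truth`.
#' @export
generateSyntheticSection <- function(n_cells, width = 192, height = 192,
                                     pixel_size = 0.001, roi = NULL,
                                     margin = 8,
                                     radius_mean = 4.5, radius_sd = 0.5,
                                     elongation_mean = 1.3, elongation_sd = 0.15,
                                     intensity_mean = 160, intensity_sd = 25,
                                     background_mean = 15, noise_sd = 4,
                                     seed = 1L, area_label = "CPi",
                                     hemisphere = "left",
                                     slice_position = NA_real_,
                                     subject_id = "S01",
                                     max_attempts = 200 * max(n_cells, 1)) {
  if (is.null(roi))
    roi <- cbind(c(margin, width - margin, width - margin, margin),
                 c(margin, margin, height - margin, height - margin))
  withSeed(seed, {
    gt <- data.frame(x = numeric(), y = numeric(), a = numeric(),
                     b = numeric(), theta = numeric(), peak = numeric())
    attempts <- 0
    while (nrow(gt) < n_cells) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("could not place ", n_cells,
             " non-overlapping cells inside the ROI")
      a <- max(rnorm(1, radius_mean, radius_sd), 1.2)
      b <- a / max(rnorm(1, elongation_mean, elongation_sd), 1)
      x <- runif(1, min(roi[, 1]), max(roi[, 1]))
      y <- runif(1, min(roi[, 2]), max(roi[, 2]))
      # whole cell inside the ROI: center plus compass points at radius a
      probe_x <- x + c(0, a, -a, 0, 0); probe_y <- y + c(0, 0, 0, a, -a)
      if (!all(pointInPolygon(probe_x, probe_y, roi))) next
      if (nrow(gt) &&
          any(sqrt((gt$x - x)^2 + (gt$y - y)^2) < gt$a + a + 2)) next
      peak <- min(max(round(rnorm(1, intensity_mean, intensity_sd)), 30), 255)
      gt <- rbind(gt, data.frame(x = x, y = y, a = a, b = b,
                                 theta = runif(1, 0, pi), peak = peak))
    }
    stain <- matrix(pmax(rnorm(height * width, background_mean, noise_sd), 0),
                    nrow = height)
    for (k in seq_len(nrow(gt))) {
      xs <- seq(max(1, floor(gt$x[k] - gt$a[k])),
                min(width, ceiling(gt$x[k] + gt$a[k]) + 1))
      ys <- seq(max(1, floor(gt$y[k] - gt$a[k])),
                min(height, ceiling(gt$y[k] + gt$a[k]) + 1))
      dx <- outer(rep(1, length(ys)), xs - 0.5 - gt$x[k])
      dy <- outer(ys - 0.5 - gt$y[k], rep(1, length(xs)))
      ct <- cos(gt$theta[k]); st <- sin(gt$theta[k])
      u <- dx * ct + dy * st
      v <- -dx * st + dy * ct
      inside <- (u / gt$a[k])^2 + (v / gt$b[k])^2 <= 1
      sub <- stain[ys, xs, drop = FALSE]
      sub[inside] <- gt$peak[k]
      stain[ys, xs] <- sub
    }
    px <- 255 - pmin(pmax(round(stain), 0), 255)
    sectionImage(px, pixel_size = pixel_size, roi = roi,
                 area_label = area_label, hemisphere = hemisphere,
                 slice_position = slice_position, subject_id = subject_id,
                 ground_truth = gt)
  })
}

#' Calibrate the staining threshold band from control sections
#'
#' Mirrors the calibration on the control region: the lower threshold is
#' the minimum stain peak among weak exemplar cells and the upper threshold
#' the maximum among intensely stained exemplars; with ground-truth
#' sections all planted peaks serve as exemplars. The band is then frozen
#' for every image of the run.
#'
#' @param control_sections List of [SectionImage-class] objects carrying
#'   ground truth, or NULL when `exemplar_peaks` is given.
#' @param exemplar_peaks Optional numeric vector of user-marked exemplar
#'   stain intensities (weak and intense).
#' @return A [ThresholdBand-class].
#' @examples
#' calibrateThresholds(exemplar_peaks = c(60, 200))  # band [60, 200]
#' @export
calibrateThresholds <- function(control_sections = NULL, exemplar_peaks = NULL) {
  peaks <- c(exemplar_peaks,
             unlist(lapply(control_sections, function(s) s@ground_truth$peak)))
  if (!length(peaks)) stop("no exemplar cells to calibrate from")
  new("ThresholdBand", lower = min(peaks), upper = max(peaks))
}

# 8-connected component labelling of a logical mask via a pixel graph.
# Returns an integer matrix, 0 = background.
labelComponents8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  id <- integer(h * w)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    nr <- r + sh[1]; nc <- c + sh[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    hit <- id[nidx] > 0L
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok]][hit], id[nidx][hit]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  lab[fg] <- igraph::components(g)$membership
  lab
}

# Second-moment shape measurement of one component. Roundness is the
# ImageJ convention 4*area/(pi*major^2) with the equal-area moment
# ellipse, i.e. sqrt(lambda_minor/lambda_major); a 1/12 per-pixel variance
# term keeps one-pixel-wide components finite.
measureComponent <- function(rows, cols) {
  n <- length(rows)
  cx <- mean(cols) - 0.5
  cy <- mean(rows) - 0.5
  mu20 <- mean((cols - 0.5 - cx)^2) + 1 / 12
  mu02 <- mean((rows - 0.5 - cy)^2) + 1 / 12
  mu11 <- mean((cols - 0.5 - cx) * (rows - 0.5 - cy))
  tr <- mu20 + mu02
  det <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det) / 2
  l2 <- (tr - det) / 2
  list(area = n, centroid_x = cx, centroid_y = cy,
       roundness = min(sqrt(max(l2, 0) / l1), 1))
}

#' Detect stained particles in a section
#'
#' Binarises the stain channel (255 minus the gray value) inside the
#' calibrated intensity band, labels 8-connected components, and keeps
#' components whose centroid lies inside the ROI with pixel area strictly
#' greater than `min_size_px` and roundness strictly greater than
#' `min_roundness` (the reference filter settings: size > 15 px,
#' roundness > 0.40).
#'
#' @param image A [SectionImage-class].
#' @param band A [ThresholdBand-class].
#' @param min_size_px Exclusive pixel-area cutoff (default 15).
#' @param min_roundness Exclusive roundness cutoff (default 0.40).
#' @return data.frame, one row per kept particle: `particle_id`,
#'   `area_px`, `area_mm2`, `roundness`, `centroid_x`, `centroid_y`.
#' @export
countParticles <- function(image, band, min_size_px = 15, min_roundness = 0.40) {
  stopifnot(is(image, "SectionImage"), is(band, "ThresholdBand"))
  if (roiAreaPx(image) == 0) stop("empty ROI")
  stain <- 255 - image@pixels
  mask <- stain >= band@lower & stain <= band@upper
  lab <- labelComponents8(mask)
  out <- data.frame(particle_id = integer(), area_px = integer(),
                    area_mm2 = numeric(), roundness = numeric(),
                    centroid_x = numeric(), centroid_y = numeric())
  if (!any(lab > 0)) return(out)
  idx <- which(lab > 0)
  h <- nrow(mask)
  comp <- split(idx, lab[idx])
  kid <- 0L
  for (px in comp) {
    rows <- ((px - 1L) %% h) + 1L
    cols <- ((px - 1L) %/% h) + 1L
    m <- measureComponent(rows, cols)
    if (m$area <= min_size_px) next
    if (m$roundness <= min_roundness) next
    if (!pointInPolygon(m$centroid_x, m$centroid_y, image@roi)) next
    kid <- kid + 1L
    out <- rbind(out, data.frame(particle_id = kid, area_px = m$area,
                                 area_mm2 = m$area * image@pixel_size^2,
                                 roundness = m$roundness,
                                 centroid_x = m$centroid_x,
                                 centroid_y = m$centroid_y))
  }
  out
}

#' Standardise a particle count to cells per square millimetre
#'
#' @param n_particles Particle count within the ROI.
#' @param roi_area_px ROI area in pixels (see [roiAreaPx()]).
#' @param pixel_size Pixel edge in mm.
#' @return Cells per mm^2.
#' @examples
#' densityPerMm2(50, roi_area_px = 250000, pixel_size = 0.001)  # 200
#' @export
densityPerMm2 <- function(n_particles, roi_area_px, pixel_size) {
  if (roi_area_px <= 0) stop("roi_area_px must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  n_particles / (roi_area_px * pixel_size^2)
}

#' Aggregate per-slice densities to one value per subject and area
#'
#' Takes the arithmetic mean over consecutive slices within each
#' hemisphere (protocol: 2 slices for CPi, 3 for NMm/NIML/MM) and then, if
#' pooling is enabled, over hemispheres. Missing slices trigger a warning
#' and aggregation over the available ones, flagged in the output.
#'
#' @param densities data.frame with columns `subject_id`, `area_label`,
#'   `hemisphere`, `slice`, `cells_per_mm2`.
#' @param pool_hemispheres Average the two hemisphere means (default TRUE,
#'   mirroring pooling after a non-significant hemisphere effect).
#' @param expected_slices Named expected slice counts per area.
#' @return data.frame: `subject_id`, `area_label`, `hemisphere` (`"pooled"`
#'   when pooling), `cells_per_mm2`, `n_slices_averaged`, `complete`.
#' @export
aggregateSubject <- function(densities, pool_hemispheres = TRUE,
                             expected_slices = c(CPi = 2, NMm = 3,
                                                 NIML = 3, MM = 3)) {
  need <- c("subject_id", "area_label", "hemisphere", "slice", "cells_per_mm2")
  stopifnot(all(need %in% names(densities)))
  key <- interaction(densities$subject_id, densities$area_label, drop = TRUE)
  out <- do.call(rbind, lapply(split(densities, key), function(d) {
    exp_n <- expected_slices[[d$area_label[1]]] %||% NA_integer_
    hem <- lapply(split(d, d$hemisphere), function(hd) {
      if (!is.na(exp_n) && nrow(hd) != exp_n)
        warning(sprintf("%s/%s/%s: %d slice(s), expected %d",
                        hd$subject_id[1], hd$area_label[1], hd$hemisphere[1],
                        nrow(hd), exp_n))
      list(mean = mean(hd$cells_per_mm2), n = nrow(hd),
           complete = is.na(exp_n) || nrow(hd) == exp_n)
    })
    if (pool_hemispheres) {
      data.frame(subject_id = d$subject_id[1], area_label = d$area_label[1],
                 hemisphere = "pooled",
                 cells_per_mm2 = mean(vapply(hem, `[[`, numeric(1), "mean")),
                 n_slices_averaged = sum(vapply(hem, `[[`, numeric(1), "n")),
                 complete = all(vapply(hem, `[[`, logical(1), "complete")),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(names(hem), function(h)
        data.frame(subject_id = d$subject_id[1], area_label = d$area_label[1],
                   hemisphere = h, cells_per_mm2 = hem[[h]]$mean,
                   n_slices_averaged = hem[[h]]$n,
                   complete = hem[[h]]$complete, stringsAsFactors = FALSE)))
    }
  }))
  rownames(out) <- NULL
  out
}

#' Read a section image from a grayscale TIFF or PNG file
#'
#' @param path Image file (`.tif`, `.tiff` or `.png`).
#' @param ... Passed to [sectionImage()] (pixel size, ROI, annotations).
#' @return A [SectionImage-class] (multi-channel images are averaged to
#'   luminance; intensities rescaled to 0-255).
#' @export
readSectionImage <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  sectionImage(round(img * 255), ...)
}
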