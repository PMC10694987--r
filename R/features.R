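asEBLabel <- function(mask) {
  # gliopath rasters are [row, col]; EBImage images are [x, y]
  EBImage::Image(t(mask))
}

emptyFeatureRow <- function() {
  data.frame(object_id = integer(), area = numeric(), perimeter = numeric(),
             radius_mean = numeric(), radius_sd = numeric(),
             radius_min = numeric(), radius_max = numeric())
}

#' Per-object shape features
#'
#' Area (pixel count), perimeter (boundary pixel count) and statistics of the
#' boundary-pixel distances to the object centroid, computed with EBImage.
#'
#' @param mask integer label matrix (0 = background), see [labelComponents()].
#' @return `data.frame` with one row per object: `object_id`, `area`,
#'   `perimeter`, `radius_mean`, `radius_sd`, `radius_min`, `radius_max`.
#' @export
shapeFeatures <- function(mask) {
  if (max(mask) == 0) return(emptyFeatureRow())
  f <- EBImage::computeFeatures.shape(asEBLabel(mask))
  data.frame(object_id = seq_len(nrow(f)),
             area = f[, "s.area"], perimeter = f[, "s.perimeter"],
             radius_mean = f[, "s.radius.mean"],
             radius_sd = f[, "s.radius.sd"],
             radius_min = f[, "s.radius.min"],
             radius_max = f[, "s.radius.max"],
             row.names = NULL)
}

#' Per-object moment features
#'
#' Centroid from first moments and the second-central-moment ellipse:
#' major axis length, eccentricity in `[0, 1)` and orientation `theta` of the
#' major axis in `(-pi/2, pi/2]`. Coordinates are 0-based with `cx` the
#' column and `cy` the row.
#'
#' @param mask integer label matrix.
#' @return `data.frame`: `object_id`, `cx`, `cy`, `major_axis`,
#'   `eccentricity`, `theta`.
#' @export
momentFeatures <- function(mask) {
  if (max(mask) == 0)
    return(data.frame(object_id = integer(), cx = numeric(), cy = numeric(),
                      major_axis = numeric(), eccentricity = numeric(),
                      theta = numeric()))
  lab <- asEBLabel(mask)
  f <- EBImage::computeFeatures.moment(lab)
  data.frame(object_id = seq_len(nrow(f)),
             cx = f[, "m.cx"] - 1, cy = f[, "m.cy"] - 1,
             major_axis = f[, "m.majoraxis"],
             eccentricity = f[, "m.eccentricity"],
             theta = f[, "m.theta"], row.names = NULL)
}

#' Per-object intensity features
#'
#' Mean, standard deviation and 5th/95th percentiles of the underlying
#' channel over each object's pixels.
#'
#' @param mask integer label matrix.
#' @param channel gray image (matrix) of the same shape.
#' @return `data.frame`: `object_id`, `intensity_mean`, `intensity_sd`,
#'   `intensity_q05`, `intensity_q95`.
#' @export
intensityFeatures <- function(mask, channel) {
  if (!identical(dim(mask), dim(channel)))
    stop("mask and channel must have the same shape")
  if (max(mask) == 0)
    return(data.frame(object_id = integer(), intensity_mean = numeric(),
                      intensity_sd = numeric(), intensity_q05 = numeric(),
                      intensity_q95 = numeric()))
  idx <- which(mask > 0)
  lab <- mask[idx]
  val <- channel[idx]
  sp <- split(val, lab)
  ids <- as.integer(names(sp))
  stats <- t(vapply(sp, function(v) {
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0,
      stats::quantile(v, c(0.05, 0.95), names = FALSE))
  }, numeric(4)))
  out <- data.frame(object_id = ids, intensity_mean = stats[, 1],
                    intensity_sd = stats[, 2], intensity_q05 = stats[, 3],
                    intensity_q95 = stats[, 4], row.names = NULL)
  out[order(out$object_id), , drop = FALSE]
}

glcmScalars <- function(counts, levels) {
  total <- sum(counts)
  p <- counts / total
  i <- row(p) - 1; j <- col(p) - 1
  contrast <- sum(p * (i - j)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  mui <- sum(p * i); muj <- sum(p * j)
  si <- sqrt(sum(p * (i - mui)^2)); sj <- sqrt(sum(p * (j - muj)^2))
  correlation <- if (si > 0 && sj > 0)
    sum(p * (i - mui) * (j - muj)) / (si * sj) else 0
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' Per-object GLCM texture features
#'
#' Gray-level co-occurrence matrix restricted to pixel pairs lying entirely
#' within the object, symmetric and normalized, quantizing the channel over
#' the fixed `[0, 1]` domain into `levels` gray levels. The four Haralick
#' scalars (contrast, correlation, energy, homogeneity) are averaged over the
#' offsets. Objects with no within-object pair at any offset get zero
#' features and `glcm_degenerate = TRUE`.
#'
#' @param mask integer label matrix.
#' @param channel gray image in `[0, 1]`, same shape.
#' @param levels number of gray levels (default 16).
#' @param offsets list of `(dRow, dCol)` integer offsets; default
#'   `(0,1)` and `(1,0)`.
#' @return `data.frame`: `object_id`, `glcm_contrast`, `glcm_correlation`,
#'   `glcm_energy`, `glcm_homogeneity`, `glcm_degenerate`.
#' @export
textureFeatures <- function(mask, channel, levels = 16,
                            offsets = list(c(0L, 1L), c(1L, 0L))) {
  if (levels < 2) stop("levels must be >= 2")
  if (!identical(dim(mask), dim(channel)))
    stop("mask and channel must have the same shape")
  nObj <- max(mask)
  if (nObj == 0)
    return(data.frame(object_id = integer(), glcm_contrast = numeric(),
                      glcm_correlation = numeric(), glcm_energy = numeric(),
                      glcm_homogeneity = numeric(),
                      glcm_degenerate = logical()))
  h <- nrow(mask); w <- ncol(mask)
  lev <- pmin(floor(pmax(pmin(channel, 1), 0) * levels), levels - 1)
  out <- matrix(0, nObj, 4)
  degenerate <- logical(nObj)
  for (obj in seq_len(nObj)) {
    idx <- which(mask == obj)
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    inObj <- matrix(FALSE, h, w); inObj[idx] <- TRUE
    perOffset <- list()
    for (o in offsets) {
      r2 <- rows + o[1]; c2 <- cols + o[2]
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      ok[ok] <- inObj[cbind(r2[ok], c2[ok])]
      if (!any(ok)) next
      a <- lev[cbind(rows[ok], cols[ok])]
      b <- lev[cbind(rows[ok] + o[1], cols[ok] + o[2])]
      counts <- matrix(0, levels, levels)
      for (t in seq_along(a)) {
        counts[a[t] + 1, b[t] + 1] <- counts[a[t] + 1, b[t] + 1] + 1
        counts[b[t] + 1, a[t] + 1] <- counts[b[t] + 1, a[t] + 1] + 1
      }
      perOffset[[length(perOffset) + 1]] <- glcmScalars(counts, levels)
    }
    if (length(perOffset) == 0) {
      degenerate[obj] <- TRUE
    } else {
      out[obj, ] <- Reduce(`+`, perOffset) / length(perOffset)
    }
  }
  data.frame(object_id = seq_len(nObj), glcm_contrast = out[, 1],
             glcm_correlation = out[, 2], glcm_energy = out[, 3],
             glcm_homogeneity = out[, 4], glcm_degenerate = degenerate,
             row.names = NULL)
}

#' Full per-cell feature table
#'
#' Joins shape, moment, intensity and texture features into one row per
#' segmented object, with identity and study labels, forming the cell
#' feature table consumed by the artifact filter, the spatial statistics and
#' morphology clustering.
#'
#' @param mask integer label matrix.
#' @param channel underlying stain channel in `[0, 1]`.
#' @param imageId image identifier.
#' @param group study group label (e.g. `"PD"` or `"psPD"`).
#' @param region histology region label (`"control"`, `"inflammatory"`,
#'   `"hypercellular"` or `NA`).
#' @param levels,offsets passed to [textureFeatures()].
#' @return `data.frame` with identity, position, morphology, intensity and
#'   texture columns plus `signal_label = "unset"`.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
#' extractCellFeatures(m, matrix(0.5, 8, 8), "img1", "PD")
#' @export
extractCellFeatures <- function(mask, channel, imageId = "image",
                                group = NA_character_,
                                region = NA_character_,
                                levels = 16,
                                offsets = list(c(0L, 1L), c(1L, 0L))) {
  sh <- shapeFeatures(mask)
  if (nrow(sh) == 0) {
    out <- cbind(data.frame(image_id = character(), group = character(),
                            region = character()),
                 momentFeatures(mask), sh[-1],
                 intensityFeatures(mask, channel)[-1],
                 textureFeatures(mask, channel)[-1])
    out$signal_label <- character()
    return(out)
  }
  mo <- momentFeatures(mask)
  it <- intensityFeatures(mask, channel)
  tx <- textureFeatures(mask, channel, levels, offsets)
  out <- data.frame(image_id = imageId, object_id = sh$object_id,
                    group = group, region = region,
                    cx = mo$cx, cy = mo$cy)
  out <- cbind(out, sh[-1],
               mo[c("major_axis", "eccentricity", "theta")],
               it[-1], tx[-1])
  out$signal_label <- "unset"
  out
}

#' Names of the morphology feature columns
#'
#' The shape and moment features (excluding x/y positions) used for
#' morphology embedding, plus the intensity/texture columns used by the
#' signal classifier.
#'
#' @param which `"morphology"` (shape + moment, no positions) or `"signal"`
#'   (morphology + intensity + texture).
#' @return Character vector of column names.
#' @export
featureColumns <- function(which = c("morphology", "signal")) {
  which <- match.arg(which)
  morpho <- c("area", "perimeter", "radius_mean", "radius_sd", "radius_min",
              "radius_max", "major_axis", "eccentricity", "theta")
  if (which == "morphology") return(morpho)
  c(morpho, "intensity_mean", "intensity_sd", "intensity_q05",
    "intensity_q95", "glcm_contrast", "glcm_correlation", "glcm_energy",
    "glcm_homogeneity")
}
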