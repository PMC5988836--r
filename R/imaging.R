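#' Two-channel image stack
#'
#' Container for a CFP / FRET time-lapse: two arrays of equal shape, either
#' `T x Y x X` or, for z-stacks, `T x Z x Y x X`, with the pixel size and
#' frame interval needed for downstream quantification.
#'
#' @param cfp,fret Nonnegative numeric arrays of identical shape.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param interval Frame interval in minutes (> 0).
#' @return An `image_stack` object.
#' @export
image_stack <- function(cfp, fret, pixel_size = 1, interval = 1.5) {
  if (!is.array(cfp) || !is.array(fret) ||
      !identical(dim(cfp), dim(fret))) {
    stop("`cfp` and `fret` must be arrays of identical shape", call. = FALSE)
  }
  if (!length(dim(cfp)) %in% c(3L, 4L)) {
    stop("stacks must be T x Y x X or T x Z x Y x X arrays", call. = FALSE)
  }
  if (interval <= 0) stop("`interval` must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (min(cfp, na.rm = TRUE) < 0 || min(fret, na.rm = TRUE) < 0) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  structure(list(cfp = cfp, fret = fret, pixel_size = pixel_size,
                 interval = interval), class = "image_stack")
}

#' Static label mask of cell ROIs
#'
#' @param labels `Y x X` matrix of nonnegative integers; 0 is background and
#'   each positive label is one cell ROI, constant over time.
#' @return A `label_mask` matrix.
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a Y x X matrix",
                               call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  structure(matrix(as.integer(labels), nrow(labels), ncol(labels)),
            class = "label_mask")
}

#' Maximum intensity projection of a z-stack
#'
#' Projects the voxel with the maximum intensity at each x-y coordinate into
#' a single plane.
#'
#' @param zstack `Z x Y x X` array (at least one slice).
#' @return `Y x X` matrix of per-pixel maxima over z.
#' @export
max_intensity_projection <- function(zstack) {
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[1] < 1) {
    stop("`zstack` must be a Z x Y x X array with >= 1 slice", call. = FALSE)
  }
  out <- zstack[1, , ]
  nz <- dim(zstack)[1]
  if (nz > 1) {
    for (z in 2:nz) out <- pmax(out, zstack[z, , ])
  }
  out
}

# Project a T x Z x Y x X channel to T x Y x X.
project_stack <- function(x) {
  if (length(dim(x)) == 3L) return(x)
  d <- dim(x)
  out <- array(NA_real_, dim = d[c(1, 3, 4)])
  for (t_i in seq_len(d[1])) {
    out[t_i, , ] <- max_intensity_projection(array(x[t_i, , , ],
                                                   dim = d[2:4]))
  }
  out
}

#' Compute a FRET/CFP ratio stack
#'
#' Per-pixel ratio `(fret - background_fret) / (cfp - background_cfp)`,
#' restricted to pixels whose background-corrected CFP exceeds `cfp_floor`
#' (elsewhere the ratio is undefined and flagged `NA`, never silently 0).
#' Z-stacks are first reduced by [max_intensity_projection()] per channel;
#' projecting before dividing avoids ratios of dim out-of-focus voxels.
#'
#' @param stack An [image_stack()].
#' @param background_cfp,background_fret Uniform background intensities to
#'   subtract (>= 0).
#' @param cfp_floor Minimum background-corrected CFP intensity for a valid
#'   ratio (>= 0).
#' @return A `ratio_stack`: list with `values` (`T x Y x X`, `NA` where
#'   invalid), `valid` (logical array), `pixel_size`, `interval`.
#' @export
compute_ratio_stack <- function(stack, background_cfp = 0,
                                background_fret = 0, cfp_floor = 0) {
  if (!inherits(stack, "image_stack"))
    stop("`stack` must be an image_stack", call. = FALSE)
  if (background_cfp < 0 || background_fret < 0 || cfp_floor < 0) {
    stop("backgrounds and `cfp_floor` must be >= 0", call. = FALSE)
  }
  cfp <- project_stack(stack$cfp) - background_cfp
  fret <- project_stack(stack$fret) - background_fret
  valid <- cfp > cfp_floor
  if (!any(valid)) {
    stop("no valid pixels: `cfp_floor`/background too high for this stack",
         call. = FALSE)
  }
  values <- array(NA_real_, dim = dim(cfp))
  values[valid] <- fret[valid] / cfp[valid]
  structure(list(values = values, valid = valid,
                 pixel_size = stack$pixel_size, interval = stack$interval),
            class = "ratio_stack")
}

#' Median filter with missing-pixel handling
#'
#' Noise reduction for ratio images: each pixel becomes the median of its
#' `size x size` neighbourhood. Invalid (`NA`) pixels are excluded from the
#' window, and the window shrinks at image borders instead of padding.
#'
#' @param image `Y x X` numeric matrix (may contain `NA`).
#' @param size Odd window side length >= 3 (default 5).
#' @return Filtered matrix; pixels whose whole window is invalid stay `NA`.
#' @export
median_filter <- function(image, size = 5) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (size %% 2 != 1 || size < 3) {
    stop("`size` must be an odd integer >= 3", call. = FALSE)
  }
  ny <- nrow(image); nx <- ncol(image)
  if (ny < size || nx < size) {
    stop("image smaller than the filter window", call. = FALSE)
  }
  half <- (size - 1L) / 2L
  offs <- -half:half
  shifted <- matrix(NA_real_, ny * nx, size * size)
  k <- 0L
  for (dy in offs) {
    ys <- seq_len(ny) + dy
    oky <- ys >= 1L & ys <= ny
    for (dx in offs) {
      k <- k + 1L
      xs <- seq_len(nx) + dx
      okx <- xs >= 1L & xs <= nx
      m <- matrix(NA_real_, ny, nx)
      m[oky, okx] <- image[ys[oky], xs[okx]]
      shifted[, k] <- as.vector(m)
    }
  }
  out <- apply(shifted, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  matrix(out, ny, nx)
}

#' Median-filter every frame of a ratio stack
#'
#' @param ratio A `ratio_stack` from [compute_ratio_stack()].
#' @param size Odd window side length (default 5).
#' @return The ratio stack with filtered `values`.
#' @export
median_filter_stack <- function(ratio, size = 5) {
  if (!inherits(ratio, "ratio_stack"))
    stop("`ratio` must be a ratio_stack", call. = FALSE)
  for (t_i in seq_len(dim(ratio$values)[1])) {
    ratio$values[t_i, , ] <- median_filter(ratio$values[t_i, , ], size)
  }
  ratio
}

#' Render a ratio frame in intensity-modulated display (IMD) mode
#'
#' Hue encodes the FRET/CFP ratio in `n_hues` steps from blue (low) to red
#' (high); brightness encodes donor (CFP) intensity in `n_levels` grades.
#' Out-of-range ratios clip to the end hues; invalid ratio pixels and zero
#' intensity render black.
#'
#' @param ratio `Y x X` ratio matrix (`NA` = invalid).
#' @param intensity `Y x X` CFP intensity matrix (>= 0).
#' @param ratio_range Length-2 `c(lo, hi)` with `lo < hi`.
#' @param n_hues Number of hue bins (default 8).
#' @param n_levels Number of brightness grades (default 32).
#' @param intensity_max Intensity mapped to the brightest grade (default the
#'   frame maximum).
#' @return `Y x X x 3` RGB array in `[0, 1]`.
#' @export
render_imd <- function(ratio, intensity, ratio_range, n_hues = 8,
                       n_levels = 32, intensity_max = NULL) {
  if (!is.matrix(ratio) || !is.matrix(intensity) ||
      !identical(dim(ratio), dim(intensity))) {
    stop("`ratio` and `intensity` must be matrices of equal shape",
         call. = FALSE)
  }
  lo <- ratio_range[1]; hi <- ratio_range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("`ratio_range` must satisfy lo < hi", call. = FALSE)
  }
  if (is.null(intensity_max)) intensity_max <- max(intensity, na.rm = TRUE)
  hue_idx <- floor((ratio - lo) / (hi - lo) * n_hues)
  hue_idx <- pmin(pmax(hue_idx, 0), n_hues - 1)
  lvl <- if (intensity_max > 0) {
    pmin(pmax(floor(intensity / intensity_max * n_levels), 0), n_levels - 1)
  } else {
    matrix(0, nrow(ratio), ncol(ratio))
  }
  # 8 evenly spaced hues from HSV blue (240 deg) down to red (0 deg)
  hues <- (240 / 360) * (1 - (seq_len(n_hues) - 1) / (n_hues - 1))
  bad <- is.na(ratio) | is.na(intensity)
  hue_idx[bad] <- 0
  lvl[bad] <- 0
  v <- lvl / (n_levels - 1)
  cols <- grDevices::hsv(h = hues[as.vector(hue_idx) + 1], s = 1,
                         v = as.vector(v))
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(ratio), ncol(ratio), 3))
  out[, , 1] <- matrix(rgb[1, ], nrow(ratio))
  out[, , 2] <- matrix(rgb[2, ], nrow(ratio))
  out[, , 3] <- matrix(rgb[3, ], nrow(ratio))
  out
}

#' Extract per-cell ratio traces
#'
#' For every ROI label, the trace value at each frame is the mean ratio over
#' that label's valid pixels; frames where a cell has no valid pixel are
#' flagged `NA`.
#'
#' @param ratio A `ratio_stack`.
#' @param mask A [label_mask()] matching the stack's Y x X shape.
#' @return Long trace table `cell_id`, `time_min`, `value`. Cell ids come
#'   from `attr(mask, "cell_ids")` when present, else `"cell_<label>"`.
#' @export
extract_cell_traces <- function(ratio, mask) {
  if (!inherits(ratio, "ratio_stack"))
    stop("`ratio` must be a ratio_stack", call. = FALSE)
  if (!inherits(mask, "label_mask")) mask <- label_mask(mask)
  d <- dim(ratio$values)
  if (!identical(dim(mask)[1:2], d[2:3])) {
    stop("mask shape does not match the ratio stack", call. = FALSE)
  }
  labs <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labs) == 0) stop("mask has no nonzero labels", call. = FALSE)
  ids <- attr(mask, "cell_ids")
  times <- (seq_len(d[1]) - 1) * ratio$interval
  out <- vector("list", length(labs))
  for (j in seq_along(labs)) {
    sel <- mask == labs[j]
    if (!any(sel)) stop("label ", labs[j], " has zero pixels", call. = FALSE)
    vals <- vapply(seq_len(d[1]), function(t_i) {
      frame <- ratio$values[t_i, , ]
      mean(frame[sel], na.rm = TRUE)
    }, numeric(1))
    vals[is.nan(vals)] <- NA_real_
    id <- if (!is.null(ids) && labs[j] <= length(ids)) ids[labs[j]] else
      paste0("cell_", labs[j])
    out[[j]] <- data.frame(cell_id = id, time_min = times, value = vals)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read / write image stacks as multi-page TIFF
#'
#' Each channel is one multi-page 32-bit float TIFF with one page per frame
#' (z-stacks are flattened as `T * Z` pages in acquisition order).
#' Intensities are stored scaled by `1 / 65535` (the 16-bit convention) and
#' rescaled on reading, so intensities up to 65535 round-trip.
#'
#' @param stack An [image_stack()] (`write_stack_tiff`).
#' @param cfp_path,fret_path Per-channel TIFF paths.
#' @param pixel_size,interval Metadata for `read_stack_tiff` (not stored in
#'   the TIFF).
#' @param nz Number of z-slices per time point (default 1).
#' @return `read_stack_tiff` returns an [image_stack()]; `write_stack_tiff`
#'   returns the paths invisibly.
#' @export
write_stack_tiff <- function(stack, cfp_path, fret_path) {
  stopifnot(inherits(stack, "image_stack"))
  write_channel <- function(x, path) {
    x <- x / 65535
    d <- dim(x)
    pages <- if (length(d) == 3L) {
      lapply(seq_len(d[1]), function(i) x[i, , ])
    } else {
      unlist(lapply(seq_len(d[1]), function(i) {
        lapply(seq_len(d[2]), function(z) x[i, z, , ])
      }), recursive = FALSE)
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  write_channel(stack$cfp, cfp_path)
  write_channel(stack$fret, fret_path)
  invisible(c(cfp_path, fret_path))
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(cfp_path, fret_path, pixel_size = 1,
                            interval = 1.5, nz = 1) {
  read_channel <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) p * 65535)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    if (nz == 1) {
      out <- array(NA_real_, dim = c(length(pages), ny, nx))
      for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
    } else {
      nt <- length(pages) / nz
      out <- array(NA_real_, dim = c(nt, nz, ny, nx))
      k <- 0L
      for (i in seq_len(nt)) for (z in seq_len(nz)) {
        k <- k + 1L
        out[i, z, , ] <- pages[[k]]
      }
    }
    out
  }
  image_stack(read_channel(cfp_path), read_channel(fret_path),
              pixel_size = pixel_size, interval = interval)
}

#' Read / write a label mask as TIFF
#'
#' Labels are stored as intensities scaled by `1 / 65535` (16-bit); `read`
#' rescales back to integers.
#'
#' @param mask A [label_mask()].
#' @param path TIFF path.
#' @return `read_mask_tiff` returns a [label_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(unclass(mask) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  label_mask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}
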