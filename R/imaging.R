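#' Estimate the outside-cell background level
#'
#' Scalar background estimate from pixels outside all cell masks, as used
#' before ROI quantification.  With no masks (or all-zero masks) the whole
#' image is used; masks covering every pixel are an error because no
#' outside-cell region remains.
#'
#' @param image Numeric matrix.
#' @param masks Optional integer label matrix (0 = outside any cell).
#' @param method `"median"` (default), `"mean"` or `"percentile"`.
#' @param prob Percentile for `method = "percentile"`.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(image, masks = NULL,
                                method = c("median", "mean", "percentile"),
                                prob = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  px <- if (is.null(masks)) as.vector(image) else {
    stopifnot(is.matrix(masks), all(dim(masks) == dim(image)))
    image[masks == 0]
  }
  if (length(px) == 0L)
    stop("cell masks cover the entire image; no outside-cell pixels",
         call. = FALSE)
  switch(method,
         median = stats::median(px),
         mean = mean(px),
         percentile = unname(stats::quantile(px, prob)))
}

#' Detect fluorescence foci as intensity local maxima
#'
#' Finds pixels that are 8-neighbourhood local maxima above
#' `background + threshold_sd * noise`, where the noise scale defaults to
#' the image's median absolute deviation, then merges maxima closer than
#' `min_separation` px, keeping the brightest of each group.
#'
#' @param marker Numeric matrix (marker channel, e.g. gamma-tubulin).
#' @param min_separation_px Merge radius in pixels.
#' @param threshold_sd Detection threshold in robust-noise units above
#'   background.
#' @param background Scalar background; defaults to `median(marker)`.
#' @param noise Robust noise scale; defaults to the upper-half quantile
#'   spread `quantile(marker, 0.8413) - median(marker)`.
#' @return data.frame `row`, `col`, `value`, brightest first (empty for a
#'   blank image).
#' @export
detect_foci <- function(marker, min_separation_px = 5, threshold_sd = 5,
                        background = NULL, noise = NULL) {
  stopifnot(is.matrix(marker), is.numeric(marker))
  background <- background %||% stats::median(marker)
  # robust noise scale: the 84.13th percentile minus the median equals the
  # Gaussian SD and, unlike the MAD, survives dark channels clamped at zero
  noise <- noise %||%
    unname(stats::quantile(marker, 0.8413) - stats::median(marker))
  if (noise == 0) noise <- stats::sd(marker)
  thr <- background + threshold_sd * noise
  nr <- nrow(marker); nc <- ncol(marker)
  # pad with -Inf so border pixels compare only against real neighbours
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- marker
  is_max <- marker > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    is_max <- is_max & (marker >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  cand <- data.frame(row = idx[, 1L], col = idx[, 2L],
                     value = marker[idx])
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Member pixels of a circular ROI: integer pixel centres within `radius`
# (inclusive) of (row0, col0), clipped to the image; `clipped` reports
# whether any member fell outside the bounds.
roi_pixels <- function(row0, col0, radius, dim_img) {
  rows <- seq.int(ceiling(row0 - radius), floor(row0 + radius))
  cols <- seq.int(ceiling(col0 - radius), floor(col0 + radius))
  grid <- expand.grid(row = rows, col = cols)
  grid <- grid[(grid$row - row0)^2 + (grid$col - col0)^2 <= radius^2 + 1e-9, ]
  inb <- grid$row >= 1L & grid$row <= dim_img[1L] &
         grid$col >= 1L & grid$col <= dim_img[2L]
  list(pixels = grid[inb, , drop = FALSE], clipped = any(!inb))
}

#' Quantify centrosomal signal in circular ROIs
#'
#' For each detected focus, sums the signal channel over a circular region
#' of `roi_diameter_px` (pixel centres within the radius, inclusive) and
#' subtracts `background * n_member_pixels`; per-cell totals are the sums
#' of the corrected per-focus values, mirroring per-cell centrosomal
#' intensity quantification.  ROIs running over the image border are
#' clipped and flagged.  Foci falling outside every cell mask are reported
#' with `cell = NA` and excluded from per-cell totals.
#'
#' @param signal Numeric matrix (quantified channel).
#' @param foci data.frame with `row`, `col` focus centres (e.g. from
#'   [detect_foci()]).
#' @param cell_masks Integer label matrix (0 = outside any cell); `NULL`
#'   assigns every focus to pseudo-cell 1.
#' @param roi_diameter_px ROI diameter (default 20 px, about 1 micron).
#' @param background Scalar background (see [estimate_background()]).
#' @return List with `per_focus` (focus, cell, row, col, n_pixels,
#'   raw_sum, corrected_sum, clipped) and `per_cell` (cell, n_foci,
#'   total_corrected).
#' @export
quantify_centrosomal_signal <- function(signal, foci, cell_masks = NULL,
                                        roi_diameter_px = 20,
                                        background = 0) {
  stopifnot(is.matrix(signal), is.data.frame(foci),
            all(c("row", "col") %in% names(foci)), roi_diameter_px >= 1)
  radius <- roi_diameter_px / 2
  n <- nrow(foci)
  per_focus <- data.frame(focus = seq_len(n), cell = NA_integer_,
                          row = foci$row, col = foci$col,
                          n_pixels = NA_integer_, raw_sum = NA_real_,
                          corrected_sum = NA_real_, clipped = FALSE)
  for (i in seq_len(n)) {
    roi <- roi_pixels(foci$row[i], foci$col[i], radius, dim(signal))
    vals <- signal[cbind(roi$pixels$row, roi$pixels$col)]
    per_focus$n_pixels[i] <- nrow(roi$pixels)
    per_focus$raw_sum[i] <- sum(vals)
    per_focus$corrected_sum[i] <- sum(vals) - background * nrow(roi$pixels)
    per_focus$clipped[i] <- roi$clipped
    per_focus$cell[i] <- if (is.null(cell_masks)) 1L else {
      r <- round(foci$row[i]); c <- round(foci$col[i])
      lab <- cell_masks[r, c]
      if (lab == 0L) NA_integer_ else as.integer(lab)
    }
  }
  assigned <- per_focus[!is.na(per_focus$cell), , drop = FALSE]
  if (nrow(assigned) > 0L) {
    total <- tapply(assigned$corrected_sum, assigned$cell, sum)
    per_cell <- data.frame(cell = as.integer(names(total)),
                           n_foci = as.integer(table(assigned$cell)),
                           total_corrected = as.numeric(total))
  } else {
    per_cell <- data.frame(cell = integer(), n_foci = integer(),
                           total_corrected = numeric())
  }
  rownames(per_cell) <- NULL
  list(per_focus = per_focus, per_cell = per_cell)
}

#' Classify centriole-count phenotypes
#'
#' Mitotic mode: per condition, the fractions of cells with more than four
#' marker foci (centriole amplification), fewer than three
#' (underduplication), and the normal three-to-four range.  Interphase
#' mode additionally applies the joint aberrant-number rule: more than
#' four centriole-marker foci together with more than two
#' centrosome-marker foci.
#'
#' @param counts Integer vector of per-cell focus counts (centriole
#'   marker, e.g. Centrin-2).
#' @param condition Optional per-cell condition labels (single group when
#'   `NULL`).
#' @param mode `"mitotic"` or `"interphase"`.
#' @param marker2_counts Per-cell counts of a second (centrosome) marker,
#'   interphase mode only.
#' @return data.frame with one row per condition: `condition`, `n_cells`,
#'   `frac_gt4`, `frac_lt3`, `frac_3to4` and, in interphase mode,
#'   `frac_aberrant`.
#' @export
classify_centriole_phenotype <- function(counts, condition = NULL,
                                         mode = c("mitotic", "interphase"),
                                         marker2_counts = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(counts), all(counts >= 0))
  condition <- condition %||% rep("all", length(counts))
  if (mode == "interphase") {
    stopifnot(!is.null(marker2_counts),
              length(marker2_counts) == length(counts))
  }
  split_idx <- split(seq_along(counts), condition)
  out <- do.call(rbind, lapply(names(split_idx), function(cond) {
    i <- split_idx[[cond]]
    x <- counts[i]
    row <- data.frame(condition = cond, n_cells = length(x),
                      frac_gt4 = mean(x > 4),
                      frac_lt3 = mean(x < 3),
                      frac_3to4 = mean(x >= 3 & x <= 4))
    if (mode == "interphase")
      row$frac_aberrant <- mean(x > 4 & marker2_counts[i] > 2)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a 16-bit TIFF image
#'
#' Convenience wrappers around the \pkg{tiff} package storing integer
#' intensities up to 65535.
#'
#' @param image Numeric matrix with values in `[0, 65535]`.
#' @param path File path.
#' @return `read_image_tiff()` returns the numeric matrix on the original
#'   count scale; `write_image_tiff()` returns `path` invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0))
  if (any(image > 65535)) stop("intensities exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}
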