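# Channel-wise image quality metrics: MSE, PSNR, SSIM, CNR, ROI profiles.

.check_same_shape <- function(f, g) {
  if (!identical(dim(f), dim(g)) || length(f) != length(g)) {
    stop("shape_mismatch: images differ in shape", call. = FALSE)
  }
}

#' Mean squared error between two images
#'
#' @param f,g Numeric matrices (or arrays) of identical shape.
#' @return Mean of squared differences.
#' @export
mse <- function(f, g) {
  .check_same_shape(f, g)
  mean((f - g)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 20 log10(peak) - 10 log10(MSE)`.  The peak is the joint maximum
#' over both images (`peak = "joint"`, the convention used here) or the
#' maximum of the reference (`peak = "reference"`).  Identical images give
#' `Inf`.
#'
#' @param f Reference image.
#' @param g Test image.
#' @param peak `"joint"` or `"reference"`.
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(f, g, peak = c("joint", "reference")) {
  peak <- match.arg(peak)
  .check_same_shape(f, g)
  if (all(f == 0) && all(g == 0)) {
    stop("degenerate_images: both images are identically zero", call. = FALSE)
  }
  m <- mse(f, g)
  if (m == 0) return(Inf)
  pk <- if (peak == "joint") max(f, g) else max(f)
  20 * log10(pk) - 10 * log10(m)
}

# uniform box filter by cumulative sums; returns the "valid" local means
.box_mean <- function(x, w) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  pad[-1, -1] <- cs
  n <- nrow(x) - w + 1
  m <- ncol(x) - w + 1
  (pad[(w + 1):(w + n), (w + 1):(w + m)] - pad[1:n, (w + 1):(w + m)] -
     pad[(w + 1):(w + n), 1:m] + pad[1:n, 1:m]) / (w * w)
}

#' Structural similarity index
#'
#' Local-window SSIM with a uniform window, averaged over all valid window
#' positions.  Constants default to `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`
#' where `L` is the data range of the reference image.
#'
#' @param f Reference image (matrix).
#' @param g Test image (matrix).
#' @param window Side of the uniform window (pixels, default 7).
#' @param data_range `L`; defaults to `max(f) - min(f)` (1 when degenerate).
#' @param constants Optional explicit `c(c1, c2)` overriding `data_range`.
#' @return SSIM in `[-1, 1]`; exactly 1 when `f == g`.
#' @export
ssim <- function(f, g, window = 7L, data_range = NULL, constants = NULL) {
  .check_same_shape(f, g)
  if (window > min(dim(f))) {
    stop("window_too_large: SSIM window exceeds the image", call. = FALSE)
  }
  if (is.null(constants)) {
    if (is.null(data_range)) {
      data_range <- diff(range(f))
      if (data_range == 0) data_range <- 1
    }
    constants <- c((0.01 * data_range)^2, (0.03 * data_range)^2)
  }
  c1 <- constants[1]; c2 <- constants[2]
  muf <- .box_mean(f, window)
  mug <- .box_mean(g, window)
  sff <- .box_mean(f * f, window) - muf^2
  sgg <- .box_mean(g * g, window) - mug^2
  sfg <- .box_mean(f * g, window) - muf * mug
  s <- ((2 * muf * mug + c1) * (2 * sfg + c2)) /
    ((muf^2 + mug^2 + c1) * (sff + sgg + c2))
  mean(s)
}

#' Region-of-interest mask
#'
#' @param pixels Logical matrix selecting the ROI (>= 1 pixel).
#' @param label Free-text label.
#' @return A `roi_mask` object.
#' @export
roi_mask <- function(pixels, label = "") {
  stopifnot(is.logical(pixels), is.matrix(pixels))
  if (!any(pixels)) {
    stop("empty_roi: mask selects no pixels", call. = FALSE)
  }
  structure(list(pixels = pixels, label = label), class = "roi_mask")
}

#' Circular ROI helper
#'
#' @param dim_hw `c(height, width)` of the image.
#' @param cx,cy,r Circle centre and radius (pixels).
#' @param label Free-text label.
#' @return A [roi_mask()].
#' @export
roi_circle <- function(dim_hw, cx, cy, r, label = "") {
  xs <- matrix(rep(seq_len(dim_hw[2]), each = dim_hw[1]), dim_hw[1])
  ys <- matrix(rep(seq_len(dim_hw[1]), times = dim_hw[2]), dim_hw[1])
  roi_mask((xs - cx)^2 + (ys - cy)^2 <= r^2, label)
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean(target) - mean(background)| / (sd(target) + sd(background))`.
#'
#' @param img Image matrix.
#' @param target,background Disjoint [roi_mask()]s with >= 2 pixels each.
#' @return CNR (>= 0); `Inf` when both regions are exactly constant but their
#'   means differ.
#' @export
cnr <- function(img, target, background) {
  stopifnot(inherits(target, "roi_mask"), inherits(background, "roi_mask"))
  if (any(target$pixels & background$pixels)) {
    stop("overlapping_rois: target and background masks intersect",
         call. = FALSE)
  }
  if (sum(target$pixels) < 2 || sum(background$pixels) < 2) {
    stop("empty_roi: each region needs at least 2 pixels", call. = FALSE)
  }
  st <- img[target$pixels]; sb <- img[background$pixels]
  num <- abs(mean(st) - mean(sb))
  den <- stats::sd(st) + stats::sd(sb)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' ROI attenuation profile across energy channels
#'
#' @param stack A [spectral_image_stack()] (or `spectral_phantom`).
#' @param roi A [roi_mask()] within the spatial extent.
#' @return List with `mean` and `sd` per channel and `channel_averaged_sd`
#'   (the mean of the per-channel SDs, the summary noise measure).
#' @export
roi_profile <- function(stack, roi) {
  arr <- if (!is.null(stack$pixels)) stack$pixels else stack$lac
  d <- dim(arr)
  stopifnot(inherits(roi, "roi_mask"),
            identical(dim(roi$pixels), as.integer(d[2:3])) ||
              identical(dim(roi$pixels), d[2:3]))
  m <- matrix(arr, d[1], d[2] * d[3])[, as.vector(roi$pixels), drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  list(mean = mu, sd = sdv, channel_averaged_sd = mean(sdv))
}

#' MSE between two per-channel profiles
#'
#' @param profile,reference Numeric vectors of equal length.
#' @return List with `mean` and `sd` of the per-channel squared errors.
#' @export
profile_mse <- function(profile, reference) {
  if (length(profile) != length(reference)) {
    stop("length_mismatch: profiles differ in length", call. = FALSE)
  }
  se <- (profile - reference)^2
  list(mean = mean(se), sd = stats::sd(se))
}

#' Full channel-wise evaluation of a stack against ground truth
#'
#' @param stack A [spectral_image_stack()].
#' @param truth A `spectral_phantom` (or stack) with matching shape.
#' @param rois Optional named list of [roi_mask()]s for profile statistics.
#' @param cnr_rois Optional list `list(target =, background =)` for
#'   channel-wise CNR.
#' @return A `metric_report`: `per_channel` data frame (energy, psnr, ssim),
#'   `summary` (mean and sd per metric), `roi_stats`, `cnr_per_channel`.
#' @export
evaluate_stack <- function(stack, truth, rois = NULL, cnr_rois = NULL) {
  tarr <- if (!is.null(truth$lac)) truth$lac else truth$pixels
  d <- dim(stack$pixels)
  if (!identical(dim(tarr), d)) {
    stop("shape_mismatch: stack and truth differ in shape", call. = FALSE)
  }
  ps <- numeric(d[1]); ss <- numeric(d[1])
  for (e in seq_len(d[1])) {
    fe <- matrix(tarr[e, , ], d[2], d[3])
    ge <- matrix(stack$pixels[e, , ], d[2], d[3])
    ps[e] <- psnr(fe, ge)
    ss[e] <- ssim(fe, ge)
  }
  per_channel <- data.frame(energy = stack$energies, psnr = ps, ssim = ss)
  fin <- is.finite(ps)
  summary <- data.frame(
    metric = c("psnr", "ssim"),
    mean = c(mean(ps[fin]), mean(ss)),
    sd = c(stats::sd(ps[fin]), stats::sd(ss))
  )
  roi_stats <- NULL
  if (!is.null(rois)) {
    roi_stats <- lapply(rois, function(r) {
      pr <- roi_profile(stack, r)
      tr <- roi_profile(list(pixels = tarr, energies = stack$energies), r)
      pm <- profile_mse(pr$mean, tr$mean)
      list(mean_profile = pr$mean, sd_profile = pr$sd,
           channel_averaged_sd = pr$channel_averaged_sd,
           profile_mse_mean = pm$mean, profile_mse_sd = pm$sd)
    })
  }
  cnr_pc <- NULL
  if (!is.null(cnr_rois)) {
    cnr_pc <- vapply(seq_len(d[1]), function(e) {
      cnr(matrix(stack$pixels[e, , ], d[2], d[3]),
          cnr_rois$target, cnr_rois$background)
    }, 1.0)
  }
  structure(list(per_channel = per_channel, summary = summary,
                 roi_stats = roi_stats, cnr_per_channel = cnr_pc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialise / restore a metric report
#'
#' The per-channel table goes to CSV; the summary and ROI statistics go to a
#' JSON sidecar, and the pair round-trips losslessly.
#'
#' @param report A `metric_report`.
#' @param path_csv,path_json Output paths.
#' @return `write_metric_report`: the paths, invisibly; `read_metric_report`:
#'   a `metric_report`.
#' @export
write_metric_report <- function(report, path_csv, path_json) {
  utils::write.csv(report$per_channel, path_csv, row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, roi_stats = report$roi_stats,
         cnr_per_channel = report$cnr_per_channel),
    path_json, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(c(path_csv, path_json))
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path_csv, path_json) {
  per_channel <- utils::read.csv(path_csv)
  js <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  structure(list(per_channel = per_channel, summary = js$summary,
                 roi_stats = js$roi_stats,
                 cnr_per_channel = js$cnr_per_channel),
            class = "metric_report")
}
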