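# Two-channel synthetic fluorescence images (DAPI nuclei + red gamma-H2AX
# foci) with exact ground truth, and the matching analysis chain: nucleus
# segmentation on the DAPI channel and spot detection on the red channel.

#' Image rendering parameters
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param pixel_um Pixel size (um).
#' @param nucleus_radius_um Range of nucleus semi-major axes (um).
#' @param ellipticity Range of semi-minor/semi-major ratios.
#' @param focus_sigma_px Gaussian focus PSF sigma (px).
#' @param focus_amp,nucleus_amp Peak amplitudes (arbitrary units in [0, 1]).
#' @param snr Peak-signal-to-noise ratio; `Inf` disables noise.
#' @param min_focus_sep_px Minimum separation between foci in one nucleus.
#' @param max_tries Rejection-placement retry budget.
#' @export
image_params <- function(width_px = 256, height_px = 256, pixel_um = 0.65,
                         nucleus_radius_um = c(6, 8),
                         ellipticity = c(0.75, 1),
                         focus_sigma_px = 1.5,
                         focus_amp = 1, nucleus_amp = 0.6,
                         snr = Inf, min_focus_sep_px = 4, max_tries = 500) {
  structure(as.list(environment()), class = "ImageParams")
}

#' Render a two-channel focus image with ground truth
#'
#' Places non-overlapping elliptical nuclei (rejection placement), renders
#' channel 1 (nuclei, smooth soft-edge profile) and channel 2 (one Gaussian
#' spot per true focus, all inside the parent nucleus), and adds
#' Poisson-Gaussian noise when `snr` is finite. Ground truth (per-focus
#' coordinates and per-nucleus counts) is returned alongside; it is
#' identical for any noise level at a fixed seed.
#'
#' @param foci_counts Integer vector: true focus count per nucleus.
#' @param params An [image_params()].
#' @param seed RNG seed.
#' @return A `FociImage` list: `dapi`, `red` (numeric matrices in [0, 1+]),
#'   `nuclei` (data frame of centres/axes), `truth` (data frame of focus
#'   coordinates), `params`, `seed`.
#' @export
render_foci_image <- function(foci_counts, params = image_params(), seed = 1L) {
  set.seed(seed)
  W <- params$width_px; H <- params$height_px
  n <- length(foci_counts)
  ax_px <- params$nucleus_radius_um / params$pixel_um

  nuc <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                    a = numeric(), b = numeric(), phi = numeric())
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(params$max_tries)) {
      a <- runif(1, ax_px[1], ax_px[2])
      b <- a * runif(1, params$ellipticity[1], params$ellipticity[2])
      phi <- runif(1, 0, pi)
      cx <- runif(1, a + 2, W - a - 2)
      cy <- runif(1, a + 2, H - a - 2)
      if (nrow(nuc) == 0 ||
          all(sqrt((nuc$cx - cx)^2 + (nuc$cy - cy)^2) > (nuc$a + a + 4))) {
        nuc <- rbind(nuc, data.frame(id = i, cx = cx, cy = cy, a = a, b = b,
                                     phi = phi))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping nuclei; use fewer cells ",
           "or a larger canvas")
  }

  xg <- matrix(rep(seq_len(W), H), nrow = W)
  yg <- matrix(rep(seq_len(H), each = W), nrow = W)
  dapi <- matrix(0, W, H)
  red <- matrix(0, W, H)
  truth <- list()
  for (i in seq_len(n)) {
    e <- nuc[i, ]
    dx <- xg - e$cx; dy <- yg - e$cy
    xr <- dx * cos(e$phi) + dy * sin(e$phi)
    yr <- -dx * sin(e$phi) + dy * cos(e$phi)
    q <- (xr / e$a)^2 + (yr / e$b)^2
    dapi <- dapi + params$nucleus_amp * exp(-q^3)   # flat core, soft edge
    k <- foci_counts[i]
    if (k > 0) {
      pts <- matrix(numeric(0), ncol = 2)
      for (j in seq_len(k)) {
        ok <- FALSE
        for (try in seq_len(params$max_tries)) {
          u <- sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          fx <- e$cx + 0.8 * e$a * u * cos(th) * cos(e$phi) -
            0.8 * e$b * u * sin(th) * sin(e$phi)
          fy <- e$cy + 0.8 * e$a * u * cos(th) * sin(e$phi) +
            0.8 * e$b * u * sin(th) * cos(e$phi)
          if (nrow(pts) == 0 ||
              all(sqrt((pts[, 1] - fx)^2 + (pts[, 2] - fy)^2) >=
                  params$min_focus_sep_px)) {
            pts <- rbind(pts, c(fx, fy))
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place ", k, " foci with the configured minimum ",
               "separation in nucleus ", i)
      }
      for (j in seq_len(nrow(pts))) {
        red <- red + params$focus_amp *
          exp(-((xg - pts[j, 1])^2 + (yg - pts[j, 2])^2) /
                (2 * params$focus_sigma_px^2))
        truth[[length(truth) + 1L]] <-
          data.frame(nucleus_id = i, x_px = pts[j, 1], y_px = pts[j, 2])
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(nucleus_id = integer(), x_px = numeric(), y_px = numeric())

  if (is.finite(params$snr)) {
    gain <- params$snr^2 / params$focus_amp
    red <- rpois(length(red), pmax(red, 0) * gain) / gain +
      rnorm(length(red), 0, params$focus_amp / (2 * params$snr))
    dim(red) <- c(W, H)
    dapi <- rpois(length(dapi), pmax(dapi, 0) * gain) / gain +
      rnorm(length(dapi), 0, params$nucleus_amp / (2 * params$snr))
    dim(dapi) <- c(W, H)
  }
  structure(list(dapi = dapi, red = red, nuclei = nuc, truth = truth,
                 params = params, seed = seed), class = "FociImage")
}

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian blur sigma (px) before thresholding.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold value (fraction of the image maximum)
#'   when `threshold = "fixed"`.
#' @param min_area_px,max_area_px Nucleus area bounds.
#' @param discard_border Drop nuclei touching the image border.
#' @param watershed Split touching nuclei by distance-transform watershed.
#' @export
segmentation_params <- function(smooth_sigma = 2, threshold = c("otsu", "fixed"),
                                fixed_threshold = 0.3, min_area_px = 40,
                                max_area_px = Inf, discard_border = TRUE,
                                watershed = FALSE) {
  threshold <- match.arg(threshold)
  structure(as.list(environment()), class = "SegmentationParams")
}

#' Segment nuclei on the DAPI channel
#'
#' Gaussian smoothing, Otsu (or fixed relative) thresholding, connected
#' component labelling, area filtering and optional watershed splitting.
#' Deterministic; intensity-scale invariant (the image is normalized to its
#' maximum before thresholding).
#'
#' @param dapi Numeric matrix (single channel).
#' @param params A [segmentation_params()].
#' @return A `SegmentationResult`: `label_mask` (integer matrix, 0 =
#'   background, labels contiguous 1..K) and `table` (per-nucleus area and
#'   centroid).
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  if (!is.matrix(dapi)) stop("dapi must be a single-channel matrix")
  mx <- max(dapi)
  empty <- list(label_mask = matrix(0L, nrow(dapi), ncol(dapi)),
                table = data.frame(nucleus_id = integer(), area_px = integer(),
                                   cx = numeric(), cy = numeric()))
  class(empty) <- "SegmentationResult"
  if (mx <= 0) return(empty)
  if (min(dapi) == mx) warning("saturated (constant) DAPI channel")
  img <- pmin(pmax(dapi / mx, 0), 1)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = params$smooth_sigma))
  thr <- if (params$threshold == "otsu")
    EBImage::otsu(EBImage::Image(sm), range = c(0, 1)) else params$fixed_threshold
  mask <- sm > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  if (params$watershed) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    lab <- EBImage::watershed(dm)
  }
  lab <- as.matrix(lab)
  if (max(lab) == 0) return(empty)
  keep <- integer(0)
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < params$min_area_px || area > params$max_area_px) next
    if (params$discard_border &&
        (any(idx[, 1] %in% c(1, nrow(lab))) || any(idx[, 2] %in% c(1, ncol(lab)))))
      next
    keep <- c(keep, k)
  }
  relab <- matrix(0L, nrow(lab), ncol(lab))
  tab <- list()
  for (j in seq_along(keep)) {
    idx <- which(lab == keep[j], arr.ind = TRUE)
    relab[idx] <- j
    tab[[j]] <- data.frame(nucleus_id = j, area_px = nrow(idx),
                           cx = mean(idx[, 1]), cy = mean(idx[, 2]))
  }
  out <- list(label_mask = relab,
              table = if (length(tab)) do.call(rbind, tab) else empty$table)
  class(out) <- "SegmentationResult"
  out
}

#' Spot detection parameters
#'
#' @param tophat_radius_px White-top-hat structuring disc radius for
#'   background removal.
#' @param log_sigma_px Laplacian-of-Gaussian scale, matched to the focus
#'   radius.
#' @param prominence Relative maxima threshold as a fraction of the global
#'   maximum filter response (intensity-scale invariant).
#' @param min_distance_px Minimum spot separation; closer maxima merge.
#' @export
detection_params <- function(tophat_radius_px = 5, log_sigma_px = 1.5,
                             prominence = 0.2, min_distance_px = 2) {
  structure(as.list(environment()), class = "DetectionParams")
}

log_kernel <- function(sigma) {
  k <- ceiling(3 * sigma)
  x <- matrix(rep(-k:k, 2 * k + 1), nrow = 2 * k + 1)
  y <- t(x)
  r2 <- x^2 + y^2
  g <- exp(-r2 / (2 * sigma^2))
  lg <- (r2 - 2 * sigma^2) / sigma^4 * g
  lg - mean(lg)
}

# greyscale max filter over a (2k+1)^2 window via shifted comparisons
max_filter <- function(m, k) {
  W <- nrow(m); H <- ncol(m)
  pad <- matrix(-Inf, W + 2 * k, H + 2 * k)
  pad[(k + 1):(k + W), (k + 1):(k + H)] <- m
  out <- matrix(-Inf, W, H)
  for (di in -k:k) for (dj in -k:k)
    out <- pmax(out, pad[(k + 1 + di):(k + W + di), (k + 1 + dj):(k + H + dj)])
  out
}

#' Count foci per nucleus on the red channel
#'
#' White-top-hat background removal, Laplacian-of-Gaussian filtering and
#' prominence-thresholded local maxima within the configured minimum spot
#' distance; maxima outside segmented nuclei are ignored. Deterministic and
#' invariant to global intensity scaling.
#'
#' @param red Numeric matrix (single channel), same shape as the mask.
#' @param seg A `SegmentationResult`.
#' @param params A [detection_params()].
#' @return A `FociCallTable`: `table` (`nucleus_id`, `n_foci`) covering
#'   every segmented nucleus, and `foci` (per-spot coordinates).
#' @export
count_foci <- function(red, seg, params = detection_params()) {
  mask <- seg$label_mask
  if (!all(dim(red) == dim(mask)))
    stop("red channel and segmentation mask shapes differ")
  ids <- seg$table$nucleus_id
  zero <- data.frame(nucleus_id = ids, n_foci = 0L)
  if (max(red) <= 0 || length(ids) == 0)
    return(structure(list(table = zero,
                          foci = data.frame(nucleus_id = integer(),
                                            x_px = numeric(), y_px = numeric())),
                     class = "FociCallTable"))
  img <- red / max(red)
  brush <- EBImage::makeBrush(2 * params$tophat_radius_px + 1, shape = "disc")
  th <- as.matrix(EBImage::whiteTopHat(EBImage::Image(img), brush))
  resp <- as.matrix(EBImage::filter2(EBImage::Image(th), -log_kernel(params$log_sigma_px)))
  # deterministic tie-break for plateau maxima
  W <- nrow(resp); H <- ncol(resp)
  resp <- resp + outer(seq_len(W), seq_len(H),
                       function(i, j) (i * H + j) * 1e-12)
  mf <- max_filter(resp, params$min_distance_px)
  thr <- params$prominence * max(resp)
  is_max <- resp == mf & resp >= thr & mask > 0
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(list(table = zero,
                          foci = data.frame(nucleus_id = integer(),
                                            x_px = numeric(), y_px = numeric())),
                     class = "FociCallTable"))
  nid <- mask[idx]
  cnt <- table(factor(nid, levels = ids))
  structure(list(table = data.frame(nucleus_id = ids,
                                    n_foci = as.integer(cnt)),
                 foci = data.frame(nucleus_id = nid, x_px = idx[, 1],
                                   y_px = idx[, 2])),
            class = "FociCallTable")
}

#' Benchmark spot detection against ground truth
#'
#' Greedy nearest-neighbour matching of detections to true focus positions
#' within `match_radius_px`; reports precision, recall and the mean count
#' bias (detected - true per nucleus).
#'
#' @param truth Data frame with `x_px`, `y_px` (and `nucleus_id`).
#' @param calls A `FociCallTable` (or data frame of detections).
#' @param true_counts Optional per-nucleus true counts for the bias.
#' @param match_radius_px Match radius.
#' @return List with `precision`, `recall`, `count_bias`, `n_matched`.
#' @export
detection_benchmark <- function(truth, calls, true_counts = NULL,
                                match_radius_px = 3) {
  det <- if (inherits(calls, "FociCallTable")) calls$foci else calls
  nt <- nrow(truth); nd <- nrow(det)
  if (nd == 0)
    return(list(precision = NA_real_, recall = 0, count_bias = -nt,
                n_matched = 0L))
  used <- rep(FALSE, nt)
  matched <- 0L
  if (nt > 0) {
    dmat <- outer(det$x_px, truth$x_px, "-")^2 + outer(det$y_px, truth$y_px, "-")^2
    for (i in seq_len(nd)) {
      j <- which.min(ifelse(used, Inf, dmat[i, ]))
      if (length(j) && !used[j] && dmat[i, j] <= match_radius_px^2) {
        used[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  bias <- if (!is.null(true_counts) && inherits(calls, "FociCallTable"))
    mean(calls$table$n_foci - true_counts) else nd - nt
  list(precision = matched / nd, recall = if (nt) matched / nt else NA_real_,
       count_bias = bias, n_matched = matched)
}
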