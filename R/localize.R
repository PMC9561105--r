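#' Render synthetic image frames from trajectories
#'
#' Draws one 2D Gaussian spot per particle per frame at the true position,
#' adds a constant background and Poisson shot noise, and clamps to the
#' 16-bit range. Pixel `(r, c)` is centred at `((c - 0.5) px, (r - 0.5) px)`
#' in image coordinates, with `x` along columns and `y` along rows.
#'
#' @param trajectories Tibble with `particle_id, frame, x_um, y_um` (use the
#'   simulator's true positions for an end-to-end localization test).
#' @param psf_sigma_px Gaussian spot width (pixels).
#' @param pixel_size_um Pixel pitch (um/px; default 0.345, the high-
#'   magnification camera pitch).
#' @param shape_px Image size `c(rows, cols)`.
#' @param background Constant background level (counts).
#' @param photon_scale Total integrated counts per spot.
#' @param noise Apply Poisson shot noise (`TRUE`) or render noiseless.
#' @param seed Optional seed for the shot noise.
#' @return A `rows x cols x frames` integer array of class `fbpm_stack` with
#'   attributes `pixel_size_um` and `frames` (the frame indices rendered).
#'   Particles outside the image are clipped with a warning.
#' @export
render_frames <- function(trajectories, psf_sigma_px = 1.2,
                          pixel_size_um = 0.345, shape_px = c(128, 128),
                          background = 100, photon_scale = 5000,
                          noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frames <- sort(unique(trajectories$frame))
  nr <- shape_px[1]; nc <- shape_px[2]
  stack <- array(background, dim = c(nr, nc, length(frames)))
  half <- ceiling(4 * psf_sigma_px)
  cx <- trajectories$x_um / pixel_size_um + 0.5  # px coords of pixel centres
  cy <- trajectories$y_um / pixel_size_um + 0.5
  oob <- cx < 1 | cx > nc | cy < 1 | cy > nr
  if (any(oob)) {
    warn(sprintf("%d spot position(s) outside the image were clipped.",
                 sum(oob)))
  }
  amp <- photon_scale / (2 * pi * psf_sigma_px^2)
  fidx <- match(trajectories$frame, frames)
  for (i in which(!oob)) {
    rows <- max(1, floor(cy[i]) - half):min(nr, floor(cy[i]) + half)
    cols <- max(1, floor(cx[i]) - half):min(nc, floor(cx[i]) + half)
    g <- amp * outer(exp(-(rows - cy[i])^2 / (2 * psf_sigma_px^2)),
                     exp(-(cols - cx[i])^2 / (2 * psf_sigma_px^2)))
    stack[rows, cols, fidx[i]] <- stack[rows, cols, fidx[i]] + g
  }
  if (noise) {
    stack[] <- rpois(length(stack), lambda = stack)
  }
  stack[stack > 65535] <- 65535
  storage.mode(stack) <- "integer"
  structure(stack, class = "fbpm_stack", pixel_size_um = pixel_size_um,
            frames = frames)
}

#' Read and write image stacks as multi-page 16-bit TIFF
#'
#' @param stack A `fbpm_stack` (or plain 3D array).
#' @param path File path.
#' @param pixel_size_um Pixel pitch recorded on read.
#' @return `read_stack()` returns a `fbpm_stack`; the writer returns `path`
#'   invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- purrr::map(seq_len(dim(stack)[3]),
                      function(k) stack[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size_um = 0.345) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0L, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
  for (k in seq_along(pages)) {
    stack[, , k] <- as.integer(round(pages[[k]] * 65535))
  }
  structure(stack, class = "fbpm_stack", pixel_size_um = pixel_size_um,
            frames = seq_along(pages))
}

#' Detect candidate spots in one frame
#'
#' Local maxima above `median + k * MAD` of the frame, with a minimum
#' pairwise separation enforced in decreasing-intensity order.
#'
#' @param frame 2D intensity matrix.
#' @param k MAD multiplier for the detection threshold (default 5).
#' @param min_sep_px Minimum centre-to-centre separation (pixels).
#' @param border Margin (pixels) inside which detections are discarded, so a
#'   full ROI fits around each detection.
#' @return A tibble `row, col, intensity`, empty for a blank frame. Warns on
#'   saturated frames.
#' @export
detect_spots <- function(frame, k = 5, min_sep_px = 5, border = 3) {
  if (length(frame) == 0) abort("Empty image.")
  if (any(frame >= 65535)) warn("Frame contains saturated pixels.")
  thr <- median(frame) + k * mad(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3 || nc < 3) abort("Image too small for spot detection.")
  inner <- frame[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & inner >= frame[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble(row = integer(0), col = integer(0),
                  intensity = numeric(0)))
  }
  det <- tibble(row = hits[, 1] + 1L, col = hits[, 2] + 1L) |>
    dplyr::mutate(intensity = frame[cbind(.data$row, .data$col)]) |>
    dplyr::filter(.data$row > border, .data$row <= nr - border,
                  .data$col > border, .data$col <= nc - border) |>
    dplyr::arrange(dplyr::desc(.data$intensity))
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- det[keep, ]
    keep[i] <- all((det$row[i] - prev$row)^2 +
                     (det$col[i] - prev$col)^2 >= min_sep_px^2)
  }
  det[keep, ]
}

#' Phasor-based subpixel localization of one ROI
#'
#' Computes the first Fourier coefficient of the ROI's marginal sums along
#' each axis; the phase angle, referenced to the ROI centre, gives the
#' subpixel offset as \eqn{-\phi N / (2\pi)} per axis. A constant background
#' cancels exactly in the first coefficient, making the estimator robust to
#' uniform offsets.
#'
#' @param roi Odd-sized square intensity matrix (>= 5 x 5).
#' @return Named numeric `c(dx, dy)`: offsets in pixels from the ROI centre
#'   (`dx` along columns, `dy` along rows).
#' @export
phasor_localize <- function(roi) {
  n <- nrow(roi)
  if (n != ncol(roi) || n %% 2 == 0 || n < 5) {
    abort("ROI must be an odd-sized square of at least 5 x 5 pixels.")
  }
  if (diff(range(roi)) == 0) {
    abort("Constant ROI: position undefined.",
          class = "fbpm_undefined_position")
  }
  c0 <- (n + 1) / 2
  u <- 0:(n - 1)
  phase_ref <- exp(2i * pi * (c0 - 1) / n)
  fx <- sum(colSums(roi) * exp(-2i * pi * u / n)) * phase_ref
  fy <- sum(rowSums(roi) * exp(-2i * pi * u / n)) * phase_ref
  if (Mod(fx) == 0 || Mod(fy) == 0) {
    abort("Vanishing first Fourier coefficient: position undefined.",
          class = "fbpm_undefined_position")
  }
  c(dx = -Arg(fx) * n / (2 * pi), dy = -Arg(fy) * n / (2 * pi))
}

#' Detect and localize all spots in an image stack
#'
#' Runs [detect_spots()] and [phasor_localize()] on every frame and returns
#' subpixel positions in micrometres.
#'
#' @param stack A `fbpm_stack` (or 3D array).
#' @param roi_px Odd ROI size for localization (default 7).
#' @param pixel_size_um Pixel pitch; default taken from the stack attribute.
#' @inheritParams detect_spots
#' @return A tibble `frame, x_um, y_um, intensity`.
#' @export
localize_stack <- function(stack, roi_px = 7, k = 5, min_sep_px = 5,
                           pixel_size_um = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(stack, "pixel_size_um") %||% 0.345
  frames <- attr(stack, "frames") %||% seq_len(dim(stack)[3])
  half <- roi_px %/% 2
  purrr::map2(seq_len(dim(stack)[3]), frames, function(k3, fr) {
    fm <- stack[, , k3]
    det <- detect_spots(fm, k = k, min_sep_px = min_sep_px, border = half)
    if (nrow(det) == 0) return(NULL)
    pos <- purrr::pmap(det, function(row, col, intensity) {
      roi <- fm[(row - half):(row + half), (col - half):(col + half)]
      off <- tryCatch(phasor_localize(roi),
                      error = function(e) c(dx = NA_real_, dy = NA_real_))
      tibble(frame = fr,
             x_um = (col + off[["dx"]] - 0.5) * pixel_size_um,
             y_um = (row + off[["dy"]] - 0.5) * pixel_size_um,
             intensity = intensity)
    })
    purrr::list_rbind(pos)
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(is.finite(.data$x_um))
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment: per frame, candidate pairs of active
#' tracks and detections within `max_disp_um` are linked in increasing
#' order of distance (ties broken by lower track id); unmatched detections
#' start new tracks; tracks missing for at most `max_gap` frames are
#' continued with the gap frames inserted as `valid = FALSE` rows
#' (linearly interpolated positions).
#'
#' @param detections Tibble `frame, x_um, y_um` (time-ordered or not).
#' @param max_disp_um Maximum per-frame displacement (um).
#' @param max_gap Maximum number of consecutive missed frames.
#' @param frame_rate_hz Used to reconstruct `t_s`.
#' @return A trajectory tibble `particle_id, frame, t_s, x_um, y_um, valid`.
#' @export
link_trajectories <- function(detections, max_disp_um, max_gap = 2,
                              frame_rate_hz = 60) {
  detections <- dplyr::arrange(detections, .data$frame)
  frames <- unique(detections$frame)
  tracks <- list()  # each: list(id, x, y, frames, xs, ys, last_frame)
  active <- integer(0)
  next_id <- 1L
  det_split <- split(detections, detections$frame)
  for (fr in frames) {
    d <- det_split[[as.character(fr)]]
    nd <- nrow(d)
    # drop tracks that exceeded the gap
    if (length(active)) {
      last <- vapply(tracks[active], function(t) t$last_frame, numeric(1))
      active <- active[fr - last <= max_gap + 1]
    }
    assigned_det <- rep(FALSE, nd)
    if (length(active) && nd > 0) {
      tx <- vapply(tracks[active], function(t) tail(t$xs, 1), numeric(1))
      ty <- vapply(tracks[active], function(t) tail(t$ys, 1), numeric(1))
      dist <- sqrt(outer(tx, d$x_um, "-")^2 + outer(ty, d$y_um, "-")^2)
      cand <- which(dist <= max_disp_um, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], active[cand[, 1]])
        used_tr <- rep(FALSE, length(active))
        for (ci in ord) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (used_tr[i] || assigned_det[j]) next
          used_tr[i] <- TRUE; assigned_det[j] <- TRUE
          ti <- active[i]
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, fr)
          tracks[[ti]]$xs <- c(tracks[[ti]]$xs, d$x_um[j])
          tracks[[ti]]$ys <- c(tracks[[ti]]$ys, d$y_um[j])
          tracks[[ti]]$last_frame <- fr
        }
      }
    }
    for (j in which(!assigned_det)) {
      tracks[[next_id]] <- list(id = next_id, frames = fr,
                                xs = d$x_um[j], ys = d$y_um[j],
                                last_frame = fr)
      active <- c(active, next_id)
      next_id <- next_id + 1L
    }
  }
  purrr::map(tracks, function(t) {
    full <- seq(min(t$frames), max(t$frames))
    if (length(t$frames) == 1) {
      xs <- t$xs; ys <- t$ys
    } else {
      xs <- approx(t$frames, t$xs, xout = full)$y
      ys <- approx(t$frames, t$ys, xout = full)$y
    }
    tibble(particle_id = t$id, frame = full,
           t_s = full / frame_rate_hz,
           x_um = xs, y_um = ys,
           valid = full %in% t$frames)
  }) |> purrr::list_rbind()
}
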