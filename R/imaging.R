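#' Frame utilities
#'
#' Frames are numeric matrices (grayscale) or height x width x 3 arrays
#' (RGB) with intensities in [0, 1]. RGB frames are reduced to luminance
#' (Rec. 601 weights) before any processing.
#'
#' @param x A matrix or 3-channel array.
#' @return A grayscale matrix.
#' @export
as_gray <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] >= 3L)
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L)
    return(x[, , 1])
  stop("as_gray: expected a matrix or an HxWx3 array")
}

check_dims <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s: dimension mismatch (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

#' Subtract the pre-experiment still from a frame
#'
#' Removes everything that was already present before the aerosol was
#' released: the per-pixel difference `frame - still`, clipped at zero.
#' Pixels darker than the still are artifacts of flicker or shadows, not
#' aerosol, so they are clipped rather than kept as absolute differences.
#'
#' @param frame,still Frames of identical dimensions (RGB is converted to
#'   luminance).
#' @return A grayscale matrix containing only content absent from the
#'   still.
#' @export
subtract_still <- function(frame, still) {
  f <- as_gray(frame); s <- as_gray(still)
  check_dims(f, s, "subtract_still")
  pmax(f - s, 0)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_sep <- function(img, k) {
  # separable convolution with edge replication
  r <- (length(k) - 1L) %/% 2L
  pad_rows <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  m <- pad_rows(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k))
    out <- out + k[i] * m[i:(i + nrow(img) - 1L), , drop = FALSE]
  m <- t(pad_rows(t(out)))
  out2 <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(k))
    out2 <- out2 + k[j] * m[, j:(j + ncol(img) - 1L), drop = FALSE]
  out2
}

shift_mat <- function(m, di, dj) {
  # shift with border replication
  n <- nrow(m); p <- ncol(m)
  i <- pmin(pmax(seq_len(n) + di, 1L), n)
  j <- pmin(pmax(seq_len(p) + dj, 1L), p)
  m[i, j, drop = FALSE]
}

#' Canny edge detection
#'
#' Classic Canny operator: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' two-threshold hysteresis (weak edges are kept only if connected to a
#' strong edge).
#'
#' @param img Grayscale matrix in [0, 1].
#' @param low,high Hysteresis thresholds on gradient magnitude
#'   (0 < low < high).
#' @param sigma Gaussian pre-smoothing standard deviation in pixels.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, low = 0.1, high = 0.2, sigma = 1.4) {
  img <- as_gray(img)
  if (low >= high) stop("canny_edges: need low < high hysteresis thresholds")
  if (low <= 0) stop("canny_edges: thresholds must be positive")
  sm <- convolve_sep(img, gaussian_kernel_1d(sigma))
  gx <- (shift_mat(sm, 0, 1) - shift_mat(sm, 0, -1)) / 2 +
    (shift_mat(sm, 1, 1) - shift_mat(sm, 1, -1)) / 4 +
    (shift_mat(sm, -1, 1) - shift_mat(sm, -1, -1)) / 4
  gy <- (shift_mat(sm, 1, 0) - shift_mat(sm, -1, 0)) / 2 +
    (shift_mat(sm, 1, 1) - shift_mat(sm, -1, 1)) / 4 +
    (shift_mat(sm, 1, -1) - shift_mat(sm, -1, -1)) / 4
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) # direction quantized to 0/45/90/135 degrees
  sector <- (round(ang / (pi / 4)) %% 4)
  nms <- mag
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L), "1" = c(1L, 1L),
                "2" = c(1L, 0L), "3" = c(1L, -1L))
    sel <- sector == s
    nb1 <- shift_mat(mag, d[1], d[2]); nb2 <- shift_mat(mag, -d[1], -d[2])
    nms[sel & (mag < nb1 | mag < nb2)] <- 0
  }
  strong <- nms >= high
  weak <- nms >= low
  # hysteresis: grow strong set through weak pixels (8-connectivity)
  repeat {
    grown <- strong
    for (di in -1:1) for (dj in -1:1)
      if (di || dj) grown <- grown | shift_mat(strong, di, dj)
    grown <- grown & weak
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

#' Overlay geometry edges on a difference frame
#'
#' Computes Canny edges on the original still (the static scene geometry)
#' and composites them over the aerosol difference frame at a fixed
#' intensity, so the experimental setup stays visible without distracting
#' from the aerosol signal. Pixels without an edge are passed through
#' unchanged.
#'
#' @param difference Difference frame from [subtract_still()].
#' @param original_still The unprocessed still frame.
#' @param low,high,sigma Canny parameters (see [canny_edges()]).
#' @param edge_intensity Intensity drawn at edge pixels (default 1).
#' @return A grayscale matrix.
#' @export
edge_overlay <- function(difference, original_still, low = 0.1, high = 0.2,
                         sigma = 1.4, edge_intensity = 1) {
  d <- as_gray(difference); s <- as_gray(original_still)
  check_dims(d, s, "edge_overlay")
  e <- canny_edges(s, low = low, high = high, sigma = sigma)
  out <- d
  out[e] <- edge_intensity
  out
}

#' Process a frame sequence
#'
#' Applies [subtract_still()] and [edge_overlay()] to every frame,
#' preserving order and count — the automated pipeline that turns raw
#' laser-sheet footage into aerosol-only imagery with a geometry overlay.
#'
#' @param frames List of frames (>= 1), all with identical dimensions.
#' @param still The pre-experiment still frame.
#' @param low,high,sigma,edge_intensity See [edge_overlay()].
#' @return List of processed grayscale matrices, same length as `frames`.
#' @export
process_sequence <- function(frames, still, low = 0.1, high = 0.2,
                             sigma = 1.4, edge_intensity = 1) {
  if (!length(frames)) stop("process_sequence: need at least one frame")
  s <- as_gray(still)
  edges <- canny_edges(s, low = low, high = high, sigma = sigma)
  lapply(seq_along(frames), function(i) {
    f <- as_gray(frames[[i]])
    if (!identical(dim(f), dim(s)))
      stop(sprintf("process_sequence: frame %d dimension mismatch", i))
    out <- pmax(f - s, 0)
    out[edges] <- edge_intensity
    out
  })
}

#' Synthetic laser-sheet frame generator
#'
#' Produces a test sequence: a static background scene (the "still"), a
#' Gaussian aerosol plume whose centre, width and amplitude vary per
#' frame, Gaussian sensor noise, and the ground-truth plume masks used as
#' oracles in tests. Uses the R RNG; seed it for byte-identical fixtures.
#'
#' @param n_frames Number of frames.
#' @param width,height Frame dimensions in pixels.
#' @param background Optional background matrix; default is a gentle
#'   gradient with a bright rectangle (something for the edge detector to
#'   find).
#' @param plume Function `(frame_index)` returning
#'   `list(x, y, sigma, amplitude)` for the plume in that frame; default is
#'   a blob translating across the frame.
#' @param noise_sd Gaussian pixel noise SD (default 0.01).
#' @return List with `frames` (list of matrices), `still` (matrix), `masks`
#'   (list of logical matrices marking pixels where the plume contributes
#'   at least half its amplitude), and `centroids` (n x 2 matrix of true
#'   plume centres, row/col).
#' @export
synth_frames <- function(n_frames = 4, width = 64, height = 48,
                         background = NULL, plume = NULL, noise_sd = 0.01) {
  if (is.null(background)) {
    background <- outer(seq(0, 0.2, length.out = height),
                        seq(0, 0.1, length.out = width), "+")
    background[(height %/% 3):(2 * height %/% 3),
               (width %/% 3):(2 * width %/% 3)] <- 0.8
  }
  if (is.null(plume)) {
    plume <- function(i) list(x = width * i / (n_frames + 1),
                              y = height / 2, sigma = 4, amplitude = 0.6)
  }
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  centroids <- matrix(NA_real_, n_frames, 2,
                      dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n_frames)) {
    p <- plume(i)
    blob <- p$amplitude * exp(-((rr - p$y)^2 + (cc - p$x)^2) / (2 * p$sigma^2))
    noise <- matrix(stats::rnorm(height * width, 0, noise_sd), height, width)
    frames[[i]] <- pmin(pmax(background + blob + noise, 0), 1)
    masks[[i]] <- blob >= p$amplitude / 2
    centroids[i, ] <- c(p$y, p$x)
  }
  list(frames = frames, still = background, masks = masks,
       centroids = centroids)
}

#' Read / write frames as PNG
#'
#' @param path PNG file path.
#' @return `read_frame` returns a matrix (grayscale files) or array;
#'   `write_frame` writes a [0, 1]-clamped frame and returns the path.
#' @export
read_frame <- function(path) png::readPNG(path)

#' @rdname read_frame
#' @param frame Frame to write.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(pmin(pmax(frame, 0), 1), path)
  path
}
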