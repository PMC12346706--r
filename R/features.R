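# Handcrafted reconstruction targets: the 354-D color-texture descriptor
# (uniform LBP histograms over R, G, B, Y, U, V) and the Sobel edge map.

check_image <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  invisible(image)
}

# BT.601 full-range YUV
.yuv_fwd <- matrix(c(
   0.299,     0.587,     0.114,
  -0.168736, -0.331264,  0.5,
   0.5,      -0.418688, -0.081312), 3, 3, byrow = TRUE)

#' Convert an RGB image to YUV (BT.601)
#'
#' Y is luma in `[0, 1]`; U and V are chroma channels centered at 0
#' (range `[-0.5, 0.5]` for inputs in `[0, 1]`).
#'
#' @param image H x W x 3 RGB array with values in `[0, 1]`
#' @return H x W x 3 array with channels (Y, U, V)
#' @examples
#' img <- array(1, c(4, 4, 3))      # white
#' yuv <- rgb_to_yuv(img)           # Y = 1, U = V = 0
#' @export
rgb_to_yuv <- function(image) {
  check_image(image)
  d <- dim(image)
  m <- matrix(image, d[1] * d[2], 3) %*% t(.yuv_fwd)
  array(m, d)
}

#' @rdname rgb_to_yuv
#' @param yuv H x W x 3 array of (Y, U, V) channels
#' @export
yuv_to_rgb <- function(yuv) {
  check_image(yuv)
  d <- dim(yuv)
  m <- matrix(yuv, d[1] * d[2], 3) %*% t(solve(.yuv_fwd))
  array(m, d)
}

reflect_pad1 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  if (h < 2L || w < 2L) stop("channel must be at least 2 x 2")
  x[c(2L, 1:h, h - 1L), c(2L, 1:w, w - 1L)]
}

# Circular neighbor order for P = 8, R = 1 (discrete 3x3 ring), starting at
# the right-hand neighbor and proceeding counter-clockwise in image
# coordinates: offsets (drow, dcol).
.lbp_offsets <- matrix(c(
   0L,  1L,
  -1L,  1L,
  -1L,  0L,
  -1L, -1L,
   0L, -1L,
   1L, -1L,
   1L,  0L,
   1L,  1L), ncol = 2, byrow = TRUE)

# Map each 8-bit code to a uniform-LBP bin: the 58 codes with at most two
# circular 0/1 transitions keep their value order (bins 0..57); all others
# share the catch-all bin 58.
lbp_uniform_table <- function() {
  codes <- 0:255
  trans <- vapply(codes, function(cd) {
    bits <- as.integer(intToBits(cd))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }, integer(1))
  uni <- codes[trans <= 2L]
  tab <- rep(58L, 256L)
  tab[uni + 1L] <- seq_along(uni) - 1L
  tab
}
.lbp_table <- lbp_uniform_table()

#' Uniform LBP code map of a single channel
#'
#' Computes the 8-neighbor, radius-1 local binary pattern at every pixel
#' (border neighbors obtained by reflect padding) with the comparator
#' "neighbor >= center", and maps each 8-bit code to its uniform-pattern bin:
#' bins 0..57 for the 58 uniform codes (at most two circular transitions) in
#' increasing code order, bin 58 for all non-uniform codes.
#'
#' @param channel H x W numeric matrix of finite values
#' @return H x W integer matrix of bin indices in `0..58`
#' @export
lbp_code_map <- function(channel) {
  if (is.null(dim(channel)) || length(channel) == 0)
    stop("channel must be a non-empty matrix")
  if (!all(is.finite(channel))) stop("channel contains non-finite values")
  p <- reflect_pad1(channel)
  h <- nrow(channel); w <- ncol(channel)
  code <- matrix(0L, h, w)
  for (b in seq_len(8L)) {
    dr <- .lbp_offsets[b, 1]; dc <- .lbp_offsets[b, 2]
    nb <- p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
    code <- code + bitwShiftL(as.integer(nb >= channel), b - 1L)
  }
  matrix(.lbp_table[code + 1L], h, w)
}

lbp_histogram <- function(channel) {
  codes <- lbp_code_map(channel)
  h <- tabulate(codes + 1L, nbins = 59L)
  h / sum(h)
}

#' Color-texture descriptor (354-D)
#'
#' Concatenates the L1-normalized 59-bin uniform LBP histograms of the six
#' channels R, G, B, Y, U, V (YUV per BT.601), in that order.
#'
#' @param image H x W x 3 RGB array with values in `[0, 1]`
#' @return numeric vector of length 354; each consecutive 59-bin block sums
#'   to 1
#' @examples
#' img <- array(0.5, c(16, 16, 3))
#' cti <- color_texture_descriptor(img)
#' length(cti)  # 354
#' @export
color_texture_descriptor <- function(image) {
  check_image(image)
  yuv <- rgb_to_yuv(image)
  chans <- c(lapply(1:3, function(k) image[, , k]),
             lapply(1:3, function(k) yuv[, , k]))
  out <- unlist(lapply(chans, lbp_histogram), use.names = FALSE)
  stopifnot(length(out) == 354L)
  out
}

sobel_xy <- function(luma) {
  p <- reflect_pad1(luma)
  h <- nrow(luma); w <- ncol(luma)
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  list(gx = gx, gy = gy)
}

#' Sobel edge map
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` of the BT.601 luma channel with
#' 3x3 Sobel kernels and reflect padding (output size equals input size).
#'
#' @param image H x W x 3 RGB array
#' @param rescale if `TRUE` (default) divide by the maximum magnitude when it
#'   is positive, so the map lies in `[0, 1]`
#' @return H x W matrix of non-negative edge magnitudes
#' @export
sobel_edge_map <- function(image, rescale = TRUE) {
  check_image(image)
  luma <- rgb_to_yuv(image)[, , 1]
  g <- sobel_xy(luma)
  e <- sqrt(g$gx^2 + g$gy^2)
  if (rescale) {
    mx <- max(e)
    if (mx > 0) e <- e / mx
  }
  e
}
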