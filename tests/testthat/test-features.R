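test_that("BT.601 conversion matches hand-derived values and inverts", {
  white <- array(1, c(4, 4, 3))
  yuv <- rgb_to_yuv(white)
  expect_equal(yuv[, , 1], matrix(1, 4, 4))
  expect_equal(max(abs(yuv[, , 2:3])), 0, tolerance = 1e-12)

  black <- array(0, c(4, 4, 3))
  expect_equal(max(abs(rgb_to_yuv(black))), 0)

  red <- array(rep(c(1, 0, 0), each = 16), c(4, 4, 3))
  yr <- rgb_to_yuv(red)
  expect_equal(yr[1, 1, 1], 0.299)
  expect_equal(yr[1, 1, 2], -0.168736)
  expect_equal(yr[1, 1, 3], 0.5)

  img <- rand_image(11, seed = 3)
  expect_equal(yuv_to_rgb(rgb_to_yuv(img)), img, tolerance = 1e-6)

  expect_error(rgb_to_yuv(matrix(0, 3, 3)), "H x W x 3")
})

test_that("uniform LBP codes follow the 59-bin contract", {
  # constant channel: every neighbor ties the center, ">=" sets all bits,
  # code 255 = the last uniform bin (57)
  cm <- lbp_code_map(matrix(0.4, 6, 6))
  expect_true(all(cm == 57L))

  # strict local maximum at an interior pixel: code 0, the first uniform bin
  ch <- matrix(0, 5, 5); ch[3, 3] <- 1
  expect_identical(lbp_code_map(ch)[3, 3], 0L)

  # alternating ring around the center: 8 circular transitions -> bin 58
  ring <- matrix(0.5, 3, 3)
  offs <- matrix(c(0, 1, -1, 1, -1, 0, -1, -1, 0, -1, 1, -1, 1, 0, 1, 1),
                 ncol = 2, byrow = TRUE)
  for (b in 1:8) ring[2 + offs[b, 1], 2 + offs[b, 2]] <- ifelse(b %% 2, 1, 0)
  expect_identical(lbp_code_map(ring)[2, 2], 58L)

  expect_error(lbp_code_map(numeric(0)), "non-empty")
})

test_that("lbp_code_map equals the brute-force comparator on random fields", {
  for (s in 1:4) {
    set.seed(100 + s)
    ch <- matrix(runif(16 * 16), 16, 16)
    expect_identical(lbp_code_map(ch), lbp_brute(ch))
  }
  # with ties present (quantized values)
  set.seed(5)
  chq <- matrix(sample(0:3, 16 * 16, replace = TRUE) / 3, 16, 16)
  expect_identical(lbp_code_map(chq), lbp_brute(chq))
})

test_that("color-texture descriptor is 354-D with unit-mass channel blocks", {
  img <- rand_image(16, seed = 11)
  v <- color_texture_descriptor(img)
  expect_length(v, 354L)
  expect_true(all(v >= 0))
  blocks <- matrix(v, 59)
  expect_equal(colSums(blocks), rep(1, 6), tolerance = 1e-9)

  const <- array(0.3, c(12, 12, 3))
  vc <- color_texture_descriptor(const)
  expect_identical(sum(vc == 1), 6L)
  expect_identical(sum(vc == 0), 354L - 6L)
})

test_that("180-degree rotation permutes LBP histograms by the code shift", {
  # rotating the image by 180 degrees shifts each 8-bit ring code by 4
  # positions, so per-channel histograms are equal only up to the induced
  # permutation of uniform bins (not bin-by-bin)
  codes_uni <- Filter(function(cd) {
    bits <- as.integer(intToBits(cd))[1:8]
    sum(bits != bits[c(2:8, 1)]) <= 2
  }, 0:255)
  bin_of <- function(code) {
    pos <- match(code, codes_uni)
    if (is.na(pos)) 58L else pos - 1L
  }
  set.seed(21)
  ch <- matrix(runif(14 * 14), 14, 14)
  rot <- ch[14:1, 14:1]
  h1 <- tabulate(lbp_code_map(ch) + 1L, 59L)
  h2 <- tabulate(lbp_code_map(rot) + 1L, 59L)
  perm_ok <- TRUE
  for (cd in codes_uni) {
    b <- bin_of(cd); b2 <- bin_of(shift4_code(cd))
    if (h2[b2 + 1L] != h1[b + 1L]) perm_ok <- FALSE
  }
  expect_true(perm_ok)
  expect_identical(h1[59], h2[59])  # non-uniform mass is shift-invariant
})

test_that("Sobel edge map: zero on constants, 4h on a step, size-preserving", {
  expect_equal(max(sobel_edge_map(array(0.7, c(9, 9, 3)))), 0)

  h <- 0.25
  img <- array(0.5, c(10, 10, 3))
  img[, 6:10, ] <- 0.5 + h     # vertical luma step between columns 5 and 6
  raw <- sobel_edge_map(img, rescale = FALSE)
  expect_equal(raw[5, 5], 4 * h, tolerance = 1e-12)
  expect_equal(raw[5, 6], 4 * h, tolerance = 1e-12)
  expect_equal(raw[5, 3], 0, tolerance = 1e-12)

  big <- rand_image(225, seed = 2)
  e <- sobel_edge_map(big)
  expect_identical(dim(e), c(225L, 225L))
  expect_true(all(e >= 0))
  expect_equal(max(e), 1)
})
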