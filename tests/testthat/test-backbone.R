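custom_cfg <- function(input) {
  backbone_config(
    input_size = input, patch_size = 9L, stride = 8L, channels = 64L,
    stem_channels = 16L,
    stages = list(
      list(blocks = 1L, mid = 8L,  out = 32L, stride = 2L, k3 = 3L),
      list(blocks = 1L, mid = 16L, out = 48L, stride = 2L, k3 = 3L),
      list(blocks = 1L, mid = 16L, out = 64L, stride = 2L, k3 = 1L)))
}

test_that("grid geometry follows (input - patch)/stride + 1 and the forward agrees", {
  for (input in c(41L, 57L, 65L)) {
    cfg <- custom_cfg(input)
    expect_identical(cfg$grid_side, (input - 9L) %/% 8L + 1L)
    bb <- build_backbone(cfg, seed = 1)
    f <- extract_features(bb, rand_image(input, seed = input))
    expect_identical(dim(f), c(cfg$grid_side, cfg$grid_side, 64L))
  }
  full <- full_backbone_config()
  expect_identical(full$grid_side, 25L)
  expect_identical(full$channels, 2048L)
  # inconsistent geometry is rejected
  expect_error(backbone_config(58L, 9L, 8L, 64L, 16L,
                               custom_cfg(57L)$stages), "divisible")
})

test_that("analytic receptive-field composition matches the declared geometry", {
  expect_identical(backbone_rf_arith(tiny_backbone_config()),
                   list(rf = 9L, stride = 8L))
  expect_identical(backbone_rf_arith(full_backbone_config()),
                   list(rf = 33L, stride = 8L))
})

test_that("features at a cell are bit-identical under out-of-patch edits", {
  bb <- build_backbone(tiny_backbone_config(), seed = 2)
  base <- rand_image(57, seed = 10)
  cell <- c(2L, 3L)
  rows <- (8L * (cell[1] - 1L) + 1L):(8L * (cell[1] - 1L) + 9L)
  cols <- (8L * (cell[2] - 1L) + 1L):(8L * (cell[2] - 1L) + 9L)
  f0 <- extract_features(bb, base)[cell[1], cell[2], ]
  set.seed(77)
  for (i in 1:100) {
    img <- rand_image(57)
    img[rows, cols, ] <- base[rows, cols, ]
    f <- extract_features(bb, img)[cell[1], cell[2], ]
    if (!identical(f, f0)) break
  }
  expect_identical(f, f0)
})

test_that("extract_features validates input and preserves batch order", {
  bb <- build_backbone(tiny_backbone_config(), seed = 3)
  expect_error(extract_features(bb, rand_image(56)), "no silent resize")
  expect_error(extract_features(bb, array(NA_real_, c(57, 57, 3))),
               "non-finite")
  imgs <- lapply(1:3, function(i) rand_image(57, seed = i))
  fs <- extract_features(bb, imgs)
  fs_perm <- extract_features(bb, imgs[c(3, 1, 2)])
  expect_identical(fs_perm[[1]], fs[[3]])
  expect_identical(fs_perm[[2]], fs[[1]])
})

test_that("a zero-weight backbone emits a spatially constant feature map", {
  bb <- build_backbone(tiny_backbone_config(), seed = 4)
  params <- dermbag:::nn_parameters(bb$layers)
  for (p in params) {
    cur <- p$layer[[p$name]]
    if (p$name %in% c("W", "b", "beta")) {
      assign(p$name, cur * 0, envir = p$layer)
    }
  }
  f <- extract_features(bb, rand_image(57, seed = 5))
  ref <- f[1, 1, ]
  expect_true(all(abs(sweep(matrix(f, 49, 64), 2, ref)) < 1e-12))
})

test_that("gradient-support probe equals the analytic receptive field", {
  bb <- build_backbone(tiny_backbone_config(), seed = 6)
  pr <- receptive_field_probe(bb, c(1L, 1L))
  expect_identical(c(pr$height, pr$width), c(9L, 9L))
  expect_identical(c(pr$row0, pr$col0), c(1L, 1L))
  pr <- receptive_field_probe(bb, c(4L, 2L))
  expect_identical(c(pr$height, pr$width), c(9L, 9L))
  expect_identical(c(pr$row0, pr$col0), c(8L * 3L + 1L, 8L * 1L + 1L))
  # a second valid geometry
  bb2 <- build_backbone(custom_cfg(41L), seed = 7)
  pr2 <- receptive_field_probe(bb2, c(3L, 3L))
  expect_identical(c(pr2$height, pr2$width), c(9L, 9L))
})
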