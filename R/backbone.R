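# Limited-receptive-field backbone: a residual bottleneck network with no
# spatial padding, arranged so each output grid cell depends on exactly one
# patch_size x patch_size input window at a fixed stride.

#' Backbone configuration
#'
#' Describes the geometry and layer plan of the local-feature backbone.  The
#' stem is a 1x1 convolution followed by a 3x3 convolution; each stage is a
#' run of residual bottleneck blocks whose first block may carry the stage's
#' single 3x3 convolution (and spatial stride).  With no padding anywhere the
#' composed receptive field and stride are fully determined by the layer plan
#' and are validated against `patch_size` and `stride`.
#'
#' @param input_size input image side length in pixels
#' @param patch_size receptive-field side of one output cell, pixels
#' @param stride composed stride of the output grid, pixels
#' @param channels channel dimensionality of the output feature map
#' @param stem_channels channels of the two stem convolutions
#' @param stages list of stages, each `list(blocks, mid, out, stride, k3)`
#' @param name label for printing
#' @return an object of class `backbone_config`
#' @examples
#' cfg <- tiny_backbone_config()
#' cfg$grid_side
#' @export
backbone_config <- function(input_size, patch_size, stride, channels,
                            stem_channels, stages, name = "custom") {
  cfg <- list(input_size = as.integer(input_size),
              patch_size = as.integer(patch_size),
              stride = as.integer(stride),
              channels = as.integer(channels),
              stem_channels = as.integer(stem_channels),
              stages = stages, name = name)
  if ((cfg$input_size - cfg$patch_size) %% cfg$stride != 0L)
    stop("(input_size - patch_size) must be divisible by stride")
  cfg$grid_side <- (cfg$input_size - cfg$patch_size) %/% cfg$stride + 1L
  rf <- backbone_rf_arith(cfg)
  if (rf$rf != cfg$patch_size || rf$stride != cfg$stride)
    stop(sprintf(
      "layer plan composes to receptive field %d / stride %d, not %d / %d",
      rf$rf, rf$stride, cfg$patch_size, cfg$stride))
  last <- cfg$stages[[length(cfg$stages)]]
  if (last$out != cfg$channels)
    stop("final stage output channels must equal config channels")
  class(cfg) <- "backbone_config"
  cfg
}

#' Analytic receptive-field composition of a backbone layer plan
#'
#' Folds kernel sizes and strides of the main path:
#' `rf <- rf + (k - 1) * jump; jump <- jump * s`.
#'
#' @param cfg a `backbone_config` (class check skipped so draft plans can be probed)
#' @return list with elements `rf` and `stride`
#' @export
backbone_rf_arith <- function(cfg) {
  rf <- 1L; jump <- 1L
  step <- function(k, s) {
    rf <<- rf + (k - 1L) * jump
    jump <<- jump * s
  }
  step(1L, 1L)              # stem 1x1
  step(3L, 1L)              # stem 3x3
  for (st in cfg$stages) {
    step(st$k3, st$stride)  # first block's spatial conv
    # remaining blocks are all-1x1, stride 1: no change
  }
  list(rf = as.integer(rf), stride = as.integer(jump))
}

#' Full-size backbone configuration (225 -> 25x25x2048, RF 33, stride 8)
#' @return a `backbone_config`
#' @export
full_backbone_config <- function() {
  backbone_config(
    input_size = 225L, patch_size = 33L, stride = 8L, channels = 2048L,
    stem_channels = 64L,
    stages = list(
      list(blocks = 3L, mid = 64L,  out = 256L,  stride = 2L, k3 = 3L),
      list(blocks = 4L, mid = 128L, out = 512L,  stride = 2L, k3 = 3L),
      list(blocks = 6L, mid = 256L, out = 1024L, stride = 2L, k3 = 3L),
      list(blocks = 3L, mid = 512L, out = 2048L, stride = 1L, k3 = 3L)),
    name = "full-33x8")
}

#' Tiny test-scale backbone configuration (57 -> 7x7x64, RF 9, stride 8)
#' @return a `backbone_config`
#' @export
tiny_backbone_config <- function() {
  backbone_config(
    input_size = 57L, patch_size = 9L, stride = 8L, channels = 64L,
    stem_channels = 16L,
    stages = list(
      list(blocks = 1L, mid = 8L,  out = 32L, stride = 2L, k3 = 3L),
      list(blocks = 1L, mid = 16L, out = 48L, stride = 2L, k3 = 3L),
      list(blocks = 1L, mid = 16L, out = 64L, stride = 2L, k3 = 1L)),
    name = "tiny-9x8")
}

#' Build a limited-receptive-field backbone
#'
#' @param config a `backbone_config`
#' @param seed optional integer; when given, parameter initialization is
#'   reproducible
#' @return a `dermbag_backbone` object
#' @examples
#' bb <- build_backbone(tiny_backbone_config(), seed = 1)
#' @export
build_backbone <- function(config, seed = NULL) {
  stopifnot(inherits(config, "backbone_config"))
  if (!is.null(seed)) set.seed(seed)
  layers <- list(
    nn_conv(3L, config$stem_channels, 1L, 1L),
    nn_bn(config$stem_channels),
    nn_relu(),
    nn_conv(config$stem_channels, config$stem_channels, 3L, 1L),
    nn_bn(config$stem_channels),
    nn_relu())
  cin <- config$stem_channels
  for (st in config$stages) {
    for (b in seq_len(st$blocks)) {
      if (b == 1L) {
        layers[[length(layers) + 1L]] <-
          nn_bottleneck(cin, st$mid, st$out, st$k3, st$stride)
      } else {
        layers[[length(layers) + 1L]] <-
          nn_bottleneck(st$out, st$mid, st$out, 1L, 1L)
      }
      cin <- st$out
    }
  }
  structure(list(config = config, layers = layers), class = "dermbag_backbone")
}

backbone_fwd <- function(backbone, xs, training = FALSE,
                         update_stats = training) {
  h <- xs
  for (ly in backbone$layers) {
    h <- if (inherits(ly, "nn_bottleneck")) {
      block_fwd(ly, h, training, update_stats)
    } else {
      layer_fwd(ly, h, training, update_stats)
    }
  }
  h
}

backbone_bwd <- function(backbone, gys, need_input = TRUE,
                         need_pgrads = TRUE) {
  g <- gys
  n <- length(backbone$layers)
  for (i in rev(seq_len(n))) {
    ly <- backbone$layers[[i]]
    want_in <- need_input || i > 1L
    g <- if (inherits(ly, "nn_bottleneck")) {
      block_bwd(ly, g, want_in, need_pgrads)
    } else {
      layer_bwd(ly, g, want_in, need_pgrads)
    }
  }
  g
}

check_image_batch <- function(images, input_size) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  stopifnot(is.list(images), length(images) > 0)
  for (x in images) {
    d <- dim(x)
    if (length(d) != 3L || d[3] != 3L)
      stop("each image must be an H x W x 3 array")
    if (d[1] != input_size || d[2] != input_size)
      stop(sprintf("image is %dx%d but the backbone expects %dx%d (no silent resize)",
                   d[1], d[2], input_size, input_size))
    if (!all(is.finite(x))) stop("image contains non-finite values")
  }
  images
}

#' Extract local features from a batch of images
#'
#' Runs the backbone in inference mode.  Each cell (i, j) of the returned
#' grid depends only on input pixels rows `[stride*(i-1) + 1, stride*(i-1) + patch]`
#' and the corresponding columns.
#'
#' @param backbone a `dermbag_backbone`
#' @param images one H x W x 3 array or a list of them; spatial size must
#'   equal the configured input size
#' @return a list of `grid x grid x channels` arrays (or one array if a
#'   single image was given)
#' @export
extract_features <- function(backbone, images) {
  single <- is.array(images) && length(dim(images)) == 3L
  images <- check_image_batch(images, backbone$config$input_size)
  out <- backbone_fwd(backbone, images, training = FALSE)
  if (single) out[[1]] else out
}

#' Measure the input support of one backbone output cell
#'
#' Backpropagates the channel-summed activation of one grid cell to the input
#' and reports the bounding box of nonzero gradient support.  With any
#' nonzero-weight initialization this equals the analytic receptive field.
#'
#' @param backbone a `dermbag_backbone`
#' @param cell integer pair (row, col), 1-based grid indices
#' @param image optional probe image; defaults to a uniform random image
#' @return list with `row0`, `col0` (1-based top-left), `height`, `width`
#' @export
receptive_field_probe <- function(backbone, cell = c(1L, 1L), image = NULL) {
  cfg <- backbone$config
  if (is.null(image)) {
    image <- array(runif(cfg$input_size^2 * 3), c(cfg$input_size, cfg$input_size, 3L))
  }
  f <- backbone_fwd(backbone, list(image), training = FALSE)[[1]]
  g <- array(0, dim(f))
  g[cell[1], cell[2], ] <- 1
  gx <- backbone_bwd(backbone, list(g), need_input = TRUE,
                     need_pgrads = FALSE)[[1]]
  supp <- apply(abs(gx), c(1, 2), max) > 0
  rows <- which(rowSums(supp) > 0)
  cols <- which(colSums(supp) > 0)
  if (length(rows) == 0)
    stop("zero gradient everywhere; probe requires nonzero weights")
  list(row0 = min(rows), col0 = min(cols),
       height = max(rows) - min(rows) + 1L,
       width = max(cols) - min(cols) + 1L)
}
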