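# Synthetic class-conditional lesion images.  Classes differ in two clinical
# cues: boundary sharpness (abrupt vs gradual pigment cutoff) and
# color-texture mottling (uniform vs blotchy pigmentation).  The generator
# knows its own geometry, so every image ships with a boundary-band mask for
# heatmap-overlap analyses.

#' Specification of a synthetic lesion dataset
#'
#' @param n_per_class images per class
#' @param classes list of class profiles, each
#'   `list(edge = "abrupt"|"gradual", texture = "uniform"|"mottled")`; the
#'   default three classes are (abrupt, uniform), (gradual, uniform),
#'   (gradual, mottled)
#' @param image_size image side in pixels (225 full scale, 57 tiny)
#' @param noise_sd standard deviation of the additive Gaussian pixel noise,
#'   intensity units on the `[0, 1]` scale
#' @param seed integer seed; generation is fully reproducible
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_per_class = 100L,
                           classes = list(
                             list(edge = "abrupt", texture = "uniform"),
                             list(edge = "gradual", texture = "uniform"),
                             list(edge = "gradual", texture = "mottled")),
                           image_size = 225L, noise_sd = 0.02, seed = 1L) {
  if (length(classes) < 2L) stop("need at least two classes")
  for (cl in classes) {
    if (!cl$edge %in% c("abrupt", "gradual") ||
        !cl$texture %in% c("uniform", "mottled"))
      stop("invalid class profile")
  }
  key <- vapply(classes, function(cl) paste(cl$edge, cl$texture), "")
  if (length(unique(key)) < 2L)
    stop("profiles must differ between at least two classes")
  structure(list(n_per_class = as.integer(n_per_class), classes = classes,
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

# smooth random field: coarse Gaussian grid, bilinearly upsampled
smooth_field <- function(size, cells) {
  g <- matrix(rnorm((cells + 1L)^2), cells + 1L)
  u <- seq(0, cells, length.out = size)
  i0 <- pmin(floor(u), cells - 1L); f <- u - i0
  a <- g[i0 + 1L, i0 + 1L, drop = FALSE]
  b <- g[i0 + 2L, i0 + 1L, drop = FALSE]
  cc <- g[i0 + 1L, i0 + 2L, drop = FALSE]
  d <- g[i0 + 2L, i0 + 2L, drop = FALSE]
  fa <- matrix(f, size, size); fb <- matrix(f, size, size, byrow = TRUE)
  (a * (1 - fa) + b * fa) * (1 - fb) + (cc * (1 - fa) + d * fa) * fb
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# palette and shape constants (fixed; see the methods vignette)
.syn <- list(
  skin = c(0.80, 0.62, 0.52),
  lesion = c(0.45, 0.30, 0.24),
  mottle_depth = 0.45,     # darkening amplitude of blotches inside lesion
  ramp = 0.45,             # relative half-width of the gradual boundary ramp
  band = 0.12,             # relative half-width of the boundary band mask
  bg_amp = 0.03)           # amplitude of background shading

synth_one_image <- function(size, profile) {
  cx <- runif(1, 0.40, 0.60) * size
  cy <- runif(1, 0.40, 0.60) * size
  ax <- runif(1, 0.24, 0.36) * size
  ay <- runif(1, 0.24, 0.36) * size
  th <- runif(1, 0, pi)
  xs <- matrix(seq_len(size) - cx, size, size)
  ys <- matrix(seq_len(size) - cy, size, size, byrow = TRUE)
  xr <- xs * cos(th) + ys * sin(th)
  yr <- -xs * sin(th) + ys * cos(th)
  d <- sqrt((xr / ax)^2 + (yr / ay)^2)   # normalized elliptical radius
  alpha <- if (profile$edge == "abrupt") {
    (d < 1) * 1.0
  } else {
    1 - smoothstep((d - (1 - .syn$ramp)) / (2 * .syn$ramp))
  }
  shading <- smooth_field(size, 4L) * .syn$bg_amp
  mottle <- if (profile$texture == "mottled") {
    f <- smooth_field(size, 8L) + 0.6 * smooth_field(size, 16L)
    smoothstep(f / 0.8) * .syn$mottle_depth
  } else {
    0
  }
  jitter <- runif(3, -0.03, 0.03)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    bg <- .syn$skin[ch] + shading
    les <- .syn$lesion[ch] + jitter[ch]
    les <- les * (1 - mottle)
    plane <- bg * (1 - alpha) + les * alpha
    img[, , ch] <- plane
  }
  img <- img + array(rnorm(length(img), sd = attr(size, "noise_sd") %||% 0),
                     dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, band = abs(d - 1) < .syn$band,
       params = list(cx = cx, cy = cy, ax = ax, ay = ay, theta = th))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic lesion dataset
#'
#' Each image is a shaded skin-toned background with one randomly placed
#' elliptical lesion; `"abrupt"` classes cut the pigment off at the boundary,
#' `"gradual"` classes blend it over a wide smoothstep ramp, and `"mottled"`
#' classes superimpose multi-scale dark blotches inside the lesion.  Labels
#' are balanced and each class is split 60/20/20 into train/val/test.
#'
#' @param spec a [synthetic_spec()]
#' @param dir optional directory; when given, PNG images, `manifest.csv`
#'   (`path,label,split`) and `geometry.json` (lesion parameters plus
#'   run-length-encoded boundary-band masks) are written there
#' @return list with `images`, `labels` (integers in `1..n_classes`),
#'   `split`, `bands` (logical boundary-band masks), `params`, `manifest`
#' @examples
#' d <- generate_lesion_dataset(synthetic_spec(n_per_class = 2,
#'                                             image_size = 57, seed = 1))
#' length(d$images)
#' @export
generate_lesion_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- length(spec$classes)
  n <- spec$n_per_class * K
  size <- spec$image_size
  attr(size, "noise_sd") <- spec$noise_sd
  images <- vector("list", n)
  bands <- vector("list", n)
  params <- vector("list", n)
  labels <- integer(n)
  split <- character(n)
  i <- 0L
  for (k in seq_len(K)) {
    n_tr <- round(0.6 * spec$n_per_class)
    n_va <- round(0.2 * spec$n_per_class)
    sp <- c(rep("train", n_tr), rep("val", n_va),
            rep("test", spec$n_per_class - n_tr - n_va))
    for (j in seq_len(spec$n_per_class)) {
      i <- i + 1L
      r <- synth_one_image(size, spec$classes[[k]])
      images[[i]] <- r$image
      bands[[i]] <- r$band
      params[[i]] <- r$params
      labels[i] <- k
      split[i] <- sp[j]
    }
  }
  manifest <- data.frame(
    path = sprintf("img_%04d.png", seq_len(n)),
    label = sprintf("class%d", labels),
    split = split, stringsAsFactors = FALSE)
  out <- list(images = images, labels = labels, split = split,
              bands = bands, params = params, manifest = manifest,
              spec = spec)
  if (!is.null(dir)) write_synthetic_dataset(out, dir)
  out
}

rle_encode <- function(mask) {
  r <- rle(as.integer(mask))
  list(lengths = r$lengths, values = r$values, dim = dim(mask))
}

write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(data$images)) {
    png::writePNG(data$images[[i]],
                  file.path(dir, data$manifest$path[i]))
  }
  write.csv(data$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  geom <- lapply(seq_along(data$images), function(i)
    list(params = data$params[[i]], band_rle = rle_encode(data$bands[[i]])))
  jsonlite::write_json(geom, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Deterministic fixtures for tests and examples
#'
#' `"tiny"` produces 57 x 57 images matched to the tiny backbone; `"full"`
#' produces 225 x 225 images.
#'
#' @param kind `"tiny"` or `"full"`
#' @param n_per_class images per class (default 20 tiny, 4 full)
#' @param seed integer seed
#' @return as [generate_lesion_dataset()]
#' @export
generate_fixture <- function(kind = c("tiny", "full"), n_per_class = NULL,
                             seed = 7L) {
  kind <- match.arg(kind)
  size <- if (kind == "tiny") 57L else 225L
  if (is.null(n_per_class)) n_per_class <- if (kind == "tiny") 20L else 4L
  generate_lesion_dataset(synthetic_spec(n_per_class = n_per_class,
                                         image_size = size, seed = seed))
}

#' Subset a synthetic dataset by split
#'
#' @param data a dataset from [generate_lesion_dataset()]
#' @param which one of `"train"`, `"val"`, `"test"`
#' @return the same structure restricted to the split
#' @export
dataset_split <- function(data, which = c("train", "val", "test")) {
  which <- match.arg(which)
  sel <- data$split == which
  list(images = data$images[sel], labels = data$labels[sel],
       bands = data$bands[sel], split = data$split[sel])
}
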