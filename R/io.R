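# Manifests, image decoding, and checkpoints.

#' Read an image file as an H x W x 3 array on the unit intensity scale
#'
#' Supports PNG and TIFF.  Grayscale images are replicated to three
#' channels; an alpha channel is dropped.
#'
#' @param path file path
#' @return H x W x 3 numeric array
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required for TIFF input")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "' (PNG or TIFF expected)"))
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] != 3L) stop("image must have 1, 3 or 4 channels: ", path)
  pmin(pmax(x, 0), 1)
}

#' Load a dataset manifest
#'
#' The manifest is a CSV with header columns `path,label,split`.  Labels are
#' mapped to contiguous integers in sorted label-name order (stable across
#' runs); splits must be one of train/val/test.
#'
#' @param path manifest CSV path
#' @param base_dir directory image paths are relative to (defaults to the
#'   manifest's directory)
#' @param check_paths verify every referenced image exists
#' @return list with `table` (data frame adding `label_id` and `abs_path`)
#'   and `levels` (label names in id order)
#' @export
load_manifest <- function(path, base_dir = dirname(path),
                          check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "split")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!df$split %in% c("train", "val", "test"))
  if (length(bad) > 0)
    stop("unknown split token in manifest row(s): ",
         paste(head(bad, 10), collapse = ", "))
  levels <- sort(unique(df$label))
  df$label_id <- match(df$label, levels)
  df$abs_path <- ifelse(grepl("^/", df$path), df$path,
                        file.path(base_dir, df$path))
  if (check_paths) {
    miss <- df$abs_path[!file.exists(df$abs_path)]
    if (length(miss) > 0)
      stop("missing image file(s): ", paste(head(miss, 10), collapse = ", "))
  }
  list(table = df, levels = levels)
}

#' Load the images of one manifest split into memory
#'
#' @param manifest result of [load_manifest()]
#' @param split one of train/val/test
#' @return list with `images` and `labels` ready for [train_model()] /
#'   [evaluate_model()]
#' @export
load_split <- function(manifest, split = c("train", "val", "test")) {
  split <- match.arg(split)
  tb <- manifest$table[manifest$table$split == split, , drop = FALSE]
  if (nrow(tb) == 0) stop("no rows for split '", split, "'")
  list(images = lapply(tb$abs_path, read_image), labels = tb$label_id)
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the model configuration, the flat parameter vector,
#' and the batch-normalization running statistics.
#'
#' @param model a `dermbag_model`
#' @param path checkpoint file path (RDS)
#' @return `save_checkpoint`: `path`, invisibly; `load_checkpoint`: a
#'   rebuilt `dermbag_model`
#' @export
save_checkpoint <- function(model, path) {
  params <- model_parameters(model)
  bn <- lapply(collect_layers(model_components(model)), function(ly) {
    if (ly$type == "bn") list(mean = ly$run_mean, var = ly$run_var)
  })
  obj <- list(config = model$config, w = param_vector(params), bn = bn)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  model <- ect_bofm(cfg$backbone, n_classes = cfg$n_classes,
                    descriptor_dim = cfg$descriptor_dim,
                    cti_mid = cfg$cti_mid, ei_mid = cfg$ei_mid,
                    dec_mid = cfg$dec_mid, gate_mid = cfg$gate_mid)
  set_param_vector(model_parameters(model), obj$w)
  layers <- collect_layers(model_components(model))
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !is.null(obj$bn[[i]])) {
      layers[[i]]$run_mean <- obj$bn[[i]]$mean
      layers[[i]]$run_var <- obj$bn[[i]]$var
    }
  }
  model
}
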