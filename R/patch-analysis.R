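# Heatmap-guided occlusion: rank candidate windows on the stride grid by
# their heatmap mass, mask (or exclusively retain) the top-k, and measure
# how classification metrics respond.

#' Rank candidate windows of a heatmap
#'
#' Candidates are all `window`-sized squares whose top-left corners lie on
#' the stride grid (grid_side^2 windows for the standard geometry).  Each is
#' scored by the sum of heatmap values it covers; ties are broken
#' deterministically in row-major order.
#'
#' @param heatmap square numeric matrix with finite entries
#' @param window window side length in pixels
#' @param stride stride of the candidate grid in pixels
#' @return data frame of class `patch_ranking` with 1-based `row`, `col`
#'   top-left corners ((row - 1) divisible by the stride) and non-increasing
#'   `score`
#' @export
rank_windows <- function(heatmap, window = 33L, stride = 8L) {
  if (!is.matrix(heatmap) || nrow(heatmap) != ncol(heatmap))
    stop("heatmap must be a square matrix")
  if (!all(is.finite(heatmap))) stop("heatmap must be finite")
  S <- nrow(heatmap)
  if ((S - window) %% stride != 0L)
    stop("window/stride do not tile the heatmap")
  tops <- seq(1L, S - window + 1L, by = stride)
  grid <- expand.grid(col = tops, row = tops)[, c("row", "col")]
  # summed-area table makes each window sum O(1)
  sat_core <- t(apply(apply(heatmap, 2, cumsum), 1, cumsum))
  sat <- rbind(0, cbind(0, sat_core))
  wsum <- function(r, c) {
    r2 <- r + window - 1L; c2 <- c + window - 1L
    sat[r2 + 1L, c2 + 1L] - sat[r, c2 + 1L] - sat[r2 + 1L, c] + sat[r, c]
  }
  grid$score <- mapply(wsum, grid$row, grid$col)
  ord <- order(-grid$score, grid$row, grid$col)
  out <- grid[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- as.integer(window)
  attr(out, "stride") <- as.integer(stride)
  class(out) <- c("patch_ranking", "data.frame")
  out
}

window_union_mask <- function(ranking, k, side) {
  w <- attr(ranking, "window")
  m <- matrix(FALSE, side, side)
  if (k == 0L) return(m)
  for (i in seq_len(k)) {
    r <- ranking$row[i]; cl <- ranking$col[i]
    m[r:(r + w - 1L), cl:(cl + w - 1L)] <- TRUE
  }
  m
}

#' Mask or retain the top-k ranked windows of an image
#'
#' `mask_top_k` zeroes every pixel covered by the union of the top-k
#' windows; `retain_top_k` zeroes every pixel outside it.  The two are
#' pixelwise complementary: their sum reconstructs the image.
#'
#' @param image H x W x 3 array
#' @param ranking a [rank_windows()] result
#' @param k number of top windows (0 <= k <= nrow(ranking)); windows overlap
#'   when the stride is smaller than the window, so k counts windows, not
#'   distinct pixels
#' @return transformed image array
#' @export
mask_top_k <- function(image, ranking, k) {
  k <- check_k(ranking, k)
  m <- window_union_mask(ranking, k, dim(image)[1])
  image * as.vector(!m)
}

#' @rdname mask_top_k
#' @export
retain_top_k <- function(image, ranking, k) {
  k <- check_k(ranking, k)
  m <- window_union_mask(ranking, k, dim(image)[1])
  image * as.vector(m)
}

check_k <- function(ranking, k) {
  if (k < 0) stop("k must be non-negative")
  if (k > nrow(ranking)) stop("k exceeds the number of candidate windows")
  as.integer(k)
}

random_ranking <- function(side, window, stride) {
  tops <- seq(1L, side - window + 1L, by = stride)
  grid <- expand.grid(col = tops, row = tops)[, c("row", "col")]
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  grid$score <- rev(seq_len(nrow(grid)))
  rownames(grid) <- NULL
  attr(grid, "window") <- as.integer(window)
  attr(grid, "stride") <- as.integer(stride)
  class(grid) <- c("patch_ranking", "data.frame")
  grid
}

#' Write / read a window ranking as CSV
#'
#' The on-disk form is a plain CSV of `row,col,score` (1-based top-left
#' corners, descending score), so rankings from other attribution methods
#' can be plugged into [occlusion_experiment()].
#'
#' @param ranking a `patch_ranking`
#' @param path CSV file path
#' @return `write_ranking`: `path`, invisibly; `read_ranking`: a
#'   `patch_ranking`
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)[, c("row", "col", "score")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param window,stride window geometry to attach to the loaded ranking
#' @export
read_ranking <- function(path, window = 33L, stride = 8L) {
  df <- read.csv(path)
  if (!all(c("row", "col", "score") %in% names(df)))
    stop("ranking CSV must have columns row,col,score")
  df <- df[order(-df$score, df$row, df$col), c("row", "col", "score")]
  rownames(df) <- NULL
  attr(df, "window") <- as.integer(window)
  attr(df, "stride") <- as.integer(stride)
  class(df) <- c("patch_ranking", "data.frame")
  df
}

#' Heatmap-guided occlusion experiment
#'
#' For every `k` in `k_values` and every requested mode, transforms each
#' test image (masking the top-k windows, retaining only them, or using a
#' uniformly random window ranking) and evaluates the model on the result.
#' Rankings from the model come from the overall heatmap of each image and
#' are computed once.  `k = 0` rows reproduce the unmasked baseline.
#'
#' @param model a trained `dermbag_model`
#' @param data list with `images` and `labels`
#' @param k_values integer vector of window counts (the standard sweep is
#'   `c(4, 8, 12, 16, 20)`)
#' @param modes subset of `c("mask", "retain", "random")`; `"random"` masks
#'   k windows drawn without replacement
#' @param seed seed for the random mode
#' @param rankings optional list of precomputed `patch_ranking`s, one per
#'   image (e.g. imported from another attribution method)
#' @return data frame with columns `mode`, `k`, `acc`, `macro_f1`,
#'   `macro_auc`
#' @export
occlusion_experiment <- function(model, data, k_values = c(4L, 8L, 12L, 16L, 20L),
                                 modes = c("mask", "retain", "random"),
                                 seed = 1L, rankings = NULL) {
  check_dataset(data)
  modes <- match.arg(modes, several.ok = TRUE)
  cfg <- model$config$backbone
  n <- length(data$images)
  if (is.null(rankings) && any(modes %in% c("mask", "retain"))) {
    rankings <- lapply(data$images, function(img) {
      hm <- heatmaps(model, img)
      rank_windows(hm$overall, cfg$patch_size, cfg$stride)
    })
  }
  set.seed(seed)
  rand_rank <- if ("random" %in% modes) {
    lapply(seq_len(n), function(i)
      random_ranking(cfg$input_size, cfg$patch_size, cfg$stride))
  }
  rows <- list()
  for (mode in modes) {
    for (k in sort(unique(as.integer(k_values)))) {
      imgs <- lapply(seq_len(n), function(i) {
        switch(mode,
          mask = mask_top_k(data$images[[i]], rankings[[i]], k),
          retain = retain_top_k(data$images[[i]], rankings[[i]], k),
          random = mask_top_k(data$images[[i]], rand_rank[[i]], k))
      })
      rep_ <- evaluate_model(model, list(images = imgs, labels = data$labels))
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, k = k, acc = rep_$acc, macro_f1 = rep_$macro_f1,
        macro_auc = rep_$macro_auc)
    }
  }
  do.call(rbind, rows)
}
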