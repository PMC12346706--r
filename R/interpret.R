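# Per-patch interpretability.  Because GAP and the affine classifier
# commute, the image logit is the mean over grid cells of per-cell FC
# responses; a per-patch class logit is therefore the FC row applied to one
# cell's concatenated gated features (plus the class bias).  Stride-1
# coverage of the zero-padded image is obtained by forwarding the
# stride*stride crop offsets of the padded image, which is exactly
# equivalent to explicit window extraction thanks to the locality of the
# backbone.

#' Classifier weight shares of the two streams
#'
#' Takes class `k`'s classifier row, zeroes its negative entries, and splits
#' the remaining mass between the first (CTI) and second (EI) halves:
#' `alpha_cti = sum(w_cti) / sum(w)` and likewise for EI, so the two shares
#' sum to one whenever the row has positive mass.  An all-nonpositive row
#' falls back to equal shares with a warning.
#'
#' @param fc_weights classifier weight matrix (`2*channels x n_classes`) or
#'   a single weight row
#' @param k class column to use when a matrix is given
#' @return list with `alpha_cti`, `alpha_ei`, and the rectified halves
#'   `w_cti`, `w_ei`
#' @export
alpha_weights <- function(fc_weights, k = 1L) {
  w <- if (is.matrix(fc_weights)) fc_weights[, k] else as.numeric(fc_weights)
  if (length(w) %% 2L != 0L) stop("weight row must split into two halves")
  w <- pmax(w, 0)
  half <- length(w) %/% 2L
  tot <- sum(w)
  if (tot <= 0) {
    warning("all-nonpositive classifier row; falling back to equal shares")
    return(list(alpha_cti = 0.5, alpha_ei = 0.5,
                w_cti = w[1:half], w_ei = w[(half + 1):(2 * half)]))
  }
  list(alpha_cti = sum(w[1:half]) / tot,
       alpha_ei = sum(w[(half + 1):(2 * half)]) / tot,
       w_cti = w[1:half], w_ei = w[(half + 1):(2 * half)])
}

pad_zero <- function(image, pad) {
  d <- dim(image)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- image
  out
}

cell_scores <- function(model, X, k) {
  # per-cell class-k logit and gate values for one backbone output
  gc_ <- gate(model, conv2d_fwd(X, model$div_cti$W, model$div_cti$b, 1L, 1L),
              "cti")
  ge_ <- gate(model, conv2d_fwd(X, model$div_ei$W, model$div_ei$b, 1L, 1L),
              "ei")
  d <- dim(X)
  Cf <- d[3]
  w <- model$cls$W[, k]
  b <- model$cls$b[k]
  mc <- matrix(gc_$gated, d[1] * d[2], Cf)
  me <- matrix(ge_$gated, d[1] * d[2], Cf)
  l <- mc %*% w[1:Cf] + me %*% w[(Cf + 1):(2 * Cf)] + b
  list(logit = matrix(l, d[1], d[2]),
       a_cti = matrix(gc_$gate[, , 1], d[1], d[2]),
       a_ei = matrix(ge_$gate[, , 1], d[1], d[2]))
}

#' Per-patch class logits and gate weights at stride 1
#'
#' Zero-pads the image by `(patch_size - 1) / 2` pixels per side and scores
#' every patch-sized window at stride 1: one window per input pixel.  For
#' each window position the class-`k` per-patch logit (FC row applied to the
#' cell's concatenated gated features, plus the class bias) and the two gate
#' values are returned.
#'
#' @param model a `dermbag_model`
#' @param image an `input_size` square image array
#' @param k class index in `1..n_classes`
#' @return list of three `input_size` square matrices: `logit`, `a_cti`,
#'   `a_ei`
#' @export
per_patch_scores <- function(model, image, k) {
  cfg <- model$config$backbone
  if (k < 1L || k > model$config$n_classes) stop("class index out of range")
  check_image_batch(list(image), cfg$input_size)
  S <- cfg$input_size; st <- cfg$stride
  pad <- (cfg$patch_size - 1L) %/% 2L
  padded <- pad_zero(image, pad)
  out_l <- out_c <- out_e <- matrix(NA_real_, S, S)
  for (dy in 0:(st - 1L)) {
    for (dx in 0:(st - 1L)) {
      sub <- padded[(dy + 1L):dim(padded)[1], (dx + 1L):dim(padded)[2], ,
                    drop = FALSE]
      X <- backbone_fwd(model$backbone, list(sub), training = FALSE)[[1]]
      sc <- cell_scores(model, X, k)
      g <- dim(sc$logit)
      rows <- dy + st * (seq_len(g[1]) - 1L) + 1L
      cols <- dx + st * (seq_len(g[2]) - 1L) + 1L
      keep_r <- rows <= S; keep_c <- cols <= S
      out_l[rows[keep_r], cols[keep_c]] <- sc$logit[keep_r, keep_c]
      out_c[rows[keep_r], cols[keep_c]] <- sc$a_cti[keep_r, keep_c]
      out_e[rows[keep_r], cols[keep_c]] <- sc$a_ei[keep_r, keep_c]
    }
  }
  list(logit = out_l, a_cti = out_c, a_ei = out_e)
}

#' Reference per-patch scores by explicit window extraction
#'
#' Literal (slow) implementation used to verify the padding contract: each
#' patch-sized window of the zero-padded image is cut out and forwarded on
#' its own.
#'
#' @inheritParams per_patch_scores
#' @param positions optional integer matrix of (row, col) window positions
#'   (1-based, in image coordinates); defaults to all positions
#' @return as [per_patch_scores()] but only at the requested positions
#'   (others `NA`)
#' @export
per_patch_scores_explicit <- function(model, image, k, positions = NULL) {
  cfg <- model$config$backbone
  S <- cfg$input_size
  pad <- (cfg$patch_size - 1L) %/% 2L
  padded <- pad_zero(image, pad)
  if (is.null(positions))
    positions <- as.matrix(expand.grid(seq_len(S), seq_len(S)))
  out_l <- out_c <- out_e <- matrix(NA_real_, S, S)
  for (i in seq_len(nrow(positions))) {
    r <- positions[i, 1]; cl <- positions[i, 2]
    win <- padded[r:(r + cfg$patch_size - 1L),
                  cl:(cl + cfg$patch_size - 1L), , drop = FALSE]
    X <- backbone_fwd(model$backbone, list(win), training = FALSE)[[1]]
    sc <- cell_scores(model, X, k)
    out_l[r, cl] <- sc$logit[1, 1]
    out_c[r, cl] <- sc$a_cti[1, 1]
    out_e[r, cl] <- sc$a_ei[1, 1]
  }
  list(logit = out_l, a_cti = out_c, a_ei = out_e)
}

minmax_norm <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) {
    warning("constant raw heatmap; normalized to all zeros")
    return(m * 0)
  }
  (m - lo) / (hi - lo)
}

#' CTI, EI and overall interpretability heatmaps
#'
#' Raw per-pixel scores are `a_cti * l`, `a_ei * l`, and their convex
#' combination weighted by the classifier-mass shares [alpha_weights()];
#' each map is then min-max normalized independently.
#'
#' @param model a `dermbag_model`
#' @param image an `input_size` square image array
#' @param k class to explain; default is the model's predicted class
#' @return list of class `dermbag_heatmaps` with `cti`, `ei`, `overall`
#'   (normalized), the `raw` maps, `k`, `alpha_cti`, `alpha_ei`
#' @export
heatmaps <- function(model, image, k = NULL) {
  if (is.null(k)) {
    p <- predict_proba(model, image)
    k <- which.max(p[1, ])
  }
  sc <- per_patch_scores(model, image, k)
  al <- alpha_weights(model$cls$W, k)
  raw <- list(cti = sc$a_cti * sc$logit,
              ei = sc$a_ei * sc$logit)
  raw$overall <- al$alpha_cti * raw$cti + al$alpha_ei * raw$ei
  structure(list(cti = minmax_norm(raw$cti), ei = minmax_norm(raw$ei),
                 overall = minmax_norm(raw$overall), raw = raw,
                 k = k, alpha_cti = al$alpha_cti, alpha_ei = al$alpha_ei),
            class = "dermbag_heatmaps")
}

#' Write heatmaps to a directory
#'
#' Writes three 8-bit grayscale PNGs, the raw score matrices as CSV, and a
#' JSON sidecar with the explained class and alpha shares.
#'
#' @param hm a `dermbag_heatmaps` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_heatmaps <- function(hm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("cti", "ei", "overall")) {
    png::writePNG(hm[[nm]], file.path(dir, paste0(nm, ".png")))
    write.csv(hm$raw[[nm]], file.path(dir, paste0(nm, "_raw.csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(k = hm$k, alpha_cti = hm$alpha_cti, alpha_ei = hm$alpha_ei),
    file.path(dir, "heatmaps.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
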