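# Training engine: dataset preparation, augmentation, the optimization loop,
# and evaluation metrics (accuracy, macro F1, macro one-vs-rest AUC).

#' Precompute reconstruction targets for a list of images
#'
#' @param images list of H x W x 3 arrays in `[0, 1]`
#' @return list with `C` (n x 354 descriptor matrix) and `E` (list of edge
#'   maps)
#' @export
prepare_targets <- function(images) {
  list(C = t(vapply(images, color_texture_descriptor, numeric(354))),
       E = lapply(images, sobel_edge_map))
}

aug_size <- function(input_size) as.integer(round(input_size * 256 / 225))

resize_image <- function(x, side) {
  y <- EBImage::resize(x, w = side, h = side)
  array(as.numeric(y), c(side, side, 3L))
}

crop_image <- function(x, side, r0, c0) {
  x[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE]
}

augment_image <- function(x, input_size) {
  a <- aug_size(input_size)
  if (dim(x)[1] != a) x <- resize_image(x, a)
  r0 <- sample.int(a - input_size + 1L, 1L)
  c0 <- sample.int(a - input_size + 1L, 1L)
  x <- crop_image(x, input_size, r0, c0)
  if (runif(1) < 0.5) x <- x[input_size:1, , , drop = FALSE]
  if (runif(1) < 0.5) x <- x[, input_size:1, , drop = FALSE]
  x
}

eval_transform_image <- function(x, input_size) {
  if (dim(x)[1] == input_size && dim(x)[2] == input_size) return(x)
  a <- aug_size(input_size)
  x <- resize_image(x, a)
  off <- (a - input_size) %/% 2L + 1L
  crop_image(x, input_size, off, off)
}

#' Accuracy, macro F1 and macro AUC of class-probability predictions
#'
#' Macro scores are unweighted means over the classes present in the truth;
#' a class absent from the truth has no defined AUC (or F1) and is excluded
#' with a warning.  All three headline values are on the percent scale.
#'
#' @param truth integer class labels in `1..K` (or a factor)
#' @param probs n x K matrix of class scores (rows need not be normalized
#'   for AUC; accuracy uses the row-wise argmax)
#' @return list of class `metrics_report` with `acc`, `macro_f1`,
#'   `macro_auc` (percent) and a `per_class` data frame
#' @export
metrics_report <- function(truth, probs) {
  truth <- as.integer(truth)
  K <- ncol(probs)
  n <- length(truth)
  stopifnot(nrow(probs) == n, all(truth >= 1L & truth <= K))
  pred <- max.col(probs, ties.method = "first")
  present <- sort(unique(truth))
  if (length(present) < K)
    warning("classes absent from the truth are excluded from macro averages: ",
            paste(setdiff(seq_len(K), present), collapse = ", "))
  f1 <- auc <- rep(NA_real_, K)
  for (k in present) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    f1[k] <- 2 * tp / (2 * tp + fp + fn)
    if (any(truth != k)) auc[k] <- auc_binary(probs[, k], truth == k)
  }
  structure(list(
    acc = 100 * mean(pred == truth),
    macro_f1 = 100 * mean(f1[present]),
    macro_auc = 100 * mean(auc[present], na.rm = TRUE),
    per_class = data.frame(class = seq_len(K), f1 = f1, auc = auc),
    n = n), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  Acc = %.2f  macro F1 = %.2f  macro AUC = %.2f\n",
              x$n, x$acc, x$macro_f1, x$macro_auc))
  invisible(x)
}

#' Rank-based binary AUC (Mann-Whitney, tie-aware)
#'
#' @param scores numeric scores, higher = more positive
#' @param positive logical vector of the same length
#' @return AUC in `[0, 1]`
#' @export
auc_binary <- function(scores, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("AUC needs both positives and negatives")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

check_dataset <- function(data, input_size = NULL) {
  stopifnot(is.list(data), !is.null(data$images), !is.null(data$labels))
  if (length(data$images) == 0) stop("empty dataset")
  if (length(data$images) != length(data$labels))
    stop("images and labels differ in length")
  invisible(data)
}

batch_losses <- function(model, imgs, yb, Cb, Eb, eps_cti, eps_ei,
                         params, update_stats) {
  zero_grads(params)
  cc <- ect_forward(model, imgs, training = TRUE,
                    update_stats = update_stats, with_decoders = TRUE,
                    eps_cti = eps_cti, eps_ei = eps_ei)
  ce <- softmax_ce(cc$logits, yb)
  nb <- length(imgs)
  gz_cti <- matrix(0, nb, model$config$descriptor_dim)
  grec <- vector("list", nb)
  l_rec <- 0
  for (i in seq_len(nb)) {
    r <- reconstruction_loss(Cb[i, ], cc$z_cti[i, ], Eb[[i]],
                             cc$rec_ei[[i]][, , 1])
    l_rec <- l_rec + r$l_rec / nb
    gz_cti[i, ] <- r$g_z_cti / nb
    g <- r$g_rec_ei / nb
    grec[[i]] <- array(g, c(dim(g), 1L))
  }
  ect_backward(model, cc, ce$grad, gz_cti = gz_cti, grec = grec,
               need_pgrads = TRUE, need_input = FALSE)
  list(grads = grad_vector(params), l = ce$loss + l_rec, l_s = ce$loss,
       l_rec = l_rec)
}

#' Train a model
#'
#' Runs the full objective (classification plus non-rigid reconstruction)
#' with the chosen optimizer and a cosine-annealed learning rate.  When a
#' validation set is supplied, the parameters achieving the best validation
#' macro F1 are restored at the end.
#'
#' @param model a `dermbag_model` (modified in place and returned)
#' @param train list with `images` (list of arrays), `labels` (integers in
#'   `1..n_classes`), and optionally precomputed targets `C` and `E`
#' @param val optional validation list of the same form (targets not needed)
#' @param epochs,batch_size training schedule (full-scale defaults: 100 / 16)
#' @param optimizer `"psam"` (default), `"sam"`, or `"sgd"`
#' @param config a [sam_config()] carrying lr / momentum / weight decay / rho
#' @param seed integer seed governing shuffling, augmentation, sampling noise
#'   and PSAM partitions
#' @param augment apply resize + random-crop + flip augmentation each epoch
#' @param verbose print one line per epoch
#' @return list with `model`, `history` (per-epoch data frame), and
#'   `best_epoch`
#' @export
train_model <- function(model, train, val = NULL, epochs = 20L,
                        batch_size = 16L, optimizer = c("psam", "sam", "sgd"),
                        config = sam_config(), seed = 1L, augment = TRUE,
                        verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  check_dataset(train)
  set.seed(seed)
  input_size <- model$config$backbone$input_size
  D <- model$config$descriptor_dim
  if (is.null(train$C) || is.null(train$E)) {
    tg <- prepare_targets(train$images)
    train$C <- tg$C; train$E <- tg$E
  }
  if (optimizer == "sgd") config$rho <- 0
  step_fn <- if (optimizer == "psam") psam_step else sam_step
  params <- model_parameters(model)
  state <- NULL
  n <- length(train$images)
  hist <- NULL
  best_f1 <- -Inf; best_w <- NULL; best_epoch <- NA_integer_
  for (ep in seq_len(epochs)) {
    lr_e <- cosine_lr(ep - 1L, epochs, config$lr)
    idx <- sample.int(n)
    ep_l <- ep_ls <- ep_lr <- 0; nb_seen <- 0
    for (start in seq(1L, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, n)]
      imgs <- lapply(train$images[bi], function(x) {
        if (augment) augment_image(x, input_size)
        else eval_transform_image(x, input_size)
      })
      # augmented geometry changes the edge target; recompute when augmenting
      Eb <- if (augment) lapply(imgs, sobel_edge_map) else train$E[bi]
      Cb <- if (augment) t(vapply(imgs, color_texture_descriptor,
                                  numeric(D))) else train$C[bi, , drop = FALSE]
      yb <- train$labels[bi]
      nbatch <- length(bi)
      eps_cti <- matrix(rnorm(nbatch * D), nbatch, D)
      g <- model$config$backbone$grid_side
      Cf <- model$config$backbone$channels
      eps_ei <- lapply(seq_len(nbatch), function(i)
        array(rnorm(g * g * Cf), c(g, g, Cf)))
      grad_fn <- function(update_stats)
        batch_losses(model, imgs, yb, Cb, Eb, eps_cti, eps_ei, params,
                     update_stats)
      r <- step_fn(params, grad_fn, state, config, lr = lr_e)
      state <- r$state
      ep_l <- ep_l + r$l; ep_ls <- ep_ls + r$l_s; ep_lr <- ep_lr + r$l_rec
      nb_seen <- nb_seen + 1
    }
    row <- data.frame(epoch = ep, lr = lr_e, l = ep_l / nb_seen,
                      l_s = ep_ls / nb_seen, l_rec = ep_lr / nb_seen,
                      val_acc = NA_real_, val_f1 = NA_real_,
                      val_auc = NA_real_)
    if (!is.null(val)) {
      vm <- evaluate_model(model, val)
      row$val_acc <- vm$acc; row$val_f1 <- vm$macro_f1
      row$val_auc <- vm$macro_auc
      if (vm$macro_f1 > best_f1) {
        best_f1 <- vm$macro_f1
        best_w <- param_vector(params)
        best_epoch <- ep
      }
    }
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.5f  L %.4f  L_S %.4f  L_Rec %.4f  val F1 %s",
        ep, lr_e, row$l, row$l_s, row$l_rec,
        ifelse(is.na(row$val_f1), "-", sprintf("%.2f", row$val_f1))))
  }
  if (!is.null(best_w)) set_param_vector(params, best_w)
  list(model = model, history = hist, best_epoch = best_epoch)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model a `dermbag_model`
#' @param data list with `images` and `labels`
#' @param batch_size images per forward batch
#' @return a [metrics_report()] with the probability matrix attached as
#'   attribute `"probs"`
#' @export
evaluate_model <- function(model, data, batch_size = 16L) {
  check_dataset(data)
  input_size <- model$config$backbone$input_size
  n <- length(data$images)
  probs <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    imgs <- lapply(data$images[bi], eval_transform_image, input_size)
    probs[bi, ] <- predict_proba(model, imgs)
  }
  rep_ <- metrics_report(data$labels, probs)
  attr(rep_, "probs") <- probs
  rep_
}
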