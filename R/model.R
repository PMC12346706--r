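# The full model: backbone -> divergers -> {gates -> classifier} and, in
# training, {non-rigid-reconstruction heads -> reparameterized samples ->
# decoders}.  Forward builds an explicit cache; backward consumes it.

fc_fwd <- function(layer, X) {
  layer$X <- X
  sweep(X %*% layer$W, 2, layer$b, "+")
}

fc_bwd <- function(layer, gY, need_pgrads = TRUE) {
  if (need_pgrads) {
    acc_grad(layer, "W", crossprod(layer$X, gY))
    acc_grad(layer, "b", colSums(gY))
  }
  gY %*% t(layer$W)
}

gap_vec <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

gap_bwd_one <- function(gvec, gh, gw) {
  array(rep(gvec, each = gh * gw) / (gh * gw), c(gh, gw, length(gvec)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct an edge- and color-texture-aware bag-of-local-features model
#'
#' @param backbone_cfg a [backbone_config()]; defaults to the full 225/33/8
#'   geometry with 2048 channels
#' @param n_classes number of lesion classes (7 and 8 for the standard
#'   dermoscopy benchmarks)
#' @param descriptor_dim length of the color-texture reconstruction target
#'   (354 = 6 channels x 59 uniform-LBP bins)
#' @param cti_mid,ei_mid,dec_mid,gate_mid bottleneck widths of the
#'   color-texture head, edge head, edge decoder and gates; defaults are the
#'   full-scale values (128, 128, 128, 64)
#' @param seed optional integer for reproducible initialization
#' @return a `dermbag_model`
#' @examples
#' m <- ect_bofm_tiny(n_classes = 3, seed = 1)
#' @export
ect_bofm <- function(backbone_cfg = full_backbone_config(), n_classes,
                     descriptor_dim = 354L, cti_mid = 128L, ei_mid = 128L,
                     dec_mid = 128L, gate_mid = 64L, seed = NULL) {
  stopifnot(n_classes >= 2L)
  if (!is.null(seed)) set.seed(seed)
  Cf <- backbone_cfg$channels
  m <- new.env(parent = emptyenv())
  m$config <- list(backbone = backbone_cfg, n_classes = as.integer(n_classes),
                   descriptor_dim = as.integer(descriptor_dim),
                   cti_mid = as.integer(cti_mid), ei_mid = as.integer(ei_mid),
                   dec_mid = as.integer(dec_mid), gate_mid = as.integer(gate_mid))
  m$backbone <- build_backbone(backbone_cfg)
  m$div_cti <- nn_conv(Cf, Cf, 1L, 1L)
  m$div_ei <- nn_conv(Cf, Cf, 1L, 1L)
  # color-texture NRR head: GAP -> ReLU -> FC -> ReLU -> FC, separate mu/sigma
  m$cti_mu_fc1 <- nn_fc(Cf, cti_mid); m$cti_mu_fc2 <- nn_fc(cti_mid, descriptor_dim)
  m$cti_sg_fc1 <- nn_fc(Cf, cti_mid); m$cti_sg_fc2 <- nn_fc(cti_mid, descriptor_dim)
  # edge NRR head: ReLU -> 1x1 conv -> ReLU -> 1x1 conv per grid cell
  m$ei_mu_r0 <- nn_relu(); m$ei_mu_c1 <- nn_conv(Cf, ei_mid, 1L, 1L)
  m$ei_mu_r1 <- nn_relu(); m$ei_mu_c2 <- nn_conv(ei_mid, Cf, 1L, 1L)
  m$ei_sg_r0 <- nn_relu(); m$ei_sg_c1 <- nn_conv(Cf, ei_mid, 1L, 1L)
  m$ei_sg_r1 <- nn_relu(); m$ei_sg_c2 <- nn_conv(ei_mid, Cf, 1L, 1L)
  # edge decoder: ReLU -> 1x1 -> ReLU -> 1x1 -> transposed conv (patch, stride)
  m$dec_r0 <- nn_relu(); m$dec_c1 <- nn_conv(Cf, dec_mid, 1L, 1L)
  m$dec_r1 <- nn_relu(); m$dec_c2 <- nn_conv(dec_mid, Cf, 1L, 1L)
  m$dec_t <- nn_tconv(Cf, 1L, backbone_cfg$patch_size, backbone_cfg$stride)
  # gates: 1x1 -> 1x1 -> sigmoid (no intermediate nonlinearity)
  m$gate_cti_c1 <- nn_conv(Cf, gate_mid, 1L, 1L)
  m$gate_cti_c2 <- nn_conv(gate_mid, 1L, 1L, 1L)
  m$gate_ei_c1 <- nn_conv(Cf, gate_mid, 1L, 1L)
  m$gate_ei_c2 <- nn_conv(gate_mid, 1L, 1L, 1L)
  m$cls <- nn_fc(2L * Cf, n_classes)
  class(m) <- "dermbag_model"
  m
}

#' @rdname ect_bofm
#' @export
ect_bofm_tiny <- function(n_classes = 3L, seed = NULL) {
  ect_bofm(tiny_backbone_config(), n_classes = n_classes,
           cti_mid = 32L, ei_mid = 16L, dec_mid = 16L, gate_mid = 8L,
           seed = seed)
}

model_components <- function(model) {
  list(model$backbone$layers, model$div_cti, model$div_ei,
       model$cti_mu_fc1, model$cti_mu_fc2, model$cti_sg_fc1, model$cti_sg_fc2,
       model$ei_mu_c1, model$ei_mu_c2, model$ei_sg_c1, model$ei_sg_c2,
       model$dec_c1, model$dec_c2, model$dec_t,
       model$gate_cti_c1, model$gate_cti_c2, model$gate_ei_c1, model$gate_ei_c2,
       model$cls)
}

#' @rdname ect_bofm
#' @param model a `dermbag_model`
#' @export
model_parameters <- function(model) nn_parameters(model_components(model))

gate_branch_fwd <- function(model, prefix, X, training, update_stats) {
  c1 <- model[[paste0(prefix, "_c1")]]
  c2 <- model[[paste0(prefix, "_c2")]]
  pre <- layer_fwd(c2, layer_fwd(c1, X, training, update_stats),
                   training, update_stats)
  A <- lapply(pre, sigmoid)
  gated <- Map(function(x, a) x * as.vector(a), X, A)
  list(A = A, gated = gated)
}

gate_branch_bwd <- function(model, prefix, X, A, ggated, need_pgrads) {
  gX <- Map(function(g, a) g * as.vector(a), ggated, A)
  gA <- Map(function(g, x, a) {
    d <- dim(x)
    array(rowSums(matrix(g * x, d[1] * d[2], d[3])), c(d[1], d[2], 1L))
  }, ggated, X, A)
  gpre <- Map(function(ga, a) ga * a * (1 - a), gA, A)
  c1 <- model[[paste0(prefix, "_c1")]]
  c2 <- model[[paste0(prefix, "_c2")]]
  gmid <- layer_bwd(c2, gpre, TRUE, need_pgrads)
  gX2 <- layer_bwd(c1, gmid, TRUE, need_pgrads)
  Map(`+`, gX, gX2)
}

ect_forward <- function(model, images, training = FALSE,
                        update_stats = training, with_decoders = training,
                        eps_cti = NULL, eps_ei = NULL) {
  cfg <- model$config
  images <- check_image_batch(images, cfg$backbone$input_size)
  n <- length(images)
  cc <- new.env(parent = emptyenv())
  cc$n <- n
  cc$X <- backbone_fwd(model$backbone, images, training, update_stats)
  cc$Xc <- layer_fwd(model$div_cti, cc$X, training, update_stats)
  cc$Xe <- layer_fwd(model$div_ei, cc$X, training, update_stats)
  gc_ <- gate_branch_fwd(model, "gate_cti", cc$Xc, training, update_stats)
  ge_ <- gate_branch_fwd(model, "gate_ei", cc$Xe, training, update_stats)
  cc$A_cti <- gc_$A; cc$Xcg <- gc_$gated
  cc$A_ei <- ge_$A; cc$Xeg <- ge_$gated
  cc$pool <- t(vapply(seq_len(n), function(i)
    c(gap_vec(cc$Xcg[[i]]), gap_vec(cc$Xeg[[i]])),
    numeric(2 * cfg$backbone$channels)))
  cc$logits <- fc_fwd(model$cls, cc$pool)
  if (with_decoders) {
    D <- cfg$descriptor_dim
    # color-texture branch (operates on pooled CTI features)
    cc$gap_c <- t(vapply(cc$Xc, gap_vec, numeric(cfg$backbone$channels)))
    cc$m0 <- cc$gap_c > 0
    u0 <- cc$gap_c * cc$m0
    h1 <- fc_fwd(model$cti_mu_fc1, u0); cc$m_mu1 <- h1 > 0
    cc$mu_cti <- fc_fwd(model$cti_mu_fc2, h1 * cc$m_mu1)
    h2 <- fc_fwd(model$cti_sg_fc1, u0); cc$m_sg1 <- h2 > 0
    cc$logsg_cti <- fc_fwd(model$cti_sg_fc2, h2 * cc$m_sg1)
    cc$sg_cti <- exp(cc$logsg_cti)
    if (is.null(eps_cti)) eps_cti <- matrix(rnorm(n * D), n, D)
    cc$eps_cti <- eps_cti
    cc$z_cti <- cc$mu_cti + cc$sg_cti * eps_cti
    # edge branch (per grid cell)
    r0m <- layer_fwd(model$ei_mu_r0, cc$Xe, training, update_stats)
    h <- layer_fwd(model$ei_mu_c1, r0m, training, update_stats)
    h <- layer_fwd(model$ei_mu_r1, h, training, update_stats)
    cc$mu_ei <- layer_fwd(model$ei_mu_c2, h, training, update_stats)
    r0s <- layer_fwd(model$ei_sg_r0, cc$Xe, training, update_stats)
    h <- layer_fwd(model$ei_sg_c1, r0s, training, update_stats)
    h <- layer_fwd(model$ei_sg_r1, h, training, update_stats)
    cc$sg_ei <- lapply(layer_fwd(model$ei_sg_c2, h, training, update_stats), exp)
    if (is.null(eps_ei))
      eps_ei <- lapply(cc$mu_ei, function(mu)
        array(rnorm(length(mu)), dim(mu)))
    cc$eps_ei <- eps_ei
    cc$z_ei <- Map(function(mu, sg, e) mu + sg * e, cc$mu_ei, cc$sg_ei, eps_ei)
    # decoder to the image-sized edge reconstruction
    d0 <- layer_fwd(model$dec_r0, cc$z_ei, training, update_stats)
    d1 <- layer_fwd(model$dec_c1, d0, training, update_stats)
    d2 <- layer_fwd(model$dec_r1, d1, training, update_stats)
    d3 <- layer_fwd(model$dec_c2, d2, training, update_stats)
    cc$rec_ei <- layer_fwd(model$dec_t, d3, training, update_stats)
  }
  cc
}

ect_backward <- function(model, cc, glogits, gz_cti = NULL, grec = NULL,
                         need_pgrads = TRUE, need_input = FALSE) {
  cfg <- model$config
  Cf <- cfg$backbone$channels
  gpool <- fc_bwd(model$cls, glogits, need_pgrads)
  gd <- dim(cc$Xcg[[1]])
  gXc <- vector("list", cc$n); gXe <- vector("list", cc$n)
  gXcg <- lapply(seq_len(cc$n), function(i)
    gap_bwd_one(gpool[i, 1:Cf], gd[1], gd[2]))
  gXeg <- lapply(seq_len(cc$n), function(i)
    gap_bwd_one(gpool[i, (Cf + 1):(2 * Cf)], gd[1], gd[2]))
  gXc <- gate_branch_bwd(model, "gate_cti", cc$Xc, cc$A_cti, gXcg, need_pgrads)
  gXe <- gate_branch_bwd(model, "gate_ei", cc$Xe, cc$A_ei, gXeg, need_pgrads)
  if (!is.null(gz_cti)) {
    gmu <- gz_cti
    glogsg <- gz_cti * cc$eps_cti * cc$sg_cti
    gh1 <- fc_bwd(model$cti_mu_fc2, gmu, need_pgrads) * cc$m_mu1
    gu0_mu <- fc_bwd(model$cti_mu_fc1, gh1, need_pgrads)
    gh2 <- fc_bwd(model$cti_sg_fc2, glogsg, need_pgrads) * cc$m_sg1
    gu0_sg <- fc_bwd(model$cti_sg_fc1, gh2, need_pgrads)
    ggap <- (gu0_mu + gu0_sg) * cc$m0
    for (i in seq_len(cc$n)) {
      gXc[[i]] <- gXc[[i]] + gap_bwd_one(ggap[i, ], gd[1], gd[2])
    }
  }
  if (!is.null(grec)) {
    gd3 <- layer_bwd(model$dec_t, grec, TRUE, need_pgrads)
    gd2 <- layer_bwd(model$dec_c2, gd3, TRUE, need_pgrads)
    gd1 <- layer_bwd(model$dec_r1, gd2, TRUE, need_pgrads)
    gd0 <- layer_bwd(model$dec_c1, gd1, TRUE, need_pgrads)
    gz <- layer_bwd(model$dec_r0, gd0, TRUE, need_pgrads)
    gmu_e <- gz
    glogsg_e <- Map(function(g, e, s) g * e * s, gz, cc$eps_ei, cc$sg_ei)
    gh <- layer_bwd(model$ei_mu_c2, gmu_e, TRUE, need_pgrads)
    gh <- layer_bwd(model$ei_mu_r1, gh, TRUE, need_pgrads)
    gh <- layer_bwd(model$ei_mu_c1, gh, TRUE, need_pgrads)
    gXe_mu <- layer_bwd(model$ei_mu_r0, gh, TRUE, need_pgrads)
    gh <- layer_bwd(model$ei_sg_c2, glogsg_e, TRUE, need_pgrads)
    gh <- layer_bwd(model$ei_sg_r1, gh, TRUE, need_pgrads)
    gh <- layer_bwd(model$ei_sg_c1, gh, TRUE, need_pgrads)
    gXe_sg <- layer_bwd(model$ei_sg_r0, gh, TRUE, need_pgrads)
    gXe <- Map(function(a, b, d) a + b + d, gXe, gXe_mu, gXe_sg)
  }
  gX1 <- layer_bwd(model$div_cti, gXc, TRUE, need_pgrads)
  gX2 <- layer_bwd(model$div_ei, gXe, TRUE, need_pgrads)
  gX <- Map(`+`, gX1, gX2)
  backbone_bwd(model$backbone, gX, need_input, need_pgrads)
}

# ---- exported head operations (contract surface) --------------------------

#' Split a shared feature map into CTI- and EI-biased maps
#'
#' Two independent 1x1 convolutions (no nonlinearity, parameters not shared).
#'
#' @param model a `dermbag_model`
#' @param X a `grid x grid x channels` feature array
#' @return list with elements `X_cti` and `X_ei`
#' @export
diverge <- function(model, X) {
  list(X_cti = conv2d_fwd(X, model$div_cti$W, model$div_cti$b, 1L, 1L),
       X_ei = conv2d_fwd(X, model$div_ei$W, model$div_ei$b, 1L, 1L))
}

#' Gaussian field of the color-texture reconstruction head
#'
#' GAP -> ReLU -> FC -> ReLU -> FC for the mean and, with separate
#' parameters, for the log standard deviation (exponentiated so sigma > 0).
#'
#' @param model a `dermbag_model`
#' @param X_cti CTI-biased feature array
#' @return list with `mu` and `sigma`, both length `descriptor_dim`
#' @export
nrr_distribution_cti <- function(model, X_cti) {
  u0 <- pmax(gap_vec(X_cti), 0)
  u0 <- matrix(u0, 1)
  mu <- fc_fwd(model$cti_mu_fc2, pmax(fc_fwd(model$cti_mu_fc1, u0), 0))
  ls <- fc_fwd(model$cti_sg_fc2, pmax(fc_fwd(model$cti_sg_fc1, u0), 0))
  list(mu = drop(mu), sigma = exp(drop(ls)))
}

#' Gaussian field of the edge reconstruction head
#'
#' Per-cell ReLU -> 1x1 conv -> ReLU -> 1x1 conv bottleneck for the mean and
#' (separate parameters) the log standard deviation.
#'
#' @param model a `dermbag_model`
#' @param X_ei EI-biased feature array
#' @return list with `mu` and `sigma` arrays shaped like `X_ei`
#' @export
nrr_distribution_ei <- function(model, X_ei) {
  f <- function(c1, c2) {
    h <- conv2d_fwd(X_ei * (X_ei > 0), c1$W, c1$b, 1L, 1L)
    conv2d_fwd(h * (h > 0), c2$W, c2$b, 1L, 1L)
  }
  list(mu = f(model$ei_mu_c1, model$ei_mu_c2),
       sigma = exp(f(model$ei_sg_c1, model$ei_sg_c2)))
}

#' Reparameterized Gaussian sample z = mu + sigma * eps
#'
#' @param mu,sigma numeric vectors/arrays of equal shape; `sigma > 0`
#' @param eps optional standard-normal draw of the same shape; if `NULL`,
#'   drawn internally (use `seed` for reproducibility)
#' @param seed optional integer seed used when `eps` is drawn internally
#' @return sample of the same shape as `mu`
#' @export
reparameterized_sample <- function(mu, sigma, eps = NULL, seed = NULL) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (is.null(eps)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- rnorm(length(mu))
    if (!is.null(dim(mu))) dim(eps) <- dim(mu)
  }
  mu + sigma * eps
}

#' Upsample an edge-branch sample to an image-sized reconstruction
#'
#' ReLU -> 1x1 conv -> ReLU -> 1x1 conv -> transposed convolution with
#' kernel `patch_size` and stride `stride`, in strict spatial correspondence
#' with the backbone's downsampling: a `g x g` grid maps to
#' `(g - 1) * stride + patch_size` pixels per side.
#'
#' @param model a `dermbag_model`
#' @param z_ei `grid x grid x channels` sample array
#' @return `input_size x input_size` matrix
#' @export
upsample_ei <- function(model, z_ei) {
  if (dim(z_ei)[1] != model$config$backbone$grid_side)
    stop("sample grid does not match the backbone grid")
  d0 <- z_ei * (z_ei > 0)
  d1 <- conv2d_fwd(d0, model$dec_c1$W, model$dec_c1$b, 1L, 1L)
  d3 <- conv2d_fwd(d1 * (d1 > 0), model$dec_c2$W, model$dec_c2$b, 1L, 1L)
  out <- convt2d_fwd(d3, model$dec_t$W, model$dec_t$b,
                     model$dec_t$k, model$dec_t$stride)
  out[, , 1]
}

#' Spatial gate: sigmoid attention map and gated features
#'
#' @param model a `dermbag_model`
#' @param X_biased a diverged feature array
#' @param branch `"cti"` or `"ei"` (selects the gate's parameters)
#' @return list with `gated` (same shape as input) and `gate`
#'   (`grid x grid x 1`, values in (0, 1))
#' @export
gate <- function(model, X_biased, branch = c("cti", "ei")) {
  branch <- match.arg(branch)
  c1 <- model[[paste0("gate_", branch, "_c1")]]
  c2 <- model[[paste0("gate_", branch, "_c2")]]
  pre <- conv2d_fwd(conv2d_fwd(X_biased, c1$W, c1$b, 1L, 1L),
                    c2$W, c2$b, 1L, 1L)
  A <- sigmoid(pre)
  list(gated = X_biased * as.vector(A), gate = A)
}

#' Classify gated feature maps
#'
#' Concatenation, global average pooling, and the affine classifier.
#'
#' @param model a `dermbag_model`
#' @param X_cti_g,X_ei_g gated feature arrays of equal shape
#' @return numeric vector of `n_classes` logits
#' @export
classify <- function(model, X_cti_g, X_ei_g) {
  stopifnot(all(dim(X_cti_g) == dim(X_ei_g)))
  feat <- matrix(c(gap_vec(X_cti_g), gap_vec(X_ei_g)), 1)
  drop(fc_fwd(model$cls, feat))
}

#' Image-level class probabilities
#'
#' Inference-mode forward pass (decoders dropped).
#'
#' @param model a `dermbag_model`
#' @param images one image array or a list of them
#' @return matrix of softmax probabilities, one row per image
#' @export
predict_proba <- function(model, images) {
  cc <- ect_forward(model, images, training = FALSE, with_decoders = FALSE)
  z <- cc$logits - apply(cc$logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- NULL
  p
}
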