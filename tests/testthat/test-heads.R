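tiny_model <- function(seed = 1) ect_bofm_tiny(n_classes = 3L, seed = seed)

rand_grid <- function(model, seed = NULL) {
  g <- model$config$backbone$grid_side
  Cf <- model$config$backbone$channels
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(g * g * Cf), c(g, g, Cf))
}

test_that("divergers are shape-preserving independent affine maps", {
  m <- tiny_model(1)
  X1 <- rand_grid(m, 1); X2 <- rand_grid(m, 2)
  d1 <- diverge(m, X1); d2 <- diverge(m, X2)
  expect_identical(dim(d1$X_cti), dim(X1))
  expect_identical(dim(d1$X_ei), dim(X1))
  # affinity: differences are linear (biases cancel)
  dz <- diverge(m, X1 - X2)
  d0 <- diverge(m, X1 * 0)
  expect_equal(d1$X_cti - d2$X_cti, dz$X_cti - d0$X_cti, tolerance = 1e-10)
  expect_equal(d1$X_ei - d2$X_ei, dz$X_ei - d0$X_ei, tolerance = 1e-10)
  # branches hold distinct parameters
  expect_false(identical(m$div_cti$W, m$div_ei$W))
  # identity-initialized CTI diverger passes features through
  m$div_cti$W <- diag(64); m$div_cti$b <- numeric(64)
  expect_equal(diverge(m, X1)$X_cti, X1, tolerance = 1e-12)
})

test_that("CTI head: 354-D field, unit sigma at zero weights, GAP sufficiency", {
  m <- tiny_model(2)
  X <- rand_grid(m, 3)
  f <- nrr_distribution_cti(m, X)
  expect_length(f$mu, 354L)
  expect_length(f$sigma, 354L)
  expect_true(all(f$sigma > 0))
  # zero sigma branch -> log sigma = 0 -> sigma = 1
  m$cti_sg_fc1$W <- m$cti_sg_fc1$W * 0; m$cti_sg_fc1$b <- m$cti_sg_fc1$b * 0
  m$cti_sg_fc2$W <- m$cti_sg_fc2$W * 0; m$cti_sg_fc2$b <- m$cti_sg_fc2$b * 0
  expect_equal(nrr_distribution_cti(m, X)$sigma, rep(1, 354))
  # the head sees only the pooled vector: permuting cells changes nothing
  idx <- sample(49)
  Xp <- array(matrix(X, 49, 64)[idx, ], dim(X))
  expect_equal(nrr_distribution_cti(m, Xp)$mu, f$mu, tolerance = 1e-12)
})

test_that("EI head is a strictly per-cell map with positive sigma", {
  m <- tiny_model(3)
  X <- rand_grid(m, 4)
  f <- nrr_distribution_ei(m, X)
  expect_identical(dim(f$mu), dim(X))
  expect_identical(dim(f$sigma), dim(X))
  expect_true(all(f$sigma > 0))
  X2 <- X; X2[2, 5, ] <- rnorm(64)
  f2 <- nrr_distribution_ei(m, X2)
  changed <- apply(abs(f2$mu - f$mu), c(1, 2), max) > 0
  expect_identical(which(changed), which(matrix(seq_len(49), 7, 7) == 30L))
  # zero weights -> bias-constant mean field
  for (nm in c("ei_mu_c1", "ei_mu_c2")) m[[nm]]$W <- m[[nm]]$W * 0
  f3 <- nrr_distribution_ei(m, X)
  expect_equal(as.numeric(f3$mu[3, 3, ]), m$ei_mu_c2$b, tolerance = 1e-12)
  expect_equal(f3$mu[1, 1, ], f3$mu[7, 7, ], tolerance = 1e-12)
})

test_that("reparameterized sampling honors z = mu + sigma * eps", {
  mu <- rnorm(10); sg <- exp(rnorm(10))
  expect_equal(reparameterized_sample(mu, sg, eps = rep(0, 10)), mu)
  expect_equal(reparameterized_sample(mu, rep(1e-12, 10), seed = 4), mu,
               tolerance = 1e-9)
  expect_error(reparameterized_sample(mu, c(sg[-10], 0)), "positive")
  expect_identical(reparameterized_sample(mu, sg, seed = 9),
                   reparameterized_sample(mu, sg, seed = 9))
  # Monte-Carlo mean recovery on a 10-dim field
  set.seed(11)
  draws <- vapply(1:10000, function(i) reparameterized_sample(mu, sg),
                  numeric(10))
  expect_true(all(abs(rowMeans(draws) - mu) < 4 * sg / 100))
})

test_that("EI decoder geometry: grid g maps to (g-1)*stride + patch pixels", {
  m <- tiny_model(5)
  z <- rand_grid(m, 6)
  rec <- upsample_ei(m, z)
  expect_identical(dim(rec), c(57L, 57L))
  expect_error(upsample_ei(m, array(0, c(5, 5, 64))), "grid")
  # transposed-conv footprint: one-hot input, bias-free -> support in one patch
  k <- 9L; s <- 8L
  w <- matrix(rnorm(64 * k * k), 64, k * k)
  x <- array(0, c(7, 7, 64)); x[1, 1, ] <- rnorm(64)
  y <- dermbag:::convt2d_fwd(x, w, 0, k, s)
  supp <- which(abs(y[, , 1]) > 0, arr.ind = TRUE)
  expect_true(all(supp <= k))
  x2 <- array(0, c(7, 7, 64)); x2[3, 2, ] <- rnorm(64)
  y2 <- dermbag:::convt2d_fwd(x2, w, 0, k, s)
  supp2 <- which(abs(y2[, , 1]) > 0, arr.ind = TRUE)
  expect_true(all(supp2[, 1] >= 2 * s + 1 & supp2[, 1] <= 2 * s + k))
  # linearity of the bias-free transposed convolution
  a <- 1.7; b <- -0.4
  yc <- dermbag:::convt2d_fwd(a * x + b * x2, w, 0, k, s)
  expect_equal(yc, a * y + b * y2, tolerance = 1e-10)
})

test_that("gates stay in (0,1), act per cell, and halve features at zero init", {
  m <- tiny_model(6)
  X <- rand_grid(m, 7)
  g <- gate(m, X, "cti")
  expect_true(all(g$gate > 0 & g$gate < 1))
  expect_identical(dim(g$gate), c(7L, 7L, 1L))
  expect_equal(g$gated, X * as.vector(g$gate), tolerance = 1e-12)
  X2 <- X; X2[4, 4, ] <- rnorm(64)
  g2 <- gate(m, X2, "cti")
  diffmap <- abs(g2$gate - g$gate)[, , 1] > 0
  expect_identical(which(diffmap), 25L)  # only cell (4,4) of the 7x7 grid
  m$gate_ei_c1$W <- m$gate_ei_c1$W * 0; m$gate_ei_c1$b <- m$gate_ei_c1$b * 0
  m$gate_ei_c2$W <- m$gate_ei_c2$W * 0; m$gate_ei_c2$b <- m$gate_ei_c2$b * 0
  ge <- gate(m, X, "ei")
  expect_equal(as.numeric(ge$gate), rep(0.5, 49))
  expect_equal(ge$gated, 0.5 * X, tolerance = 1e-12)
})

test_that("classifier consumes 2*channels features and commutes with GAP", {
  m <- tiny_model(7)
  expect_identical(nrow(m$cls$W), 128L)
  expect_identical(ncol(m$cls$W), 3L)
  # spatially constant gated maps: GAP is the identity on the constant
  v1 <- rnorm(64); v2 <- rnorm(64)
  Xc <- array(rep(v1, each = 49), c(7, 7, 64))
  Xe <- array(rep(v2, each = 49), c(7, 7, 64))
  l <- classify(m, Xc, Xe)
  expect_equal(l, drop(c(v1, v2) %*% m$cls$W + m$cls$b), tolerance = 1e-10)
  # per-patch decomposability on a real forward pass
  img <- rand_image(57, seed = 30)
  cc <- dermbag:::ect_forward(m, list(img), with_decoders = FALSE)
  for (k in 1:3) {
    sc <- dermbag:::cell_scores(m, cc$X[[1]], k)
    expect_equal(mean(sc$logit), cc$logits[1, k], tolerance = 1e-5)
  }
})

test_that("swapping branch parameters and concatenation order fixes logits", {
  m1 <- tiny_model(8)
  m2 <- tiny_model(9)
  dermbag:::set_param_vector(model_parameters(m2),
                             dermbag:::param_vector(model_parameters(m1)))
  swap <- function(a, b) {
    for (nm in c("W", "b")) {
      tmp <- m2[[a]][[nm]]
      m2[[a]][[nm]] <- m2[[b]][[nm]]
      m2[[b]][[nm]] <- tmp
    }
  }
  swap("div_cti", "div_ei")
  swap("gate_cti_c1", "gate_ei_c1")
  swap("gate_cti_c2", "gate_ei_c2")
  m2$cls$W <- m2$cls$W[c(65:128, 1:64), ]
  img <- rand_image(57, seed = 31)
  expect_equal(predict_proba(m1, img), predict_proba(m2, img),
               tolerance = 1e-10)
})

test_that("inference forward is deterministic and reproducible", {
  m <- tiny_model(10)
  img <- rand_image(57, seed = 40)
  expect_identical(predict_proba(m, img), predict_proba(m, img))
})
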