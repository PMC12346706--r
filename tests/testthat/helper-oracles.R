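# Independent brute-force oracles used across test files.

# reflect index matching a 1-pixel mirror pad (edge pixel not repeated)
reflect_idx <- function(i, n) {
  if (i < 1L) 2L else if (i > n) n - 1L else i
}

# per-pixel uniform LBP: explicit neighbor loop + transition counting
lbp_brute <- function(channel) {
  offsets <- matrix(c(0, 1, -1, 1, -1, 0, -1, -1, 0, -1, 1, -1, 1, 0, 1, 1),
                    ncol = 2, byrow = TRUE)
  codes_uni <- Filter(function(cd) {
    bits <- as.integer(intToBits(cd))[1:8]
    sum(bits != bits[c(2:8, 1)]) <= 2
  }, 0:255)
  h <- nrow(channel); w <- ncol(channel)
  out <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      code <- 0L
      for (b in 1:8) {
        ni <- reflect_idx(i + offsets[b, 1], h)
        nj <- reflect_idx(j + offsets[b, 2], w)
        if (channel[ni, nj] >= channel[i, j])
          code <- code + 2L^(b - 1L)
      }
      pos <- match(code, codes_uni)
      out[i, j] <- if (is.na(pos)) 58L else pos - 1L
    }
  }
  out
}

# circular shift of an 8-bit code by 4 positions (the bit permutation a
# 180-degree image rotation induces on the LBP ring)
shift4_code <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits[c(5:8, 1:4)] * 2^(0:7))
}

# pairwise-comparison AUC with half-credit ties
auc_brute <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

# all window sums by direct summation
rank_brute <- function(heatmap, window, stride) {
  tops <- seq(1L, nrow(heatmap) - window + 1L, by = stride)
  g <- expand.grid(col = tops, row = tops)[, c("row", "col")]
  g$score <- mapply(function(r, c)
    sum(heatmap[r:(r + window - 1L), c:(c + window - 1L)]), g$row, g$col)
  g[order(-g$score, g$row, g$col), ]
}

rand_image <- function(size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(size * size * 3), c(size, size, 3))
}

# simple parameter holder for optimizer tests
toy_params <- function(w0) {
  e <- new.env()
  e$w <- w0
  e$param_names <- "w"
  class(e) <- c("nn_toy", "nn_layer")
  list(list(layer = e, name = "w"))
}

toy_get <- function(params) params[[1]]$layer$w

# quadratic toy problem L(w) = sum(w^2) for optimizer tests
quad_grad_fn <- function(params) {
  function(update_stats) list(grads = 2 * toy_get(params),
                              l = sum(toy_get(params)^2))
}

run_steps <- function(stepper, w0, cfg, n_steps, grad_maker = quad_grad_fn) {
  params <- toy_params(w0)
  state <- NULL
  for (i in seq_len(n_steps)) {
    r <- stepper(params, grad_maker(params), state, cfg)
    state <- r$state
  }
  toy_get(params)
}
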