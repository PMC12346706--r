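# Losses: softmax cross-entropy for classification and a log-damped KL
# reconstruction loss for the two handcrafted targets.  Targets are mapped to
# the probability simplex (L1 normalization; edge maps get a 1e-8 floor) and
# predictions through log-softmax, so KL(target || prediction) with a sum
# reduction is well defined.

log_softmax <- function(v) {
  v <- as.numeric(v)
  m <- max(v)
  v - m - log(sum(exp(v - m)))
}

#' KL divergence of a target distribution from a predicted logit vector
#'
#' `KL(t || softmax(pred)) = sum_i t_i (log t_i - logsoftmax(pred)_i)`, with
#' `0 log 0 = 0`.  `target` must be non-negative; it is L1-normalized here.
#'
#' @param target non-negative vector/array (normalized internally)
#' @param pred real-valued vector/array of the same length (logits)
#' @return list with `kl` (scalar, >= 0) and `grad` (d kl / d pred, same
#'   length as `pred`)
#' @export
kl_loss <- function(target, pred) {
  t <- as.numeric(target)
  if (any(t < 0)) stop("target must be non-negative")
  s <- sum(t)
  if (s <= 0) stop("target must have positive mass")
  t <- t / s
  ls <- log_softmax(pred)
  pos <- t > 0
  kl <- sum(t[pos] * (log(t[pos]) - ls[pos]))
  list(kl = max(kl, 0), grad = exp(ls) - t)
}

normalize_edge_target <- function(E, eps = 1e-8) {
  v <- as.numeric(E) + eps
  v / sum(v)
}

#' Non-rigid reconstruction loss
#'
#' `L_rec = log(KL(C, z_cti) + 1) + log(KL(E, rec_ei) + 1)`: each handcrafted
#' target is L1-normalized (the edge map after adding a 1e-8 floor), each
#' prediction is taken through log-softmax, the two KL divergences use a sum
#' reduction, and each term is damped by `log(. + 1)`.
#'
#' @param C color-texture descriptor target (length 354, non-negative)
#' @param z_cti sampled color-texture reconstruction (same length, real)
#' @param E edge-map target (non-negative matrix)
#' @param rec_ei reconstructed edge map (same spatial size, real)
#' @return list with `l_rec`, `kl_cti`, `kl_ei` and the gradients
#'   `g_z_cti`, `g_rec_ei`
#' @export
reconstruction_loss <- function(C, z_cti, E, rec_ei) {
  if (length(C) != length(z_cti))
    stop("descriptor target and sample differ in length")
  if (!all(dim(as.matrix(E)) == dim(as.matrix(rec_ei))))
    stop("edge target and reconstruction differ in shape")
  a <- kl_loss(C, z_cti)
  te <- normalize_edge_target(E)
  b <- kl_loss_prenorm(te, rec_ei)
  grec <- b$grad
  dim(grec) <- dim(as.matrix(rec_ei))
  list(l_rec = log(a$kl + 1) + log(b$kl + 1),
       kl_cti = a$kl, kl_ei = b$kl,
       g_z_cti = a$grad / (a$kl + 1),
       g_rec_ei = grec / (b$kl + 1))
}

# target already on the simplex
kl_loss_prenorm <- function(t, pred) {
  ls <- log_softmax(pred)
  pos <- t > 0
  kl <- max(sum(t[pos] * (log(t[pos]) - ls[pos])), 0)
  list(kl = kl, grad = exp(ls) - t)
}

#' Softmax cross-entropy
#'
#' @param logits n x K matrix (or length-K vector)
#' @param labels integer class labels in `1..K`
#' @return list with `loss` (mean over rows) and `grad`
#'   (d loss / d logits, already divided by n)
#' @export
softmax_ce <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1)
  n <- nrow(logits); K <- ncol(logits)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > K)) stop("labels out of range 1..K")
  m <- apply(logits, 1, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  picked <- z[cbind(seq_len(n), labels)]
  loss <- mean(lse - picked)
  p <- exp(z) / rowSums(exp(z))
  g <- p
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  list(loss = loss, grad = g / n)
}

#' Total training loss bundle
#'
#' `L = L_S + L_rec` with `L_S` the softmax cross-entropy of the logits.
#'
#' @param logits n x K logit matrix (or vector)
#' @param labels integer labels in `1..K`
#' @param l_rec reconstruction loss scalar (default 0)
#' @return list with `l`, `l_s`, `l_rec`
#' @export
total_loss <- function(logits, labels, l_rec = 0) {
  ce <- softmax_ce(logits, labels)
  list(l = ce$loss + l_rec, l_s = ce$loss, l_rec = l_rec)
}
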