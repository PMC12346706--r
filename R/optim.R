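# Optimizers: SGD with momentum and weight decay, sharpness-aware
# minimization (SAM), and partial SAM (PSAM), which updates a random half of
# the parameter elements with the plain gradient and the other half with the
# SAM gradient.  All operate on parameter-handle lists (see nn_parameters())
# through a gradient closure, so they apply equally to toy problems and to
# full models.

#' Optimizer configuration
#'
#' Defaults follow the training recipe used throughout the package: SGD with
#' momentum 0.9, weight decay 5e-4, initial learning rate 0.002 (cosine
#' annealed), and SAM radius rho = 0.05.
#'
#' @param rho SAM neighborhood radius (>= 0; 0 disables the perturbation)
#' @param psam_fraction fraction of parameter elements assigned to the plain
#'   SGD partition in a PSAM step (0.5 = the half/half split; 1 reduces to
#'   SGD, 0 to full SAM)
#' @param lr initial learning rate
#' @param momentum SGD momentum
#' @param weight_decay L2 weight decay coefficient
#' @return list of class `sam_config`
#' @export
sam_config <- function(rho = 0.05, psam_fraction = 0.5, lr = 0.002,
                       momentum = 0.9, weight_decay = 5e-4) {
  stopifnot(rho >= 0, psam_fraction >= 0, psam_fraction <= 1)
  structure(list(rho = rho, psam_fraction = psam_fraction, lr = lr,
                 momentum = momentum, weight_decay = weight_decay),
            class = "sam_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(epoch) = lr0 / 2 * (1 + cos(pi * epoch / total))` with `epoch`
#' 0-based, so the midpoint of training runs at half the initial rate.
#'
#' @param epoch 0-based epoch index
#' @param total total number of epochs
#' @param lr0 initial learning rate
#' @return learning rate for the epoch
#' @export
cosine_lr <- function(epoch, total, lr0) {
  lr0 / 2 * (1 + cos(pi * epoch / total))
}

new_opt_state <- function(params) {
  list(velocity = numeric(sum(param_lengths(params))))
}

sgd_apply <- function(params, state, g, lr, momentum, weight_decay) {
  w <- param_vector(params)
  g <- g + weight_decay * w
  state$velocity <- momentum * state$velocity + g
  set_param_vector(params, w - lr * state$velocity)
  state
}

#' One SAM optimization step
#'
#' First-order SAM: with gradient `g` at the current weights, weights are
#' perturbed by `zeta = rho * g / ||g||_2`, the gradient is re-evaluated at
#' the perturbed point (with batch-normalization running statistics frozen),
#' the weights are restored, and the base SGD update is applied with the
#' re-evaluated gradient.  A zero gradient norm skips the perturbation, and
#' `rho = 0` is exactly the base SGD step.
#'
#' @param params parameter-handle list (see [model_parameters()])
#' @param grad_fn `function(update_stats)` that recomputes the loss and
#'   gradients at the current weights and returns
#'   `list(grads = <vector>, ...)`; called once or twice per step
#' @param state optimizer state from a previous step, or `NULL`
#' @param config a [sam_config()]
#' @param lr learning rate for this step (default `config$lr`)
#' @return list with updated `state` and the first pass's loss fields
#' @export
sam_step <- function(params, grad_fn, state = NULL, config = sam_config(),
                     lr = config$lr) {
  if (is.null(state)) state <- new_opt_state(params)
  r1 <- grad_fn(update_stats = TRUE)
  g <- r1$grads
  if (config$rho > 0) {
    nrm <- sqrt(sum(g^2))
    if (nrm > 0) {
      w0 <- param_vector(params)
      set_param_vector(params, w0 + config$rho * g / nrm)
      r2 <- grad_fn(update_stats = FALSE)
      set_param_vector(params, w0)
      g <- r2$grads
    }
  }
  state <- sgd_apply(params, state, g, lr, config$momentum,
                     config$weight_decay)
  c(list(state = state), r1[setdiff(names(r1), "grads")])
}

#' One PSAM optimization step
#'
#' Draws an exact half/half (per `psam_fraction`) random partition of all
#' parameter elements; elements in the general partition receive the plain
#' gradient evaluated at the current weights, the rest receive the SAM
#' gradient evaluated at the perturbed weights, and one base SGD update is
#' applied to the combined gradient.  The partition is resampled every step.
#'
#' @inheritParams sam_step
#' @return list with updated `state` and the first pass's loss fields
#' @export
psam_step <- function(params, grad_fn, state = NULL, config = sam_config(),
                      lr = config$lr) {
  if (is.null(state)) state <- new_opt_state(params)
  r1 <- grad_fn(update_stats = TRUE)
  g1 <- r1$grads
  g <- g1
  if (config$rho > 0 && config$psam_fraction < 1) {
    nrm <- sqrt(sum(g1^2))
    if (nrm > 0) {
      w0 <- param_vector(params)
      set_param_vector(params, w0 + config$rho * g1 / nrm)
      r2 <- grad_fn(update_stats = FALSE)
      set_param_vector(params, w0)
      general <- psam_partition(length(g1), config$psam_fraction)
      g <- r2$grads
      g[general] <- g1[general]
    }
  }
  state <- sgd_apply(params, state, g, lr, config$momentum,
                     config$weight_decay)
  c(list(state = state), r1[setdiff(names(r1), "grads")])
}

#' @rdname psam_step
#' @param n total number of parameter elements
#' @param psam_fraction fraction assigned to the general partition
#' @return `psam_partition`: integer indices of the general partition
#' @export
psam_partition <- function(n, psam_fraction = 0.5) {
  sample.int(n, round(psam_fraction * n))
}
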