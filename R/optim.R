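#' Initialise AdamW optimizer state
#'
#' First and second gradient-moment estimates start at zero and mirror the
#' parameter shapes; the step counter starts at 0.  Default hyperparameters:
#' learning rate `alpha = 3e-4`, decay coefficients `beta1 = 0.9`,
#' `beta2 = 0.999`, decoupled weight decay `lambda = 0.01`, and numerical
#' constant `eps = 1e-8`.
#'
#' @param params Named list of parameter arrays (or a single numeric array).
#' @param alpha,beta1,beta2,lambda,eps Hyperparameters.
#' @return A list of class `adamw_state`.
#' @export
adamw_init <- function(params, alpha = 3e-4, beta1 = 0.9, beta2 = 0.999,
                       lambda = 0.01, eps = 1e-8) {
  if (!is.list(params)) params <- list(theta = params)
  zeros <- lapply(params, function(p) p * 0)
  structure(
    list(m = zeros, v = zeros, t = 0L,
         alpha = alpha, beta1 = beta1, beta2 = beta2,
         lambda = lambda, eps = eps),
    class = "adamw_state")
}

#' One AdamW update step
#'
#' Implements the moment recursions with bias correction and the decoupled
#' weight-decay update
#' `theta_t = theta_{t-1} - alpha * m_hat / (sqrt(v_hat) + eps)
#'  - lambda * theta_{t-1}`,
#' i.e. the decay term multiplies the previous parameters by `lambda`
#' directly (it is not scaled by the learning rate).  The step counter is
#' incremented before bias correction.
#'
#' @param params Named list of parameter arrays (or a single numeric array).
#' @param grads Gradients with shapes matching `params`.
#' @param state An `adamw_state` from [adamw_init()].
#' @return A list with updated `params` and `state`.
#' @export
#' @examples
#' st <- adamw_init(1)
#' adamw_step(1, 1, st)$params  # ~ 1 - 3e-4 - 0.01 = 0.9897
adamw_step <- function(params, grads, state) {
  single <- !is.list(params)
  if (single) {
    params <- list(theta = params)
    grads <- list(theta = grads)
  }
  if (!identical(names(params), names(state$m))) {
    abort("Parameter names do not match the optimizer state.")
  }
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (length(g) != length(params[[nm]])) {
      abort(sprintf("Gradient shape mismatch for `%s`.", nm))
    }
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    m_hat <- state$m[[nm]] / bc1
    v_hat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      state$alpha * m_hat / (sqrt(v_hat) + state$eps) -
      state$lambda * params[[nm]]
  }
  if (single) params <- params$theta
  list(params = params, state = state)
}
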