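# Adam optimizer over nested parameter lists.

#' Initialize Adam state for a parameter structure
#'
#' @param params Nested parameter list (as from [initModelParams()]).
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return Optimizer state list.
#' @export
adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  zeros <- mapParams(function(x) x * 0, params)
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1,
       beta2 = beta2, eps = eps)
}

#' One Adam update
#'
#' @param params Current parameters.
#' @param grads Gradients with the same structure.
#' @param state State from [adamInit()].
#' @return List with updated `params` and `state`.
#' @export
adamStep <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  state$m <- mapParams(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- mapParams(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  lr <- state$lr
  eps <- state$eps
  params <- mapParams(
    function(p, m, v) p - lr * (m / corr1) / (sqrt(v / corr2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}
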