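#' Unrolled model-based reconstruction networks
#'
#' The reconstruction alternates a conjugate-gradient data-consistency solve
#' with learned priors, unrolled for a fixed number of iterations with shared
#' weights:
#'
#' \deqn{x_{n+1} = (A^H A + \lambda_1 I + \lambda_2 I)^{-1}
#'       (A^H y + \lambda_1 \eta_n + \lambda_2 \zeta_n)}
#'
#' where `eta` is the output of the image-domain residual denoiser
#' `V^H N_i(V x)` and `zeta` the k-space-domain denoiser
#' `V^H F^H N_k(F V x)`, with `V` the virtual-coil augmentation.  The
#' dual-domain variant (`"zero_mirid"`) carries both priors; the single-domain
#' baseline (`"zs_ssl"`) fixes `lambda2 = 0`, drops the k-space denoiser and
#' uses no virtual-coil augmentation.  `lambda1`, `lambda2` are trainable and
#' kept positive through a log parametrisation.
#'
#' @name unrolled
NULL

#' Construct an unrolled reconstruction model
#'
#' @param variant `"zero_mirid"` (dual-domain) or `"zs_ssl"` (single-domain).
#' @param n_unrolls number of unrolled iterations (weights shared; default 10).
#' @param n_cg CG iterations in each data-consistency solve (default 10).
#' @param n_layers,channels denoiser depth and width (reference scale: 15
#'   layers, 46 channels dual-domain / 64 single-domain).
#' @param activation_slope leaky-ReLU negative slope.
#' @param lambda_init initial value of the trainable regularisation weights.
#'   The default 0.05 follows the initialisation used by self-supervised
#'   unrolled-reconstruction implementations in the field; under the unitary
#'   FFT convention the normal operator has spectral norm 1, so a small
#'   initial penalty lets the data-consistency solve dominate early training
#'   while the weights remain free to grow.
#' @param seed RNG seed for weight initialisation.
#' @return an `unrolled_model` list.
#' @export
unrolled_model <- function(variant = c("zero_mirid", "zs_ssl"),
                           n_unrolls = 10, n_cg = 10,
                           n_layers = 15,
                           channels = if (variant == "zero_mirid") 46 else 64,
                           activation_slope = 0.1,
                           lambda_init = 0.05, seed = 1) {
  variant <- match.arg(variant)
  use_vc <- variant == "zero_mirid"
  in_ch <- if (use_vc) 4L else 2L
  cfg <- denoiser_config(n_layers = n_layers, channels = channels,
                         activation_slope = activation_slope,
                         in_channels = in_ch)
  m <- list(variant = variant, use_vc = use_vc,
            n_unrolls = n_unrolls, n_cg = n_cg,
            image_net = init_denoiser(cfg, seed = seed),
            kspace_net = if (variant == "zero_mirid")
              init_denoiser(cfg, seed = seed + 1L) else NULL,
            rho1 = log(lambda_init),
            rho2 = if (variant == "zero_mirid") log(lambda_init) else -Inf)
  structure(m, class = "unrolled_model")
}

#' @export
print.unrolled_model <- function(x, ...) {
  cat(sprintf("<unrolled_model> variant=%s, %d unrolls x %d CG, lambda1=%.4g lambda2=%.4g, %d trainable parameters\n",
              x$variant, x$n_unrolls, x$n_cg, exp(x$rho1),
              if (is.finite(x$rho2)) exp(x$rho2) else 0, n_params(x)))
  invisible(x)
}

#' Trainable parameter count
#'
#' Independent of the number of unrolls (weights are shared across unrolls).
#'
#' @param model an [unrolled_model()].
#' @return integer count including the regularisation weights.
#' @export
n_params <- function(model) {
  n <- n_params_denoiser(model$image_net) + 1L
  if (!is.null(model$kspace_net)) n <- n + n_params_denoiser(model$kspace_net) + 1L
  n
}

model_lambdas <- function(model) {
  c(lambda1 = exp(model$rho1),
    lambda2 = if (is.finite(model$rho2)) exp(model$rho2) else 0)
}

#' Run the unrolled reconstruction network
#'
#' `x_0 = A^H y`, `eta_0 = zeta_0 = x_0`, then `n_unrolls` alternations of the
#' CG data-consistency solve and the denoiser priors.  `mask_in` must mark
#' exactly the k-space locations present in `y_in` (it is both the input and
#' the data-consistency mask).
#'
#' @param y_in complex multicoil k-space (ny x nx x C), zero where unsampled.
#' @param S sensitivity array (ny x nx x C).
#' @param mask_in a [sampling_mask] or binary matrix.
#' @param model an [unrolled_model()].
#' @param with_tape internal: also return the backpropagation tape.
#' @return complex image matrix, or a list `(x, tape)` when `with_tape`.
#' @export
unrolled_forward <- function(y_in, S, mask_in, model, with_tape = FALSE) {
  lam <- model_lambdas(model)
  l1 <- lam[1]; l2 <- lam[2]
  lt <- l1 + l2
  x0 <- adjoint_op(y_in, S, mask_in)
  eta <- x0; zeta <- x0
  N <- model$n_unrolls
  if (N == 0) return(if (with_tape) list(x = x0, tape = list()) else x0)
  tape <- if (with_tape) vector("list", N) else NULL
  x <- x0
  for (n in seq_len(N)) {
    rhs <- x0 + l1 * eta + l2 * zeta
    if (any(!is.finite(Re(rhs))) || any(!is.finite(Im(rhs))))
      stop(sprintf("unrolled_forward: non-finite values at unroll %d", n))
    x <- cg_normal_solve(rhs, S, mask_in, lt, model$n_cg)
    if (anyNA(x) || any(!is.finite(Re(x))))
      stop(sprintf("unrolled_forward: non-finite values at unroll %d", n))
    if (with_tape)
      tape[[n]] <- list(x = x, eta_in = eta, zeta_in = zeta)
    if (n < N) {
      di <- denoiser_complex_forward(x, model$image_net, "image", model$use_vc)
      eta <- di$out
      if (with_tape) tape[[n]]$tape_i <- di$tape
      if (model$variant == "zero_mirid") {
        dk <- denoiser_complex_forward(x, model$kspace_net, "kspace", TRUE)
        zeta <- dk$out
        if (with_tape) tape[[n]]$tape_k <- dk$tape
      }
    }
  }
  if (with_tape) list(x = x, tape = tape) else x
}

zero_net_grads <- function(net) {
  list(gW = lapply(net$W, function(w) array(0, dim(w))),
       gb = lapply(net$b, function(bb) numeric(length(bb))))
}

add_net_grads <- function(a, b) {
  list(gW = Map(`+`, a$gW, b$gW), gb = Map(`+`, a$gb, b$gb))
}

# Backpropagate a complex output gradient g_x (dL/dRe + i dL/dIm convention)
# through the unrolled iteration.  The CG solve is differentiated via its
# adjoint system: since M = A^H A + lambda_t I is Hermitian, dL/d(rhs) =
# M^{-1} g (a second CG solve) and dL/dlambda_t = Re<M^{-1} g, -x>.  This is
# exact when CG has converged and matches finite differences there.
unrolled_backward <- function(g_x, fw, y_in, S, mask_in, model) {
  lam <- model_lambdas(model)
  l1 <- lam[1]; l2 <- lam[2]
  lt <- l1 + l2
  N <- model$n_unrolls
  gi <- zero_net_grads(model$image_net)
  gk <- if (!is.null(model$kspace_net)) zero_net_grads(model$kspace_net) else NULL
  dl1 <- 0; dl2 <- 0
  dual <- model$variant == "zero_mirid"
  for (n in rev(seq_len(N))) {
    st <- fw$tape[[n]]
    q <- cg_normal_solve(g_x, S, mask_in, lt, model$n_cg)
    dlt <- Re(cdot(q, -st$x))
    dl1 <- dl1 + dlt
    if (dual) dl2 <- dl2 + dlt
    dl1 <- dl1 + Re(cdot(q, st$eta_in))
    if (dual) dl2 <- dl2 + Re(cdot(q, st$zeta_in))
    g_eta <- l1 * q
    g_zeta <- if (dual) l2 * q else NULL
    if (n == 1) break  # eta_0 = zeta_0 = A^H y carry no parameters
    prev <- fw$tape[[n - 1]]
    bi <- denoiser_complex_backward(g_eta, prev$tape_i, model$image_net,
                                    "image", model$use_vc)
    gi <- add_net_grads(gi, list(gW = bi$gW, gb = bi$gb))
    g_x <- bi$gx
    if (dual) {
      bk <- denoiser_complex_backward(g_zeta, prev$tape_k, model$kspace_net,
                                      "kspace", TRUE)
      gk <- add_net_grads(gk, list(gW = bk$gW, gb = bk$gb))
      g_x <- g_x + bk$gx
    }
  }
  list(image = gi, kspace = gk,
       rho1 = l1 * dl1,
       rho2 = if (dual) l2 * dl2 else 0)
}
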