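#' Residual denoiser CNNs
#'
#' The image- and k-space-domain priors of the unrolled model are small
#' residual CNNs: a stack of same-padded convolutions with leaky-ReLU
#' activations and a global skip, `N(x) = x + conv_stack(x)`, so the network
#' predicts the artifact/noise component and an all-zero-weight network is
#' the identity.  Complex maps enter as separate real/imaginary channels
#' (2 channels per complex map; 4 with virtual-coil augmentation) and are
#' reassembled on exit.  Layers and their gradients are implemented directly
#' (im2col + matrix products), so the whole model is trainable with plain R
#' linear algebra.
#'
#' @name networks
NULL

#' Denoiser configuration
#'
#' @param n_layers number of convolutional layers (>= 2); the reference model
#'   uses 15.
#' @param kernel odd spatial kernel size (default 3).
#' @param channels hidden width per layer (46 for the dual-domain model,
#'   64 for the single-domain baseline at reference scale).
#' @param activation_slope negative slope of the leaky ReLU.
#' @param in_channels input channels: 4 for real/imag x virtual-coil stack,
#'   2 without virtual coils.
#' @return a `denoiser_config` list.
#' @export
denoiser_config <- function(n_layers = 15, kernel = 3, channels = 46,
                            activation_slope = 0.1, in_channels = 4) {
  stopifnot(n_layers >= 2, channels >= 1, kernel %% 2 == 1,
            activation_slope >= 0, in_channels >= 1)
  structure(list(n_layers = n_layers, kernel = kernel, channels = channels,
                 activation_slope = activation_slope,
                 in_channels = in_channels),
            class = "denoiser_config")
}

#' Initialise denoiser weights
#'
#' He-scaled Gaussian initialisation for all layers except the final one,
#' which starts at zero so the residual network is the identity map at
#' initialisation (training then moves it away from identity).
#'
#' @param config a [denoiser_config()].
#' @param seed integer RNG seed.
#' @return list with elements `config`, `W` (list of (k x k x cin x cout)
#'   arrays) and `b` (list of per-output-channel biases).
#' @export
init_denoiser <- function(config, seed = 1) {
  k <- config$kernel
  L <- config$n_layers
  widths <- c(config$in_channels, rep(config$channels, L - 1),
              config$in_channels)
  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- widths[l]; cout <- widths[l + 1]
      sd <- sqrt(2 / (k * k * cin))
      W[[l]] <- if (l == L) array(0, c(k, k, cin, cout))
                else array(stats::rnorm(k * k * cin * cout, sd = sd),
                           c(k, k, cin, cout))
      b[[l]] <- numeric(cout)
    }
    list(config = config, W = W, b = b)
  })
}

n_params_denoiser <- function(net) {
  sum(vapply(net$W, length, 1L)) + sum(vapply(net$b, length, 1L))
}

# --- convolution primitive (compiled; see src/conv.cpp) --------------------

conv2d_forward <- function(x, W, b) {
  d <- dim(x)
  list(y = cpp_conv2d(x, W, b, d[1], d[2], d[3], dim(W)[1], dim(W)[4]),
       xin = x)
}

conv2d_backward <- function(dY, xin, W) {
  d <- dim(xin)
  cpp_conv2d_grad(dY, xin, W, d[1], d[2], d[3], dim(W)[1], dim(W)[4])
}

lrelu <- function(x, slope) {
  fac <- 1 + (slope - 1) * (x < 0)
  x * fac
}
lrelu_grad <- function(pre, slope) 1 + (slope - 1) * (pre < 0)

# --- real-channel denoiser forward/backward --------------------------------

denoiser_forward <- function(ch, net) {
  L <- net$config$n_layers
  slope <- net$config$activation_slope
  tape <- vector("list", L)
  h <- ch
  for (l in seq_len(L)) {
    cf <- conv2d_forward(h, net$W[[l]], net$b[[l]])
    tape[[l]] <- list(xin = cf$xin, pre = if (l < L) cf$y else NULL)
    h <- if (l < L) lrelu(cf$y, slope) else cf$y
  }
  list(out = ch + h, tape = tape)
}

denoiser_backward <- function(dOut, tape, net) {
  L <- net$config$n_layers
  slope <- net$config$activation_slope
  gW <- vector("list", L); gb <- vector("list", L)
  dh <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) dh <- dh * lrelu_grad(tape[[l]]$pre, slope)
    cb <- conv2d_backward(dh, tape[[l]]$xin, net$W[[l]])
    gW[[l]] <- cb$dW; gb[[l]] <- cb$db
    dh <- cb$dX
  }
  # global residual skip
  list(dIn = dOut + dh, gW = gW, gb = gb)
}

# --- complex plumbing ------------------------------------------------------

stack_to_channels <- function(s) {
  K <- dim(s)[3]
  ch <- array(0, c(dim(s)[1], dim(s)[2], 2 * K))
  for (k in seq_len(K)) {
    ch[, , 2 * k - 1] <- Re(s[, , k])
    ch[, , 2 * k] <- Im(s[, , k])
  }
  ch
}

channels_to_stack <- function(ch) {
  K <- dim(ch)[3] %/% 2L
  s <- array(0i, c(dim(ch)[1], dim(ch)[2], K))
  for (k in seq_len(K)) {
    s[, , k] <- ch[, , 2 * k - 1] + 1i * ch[, , 2 * k]
  }
  s
}

# Forward pass of a denoiser on a complex image, recording a tape for
# backpropagation.  domain "kspace" wraps the CNN in centered FFTs per
# virtual-coil channel; with use_vc the input is the [x, conj(x)] stack.
denoiser_complex_forward <- function(x, net, domain, use_vc) {
  s <- if (use_vc) vc_augment(x) else {
    a <- array(0i, c(nrow(x), ncol(x), 1)); a[, , 1] <- x; a
  }
  if (domain == "kspace") {
    for (k in seq_len(dim(s)[3])) s[, , k] <- centered_fft(s[, , k], "forward")
  }
  df <- denoiser_forward(stack_to_channels(s), net)
  so <- channels_to_stack(df$out)
  if (domain == "kspace") {
    for (k in seq_len(dim(so)[3])) so[, , k] <- centered_fft(so[, , k], "inverse")
  }
  out <- if (use_vc) vc_reduce(so) else so[, , 1]
  list(out = out, tape = df$tape)
}

# Backward pass: g is the complex gradient (dL/dRe + i dL/dIm) wrt the output.
# Returns the complex gradient wrt the input and the weight gradients.
denoiser_complex_backward <- function(g, tape, net, domain, use_vc) {
  K <- if (use_vc) 2L else 1L
  gs <- array(0i, c(nrow(g), ncol(g), K))
  if (use_vc) {           # vc_reduce: (s1 + conj(s2))/2
    gs[, , 1] <- g / 2
    gs[, , 2] <- Conj(g) / 2
  } else gs[, , 1] <- g
  if (domain == "kspace") {  # adjoint of inverse FFT is forward FFT (unitary)
    for (k in seq_len(K)) gs[, , k] <- centered_fft(gs[, , k], "forward")
  }
  dch <- array(0, c(nrow(g), ncol(g), 2 * K))
  for (k in seq_len(K)) {
    dch[, , 2 * k - 1] <- Re(gs[, , k])
    dch[, , 2 * k] <- Im(gs[, , k])
  }
  db <- denoiser_backward(dch, tape, net)
  gin <- array(0i, c(nrow(g), ncol(g), K))
  for (k in seq_len(K)) {
    gin[, , k] <- db$dIn[, , 2 * k - 1] + 1i * db$dIn[, , 2 * k]
  }
  if (domain == "kspace") {  # adjoint of forward FFT
    for (k in seq_len(K)) gin[, , k] <- centered_fft(gin[, , k], "inverse")
  }
  gx <- if (use_vc) gin[, , 1] + Conj(gin[, , 2]) else gin[, , 1]
  list(gx = gx, gW = db$gW, gb = db$gb)
}

#' Apply a residual denoiser to a complex image
#'
#' Image domain computes `V^H N(V x)`; k-space domain computes
#' `V^H F^H N(F V x)` (the CNN acts on the spectra of both virtual-coil
#' channels).  Without `use_vc`, `V` is dropped and the CNN sees 2 real
#' channels.
#'
#' @param x complex image matrix.
#' @param net weights from [init_denoiser()].
#' @param domain `"image"` or `"kspace"`.
#' @param use_vc apply virtual-coil augmentation/reduction around the CNN.
#' @return complex image matrix.
#' @export
apply_denoiser <- function(x, net, domain = c("image", "kspace"),
                           use_vc = TRUE) {
  domain <- match.arg(domain)
  need <- if (use_vc) 4L else 2L
  if (net$config$in_channels != need)
    stop(sprintf("denoiser expects %d input channels, need %d for use_vc=%s",
                 net$config$in_channels, need, use_vc))
  denoiser_complex_forward(x, net, domain, use_vc)$out
}
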