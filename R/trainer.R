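#' Scan-specific self-supervised training
#'
#' The network is trained only on the undersampled measurements of the scan
#' being reconstructed.  Each optimization step draws one (slice, pair)
#' combination: the network input is `P_Lambda y` (with Lambda also the
#' data-consistency mask) and the loss compares `F S f(P_Lambda y)` with the
#' measured data on Theta.  After each epoch, a validation loss is evaluated
#' with input `P_{Lambda union Theta} y` on the held-out set Psi; the weights
#' with the lowest validation loss are retained and training stops early
#' after `patience` epochs without improvement.  At inference the entire
#' acquired set Omega is used as input and data-consistency mask.
#'
#' @name trainer
NULL

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param max_epochs maximum number of epochs (one pass over slices x pairs).
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed controlling pair ordering (and nothing else).
#' @param loss a [loss_spec()].
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, max_epochs = 30, patience = 10, seed = 1,
                         loss = loss_spec("combined")) {
  stopifnot(lr > 0, patience <= max_epochs)
  list(lr = lr, max_epochs = max_epochs, patience = patience, seed = seed,
       loss = loss)
}

# --- flat parameter packing for the optimizer ------------------------------

pack_params <- function(model) {
  v <- c(unlist(model$image_net$W), unlist(model$image_net$b))
  if (!is.null(model$kspace_net))
    v <- c(v, unlist(model$kspace_net$W), unlist(model$kspace_net$b))
  v <- c(v, model$rho1)
  if (!is.null(model$kspace_net)) v <- c(v, model$rho2)
  v
}

pack_grads <- function(gr, model) {
  v <- c(unlist(gr$image$gW), unlist(gr$image$gb))
  if (!is.null(model$kspace_net))
    v <- c(v, unlist(gr$kspace$gW), unlist(gr$kspace$gb))
  v <- c(v, gr$rho1)
  if (!is.null(model$kspace_net)) v <- c(v, gr$rho2)
  v
}

unpack_params <- function(v, model) {
  i <- 0L
  take <- function(n) {
    out <- v[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  refill <- function(net) {
    for (l in seq_along(net$W)) net$W[[l]][] <- take(length(net$W[[l]]))
    for (l in seq_along(net$b)) net$b[[l]][] <- take(length(net$b[[l]]))
    net
  }
  model$image_net <- refill(model$image_net)
  if (!is.null(model$kspace_net)) model$kspace_net <- refill(model$kspace_net)
  model$rho1 <- take(1L)
  if (!is.null(model$kspace_net)) model$rho2 <- take(1L)
  model
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# --- loss evaluation for one slice ----------------------------------------

# Scale k-space restricted to in_idx so max |A^H y_in| = 1, run the model,
# and return loss on loss_idx plus the tape needed for backprop.
slice_pass <- function(slice, in_idx, loss_idx, model, spec, with_tape) {
  d2 <- dim(slice$kspace)[1:2]
  in_mask <- subset_mask(in_idx, d2)
  y_in <- slice$kspace * array(rep(in_mask, dim(slice$kspace)[3]),
                               dim(slice$kspace))
  x0 <- adjoint_op(y_in, S = slice$sens, mask = in_mask)
  sc <- max(Mod(x0))
  if (sc == 0) stop("input k-space subset carries no signal")
  y_in <- y_in / sc
  y_ref <- slice$kspace / sc
  fw <- unrolled_forward(y_in, slice$sens, in_mask, model, with_tape = with_tape)
  x <- if (with_tape) fw$x else fw
  full <- matrix(1, d2[1], d2[2])
  y_hat <- forward_op(x, slice$sens, full)
  loss <- composite_loss(y_hat, y_ref, loss_idx, spec)
  list(loss = loss, fw = fw, y_in = y_in, y_ref = y_ref, y_hat = y_hat,
       in_mask = in_mask, scale = sc, full = full)
}

validation_loss <- function(dataset, partitions, model, spec) {
  vals <- vapply(seq_along(dataset), function(s) {
    p <- partitions[[s]]
    slice_pass(dataset[[s]], setdiff(p$omega, p$psi), p$psi, model, spec,
               with_tape = FALSE)$loss
  }, numeric(1))
  mean(vals)
}

#' Train a model scan-specifically
#'
#' One model is trained across all slices of the scan (batch size 1: one
#' (slice, Lambda/Theta pair) per optimization step, order shuffled each
#' epoch).  Fully reproducible from `cfg$seed`.
#'
#' @param dataset list of slices, each `list(kspace = (ny x nx x C) complex
#'   array, sens = (ny x nx x C) sensitivity array)`.
#' @param mask the acquisition [sampling_mask] (shared across slices).
#' @param partitions list of [partition_kspace()] results, one per slice.
#' @param model an [unrolled_model()].
#' @param cfg a [train_config()].
#' @return list `(model, history)`: the best-validation-loss weights and a
#'   `train_history` data.frame (epoch, train_loss, val_loss, lambda1,
#'   lambda2) with attribute `best_epoch`.
#' @export
train_scan_specific <- function(dataset, mask, partitions, model, cfg) {
  stopifnot(length(partitions) == length(dataset))
  for (p in partitions) {
    if (length(p$psi) == 0) stop("empty validation subset Psi")
    for (pr in p$pairs) if (length(pr$theta) == 0) stop("empty loss subset Theta")
  }
  spec <- cfg$loss
  combos <- expand.grid(slice = seq_along(dataset),
                        pair = seq_along(partitions[[1]]$pairs))
  theta <- pack_params(model)
  opt <- adam_init(length(theta))
  best <- list(val = Inf, theta = theta, epoch = 0L)
  hist <- data.frame()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(nrow(combos))
      step_losses <- numeric(nrow(combos))
      for (k in seq_along(ord)) {
        cb <- combos[ord[k], ]
        p <- partitions[[cb$slice]]
        pr <- p$pairs[[cb$pair]]
        sp <- slice_pass(dataset[[cb$slice]], pr$lambda, pr$theta, model,
                         spec, with_tape = TRUE)
        if (!is.finite(sp$loss))
          stop(sprintf("non-finite training loss at epoch %d, step %d", epoch, k))
        step_losses[k] <- sp$loss
        g_y <- composite_loss_grad(sp$y_hat, sp$y_ref, pr$theta, spec)
        g_x <- adjoint_op(g_y, dataset[[cb$slice]]$sens, sp$full)
        gr <- unrolled_backward(g_x, sp$fw, sp$y_in, dataset[[cb$slice]]$sens,
                                sp$in_mask, model)
        opt <- adam_step(opt, pack_grads(gr, model), cfg$lr)
        theta <- theta + opt$delta
        model <- unpack_params(theta, model)
      }
      val <- validation_loss(dataset, partitions, model, spec)
      lam <- model_lambdas(model)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(step_losses),
                                     val_loss = val,
                                     lambda1 = lam[1], lambda2 = lam[2]))
      if (val < best$val) best <- list(val = val, theta = theta, epoch = epoch)
      if (epoch - best$epoch >= cfg$patience) break
    }
  })
  model <- unpack_params(best$theta, model)
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "best_val") <- best$val
  class(hist) <- c("train_history", class(hist))
  list(model = model, history = hist)
}

#' Reconstruct from the full measurement set
#'
#' Runs the (trained) unrolled model with the entire acquired set Omega as
#' both input and data-consistency mask, undoing the internal intensity
#' normalization on output.
#'
#' @param y complex multicoil k-space (ny x nx x C), zero where unsampled.
#' @param S sensitivity array.
#' @param mask acquisition [sampling_mask].
#' @param model a (trained) [unrolled_model()].
#' @return complex image matrix.
#' @export
reconstruct_inference <- function(y, S, mask, model) {
  x0 <- adjoint_op(y, S, mask)
  sc <- max(Mod(x0))
  if (sc == 0) return(x0)
  unrolled_forward(y / sc, S, mask, model) * sc
}
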