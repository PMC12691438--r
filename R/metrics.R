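#' Image quality metrics
#'
#' Reconstruction quality against a reference, evaluated on magnitude images
#' scaled by the reference maximum: NRMSE (percent), PSNR (dB), SSIM, HFEN
#' (relative l2 error between Laplacian-of-Gaussian filtered images,
#' sensitive to edges/fine structure) and GMSD (standard deviation of the
#' pointwise gradient-magnitude similarity map).  FSIM and LPIPS are exposed
#' only as optional plug-in hooks ([register_metric_plugin()]) because they
#' require external implementations / pretrained weights.
#'
#' @name metrics
NULL

# separable filtering with replicate ("nearest") boundary handling
sep_filter <- function(img, kern) {
  r <- (length(kern) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2 * r) - r, 1), n)
  a <- img[pad_idx(nrow(img)), , drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (k in seq_along(kern)) out <- out + kern[k] * a[(seq_len(nrow(img))) + k - 1L, , drop = FALSE]
  a <- out[, pad_idx(ncol(img)), drop = FALSE]
  out2 <- matrix(0, nrow(img), ncol(img))
  for (k in seq_along(kern)) out2 <- out2 + kern[k] * a[, (seq_len(ncol(img))) + k - 1L, drop = FALSE]
  out2
}

gauss_kernel <- function(sigma, radius) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# full 2D convolution, zero-padded, 'same' output
conv2_same <- function(img, kern) {
  ny <- nrow(img); nx <- ncol(img)
  kr <- (nrow(kern) - 1L) %/% 2L; kc <- (ncol(kern) - 1L) %/% 2L
  p <- matrix(0, ny + 2 * kr, nx + 2 * kc)
  p[kr + seq_len(ny), kc + seq_len(nx)] <- img
  out <- matrix(0, ny, nx)
  for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
    if (kern[a, b] != 0)
      out <- out + kern[a, b] * p[(a - 1L) + seq_len(ny), (b - 1L) + seq_len(nx)]
  }
  out
}

log_kernel <- function(size = 15, sigma = 1.5) {
  r <- (size - 1) / 2
  x <- matrix(rep(-r:r, size), size, size)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  g <- g / sum(g)
  k <- g * (x^2 + y^2 - 2 * sigma^2) / sigma^4
  k - mean(k)  # zero-sum so constants are annihilated
}

ssim_index <- function(x, y, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       data_range = 1) {
  radius <- as.integer(3.5 * sigma + 0.5)   # 11-tap window for sigma 1.5
  k <- gauss_kernel(sigma, radius)
  f <- function(m) sep_filter(m, k)
  ux <- f(x); uy <- f(y)
  uxx <- f(x * x); uyy <- f(y * y); uxy <- f(x * y)
  vx <- uxx - ux * ux; vy <- uyy - uy * uy; vxy <- uxy - ux * uy
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  # exclude the filter-support border from the mean
  ri <- (radius + 1):(nrow(x) - radius)
  ci <- (radius + 1):(ncol(x) - radius)
  mean(S[ri, ci])
}

gmsd_index <- function(x, y, c = 170 / 255^2) {
  px <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1) / 3, 3, 3)  # Prewitt, d/drow
  gx <- sqrt(conv2_same(x, px)^2 + conv2_same(x, t(px))^2)
  gy <- sqrt(conv2_same(y, px)^2 + conv2_same(y, t(px))^2)
  gms <- (2 * gx * gy + c) / (gx^2 + gy^2 + c)
  sqrt(mean((gms - mean(gms))^2))
}

PSNR_CAP <- 100  # dB sentinel reported for identical images

#' Compute one image quality metric
#'
#' Operates on magnitude images, both scaled by `max(|reference|)` so the
#' reference lies in `[0, 1]`.  Conventions: NRMSE in percent; PSNR in dB
#' with peak = max reference magnitude (capped at 100 dB for identical
#' inputs); SSIM with Gaussian window sigma 1.5, K1 = 0.01, K2 = 0.03; HFEN
#' with a 15x15 Laplacian-of-Gaussian kernel, sigma 1.5; GMSD with Prewitt
#' gradients and stability constant 170/255^2 on the unit scale.
#'
#' @param recon complex (or numeric) reconstruction matrix.
#' @param reference complex (or numeric) reference matrix, nonzero.
#' @param name one of `"nrmse"`, `"psnr"`, `"ssim"`, `"hfen"`, `"gmsd"`.
#' @return scalar metric value.
#' @export
compute_metric <- function(recon, reference,
                           name = c("nrmse", "psnr", "ssim", "hfen", "gmsd")) {
  name <- match.arg(name)
  if (!all(dim(recon) == dim(reference))) stop("shape mismatch")
  mref <- Mod(reference)
  peak <- max(mref)
  if (peak == 0) stop("zero reference image")
  a <- Mod(recon) / peak
  b <- mref / peak
  switch(name,
    nrmse = 100 * l2norm(a - b) / l2norm(b),
    psnr = {
      rmse <- sqrt(mean((a - b)^2))
      if (rmse == 0) PSNR_CAP else min(PSNR_CAP, 20 * log10(1 / rmse))
    },
    ssim = ssim_index(a, b),
    hfen = {
      k <- log_kernel(15, 1.5)
      l2norm(conv2_same(a, k) - conv2_same(b, k)) / l2norm(conv2_same(b, k))
    },
    gmsd = gmsd_index(a, b))
}

metric_plugins <- new.env(parent = emptyenv())

#' Register an external metric plug-in
#'
#' Hook for metrics whose canonical implementations live outside this package
#' (e.g. FSIM, LPIPS).  The function must accept `(recon, reference)`
#' magnitude matrices on the unit scale and return a scalar.
#'
#' @param name metric name.
#' @param fn function `(recon, reference) -> scalar`, or `NULL` to remove.
#' @export
register_metric_plugin <- function(name, fn) {
  if (is.null(fn)) rm(list = name, envir = metric_plugins)
  else assign(name, fn, envir = metric_plugins)
  invisible(name)
}

#' Per-slice metrics report
#'
#' @param recons list of reconstruction matrices.
#' @param references list of reference matrices.
#' @param metrics metric names (built-in and registered plug-ins).
#' @return data.frame with one row per slice plus a `"mean"` row.
#' @export
metrics_report <- function(recons, references,
                           metrics = c("nrmse", "psnr", "ssim", "hfen", "gmsd")) {
  stopifnot(length(recons) == length(references))
  builtin <- c("nrmse", "psnr", "ssim", "hfen", "gmsd")
  rows <- lapply(seq_along(recons), function(s) {
    vals <- vapply(metrics, function(m) {
      if (m %in% builtin) compute_metric(recons[[s]], references[[s]], m)
      else if (exists(m, envir = metric_plugins)) {
        f <- get(m, envir = metric_plugins)
        peak <- max(Mod(references[[s]]))
        f(Mod(recons[[s]]) / peak, Mod(references[[s]]) / peak)
      } else stop(sprintf("unknown metric '%s'", m))
    }, numeric(1))
    as.data.frame(as.list(vals))
  })
  out <- do.call(rbind, rows)
  out <- cbind(slice = as.character(seq_along(recons)), out)
  mean_row <- cbind(slice = "mean", as.data.frame(as.list(colMeans(out[-1]))))
  rbind(out, mean_row)
}
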