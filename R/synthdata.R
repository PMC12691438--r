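#' Synthetic multicoil acquisition generator
#'
#' Emulates the structure of multicoil brain scans (complex images with
#' smooth phase, smooth complex coil sensitivities with unit
#' root-sum-of-squares, additive circular complex Gaussian k-space noise) so
#' every pipeline stage is testable without downloading data.  The desk-scale
#' default is a 64 x 64 grid with 8 coils; a full-scale preset mirrors the
#' 320 x 320, 20-coil geometry of clinical head-coil data.
#'
#' @name synthdata
NULL

# Modified Shepp-Logan ellipse table: intensity, semi-axes, centre, angle.
shepp_logan_ellipses <- function() {
  matrix(c(
     1.0, 0.6900, 0.920,  0.00,  0.0000,   0,
    -0.8, 0.6624, 0.874,  0.00, -0.0184,   0,
    -0.2, 0.1100, 0.310,  0.22,  0.0000, -18,
    -0.2, 0.1600, 0.410, -0.22,  0.0000,  18,
     0.1, 0.2100, 0.250,  0.00,  0.3500,   0,
     0.1, 0.0460, 0.046,  0.00,  0.1000,   0,
     0.1, 0.0460, 0.046,  0.00, -0.1000,   0,
     0.1, 0.0460, 0.023, -0.08, -0.6050,   0,
     0.1, 0.0230, 0.023,  0.00, -0.6060,   0,
     0.1, 0.0230, 0.046,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
}

rasterize_ellipses <- function(ny, nx, ell) {
  u <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny, nx)
  v <- matrix(rep(seq(1, -1, length.out = ny), nx), ny, nx)
  img <- matrix(0, ny, nx)
  for (r in seq_len(nrow(ell))) {
    A <- ell[r, 1]; a <- ell[r, 2]; b <- ell[r, 3]
    x0 <- ell[r, 4]; y0 <- ell[r, 5]; phi <- ell[r, 6] * pi / 180
    uc <- (u - x0) * cos(phi) + (v - y0) * sin(phi)
    vc <- -(u - x0) * sin(phi) + (v - y0) * cos(phi)
    img <- img + A * ((uc / a)^2 + (vc / b)^2 <= 1)
  }
  img
}

#' Phantom specification
#'
#' @param kind `"shepp_logan"` or `"random_ellipses"`.
#' @param ny,nx grid size (>= 16).
#' @param phase_amp amplitude (radians) of the smooth low-order polynomial
#'   phase; complex phase is essential for partial-Fourier and virtual-coil
#'   behaviour to be meaningful.
#' @param seed RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("shepp_logan", "random_ellipses"),
                         ny = 64, nx = 64, phase_amp = 0.5, seed = 1) {
  kind <- match.arg(kind)
  list(kind = kind, ny = ny, nx = nx, phase_amp = phase_amp, seed = seed)
}

#' Generate a complex phantom image
#'
#' Magnitude in `[0, 1]`; phase is a seeded random quadratic polynomial of
#' the normalized coordinates, scaled to `phase_amp` radians peak.
#'
#' @param spec a [phantom_spec()].
#' @return complex image matrix (ny x nx).
#' @export
generate_phantom <- function(spec) {
  ny <- spec$ny; nx <- spec$nx
  if (ny < 16 || nx < 16) stop("phantom grid must be at least 16 x 16")
  with_seed(spec$seed, {
    mag <- if (spec$kind == "shepp_logan") {
      rasterize_ellipses(ny, nx, shepp_logan_ellipses())
    } else {
      n_ell <- sample(6:10, 1)
      ell <- cbind(stats::runif(n_ell, 0.1, 0.5) * sample(c(-1, 1), n_ell, TRUE),
                   stats::runif(n_ell, 0.08, 0.45),
                   stats::runif(n_ell, 0.08, 0.45),
                   stats::runif(n_ell, -0.45, 0.45),
                   stats::runif(n_ell, -0.45, 0.45),
                   stats::runif(n_ell, -90, 90))
      base <- cbind(0.5, 0.85, 0.85, 0, 0, 0)
      rasterize_ellipses(ny, nx, rbind(base, ell))
    }
    mag <- pmin(pmax(mag, 0), 1)
    u <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny, nx)
    v <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny, nx)
    cf <- stats::runif(5, -1, 1)
    p <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
    if (max(abs(p)) > 0) p <- p / max(abs(p))
    mag * exp(1i * spec$phase_amp * p)
  })
}

#' Coil specification
#'
#' @param n_coils number of receiver coils (default 8 desk-scale; clinical
#'   head coils typically have 20 channels).
#' @param width Gaussian bell width of each coil profile (normalized units).
#' @param seed RNG seed for per-coil phase.
#' @return a `coil_spec` list.
#' @export
coil_spec <- function(n_coils = 8, width = 0.9, seed = 1) {
  stopifnot(n_coils >= 1)
  list(n_coils = n_coils, width = width, seed = seed)
}

#' Simulate smooth complex coil sensitivities
#'
#' Gaussian bells centred on a ring around the field of view with per-coil
#' linear phase, normalized so the root-sum-of-squares over coils is exactly
#' 1 everywhere (hence inside any object support); with unit-RSS maps and
#' full sampling the normal operator `A^H A` is the identity.
#'
#' @param spec a [coil_spec()].
#' @param support binary matrix marking the object region (used for
#'   validation; must contain at least one pixel).
#' @return complex sensitivity array (ny x nx x n_coils).
#' @export
simulate_coils <- function(spec, support) {
  if (sum(support) == 0) stop("empty object support")
  ny <- nrow(support); nx <- ncol(support)
  u <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny, nx)
  v <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny, nx)
  C <- spec$n_coils
  S <- array(0i, c(ny, nx, C))
  with_seed(spec$seed, {
    ph_u <- stats::runif(C, -pi / 2, pi / 2)
    ph_v <- stats::runif(C, -pi / 2, pi / 2)
    ph_0 <- stats::runif(C, -pi, pi)
    for (c in seq_len(C)) {
      th <- 2 * pi * (c - 1) / C
      d2 <- (u - 1.3 * cos(th))^2 + (v - 1.3 * sin(th))^2
      mag <- exp(-d2 / (2 * spec$width^2))
      S[, , c] <- mag * exp(1i * (ph_u[c] * u + ph_v[c] * v + ph_0[c]))
    }
  })
  rss <- sqrt(apply(Mod(S)^2, c(1, 2), sum))
  for (c in seq_len(C)) S[, , c] <- S[, , c] / rss
  S
}

#' Noise specification
#'
#' @param sigma standard deviation of the circular complex Gaussian k-space
#'   noise, `sqrt(E|eps|^2) = sigma` (real and imaginary parts each
#'   `sigma/sqrt(2)`).
#' @param seed RNG seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(sigma = 0, seed = 1) {
  stopifnot(sigma >= 0)
  list(sigma = sigma, seed = seed)
}

#' Simulate an undersampled multicoil acquisition
#'
#' `P_Omega F S x + P_Omega eps` with seeded circular complex Gaussian noise.
#'
#' @param x complex phantom image.
#' @param S sensitivity array.
#' @param mask acquisition [sampling_mask].
#' @param noise a [noise_spec()].
#' @return complex multicoil k-space array, zero where unsampled.
#' @export
simulate_acquisition <- function(x, S, mask, noise = noise_spec(0)) {
  y <- forward_op(x, S, mask)
  if (noise$sigma > 0) {
    g <- mask_grid(mask)
    n <- length(y)
    eps <- with_seed(noise$seed, {
      complex(real = stats::rnorm(n, sd = noise$sigma / sqrt(2)),
              imaginary = stats::rnorm(n, sd = noise$sigma / sqrt(2)))
    })
    y <- y + array(eps, dim(y)) * array(rep(g, dim(y)[3]), dim(y))
  }
  y
}

#' Simulate a complete multi-slice scan
#'
#' Convenience wrapper producing the dataset structure consumed by
#' [train_scan_specific()]: per-slice ground truth, shared coil
#' sensitivities, and masked noisy k-space.  Slice 1 is the Shepp-Logan
#' phantom; further slices are random-ellipse phantoms.
#'
#' @param ny,nx,n_coils geometry.
#' @param n_slices number of slices.
#' @param mask acquisition [sampling_mask].
#' @param sigma k-space noise level.
#' @param phase_amp phantom phase amplitude (radians).
#' @param seed master seed; all per-slice seeds derive from it.
#' @return list of slices, each `list(kspace, sens, truth)`, with attributes
#'   `mask` and `geometry`.
#' @export
synth_scan <- function(ny = 64, nx = 64, n_coils = 8, n_slices = 2, mask,
                       sigma = 0.01, phase_amp = 0.5, seed = 1) {
  slices <- vector("list", n_slices)
  sens <- NULL
  for (s in seq_len(n_slices)) {
    kind <- if (s == 1) "shepp_logan" else "random_ellipses"
    truth <- generate_phantom(phantom_spec(kind, ny, nx, phase_amp,
                                           seed = seed * 101 + s))
    if (is.null(sens))
      sens <- simulate_coils(coil_spec(n_coils, seed = seed * 131 + 7),
                             support = (Mod(truth) > 0) * 1)
    ks <- simulate_acquisition(truth, sens, mask,
                               noise_spec(sigma, seed = seed * 151 + s))
    slices[[s]] <- list(kspace = ks, sens = sens, truth = truth)
  }
  attr(slices, "mask") <- mask
  attr(slices, "geometry") <- c(ny = ny, nx = nx, n_coils = n_coils)
  slices
}

# --- plain-text fixture I/O ------------------------------------------------

write_cplx_csv <- function(z, path) {
  utils::write.csv(data.frame(re = as.vector(Re(z)), im = as.vector(Im(z))),
                   path, row.names = FALSE)
}

read_cplx_csv <- function(path, dim) {
  d <- utils::read.csv(path)
  array(complex(real = d$re, imaginary = d$im), dim)
}

#' Write a scan fixture as a plain-text bundle
#'
#' A directory with a JSON manifest (geometry + mask spec) and CSV arrays
#' (real/imaginary columns) for the mask, sensitivities and per-slice
#' k-space and ground truth.
#'
#' @param scan result of [synth_scan()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- attr(scan, "mask")
  geom <- attr(scan, "geometry")
  manifest <- list(ny = geom[["ny"]], nx = geom[["nx"]],
                   n_coils = geom[["n_coils"]], n_slices = length(scan),
                   mask_spec = mask$spec[setdiff(names(mask$spec), "acs_idx")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(mask_grid(mask), file.path(dir, "mask.csv"),
                   row.names = FALSE)
  write_cplx_csv(scan[[1]]$sens, file.path(dir, "sensitivities.csv"))
  for (s in seq_along(scan)) {
    write_cplx_csv(scan[[s]]$kspace, file.path(dir, sprintf("slice%02d_kspace.csv", s)))
    write_cplx_csv(scan[[s]]$truth, file.path(dir, sprintf("slice%02d_truth.csv", s)))
  }
  invisible(dir)
}

#' Read a scan fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return scan structure as produced by [synth_scan()].
#' @export
read_fixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.csv(file.path(dir, "mask.csv")))
  dimnames(grid) <- NULL
  mask <- new_sampling_mask(grid, c(man$mask_spec, list(
    acs_idx = acs_index_set(man$ny, man$nx, man$mask_spec$acs_width %||% 0,
                            if (identical(man$mask_spec$pattern, "caipi")) "block" else "rows"))))
  d3 <- c(man$ny, man$nx, man$n_coils)
  sens <- read_cplx_csv(file.path(dir, "sensitivities.csv"), d3)
  slices <- lapply(seq_len(man$n_slices), function(s) {
    list(kspace = read_cplx_csv(file.path(dir, sprintf("slice%02d_kspace.csv", s)), d3),
         sens = sens,
         truth = read_cplx_csv(file.path(dir, sprintf("slice%02d_truth.csv", s)),
                               c(man$ny, man$nx)))
  })
  attr(slices, "mask") <- mask
  attr(slices, "geometry") <- c(ny = man$ny, nx = man$nx, n_coils = man$n_coils)
  slices
}
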