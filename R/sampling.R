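#' Sampling masks and self-supervised k-space partitions
#'
#' Acquisition masks describe the sampled k-space set Omega.  Two families are
#' provided: 1D uniform undersampling of the phase-encode axis (2D multi-slice
#' scans) and 2D CAIPI lattices (3D scans), both optionally combined with
#' partial Fourier, which omits the highest positive-frequency rows and relies
#' on approximate conjugate symmetry for their recovery.  For scan-specific
#' self-supervision, Omega is further partitioned into disjoint subsets:
#' Lambda (network input), Theta (training loss), Psi (validation loss).
#'
#' @name sampling
NULL

new_sampling_mask <- function(grid, spec) {
  storage.mode(grid) <- "double"
  stopifnot(all(grid %in% c(0, 1)))
  structure(list(grid = grid, spec = spec), class = "sampling_mask")
}

#' Extract the binary grid of a mask
#'
#' Accepts either a [sampling_mask] or a plain binary matrix, so operators can
#' be called with ad-hoc masks in tests.
#'
#' @param mask a `sampling_mask` or binary matrix.
#' @return numeric 0/1 matrix.
#' @export
mask_grid <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$grid
  else if (is.matrix(mask)) mask
  else stop("not a sampling mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<sampling_mask> %dx%d, pattern=%s, sampled %d/%d (%.3f)\n",
              nrow(g), ncol(g), x$spec$pattern %||% "custom",
              sum(g), length(g), sum(g) / length(g)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based indices of the partial-Fourier-removed rows: the ceil((1-pf)*ny)
# highest positive-frequency rows (DC sits at floor(ny/2)).
pf_removed_rows <- function(ny, pf_fraction) {
  if (pf_fraction > 1 || pf_fraction <= 0.5)
    stop("pf_fraction must satisfy 1/2 < pf <= 1")
  n_rm <- ceiling((1 - pf_fraction) * ny)
  if (n_rm == 0) integer(0) else (ny - n_rm):(ny - 1)
}

acs_rows <- function(ny, acs_width) {
  if (acs_width == 0) return(integer(0))
  dc <- ny %/% 2
  (dc - acs_width %/% 2):(dc + ceiling(acs_width / 2) - 1)
}

#' 1D uniform undersampling mask with partial Fourier and ACS block
#'
#' Phase-encode rows on a uniform lattice of spacing `R` (offset chosen so the
#' DC row is on the lattice), restricted to the partial-Fourier-retained
#' region; `acs_width` central rows are always sampled; the frequency-encode
#' (column) axis is fully sampled.
#'
#' @param ny,nx grid size (rows are phase encodes).
#' @param R acceleration factor (lattice spacing), >= 1.
#' @param pf_fraction partial-Fourier fraction in (1/2, 1]; the
#'   `ceiling((1-pf)*ny)` highest positive-frequency rows are never sampled.
#' @param acs_width number of always-sampled central calibration rows.
#' @return a [sampling_mask].
#' @export
make_1d_mask <- function(ny, nx, R, pf_fraction = 1, acs_width = 0) {
  stopifnot(R >= 1, acs_width >= 0)
  removed <- pf_removed_rows(ny, pf_fraction)
  retained <- setdiff(0:(ny - 1), removed)
  acs <- acs_rows(ny, acs_width)
  if (length(acs) && !all(acs %in% retained))
    stop("ACS block extends into the partial-Fourier-removed region")
  offset <- (ny %/% 2) %% R
  lattice <- retained[retained %% R == offset]
  rows <- union(lattice, acs)
  grid <- matrix(0, ny, nx)
  grid[rows + 1L, ] <- 1
  new_sampling_mask(grid, list(pattern = "1d", R = R,
                               pf_fraction = pf_fraction,
                               acs_width = acs_width,
                               acs_idx = acs_index_set(ny, nx, acs_width, "rows")))
}

# Linear (column-major, 1-based) indices of the ACS region.
acs_index_set <- function(ny, nx, acs_width, kind) {
  if (acs_width == 0) return(integer(0))
  r <- acs_rows(ny, acs_width) + 1L
  cc <- if (kind == "rows") seq_len(nx) else acs_rows(nx, acs_width) + 1L
  as.integer(outer(r, (cc - 1L) * ny, `+`))
}

#' 2D CAIPI undersampling mask with partial Fourier and ACS block
#'
#' Both axes are phase encodes.  A point (i, j) (0-based) is sampled when
#' `j %% Rz == 0` and `(i - shift * (j %/% Rz)) %% Ry == 0`: every `Rz`-th
#' column carries a row lattice of spacing `Ry` whose offset advances by
#' `shift` from one sampled column to the next, spreading aliasing for better
#' coil-geometry conditioning.  Partial Fourier removes the highest
#' positive-frequency rows; a central `acs_width x acs_width` block is always
#' sampled.
#'
#' @param ny,nx grid size.
#' @param Ry,Rz acceleration factors along rows / columns.
#' @param shift CAIPI row shift per sampled column, `0 <= shift < Ry`.
#' @param pf_fraction,acs_width as in [make_1d_mask()].
#' @return a [sampling_mask].
#' @export
make_caipi_mask <- function(ny, nx, Ry, Rz, shift = 1, pf_fraction = 1,
                            acs_width = 0) {
  stopifnot(Ry >= 1, Rz >= 1, shift >= 0, shift < Ry)
  removed <- pf_removed_rows(ny, pf_fraction)
  acs <- acs_rows(ny, acs_width)
  if (length(acs) && length(removed) && any(acs %in% removed))
    stop("ACS block extends into the partial-Fourier-removed region")
  i <- matrix(0:(ny - 1), ny, nx)
  j <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  grid <- (j %% Rz == 0) & ((i - shift * (j %/% Rz)) %% Ry == 0)
  grid[removed + 1L, ] <- FALSE
  grid <- grid * 1
  if (acs_width > 0) {
    grid[acs_rows(ny, acs_width) + 1L, acs_rows(nx, acs_width) + 1L] <- 1
  }
  new_sampling_mask(grid, list(pattern = "caipi", Ry = Ry, Rz = Rz,
                               shift = shift, pf_fraction = pf_fraction,
                               acs_width = acs_width,
                               acs_idx = acs_index_set(ny, nx, acs_width, "block")))
}

#' Fully sampled mask
#' @param ny,nx grid size.
#' @return a [sampling_mask].
#' @export
make_full_mask <- function(ny, nx) {
  new_sampling_mask(matrix(1, ny, nx),
                    list(pattern = "full", R = 1, pf_fraction = 1,
                         acs_width = 0, acs_idx = integer(0)))
}

#' Partition acquired k-space into input/loss/validation subsets
#'
#' Draws the validation set Psi once (uniformly over Omega, of size
#' `floor(r_psi * |Omega|)`), then for each of `n_pairs` training pairs splits
#' the remaining points uniformly at random into Lambda (network input) and
#' Theta (training loss) with `|Theta| = floor(r_theta * |Omega|)` and Lambda
#' taking the remainder.  With `protect_acs`, ACS calibration points are never
#' placed in Psi or Theta, so the network input always contains the fully
#' sampled centre.  Fully reproducible from `seed`.
#'
#' @param mask a [sampling_mask] defining Omega.
#' @param ratios length-3 positive vector (Lambda, Theta, Psi) summing to 1.
#' @param n_pairs number of (Lambda, Theta) training pairs.
#' @param seed integer RNG seed.
#' @param protect_acs keep the ACS block in Lambda for every pair.
#' @return object of class `partition_set` with fields `psi` (linear indices),
#'   `pairs` (list of `list(lambda, theta)`), `ratios`, `seed`.
#' @export
partition_kspace <- function(mask, ratios = c(0.48, 0.32, 0.20), n_pairs = 50,
                             seed = 1, protect_acs = TRUE) {
  stopifnot(length(ratios) == 3, all(ratios > 0), n_pairs >= 1)
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  g <- mask_grid(mask)
  omega <- which(g == 1)
  acs <- if (protect_acs && inherits(mask, "sampling_mask"))
    intersect(mask$spec$acs_idx %||% integer(0), omega) else integer(0)
  n_psi <- floor(ratios[3] * length(omega))
  n_theta <- floor(ratios[2] * length(omega))
  free <- setdiff(omega, acs)
  if (n_psi + n_theta > length(free))
    stop("ratios infeasible for this mask (too few non-ACS samples)")
  if (n_psi < 1 || n_theta < 1)
    stop("ratios infeasible: empty Theta or Psi")
  with_seed(seed, {
    psi <- sort(sample(free, n_psi))
    rest <- setdiff(omega, psi)
    rest_free <- setdiff(rest, acs)
    pairs <- lapply(seq_len(n_pairs), function(k) {
      theta <- sort(sample(rest_free, n_theta))
      list(lambda = sort(setdiff(rest, theta)), theta = theta)
    })
    structure(list(psi = psi, pairs = pairs, ratios = ratios, seed = seed,
                   omega = sort(omega), dim = dim(g)),
              class = "partition_set")
  })
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> |Omega|=%d |Psi|=%d, %d (Lambda,Theta) pairs, seed=%d\n",
              length(x$omega), length(x$psi), length(x$pairs), x$seed))
  invisible(x)
}

#' Binary mask for an index subset
#'
#' Converts a set of linear k-space indices (as stored in a
#' [partition_kspace()] result) into a 0/1 grid of the given dimension.
#'
#' @param idx integer linear indices (column-major, 1-based).
#' @param dim length-2 grid dimension.
#' @return numeric 0/1 matrix.
#' @export
subset_mask <- function(idx, dim) {
  g <- matrix(0, dim[1], dim[2])
  g[idx] <- 1
  g
}
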