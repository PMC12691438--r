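#' Virtual-coil conjugate-symmetry augmentation
#'
#' For a real-valued object the k-space is Hermitian symmetric:
#' `Y(-k) = conj(Y(k))`.  Partial-Fourier acquisitions exploit this by
#' omitting one side of k-space.  The virtual-coil trick injects that
#' symmetry into a network by stacking the image with its complex conjugate,
#' `V x = [x, conj(x)]`: the spectrum of `conj(x)` is the conjugated,
#' index-reflected spectrum of `x`, so a k-space denoiser seeing both
#' channels can fill the unsampled partial-Fourier region.  The reduction
#' `V^H` used here is the averaging left-inverse `(s1 + conj(s2))/2`, so that
#' `vc_reduce(vc_augment(x)) == x` exactly.
#'
#' @name virtual-coil
NULL

#' Augment an image with its virtual (conjugate) channel
#'
#' @param x complex image matrix (ny x nx).
#' @return complex array (ny x nx x 2): channel 1 is `x`, channel 2 `conj(x)`.
#' @export
vc_augment <- function(x) {
  stopifnot(is.matrix(x))
  s <- array(0i, dim = c(nrow(x), ncol(x), 2))
  s[, , 1] <- x
  s[, , 2] <- Conj(x)
  s
}

#' Reduce a virtual-coil stack back to one image
#'
#' The averaging left-inverse of [vc_augment()]: `(s1 + conj(s2)) / 2`.
#'
#' @param s complex array (ny x nx x 2).
#' @return complex image matrix.
#' @export
vc_reduce <- function(s) {
  if (length(dim(s)) != 3L || dim(s)[3] != 2L)
    stop("vc_reduce: expected a 2-channel stack")
  (s[, , 1] + Conj(s[, , 2])) / 2
}
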