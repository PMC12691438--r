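# Shared fixtures and independent dense-matrix oracles.

rcmat <- function(ny, nx) {
  matrix(complex(real = rnorm(ny * nx), imaginary = rnorm(ny * nx)), ny, nx)
}

rcarr <- function(ny, nx, C) {
  array(complex(real = rnorm(ny * nx * C), imaginary = rnorm(ny * nx * C)),
        c(ny, nx, C))
}

random_mask <- function(ny, nx, p = 0.5) {
  m <- matrix(rbinom(ny * nx, 1, p), ny, nx)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

# Unitary centered 1D DFT matrix: fftshift . DFT . ifftshift
dense_dft1 <- function(n) {
  W <- outer(0:(n - 1), 0:(n - 1),
             function(j, k) exp(-2i * pi * j * k / n)) / sqrt(n)
  s <- n %/% 2
  P <- diag(n)[, ((seq_len(n) - 1 + s) %% n) + 1]   # fftshift permutation
  Q <- diag(n)[, ((seq_len(n) - 1 - s) %% n) + 1]   # ifftshift permutation
  P %*% W %*% Q
}

# Matrix of the centered unitary 2D DFT acting on vec(x) (column-major)
dense_dft2 <- function(ny, nx) {
  kronecker(dense_dft1(nx), dense_dft1(ny))
}

# Dense SENSE forward operator A = P_Omega F S, stacked over coils
dense_forward <- function(S, mask) {
  d <- dim(S)
  F2 <- dense_dft2(d[1], d[2])
  do.call(rbind, lapply(seq_len(d[3]), function(c) {
    diag(as.vector(mask_grid(mask))) %*% F2 %*% diag(as.vector(S[, , c]))
  }))
}

nrmse_pct <- function(a, b) 100 * sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# small multicoil scan for trainer tests
tiny_scan <- function(ny = 32, nx = 32, C = 4, n_slices = 2, R = 2,
                      acs = 6, sigma = 0.01, seed = 1) {
  mask <- make_1d_mask(ny, nx, R, 1, acs)
  synth_scan(ny, nx, C, n_slices, mask, sigma = sigma, seed = seed)
}

# Python-based reference oracles (scikit-image / numpy via the system python)
py_eval <- function(code) {
  out <- suppressWarnings(system2("python", "-", stdout = TRUE, input = code))
  as.numeric(out[length(out)])
}

write_mat_csv <- function(m) {
  f <- tempfile(fileext = ".csv")
  utils::write.table(m, f, row.names = FALSE, col.names = FALSE, sep = ",")
  f
}

py_ssim <- function(a, b) {
  fa <- write_mat_csv(a); fb <- write_mat_csv(b)
  py_eval(sprintf("
import numpy as np
from skimage.metrics import structural_similarity
a = np.loadtxt('%s', delimiter=',')
b = np.loadtxt('%s', delimiter=',')
print('%%.15f' %% structural_similarity(a, b, gaussian_weights=True, sigma=1.5,
      use_sample_covariance=False, data_range=1.0))", fa, fb))
}

# Independent GMSD implementation from the metric's published definition
py_gmsd <- function(a, b) {
  fa <- write_mat_csv(a); fb <- write_mat_csv(b)
  py_eval(sprintf("
import numpy as np
from scipy.ndimage import correlate
a = np.loadtxt('%s', delimiter=',')
b = np.loadtxt('%s', delimiter=',')
h = np.array([[1,0,-1],[1,0,-1],[1,0,-1]])/3.0
c = 170/255.0**2
ga = np.sqrt(correlate(a,h,mode='constant')**2 + correlate(a,h.T,mode='constant')**2)
gb = np.sqrt(correlate(b,h,mode='constant')**2 + correlate(b,h.T,mode='constant')**2)
gms = (2*ga*gb + c)/(ga**2+gb**2+c)
print('%%.15f' %% gms.std())", fa, fb))
}
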