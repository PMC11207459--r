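## Exact non-uniform DFT on radial spokes, evaluated separably per spoke
## (two complex BLAS products per spoke). k is measured in cycles/FOV,
## pixel coordinates in pixels; the phase convention is
##   S(k) = sum_{x,y} I[y,x] exp(-2i*pi*(ky*y + kx*x)/N).

golden_angle_rad <- pi * (3 - sqrt(5)) / 2 * 2  # 111.246 degrees

spoke_angles <- function(n_spokes) (seq_len(n_spokes) - 1) * golden_angle_rad

spoke_radii <- function(n_readout, matrix_size) {
  dk <- matrix_size / n_readout   # cycles/FOV per radial sample
  ((seq_len(n_readout) - 1) - n_readout / 2) * dk
}

pixel_coords <- function(n) (seq_len(n) - 1) - n / 2

## forward NDFT of one image on one spoke
ndft_spoke <- function(img, rho, theta, N) {
  y <- pixel_coords(nrow(img)); x <- pixel_coords(ncol(img))
  ky <- rho * sin(theta); kx <- rho * cos(theta)
  Ey <- exp(-2i * pi * outer(ky, y) / N)    # n_ro x H
  Ex <- exp(-2i * pi * outer(kx, x) / N)    # n_ro x W
  rowSums((Ey %*% img) * Ex)
}

## adjoint NDFT accumulation for one spoke: returns H x W complex image
ndft_spoke_adjoint <- function(s_weighted, rho, theta, N, H, W) {
  y <- pixel_coords(H); x <- pixel_coords(W)
  ky <- rho * sin(theta); kx <- rho * cos(theta)
  Ey <- exp(2i * pi * outer(ky, y) / N)     # n_ro x H
  Ex <- exp(2i * pi * outer(kx, x) / N)     # n_ro x W
  crossprod(Ey, (s_weighted * Ex))          # t(Ey) %*% ... : H x W
}

## Radial (ramp) density-compensation: polar area element |k| dk dtheta
## with a half-cell disc weight at the centre sample. The angular element
## is the Voronoi gap of each spoke direction modulo pi (golden-angle
## spokes are not exactly uniform, and gated subsets even less so).
radial_density_weights <- function(rho, dtheta) {
  dk <- abs(rho[2] - rho[1])
  w <- abs(rho) * dk
  w[rho == 0] <- (dk / 2)^2 / 2    # half-disc cell, per unit angle
  outer(w, dtheta)
}

## per-spoke angular Voronoi widths on the half-circle (spokes sample
## both k and -k, so directions live modulo pi)
spoke_angular_gaps <- function(angles) {
  a <- angles %% pi
  ord <- order(a)
  s <- a[ord]
  n <- length(s)
  if (n == 1) return(rep(pi, 1))
  gaps <- diff(c(s, s[1] + pi))        # circular gaps on [0, pi)
  half <- (gaps + c(gaps[n], gaps[-n])) / 2
  out <- numeric(n)
  out[ord] <- half
  out
}

#' Density-compensated adjoint reconstruction of radial k-space
#'
#' Gridding-free inverse: applies analytic ramp (Ram-Lak style) density
#' compensation to every radial sample and evaluates the adjoint
#' non-uniform Fourier transform exactly on the Cartesian image grid.
#' Deterministic for a fixed input.
#'
#' @param kspace a `kspace_series` (see [simulate_radial_kspace()]).
#' @param matrix_size output image matrix; defaults to the acquisition
#'   matrix.
#' @return magnitude image (matrix `matrix_size` x `matrix_size`).
#' @export
reconstruct_nufft <- function(kspace, matrix_size = NULL) {
  stopifnot(inherits(kspace, "kspace_series"))
  if (is.null(matrix_size)) matrix_size <- kspace$seq$matrix_size
  lines <- kspace_lines_2d(kspace)
  n_lines <- ncol(lines)
  if (n_lines < 1) stop("k-space series contains no lines", call. = FALSE)
  if (nrow(lines) != kspace$seq$n_readout)
    stop("inconsistent readout sample count", call. = FALSE)
  N <- matrix_size
  rho <- spoke_radii(kspace$seq$n_readout, kspace$seq$matrix_size)
  w <- radial_density_weights(rho, spoke_angular_gaps(kspace$angles))
  acc <- matrix(0 + 0i, N, N)
  for (k in seq_len(n_lines)) {
    sw <- w[, k] * lines[, k]
    acc <- acc + ndft_spoke_adjoint(sw, rho, kspace$angles[k], N, N, N)
  }
  Mod(acc) / N^2
}

## collapse an (n_ro x n_lines x n_ch) array to the first channel when 2D
## behaviour is wanted internally
kspace_lines_2d <- function(kspace, channel = 1L) {
  if (length(dim(kspace$lines)) == 3L) kspace$lines[, , channel] else kspace$lines
}
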