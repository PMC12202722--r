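#' Centric-centric 2D FID-CSI k-space encoding order
#'
#' The first acquired point is the k-space center. Within each vertical
#' column (fixed kx) the ky indices are acquired in an up-down alternating
#' center-out pattern, and the columns themselves are visited in a similar
#' left-right alternating center-out order. Because every point of a column
#' is acquired before moving to the next column, the acquisition index (and
#' hence the hyperpolarized signal remaining) changes far more between
#' horizontally adjacent k-space points than vertically adjacent ones.
#' Indices are 0-based with the center at index `floor(N/2)`.
#'
#' @param nx,ny Matrix size (>= 1).
#' @param up_first Tie-break for the alternating pattern: take the positive
#'   offset first (default TRUE).
#' @return data.frame of class `encoding_order` with columns `j` (1-based
#'   acquisition index), `kx`, `ky` (0-based grid indices); a permutation of
#'   the full grid.
#' @export
#' @examples
#' centric_order(4, 4)
centric_order <- function(nx, ny, up_first = TRUE) {
  if (nx < 1 || ny < 1) stop_invalid("nx and ny must be >= 1")
  ord1d <- function(n) {
    ctr <- n %/% 2
    offs <- c(0, as.vector(rbind(seq_len(n), -seq_len(n))))
    if (!up_first) offs <- -offs
    idx <- ctr + offs
    idx[idx >= 0 & idx < n][seq_len(n)]
  }
  cols <- ord1d(nx)
  rows <- ord1d(ny)
  out <- data.frame(kx = rep(cols, each = ny), ky = rep(rows, times = nx))
  out$j <- seq_len(nrow(out))
  out <- out[, c("j", "kx", "ky")]
  class(out) <- c("encoding_order", "data.frame")
  out
}

#' Acquisition-order k-space weights from RF saturation and T1 decay
#'
#' With a constant flip angle theta every TR on a non-renewable pool, the
#' j-th acquired FID carries weight
#' `w_j = sin(theta) * cos(theta)^(j-1) * exp(-(j-1) * TR / T1)`.
#'
#' @param order An [centric_order()] result (or any data.frame with `j`,
#'   `kx`, `ky`).
#' @param flip_deg Flip angle in degrees, in (0, 90].
#' @param tr_ms Repetition time in ms.
#' @param t1_s Intrinsic T1 in s (> 0; `Inf` for no decay).
#' @return The input with a `weight` column appended, class
#'   `weighted_kspace`.
#' @export
kspace_weights <- function(order, flip_deg, tr_ms, t1_s) {
  if (flip_deg <= 0 || flip_deg > 90) stop_invalid("flip_deg must be in (0, 90]")
  if (t1_s <= 0) stop_invalid("t1_s must be > 0")
  th <- flip_deg * pi / 180
  j <- order$j
  order$weight <- sin(th) * cos(th)^(j - 1) * exp(-(j - 1) * (tr_ms / 1000) / t1_s)
  class(order) <- c("weighted_kspace", "data.frame")
  order
}

# weight map as a matrix with k=0 at [cx+1, cy+1] (0-based centers floor(n/2))
weight_matrix <- function(weighted, nx = max(weighted$kx) + 1,
                          ny = max(weighted$ky) + 1) {
  W <- matrix(0, nx, ny)
  W[cbind(weighted$kx + 1, weighted$ky + 1)] <- weighted$weight
  W
}

fftshift2 <- function(m) {
  d <- dim(m)
  m[c(((d[1] %/% 2) + 1):d[1], 1:(d[1] %/% 2)),
    c(((d[2] %/% 2) + 1):d[2], 1:(d[2] %/% 2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  s1 <- (d[1] + 1) %/% 2
  s2 <- (d[2] + 1) %/% 2
  m[c((s1 + 1):d[1], 1:s1)[seq_len(d[1])],
    c((s2 + 1):d[2], 1:s2)[seq_len(d[2])], drop = FALSE]
}

#' Point-spread function of a weighted k-space acquisition
#'
#' Inverse discrete Fourier transform of the k-space weight map, returned
#' with the spatial origin at the matrix center and normalized to unit peak
#' magnitude. Uniform weights give the separable Dirichlet kernel (nominal
#' one-voxel main lobe); decaying centric weights broaden the main lobe and
#' raise sidelobes, i.e. signal bleeding.
#'
#' @param weighted A [kspace_weights()] result covering the full grid.
#' @param nx,ny Grid size (inferred from the indices by default).
#' @return Complex `nx x ny` matrix of class `csi_psf` (peak magnitude 1),
#'   with attribute `norm` holding the pre-normalization peak.
#' @export
psf <- function(weighted, nx = max(weighted$kx) + 1, ny = max(weighted$ky) + 1) {
  if (nrow(weighted) != nx * ny)
    stop_invalid("weighted k-space must cover the full grid")
  W <- weight_matrix(weighted, nx, ny)
  img <- stats::fft(ifftshift2(W), inverse = TRUE) / (nx * ny)
  out <- fftshift2(img)
  pk <- max(Mod(out))
  structure(out / pk, class = "csi_psf", norm = pk)
}

#' Sidelobe energy of a PSF along one image direction
#'
#' Sums `|PSF|^2` along the central row (`direction = "x"`, left-right) or
#' central column (`direction = "y"`) outside the nominal one-voxel main
#' lobe (the center pixel plus `main_halfwidth` pixels on either side).
#' Energy outside that window is signal bled into neighboring voxels.
#'
#' @param p A [psf()] result.
#' @param direction `"x"` (row direction) or `"y"` (column direction).
#' @param main_halfwidth Half-width of the nominal main lobe in pixels
#'   (default 1).
#' @return Summed sidelobe energy.
#' @export
psf_sidelobe_energy <- function(p, direction = c("x", "y"),
                                main_halfwidth = 1) {
  direction <- match.arg(direction)
  d <- dim(p)
  cx <- d[1] %/% 2 + 1
  cy <- d[2] %/% 2 + 1
  cut <- if (direction == "x") Mod(p[, cy]) else Mod(p[cx, ])
  ctr <- if (direction == "x") cx else cy
  keep <- max(1, ctr - main_halfwidth):min(length(cut), ctr + main_halfwidth)
  sum(cut[-keep]^2)
}

#' Convolve an object map with the CSI sampling PSF
#'
#' Circular (DFT-consistent) convolution of a 2D intensity map with the
#' point-spread function implied by the k-space weights, scaled so that the
#' k-space center weight passes unchanged (uniform weights reproduce the
#' object exactly). The bleed map is the difference from ideal boxcar
#' sampling, i.e. from the object itself.
#'
#' @param object Numeric `nx x ny` intensity matrix.
#' @param weighted A [kspace_weights()] result on the same grid.
#' @return list with complex `image`, `bleed` (`image - object`) matrices.
#' @export
convolve_object <- function(object, weighted) {
  nx <- nrow(object); ny <- ncol(object)
  if (nrow(weighted) != nx * ny)
    stop_invalid("object and weighted k-space grids must match")
  W <- weight_matrix(weighted, nx, ny)
  w0 <- W[nx %/% 2 + 1, ny %/% 2 + 1]
  if (w0 == 0) stop_invalid("k-space center weight is zero")
  Wk <- ifftshift2(W / w0)
  img <- stats::fft(stats::fft(object) * Wk, inverse = TRUE) / (nx * ny)
  list(image = img, bleed = img - object)
}
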