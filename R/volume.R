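#' 3D image volume with voxel spacing and origin
#'
#' Lightweight container used throughout the package for MR images, CT
#' images, bias fields, property maps and dose distributions.  Coordinates
#' of voxel `(i, j, k)` (1-based) are `origin + (c(i, j, k) - 1) * spacing`,
#' in millimetres.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing in mm (length 3, positive).
#' @param origin World coordinate of the first voxel centre in mm.  Defaults
#'   to centring the grid on the world origin.
#' @return An object of class `image_volume` with elements `data`, `spacing`
#'   and `origin`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (mm)")
  }
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' Integer label volume over \{air = 0, soft = 1, bone = 2\}
#'
#' @inheritParams image_volume
#' @return An object of classes `label_volume` and `image_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  storage.mode(data) <- "integer"
  if (!all(data %in% TISSUE_CODES)) {
    stop("labels must be in {air=0, soft=1, bone=2}")
  }
  v <- image_volume(data, spacing, origin)
  class(v) <- c("label_volume", class(v))
  v
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

# New volume sharing the grid of `like`.
volume_like <- function(data, like) {
  image_volume(data, spacing = like$spacing, origin = like$origin)
}

# Per-axis world coordinates of voxel centres (list of three vectors, mm).
axis_coords <- function(vol) {
  lapply(1:3, function(a) vol$origin[a] + (seq_len(dim(vol$data)[a]) - 1) * vol$spacing[a])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' Write a volume to NIfTI
#'
#' Spacing and origin are stored in the qform/sform affine (diagonal
#' orientation); label volumes are written as integer data.
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  a <- vol$data
  attr(a, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(a)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file written by [write_volume()] (or any NIfTI with a
#'   diagonal affine).
#' @param labels If `TRUE`, return a [label_volume()].
#' @return An [image_volume()].
#' @export
read_volume <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- aff[1:3, 4]
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  if (labels) label_volume(round(data), spacing, origin)
  else image_volume(data, spacing, origin)
}

# ---- separable Gaussian smoothing -------------------------------------------

# Banded 1D Gaussian kernel matrix over n samples at spacing `sp` (mm).
gaussian_kernel_matrix <- function(n, sigma_mm, sp, truncate = 3, normalize = FALSE) {
  r <- max(1L, ceiling(truncate * sigma_mm / sp))
  off <- -r:r
  w <- exp(-(off * sp)^2 / (2 * sigma_mm^2))
  w <- w / sum(w)
  D <- outer(seq_len(n), seq_len(n), "-")
  M <- matrix(0, n, n)
  sel <- abs(D) <= r
  M[sel] <- w[D[sel] + r + 1L]
  if (normalize) M <- M / rowSums(M)
  M
}

# Separable 3D Gaussian filter, spacing-aware.  With `normalize = TRUE` the
# kernel is renormalized at the boundary (used for synthesizing smooth
# fields); with `normalize = FALSE` it is a fixed truncated kernel summing
# to one in the grid interior (used as the CLIC window K).
gaussian_smooth <- function(arr, sigma_mm, spacing, truncate = 3, normalize = FALSE) {
  d <- dim(arr)
  M1 <- gaussian_kernel_matrix(d[1], sigma_mm, spacing[1], truncate, normalize)
  M2 <- gaussian_kernel_matrix(d[2], sigma_mm, spacing[2], truncate, normalize)
  M3 <- gaussian_kernel_matrix(d[3], sigma_mm, spacing[3], truncate, normalize)
  out <- M1 %*% matrix(arr, d[1], d[2] * d[3])
  dim(out) <- d
  out <- aperm(out, c(2, 1, 3))
  out <- M2 %*% matrix(out, d[2], d[1] * d[3])
  dim(out) <- c(d[2], d[1], d[3])
  out <- aperm(out, c(2, 1, 3))
  out <- matrix(out, d[1] * d[2], d[3]) %*% t(M3)
  dim(out) <- d
  out
}

# ---- binary morphology ------------------------------------------------------

ball_offsets <- function(r) {
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= r^2, , drop = FALSE]
}

# Offsets within a physical radius (mm) on an anisotropic grid.
ball_offsets_mm <- function(r_mm, spacing) {
  rv <- pmax(1L, ceiling(r_mm / spacing))
  g <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= r_mm^2, , drop = FALSE]
}

# out[i] <- m[i - o], FALSE outside the grid.
shift_mask <- function(m, o) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_dst <- idx_src <- vector("list", 3)
  for (a in 1:3) {
    dst <- seq.int(max(1, 1 + o[a]), min(d[a], d[a] + o[a]))
    if (length(dst) == 0) return(out)
    idx_dst[[a]] <- dst
    idx_src[[a]] <- dst - o[a]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

dilate_mask <- function(m, radius, spacing = NULL) {
  offs <- if (is.null(spacing)) ball_offsets(radius)
          else ball_offsets_mm(radius, spacing)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out | shift_mask(m, offs[i, ])
  out
}

erode_mask <- function(m, radius) {
  offs <- ball_offsets(radius)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out & shift_mask(m, offs[i, ])
  out
}

close_mask <- function(m, radius) erode_mask(dilate_mask(m, radius), radius)

# Largest 6-connected component of a binary mask.
largest_component <- function(m) {
  labs <- label_components_cpp(as.logical(m), dim(m))
  if (max(labs) == 0L) stop("mask is empty: no connected component")
  tab <- tabulate(labs[labs > 0L])
  out <- array(labs == which.max(tab), dim(m))
  out
}

# Number of 6-connected components of a binary mask.
count_components <- function(m) {
  max(label_components_cpp(as.logical(m), dim(m)))
}

# ---- Otsu threshold ---------------------------------------------------------

# Histogram-based Otsu threshold on a numeric vector/array.
otsu_threshold <- function(v, n_bins = 256) {
  v <- as.numeric(v)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, edges, all.inside = TRUE), n_bins), n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / pmax(w0 * (1 - w0), .Machine$double.eps)
  sigma_b[w0 <= 0 | w0 >= 1] <- 0
  centers[which.max(sigma_b)]
}
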