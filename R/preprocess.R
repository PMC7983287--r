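#' Temporal anti-aliasing (VENC unwrap)
#'
#' Phase-contrast velocities beyond +/-VENC alias into `(-venc, +venc]`.
#' This correction scans frames in temporal order per voxel and component:
#' wherever the jump from the (already corrected) previous frame exceeds the
#' VENC, the multiple of `2 * venc` that minimises the jump is added. The
#' first frame is taken as reference. Any wrap chain recoverable from
#' temporal continuity (inter-frame jumps of the true field below VENC and
#' first-frame values inside the encoded range) is undone exactly.
#'
#' @param field A [velocity_field()] with a VENC set.
#' @param max_passes Maximum sweeps over the time axis (the minimal-jump rule
#'   converges in one; further passes are a safety net).
#' @return The unwrapped [velocity_field()] (`wrapped = FALSE`).
#' @export
unwrap_aliasing <- function(field, max_passes = 3L) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(field$venc_m_s)) {
    stop("unwrap_aliasing requires a VENC on the field", call. = FALSE)
  }
  nt <- field$grid$n_frames
  stopifnot(nt >= 2)
  venc <- field$venc_m_s
  dims <- dim(field$data)
  nvox <- prod(dims[1:3])
  data <- field$data
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (c_ in 1:3) {
      v <- matrix(data[, , , , c_], nrow = nvox, ncol = nt)
      for (t_ in 2:nt) {
        # frame t-1 is already corrected, so the rule applies sequentially
        k <- round((v[, t_] - v[, t_ - 1]) / (2 * venc))
        if (any(k != 0)) {
          changed <- TRUE
          v[, t_] <- v[, t_] - 2 * venc * k
        }
      }
      data[, , , , c_] <- array(v, dims[1:4])
    }
    if (!changed) break
  }
  out <- velocity_field(data, field$grid, venc_m_s = venc, wrapped = FALSE,
                        log = field$log)
  annotate_field(out, sprintf("unwrap[max_passes=%d]", max_passes))
}

#' Eddy-current offset correction
#'
#' Phase-contrast background offsets from eddy currents vary smoothly in
#' space and slowly in time; the standard stationary-tissue correction fits a
#' low-order spatial polynomial to the temporally averaged velocity over
#' voxels known to be static and subtracts the fitted surface from every
#' frame.
#'
#' @param field A [velocity_field()] (unwrap first if aliased).
#' @param static_mask Logical 3-D array (or [la_mask()]) marking static
#'   voxels; must contain at least 10 voxels per fitted coefficient.
#' @param order Polynomial order, 1 (affine, default) or 2.
#' @return List with elements `field` (corrected) and `fit`, an `eddy_fit`
#'   holding the 3 x p coefficient matrix (columns: intercept in m/s, then
#'   per-mm terms) and per-component residual RMS over static voxels.
#' @export
correct_eddy_currents <- function(field, static_mask, order = 1L) {
  stopifnot(inherits(field, "velocity_field"), order %in% c(1L, 2L))
  if (inherits(static_mask, "la_mask")) static_mask <- static_mask$data
  stopifnot(all(dim(static_mask) == field$grid$shape))
  static_mask <- array(as.logical(static_mask), dim(static_mask))
  grid <- field$grid
  co <- voxel_coords_mm(grid)
  dims <- grid$shape
  X <- array(rep(co[[1]], times = prod(dims[2:3])), dims)
  Y <- array(rep(rep(co[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(co[[3]], each = prod(dims[1:2])), dims)
  basis <- list(intercept = array(1, dims), x = X, y = Y, z = Z)
  if (order == 2L) {
    basis <- c(basis, list(x2 = X^2, y2 = Y^2, z2 = Z^2,
                           xy = X * Y, xz = X * Z, yz = Y * Z))
  }
  p <- length(basis)
  n_static <- sum(static_mask)
  if (n_static < 10L * p) {
    stop("need at least ", 10L * p, " static voxels for an order-", order,
         " fit; got ", n_static, call. = FALSE)
  }
  design <- vapply(basis, function(b) b[static_mask], numeric(n_static))
  qrd <- qr(design)
  if (qrd$rank < p) {
    stop("eddy-current design is rank deficient (rank ", qrd$rank, " < ", p,
         "): static voxels do not span the order-", order,
         " polynomial space (e.g. coplanar voxels for order 1)",
         call. = FALSE)
  }
  tmean <- apply(field$data, c(1, 2, 3, 5), mean)   # temporal mean per comp
  coefs <- matrix(0, 3, p, dimnames = list(NULL, names(basis)))
  resid_rms <- numeric(3)
  data <- field$data
  for (c_ in 1:3) {
    y <- tmean[, , , c_][static_mask]
    beta <- qr.coef(qrd, y)
    coefs[c_, ] <- beta
    resid_rms[c_] <- sqrt(mean((y - design %*% beta)^2))
    surface <- Reduce(`+`, Map(function(b, w) b * w, basis, beta))
    for (t_ in seq_len(grid$n_frames)) {
      data[, , , t_, c_] <- data[, , , t_, c_] - surface
    }
  }
  out <- velocity_field(data, grid, venc_m_s = field$venc_m_s,
                        wrapped = field$wrapped, log = field$log)
  out <- annotate_field(out, sprintf("eddy_correct[order=%d]", order))
  fit <- structure(list(coefficients = coefs, residual_rms = resid_rms,
                        order = order, n_static = n_static),
                   class = "eddy_fit")
  list(field = out, fit = fit)
}

#' @export
print.eddy_fit <- function(x, ...) {
  cat("<eddy_fit> order ", x$order, ", ", x$n_static, " static voxels\n",
      sep = "")
  print(signif(x$coefficients, 4))
  cat("residual RMS (m/s):", signif(x$residual_rms, 4), "\n")
  invisible(x)
}

#' Divergence-free (solenoidal) projection
#'
#' Blood is incompressible, so the measured velocity field should be
#' divergence free; measurement noise is not. This denoising step removes,
#' frame by frame, the discretely curl-free part of the field: it solves the
#' Helmholtz decomposition in Fourier space using modified wavenumbers
#' `sin(k h) / h` that correspond exactly to the package's central-difference
#' operators. Consequences of that choice:
#'
#' * the central-difference divergence of the output vanishes to machine
#'   precision at interior voxels,
#' * the projection is exactly idempotent,
#' * fields whose discrete divergence is already zero (e.g. a rigid
#'   rotation, where each component is constant along its own axis) pass
#'   through unchanged,
#' * the per-frame mean velocity (bulk flow) is preserved.
#'
#' The grid is treated as one period of a periodic domain; for non-periodic
#' fields the correction near the outermost voxel layers absorbs the
#' wrap-around mismatch, and the guarantees above are stated for interior
#' voxels.
#'
#' @param field A [velocity_field()]; each axis needs >= 4 voxels.
#' @return The projected [velocity_field()].
#' @export
project_divergence_free <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  grid <- field$grid
  if (any(grid$shape < 4L)) {
    stop("projection needs at least 4 voxels per axis", call. = FALSE)
  }
  n <- grid$shape
  h_m <- grid$spacing_mm / 1000
  ktil <- lapply(1:3, function(a) {
    m <- 0:(n[a] - 1)
    sin(2 * pi * m / n[a]) / h_m[a]
  })
  KX <- array(rep(ktil[[1]], times = prod(n[2:3])), n)
  KY <- array(rep(rep(ktil[[2]], each = n[1]), times = n[3]), n)
  KZ <- array(rep(ktil[[3]], each = prod(n[1:2])), n)
  K2 <- KX^2 + KY^2 + KZ^2
  scale_div <- ifelse(K2 > 0, 1 / K2, 0)   # null modes left untouched
  data <- field$data
  for (t_ in seq_len(grid$n_frames)) {
    mu <- numeric(3)
    Fc <- vector("list", 3)
    for (c_ in 1:3) {
      v <- data[, , , t_, c_]
      mu[c_] <- mean(v)
      Fc[[c_]] <- stats::fft(v - mu[c_])
    }
    dotk <- KX * Fc[[1]] + KY * Fc[[2]] + KZ * Fc[[3]]
    corr <- dotk * scale_div
    Fc[[1]] <- Fc[[1]] - KX * corr
    Fc[[2]] <- Fc[[2]] - KY * corr
    Fc[[3]] <- Fc[[3]] - KZ * corr
    nvox <- prod(n)
    for (c_ in 1:3) {
      data[, , , t_, c_] <- Re(stats::fft(Fc[[c_]], inverse = TRUE)) / nvox +
        mu[c_]
    }
  }
  out <- velocity_field(data, grid, venc_m_s = field$venc_m_s,
                        wrapped = field$wrapped, log = field$log)
  annotate_field(out, "divergence_free_projection")
}

#' Full preprocessing chain
#'
#' Convenience wrapper running unwrap, eddy-current correction, and
#' (optionally) the divergence-free projection in the standard order.
#'
#' @inheritParams unwrap_aliasing
#' @inheritParams correct_eddy_currents
#' @param denoise Apply [project_divergence_free()] last?
#' @return List `field` (analysis-ready) and `eddy_fit`.
#' @export
preprocess_field <- function(field, static_mask, order = 1L,
                             max_passes = 3L, denoise = TRUE) {
  f <- unwrap_aliasing(field, max_passes = max_passes)
  ec <- correct_eddy_currents(f, static_mask, order = order)
  f <- ec$field
  if (denoise) f <- project_divergence_free(f)
  list(field = f, eddy_fit = ec$fit)
}
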