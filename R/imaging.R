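# Self-contained image numerics for the toy modules: integer-shift
# realignment, separable Gaussian smoothing, successive-difference QC
# metrics, voxelwise OLS, and the one-sample group t-test.

read_nifti_array <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  structure(arr, pixdim = RNifti::pixdim(RNifti::readNifti(path)))
}

write_nifti_array <- function(arr, path, voxel_mm = c(3, 3, 3), tr = 2) {
  img <- RNifti::asNifti(unclass(arr))
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd == 4L) c(voxel_mm, tr) else voxel_mm
  # write-temp-then-rename: an output may replace a hard-linked placed
  # input of the same name, and truncating the shared inode in place would
  # corrupt the upstream instance's registered file
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".nii.gz")
  RNifti::writeNifti(img, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Discard dummy scans from a 4D series
#'
#' Removes the first `numdummies` volumes (acquired before steady-state
#' magnetization). Event onsets defined on the original grid are *not*
#' adjusted here; specify onsets on the post-dummy grid.
#'
#' @param series 4D array (x, y, z, t).
#' @param numdummies number of leading volumes to drop; must be smaller
#'   than the number of scans.
#' @return 4D array with `dim(series)[4] - numdummies` volumes.
#' @export
discard_dummies <- function(series, numdummies) {
  stopifnot(length(dim(series)) == 4L)
  n <- dim(series)[4]
  numdummies <- as.integer(numdummies)
  if (numdummies < 0 || numdummies >= n) {
    abort_aq(sprintf("numdummies (%d) must be in [0, n_scans) with n_scans = %d",
                     numdummies, n), "aqueduct_spec_error")
  }
  if (numdummies == 0L) return(series)
  series[, , , (numdummies + 1L):n, drop = FALSE]
}

# translate a 3D volume by an integer voxel shift, zero-filling the
# vacated region
shift_volume <- function(vol, shift) {
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[[ax]]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) {
      dst[[ax]] <- (1 + s):d[ax]; src[[ax]] <- 1:(d[ax] - s)
    } else {
      dst[[ax]] <- 1:(d[ax] + s); src[[ax]] <- (1 - s):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Toy rigid realignment by exhaustive integer translation search
#'
#' Estimates a per-volume integer voxel shift (within `max_shift` per axis)
#' maximizing the correlation with the first volume, then shifts each
#' volume back. Rotations are not modeled; the 6-column motion table
#' carries the three translations (in voxels) and three zero rotation
#' columns, matching the realignment-parameter convention.
#'
#' @param series 4D array with at least 2 volumes.
#' @param max_shift search radius in voxels per axis.
#' @return list: `corrected` (4D array), `motion` (scans x 6 matrix),
#'   `mean` (3D mean of the corrected series).
#' @export
toy_realign <- function(series, max_shift = 3L) {
  stopifnot(length(dim(series)) == 4L, dim(series)[4] >= 2L)
  ref <- series[, , , 1]
  if (stats::sd(ref) == 0) {
    warning("reference volume is constant; assuming zero motion")
    zero <- matrix(0, dim(series)[4], 6L)
    return(list(corrected = series, motion = zero,
                mean = apply(series, 1:3, mean)))
  }
  n <- dim(series)[4]
  d <- dim(series)[1:3]
  shifts <- seq.int(-max_shift, max_shift)
  grid <- as.matrix(expand.grid(dx = shifts, dy = shifts, dz = shifts))
  motion <- matrix(0, n, 6L)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  corrected <- series
  # correlation restricted to the overlap window of a candidate shift, so
  # zero-filled borders cannot swamp the alignment signal; a shift s means
  # vol[x] corresponds to ref[x - s]
  shift_cor <- function(vol, s) {
    vol_idx <- lapply(1:3, function(ax)
      seq.int(1L + max(s[ax], 0L), d[ax] + min(s[ax], 0L)))
    ref_idx <- lapply(1:3, function(ax)
      seq.int(1L - min(s[ax], 0L), d[ax] - max(s[ax], 0L)))
    suppressWarnings(stats::cor(
      as.vector(vol[vol_idx[[1]], vol_idx[[2]], vol_idx[[3]]]),
      as.vector(ref[ref_idx[[1]], ref_idx[[2]], ref_idx[[3]]])))
  }
  for (t in 2:n) {
    vol <- series[, , , t]
    if (stats::sd(vol) == 0) {
      warning(sprintf("volume %d is constant; assuming zero motion", t))
      next
    }
    cors <- vapply(seq_len(nrow(grid)), function(g)
      shift_cor(vol, grid[g, ]), 0)
    cors[is.na(cors)] <- -Inf
    best <- as.integer(grid[which.max(cors), ])
    motion[t, 1:3] <- best
    fixed <- shift_volume(vol, -best)
    if (any(best != 0L)) {
      # voxels vacated by the back-shift have no data; impute them from the
      # reference volume rather than leaving design-correlated zeros
      support <- shift_volume(array(1, d), best)
      support <- shift_volume(support, -best)
      fixed[support == 0] <- ref[support == 0]
    }
    corrected[, , , t] <- fixed
  }
  list(corrected = corrected, motion = motion,
       mean = apply(corrected, 1:3, mean))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

convolve_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1L) return(vol)
  r <- (length(kernel) - 1L) / 2L
  d <- dim(vol)
  out <- array(0, d)
  for (off in seq_along(kernel)) {
    s <- off - r - 1L
    w <- kernel[[off]]
    if (w == 0) next
    idx_src <- idx_dst <- lapply(d, seq_len)
    lo <- max(1L, 1L - s); hi <- min(d[axis], d[axis] - s)
    if (hi < lo) next
    idx_dst[[axis]] <- lo:hi
    idx_src[[axis]] <- (lo + s):(hi + s)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      w * vol[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian with `sigma = FWHM / sqrt(8 * ln 2)` per axis,
#' converted to voxel units by the voxel size. Boundaries are zero-padded,
#' so total intensity is conserved for interior structure only.
#'
#' @param volume 3D array.
#' @param fwhm_mm full-width at half maximum of the kernel in millimeters
#'   (0 = identity).
#' @param voxel_size_mm voxel edge lengths in mm (length 1 or 3).
#' @return smoothed 3D array.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  if (fwhm_mm < 0) abort_aq("FWHM must be >= 0", "aqueduct_spec_error")
  if (fwhm_mm == 0) return(volume)
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3L)
  sigma_vox <- fwhm_mm / sqrt(8 * log(2)) / voxel_size_mm
  out <- volume
  for (ax in 1:3) out <- convolve_axis(out, gaussian_kernel_1d(sigma_vox[ax]),
                                       ax)
  out
}

#' Successive-volume difference QC metrics
#'
#' For each adjacent volume pair, the mean over voxels of the squared
#' intensity difference, scaled by the square of the series' global mean
#' (which makes the metric invariant to global intensity scaling). Volumes
#' adjacent to a metric exceeding `outlier_mult` times the median metric
#' are flagged.
#'
#' @param series 4D array with at least 2 volumes.
#' @param outlier_mult outlier threshold as a multiple of the median
#'   metric.
#' @return object of class `qc_report`: `metrics` (length scans-1),
#'   `mean_intensity` (per volume), `outliers` (indices of flagged
#'   metrics), `threshold`.
#' @export
tsdiffana_metrics <- function(series, outlier_mult = 10) {
  stopifnot(length(dim(series)) == 4L, dim(series)[4] >= 2L)
  n <- dim(series)[4]
  g <- mean(series)
  scale2 <- if (g == 0) 1 else g^2
  metrics <- vapply(seq_len(n - 1L), function(t) {
    mean((series[, , , t + 1L] - series[, , , t])^2) / scale2
  }, 0)
  med <- stats::median(metrics)
  threshold <- outlier_mult * med
  outliers <- if (med > 0) which(metrics > threshold) else integer(0)
  structure(list(metrics = metrics,
                 mean_intensity = apply(series, 4, mean),
                 outliers = outliers, threshold = threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d metric(s), %d outlier(s)\n",
              length(x$metrics), length(x$outliers)))
  invisible(x)
}

#' Voxelwise ordinary least squares with contrasts
#'
#' Fits `y = X b + e` independently at every voxel and computes, for each
#' contrast row `c`, the effect `c b` and `t = c b / sqrt(s2 * c (X'X)^-1
#' c')` with `n - rank(X)` residual degrees of freedom. A rank-deficient
#' design is handled by pseudoinverse with a warning and reduced df.
#'
#' @param series 4D array whose 4th dimension matches `nrow(X)`.
#' @param X design matrix (scans x columns).
#' @param contrasts list of numeric contrast row vectors (full design
#'   width); may be empty.
#' @return list: `beta` (4D, columns last), `sigma2` (3D), `df`,
#'   `effects` and `tstat` (lists of 3D maps, one per contrast).
#' @export
fit_first_level <- function(series, X, contrasts = list()) {
  d <- dim(series)
  stopifnot(length(d) == 4L, d[4] == nrow(X))
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(series, nrow = prod(d[1:3]), ncol = n)  # voxels x scans
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank < p) {
    warning(sprintf("rank-deficient design (rank %d of %d columns); using pseudoinverse",
                    rank, p))
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    B <- Y %*% t(pinv)                      # voxels x p
    XtXinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
  } else {
    B <- t(qr.coef(qrX, t(Y)))
    XtXinv <- chol2inv(qr.R(qrX))
  }
  df <- n - rank
  resid <- Y - B %*% t(X)
  sigma2 <- rowSums(resid^2) / max(df, 1L)
  effects <- tstat <- vector("list", length(contrasts))
  for (k in seq_along(contrasts)) {
    cvec <- as.numeric(contrasts[[k]])
    stopifnot(length(cvec) == p)
    eff <- drop(B %*% cvec)
    se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
    tk <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, Inf * sign(eff)))
    effects[[k]] <- array(eff, d[1:3])
    tstat[[k]] <- array(tk, d[1:3])
  }
  list(beta = array(B, c(d[1:3], p)), sigma2 = array(sigma2, d[1:3]),
       df = df, effects = effects, tstat = tstat)
}

#' Voxelwise one-sample t-test across subjects
#'
#' The second-level group statistic: at each voxel, a one-sample t on the
#' per-subject contrast values with `n - 1` degrees of freedom. Voxels with
#' zero between-subject variance and nonzero mean give infinite t and are
#' flagged degenerate.
#'
#' @param maps list (one per subject, >= 2) of aligned arrays.
#' @return list: `tstat` array, `mean`, `sd`, `df`, `degenerate` (logical
#'   array).
#' @export
second_level_ttest <- function(maps) {
  n <- length(maps)
  if (n < 2L) {
    abort_aq("second-level t-test needs at least 2 subjects",
             "aqueduct_spec_error")
  }
  d <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), d))
  Y <- vapply(maps, as.vector, numeric(prod(d)))
  mu <- rowMeans(Y)
  sdv <- apply(Y, 1L, stats::sd)
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)),
                 ifelse(mu == 0, 0, Inf * sign(mu)))
  list(tstat = array(tval, d), mean = array(mu, d), sd = array(sdv, d),
       df = n - 1L, degenerate = array(sdv == 0 & mu != 0, d))
}
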