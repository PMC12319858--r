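#' Sinusoidal benchmark signal
#'
#' A pure sinusoid of given period, in samples:
#' `amplitude * sin(2*pi*t/period + phase)` for `t = 0, ..., n-1`.
#' A single sinusoid is periodic and fully balanced between positive and
#' negative excursions, which makes it the benchmark of choice for the
#' coherence/anti-coherence balance metrics.
#'
#' @param period Period in samples (>= 2).
#' @param n Number of samples (>= period).
#' @param phase Phase offset in radians.
#' @param amplitude Peak amplitude.
#' @return Numeric vector of length `n`.
#' @examples
#' gen_sinusoid(4, 4)  # 0, 1, 0, -1
#' @export
gen_sinusoid <- function(period, n, phase = 0, amplitude = 1) {
  if (!is.finite(period) || period < 2)
    stop("`period` must be >= 2 samples", call. = FALSE)
  if (!is.finite(n) || n < period)
    stop("`n` must be >= `period`", call. = FALSE)
  amplitude * sin(2 * pi * (seq_len(n) - 1) / period + phase)
}

#' White Gaussian benchmark noise
#'
#' i.i.d. standard normal samples, reproducible per seed. The global RNG
#' state is left untouched.
#'
#' @param n Number of samples (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' identical(gen_gaussian_noise(100, 1), gen_gaussian_noise(100, 1))
#' @export
gen_gaussian_noise <- function(n, seed) {
  if (!is.finite(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  withr::with_seed(as.integer(seed), stats::rnorm(n))
}

#' 1/f (pink) benchmark noise
#'
#' Zero-mean, unit-variance noise whose power spectrum follows
#' `1/f^exponent`, built by spectral shaping: white Gaussian noise is
#' Fourier transformed, each frequency bin's amplitude is scaled by
#' `f^(-exponent/2)`, the DC term is zeroed, and the inverse transform is
#' standardized. `exponent = 1` gives classic pink noise, the canonical
#' stand-in for signals with long-range temporal correlations;
#' `exponent = 0` degenerates to white noise.
#'
#' @param n Number of samples (>= 16).
#' @param seed Integer seed.
#' @param exponent Spectral exponent (>= 0), default 1.
#' @return Numeric vector of length `n` with mean 0 and sample variance 1.
#' @examples
#' x <- gen_pink_noise(1024, seed = 7)
#' c(mean(x), var(x))
#' @export
gen_pink_noise <- function(n, seed, exponent = 1) {
  if (!is.finite(n) || n < 16) stop("`n` must be >= 16", call. = FALSE)
  if (!is.finite(exponent) || exponent < 0)
    stop("`exponent` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  white <- gen_gaussian_noise(n, seed)
  z <- stats::fft(white)
  # frequencies of the DFT bins in cycles/sample; bin 1 is DC
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k) / n
  scale <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(z * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

# Deterministic per-voxel seed from (master seed, flat voxel index);
# stays below 2^31 and is order-independent by construction.
voxel_seed <- function(seed, idx) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(idx) * 16807) %% m)
}

gen_from_recipe <- function(spec, n_timepoints, seed) {
  kind <- match.arg(spec$kind, c("sinusoid", "white", "pink"))
  switch(kind,
    sinusoid = gen_sinusoid(spec$period, n_timepoints,
                            phase = spec$phase %||% 0,
                            amplitude = spec$amplitude %||% 1),
    white = gen_gaussian_noise(n_timepoints, seed),
    pink = gen_pink_noise(n_timepoints, seed,
                          exponent = spec$exponent %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic 4D volume of labeled benchmark signals
#'
#' Builds a small 4D volume in which every in-mask voxel carries a time
#' series drawn from one of the benchmark generators, so the whole
#' voxelwise mapping pipeline can be exercised without external imaging
#' data. Each stochastic voxel gets its own seed derived deterministically
#' from `(seed, flat voxel index)`, so the result is independent of the
#' order in which voxels are filled and is bit-identical across repeated
#' calls and worker counts.
#'
#' @param shape Integer vector of 3 spatial dimensions.
#' @param n_timepoints Number of timepoints per voxel.
#' @param recipe Named list of generator descriptors; each element is a
#'   list with `kind` in `"sinusoid"`, `"white"`, `"pink"` plus that
#'   generator's parameters (`period`, `phase`, `amplitude`, `exponent`).
#' @param seed Master integer seed.
#' @param labels Optional 3D character array (dims = `shape`) assigning
#'   each voxel a recipe name; `NA` marks out-of-mask voxels. By default
#'   all voxels are in-mask and recipe names are assigned round-robin in
#'   column-major voxel order.
#' @return A `tcm_synthetic_volume`: list with `data` (4D array, zeros
#'   outside the mask), `mask` (3D logical), `labels` (3D character),
#'   `seed`.
#' @examples
#' vol <- gen_synthetic_volume(c(4, 4, 2), 100,
#'   recipe = list(pink = list(kind = "pink"), white = list(kind = "white")),
#'   seed = 1)
#' table(vol$labels)
#' @export
gen_synthetic_volume <- function(shape, n_timepoints, recipe, seed,
                                 labels = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(names(recipe)) || any(names(recipe) == ""))
    stop("`recipe` must be a fully named list", call. = FALSE)
  nvox <- prod(shape)
  if (is.null(labels)) {
    labels <- array(rep_len(names(recipe), nvox), dim = shape)
  } else {
    labels <- array(as.character(labels), dim = shape)
  }
  mask <- !is.na(labels)
  if (!any(mask)) stop("empty mask: no labeled voxels", call. = FALSE)
  bad <- setdiff(unique(labels[mask]), names(recipe))
  if (length(bad))
    stop("labels without a recipe entry: ", paste(bad, collapse = ", "),
         call. = FALSE)
  data <- array(0, dim = c(shape, n_timepoints))
  flat <- which(mask)            # column-major flat indices
  for (idx in flat) {
    spec <- recipe[[labels[[idx]]]]
    series <- gen_from_recipe(spec, n_timepoints, voxel_seed(seed, idx))
    ijk <- arrayInd(idx, shape)
    data[ijk[1], ijk[2], ijk[3], ] <- series
  }
  structure(list(data = data, mask = mask, labels = labels,
                 seed = as.integer(seed)),
            class = "tcm_synthetic_volume")
}

#' @export
print.tcm_synthetic_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Synthetic 4D volume %dx%dx%d, %d timepoints, %d/%d in-mask voxels (seed %d)\n",
              d[1], d[2], d[3], d[4], sum(x$mask), prod(d[1:3]), x$seed))
  print(table(x$labels[x$mask]))
  invisible(x)
}

#' Write a synthetic volume to disk
#'
#' Writes `data` and `mask` as NIfTI-1 files and the voxel labels as a
#' CSV of coordinates.
#'
#' @param vol A `tcm_synthetic_volume`.
#' @param path_data,path_mask,path_labels Output file paths; `NULL`
#'   label path skips the label table.
#' @return Invisibly, the data path.
#' @export
write_synthetic_volume <- function(vol, path_data, path_mask,
                                   path_labels = NULL) {
  stopifnot(inherits(vol, "tcm_synthetic_volume"))
  RNifti::writeNifti(RNifti::asNifti(vol$data), path_data)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(vol$mask),
                                           dim = dim(vol$mask))), path_mask)
  if (!is.null(path_labels)) {
    idx <- which(vol$mask, arr.ind = TRUE)
    utils::write.csv(data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                                label = vol$labels[vol$mask]),
                     path_labels, row.names = FALSE)
  }
  invisible(path_data)
}
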