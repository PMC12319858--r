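#' Load a masked 4D series from NIfTI files
#'
#' Reads a 4D volume and a 3D binary mask, checks that their spatial
#' grids agree, and carries the volume's NIfTI header through to any maps
#' later written from it, so orientation and voxel-size metadata survive
#' the round trip.
#'
#' @param volume Path to a 4D NIfTI-1 file.
#' @param mask Path to a 3D NIfTI-1 mask (nonzero = in-mask).
#' @return A `tcm_volume_series`: list with `data` (4D array, double),
#'   `mask` (3D logical), `header` (the source NIfTI image used as a
#'   metadata template), `source` (file paths).
#' @export
load_masked_series <- function(volume, mask) {
  if (!file.exists(volume)) stop("volume file not found: ", volume, call. = FALSE)
  if (!file.exists(mask)) stop("mask file not found: ", mask, call. = FALSE)
  img <- RNifti::readNifti(volume)
  msk <- RNifti::readNifti(mask)
  if (length(dim(img)) != 4L)
    stop("expected a 4D volume, got ", length(dim(img)), "D", call. = FALSE)
  if (!identical(dim(img)[1:3], dim(msk)[1:3]))
    stop("spatial grid mismatch: volume ", paste(dim(img)[1:3], collapse = "x"),
         " vs mask ", paste(dim(msk)[1:3], collapse = "x"), call. = FALSE)
  m <- array(as.array(msk) != 0, dim = dim(msk)[1:3])
  if (!any(m)) stop("mask is empty", call. = FALSE)
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 mask = m, header = img,
                 source = c(volume = volume, mask = mask)),
            class = "tcm_volume_series")
}

#' Wrap an in-memory synthetic volume for mapping
#'
#' @param vol A `tcm_synthetic_volume` from [gen_synthetic_volume()].
#' @return A `tcm_volume_series` without file-backed metadata.
#' @export
as_volume_series <- function(vol) {
  stopifnot(inherits(vol, "tcm_synthetic_volume"))
  structure(list(data = vol$data, mask = vol$mask, header = NULL,
                 source = c(volume = NA_character_, mask = NA_character_)),
            class = "tcm_volume_series")
}

#' Voxelwise TCM maps
#'
#' Runs the streaming TCM metric computation on every in-mask voxel of a
#' 4D series and collects the six metrics into parametric maps.
#' Out-of-mask voxels are `NaN` so downstream statistics cannot silently
#' include background. Voxels are processed in flat column-major order
#' and are fully independent, so results are bit-identical for any
#' `workers >= 1`; a degenerate voxel (flat series) yields zeros with a
#' single summary warning, never an abort.
#'
#' @param series A `tcm_volume_series` from [load_masked_series()] or
#'   [as_volume_series()].
#' @param cfg A [tcm_config()].
#' @param workers Number of parallel worker processes (forked; default 1).
#' @return A `tcm_maps` object: named list of six 3D arrays (`tc`, `tac`,
#'   `cab1`, `mlp`, `mln`, `cab2`) with the mask, config and header as
#'   attributes.
#' @export
compute_tcm_maps <- function(series, cfg = tcm_config(), workers = 1L) {
  stopifnot(inherits(series, "tcm_volume_series"), inherits(cfg, "tcm_config"))
  dims <- dim(series$data)
  nt <- dims[4]
  if (nt < cfg$w + cfg$g)
    stop("too few timepoints (", nt, ") for w=", cfg$w, ", g=", cfg$g,
         call. = FALSE)
  flat <- which(series$mask)
  nxyz <- prod(dims[1:3])
  mat <- matrix(series$data, nrow = nxyz, ncol = nt)

  one_voxel <- function(idx) {
    x <- mat[idx, ]
    if (stats::var(x) == 0)
      return(c(0, 0, 0, 0, 0, 0, 1))
    m <- suppressWarnings(tcm_metrics(x, cfg))
    c(m$tc, m$tac, m$cab1, m$mlp, m$mln, m$cab2, m$n_undefined > 0)
  }

  res <- if (workers > 1L) {
    do.call(cbind, parallel::mclapply(flat, one_voxel,
                                      mc.cores = workers,
                                      mc.preschedule = TRUE))
  } else {
    vapply(flat, one_voxel, numeric(7))
  }
  n_degen <- sum(res[7, ] > 0)
  if (n_degen > 0)
    warning(n_degen, " voxel(s) had degenerate (flat) series; ",
            "their metrics are 0", call. = FALSE)

  metric_names <- c("tc", "tac", "cab1", "mlp", "mln", "cab2")
  maps <- lapply(seq_along(metric_names), function(j) {
    v <- array(NaN, dim = dims[1:3])
    v[flat] <- res[j, ]
    v
  })
  names(maps) <- metric_names
  structure(maps, class = "tcm_maps", mask = series$mask, config = cfg,
            header = series$header, source = series$source)
}

#' @export
print.tcm_maps <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("TCM maps %dx%dx%d (%d in-mask voxels)\n",
              d[1], d[2], d[3], sum(attr(x, "mask"))))
  msk <- attr(x, "mask")
  for (nm in names(x))
    cat(sprintf("  %-4s mean %+.4f  sd %.4f\n", toupper(nm),
                mean(x[[nm]][msk]), stats::sd(x[[nm]][msk])))
  invisible(x)
}

#' Voxelwise average of metric maps
#'
#' Arithmetic mean of two or more maps of the same metric on the same
#' grid, the operation used to collapse paired opposite-phase-encoding
#' scans of one session into a single session map. A voxel is `NaN` in
#' the result only where it is `NaN` in every input.
#'
#' @param maps A list of 3D arrays (or single metrics extracted from
#'   `tcm_maps` objects) sharing dimensions.
#' @return A 3D array of the same shape.
#' @export
average_maps <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 2L)
  dims <- dim(maps[[1]])
  for (m in maps)
    if (!identical(dim(m), dims))
      stop("map grids differ", call. = FALSE)
  acc <- array(0, dim = dims)
  cnt <- array(0L, dim = dims)
  for (m in maps) {
    ok <- is.finite(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt           # 0/0 -> NaN where every input was NaN
  out
}

#' Average two sets of six maps session-wise
#'
#' Convenience wrapper around [average_maps()] applied metric-by-metric
#' to whole `tcm_maps` objects (e.g., an LR and an RL scan of the same
#' session).
#'
#' @param a,b `tcm_maps` objects on the same grid.
#' @return A `tcm_maps` object of voxelwise means.
#' @export
average_tcm_maps <- function(a, b) {
  stopifnot(inherits(a, "tcm_maps"), inherits(b, "tcm_maps"),
            identical(names(a), names(b)))
  out <- lapply(names(a), function(nm) average_maps(list(a[[nm]], b[[nm]])))
  names(out) <- names(a)
  structure(out, class = "tcm_maps", mask = attr(a, "mask"),
            config = attr(a, "config"), header = attr(a, "header"),
            source = attr(a, "source"))
}

#' Write TCM maps as NIfTI files with a JSON sidecar
#'
#' One NIfTI-1 file per metric, named `<prefix>_<metric>.nii.gz`, storing
#' float32 voxels (computation stays float64 in memory) and restoring the
#' source volume's spatial metadata when available, plus a JSON sidecar
#' echoing the full configuration and package version.
#'
#' @param maps A `tcm_maps` object.
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"tcm"`.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_maps <- function(maps, out_dir, prefix = "tcm") {
  stopifnot(inherits(maps, "tcm_maps"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- attr(maps, "header")
  cfg <- attr(maps, "config")
  files <- character(0)
  for (nm in names(maps)) {
    path <- file.path(out_dir, paste0(prefix, "_", nm, ".nii.gz"))
    img <- if (!is.null(hdr)) {
      RNifti::asNifti(array(maps[[nm]], dim = dim(maps[[nm]])),
                      reference = hdr)
    } else {
      RNifti::asNifti(array(maps[[nm]], dim = dim(maps[[nm]])))
    }
    RNifti::writeNifti(img, path, datatype = "float")
    files[nm] <- path
  }
  sidecar <- file.path(out_dir, paste0(prefix, "_config.json"))
  jsonlite::write_json(
    list(w = cfg$w, r = cfg$r, g = cfg$g, dia_s = cfg$dia_s,
         dia_e = cfg$dia_e, corr_kind = cfg$corr_kind,
         convention = cfg$convention,
         software = paste0("tcmap ",
                           as.character(utils::packageVersion("tcmap"))),
         source = as.list(attr(maps, "source"))),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  files["config"] <- sidecar
  invisible(files)
}

#' Read one metric map written by [write_maps()]
#'
#' @param path NIfTI file path.
#' @return A 3D array.
#' @export
read_metric_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img)[1:3])
}
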