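#' Read / write grayscale TIFF stacks
#'
#' Frames are stored as 32-bit float single- or multi-page grayscale
#' TIFF.  The underlying TIFF writer stores values on a `[0, 1]` scale,
#' so frames are divided by `scale` on write and multiplied back on
#' read; the default `scale = 1024` keeps the full simulated dynamic
#' range (beads plus background can exceed 255) without clipping.  For
#' user-supplied 8/16-bit TIFFs use `scale = 255` to obtain the native
#' `[0, 255]` training scale.
#'
#' @param path file path.
#' @param frames a matrix or list of matrices.
#' @param scale storage scale factor.
#' @return `read_tiff_stack`: list of matrices; `write_tiff_stack`: the
#'   path, invisibly.
#' @export
read_tiff_stack <- function(path, scale = 1024) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("cannot read TIFF file ", path, ": ",
                           conditionMessage(e)))
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) {
      if (dim(pg)[3] > 1 &&
          !all(pg[, , 1] == pg[, , 2]))
        stop("non-grayscale TIFF page in ", path)
      pg <- pg[, , 1]
    }
    pg * scale
  })
}

#' @rdname read_tiff_stack
#' @export
write_tiff_stack <- function(frames, path, scale = 1024) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(all(vapply(frames, is.matrix, logical(1))))
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > scale)
    warning("frame values outside [0, ", scale,
            "] are clipped by the TIFF writer")
  tiff::writeTIFF(lapply(frames, function(f) f / scale), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Write a generated dataset to disk
#'
#' Each pair `i` becomes `<i>_input.tif`, `<i>_target.tif` and
#' `<i>_truth.csv` (columns `id`, `cx_px`, `cy_px`, `radius_px`,
#' `z_um`); `manifest.json` echoes the generating spec, the storage
#' scale, the split membership and the per-pair seeds.
#'
#' @param ds a `bead_dataset`.
#' @param dir output directory (created if missing).
#' @param scale TIFF storage scale.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, scale = 1024) {
  stopifnot(inherits(ds, "bead_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pair in ds$pairs) {
    stem <- file.path(dir, sprintf("%04d", pair$id))
    write_tiff_stack(pair$input, paste0(stem, "_input.tif"), scale)
    write_tiff_stack(pair$target, paste0(stem, "_target.tif"), scale)
    utils::write.csv(pair$truth, paste0(stem, "_truth.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    spec = spec_to_list(ds$spec), scale = scale, split = ds$split,
    slice_index = vapply(ds$pairs, `[[`, integer(1), "slice_index"),
    seeds = lapply(ds$pairs, `[[`, "seeds"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return A `bead_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  spec <- spec_from_list(manifest$spec)
  pairs <- lapply(seq_len(spec$n_images), function(i) {
    stem <- file.path(dir, sprintf("%04d", i))
    structure(list(
      input = read_tiff_stack(paste0(stem, "_input.tif"),
                              manifest$scale)[[1]],
      target = read_tiff_stack(paste0(stem, "_target.tif"),
                               manifest$scale)[[1]],
      truth = utils::read.csv(paste0(stem, "_truth.csv"),
                              colClasses = c(id = "integer",
                                             cx_px = "numeric",
                                             cy_px = "numeric",
                                             radius_px = "numeric",
                                             z_um = "numeric")),
      slice_index = manifest$slice_index[i],
      seeds = as.list(manifest$seeds[i, ]), id = i),
      class = "frame_pair")
  })
  structure(list(pairs = pairs,
                 split = lapply(manifest$split, as.integer), spec = spec),
            class = "bead_dataset")
}

spec_to_list <- function(spec) {
  list(n_images = spec$n_images, split = spec$split,
       count_range = spec$count_range, radius_spec = spec$radius_spec,
       bead_value = spec$bead_value,
       vol = unclass(spec$vol)[c("Dx", "Dy", "Dz", "n", "nz")],
       bg = unclass(spec$bg), noise = unclass(spec$noise), seed = spec$seed)
}

spec_from_list <- function(x) {
  dataset_spec(n_images = x$n_images, split = unlist(x$split),
               count_range = unlist(x$count_range),
               radius_spec = unlist(x$radius_spec),
               bead_value = x$bead_value,
               vol = do.call(volume_spec, as.list(x$vol)),
               bg = do.call(background_params, as.list(x$bg)),
               noise = do.call(noise_params, as.list(x$noise)),
               seed = x$seed)
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a pair of files: `<stem>.json` holds the
#' architecture, parameter shapes (in order) and batch-norm running
#' statistics; `<stem>.bin` holds all parameter values as little-endian
#' doubles in that order.
#'
#' @param net a `restoration_net` or `upunet_fit`.
#' @param stem path stem (without extension).
#' @return `save_checkpoint`: `stem`, invisibly; `load_checkpoint`: the
#'   network.
#' @export
save_checkpoint <- function(net, stem) {
  if (inherits(net, "upunet_fit")) net <- net$net
  stopifnot(inherits(net, "restoration_net"))
  header <- list(
    class = class(net)[1],
    spec = unclass(net$spec),
    tensors = lapply(net$params, function(p) dim(p) %||% length(p)),
    running = net$running)
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  for (p in net$params) writeBin(as.numeric(p), con, size = 8,
                                 endian = "little")
  invisible(stem)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"),
                                simplifyVector = TRUE)
  net <- if (header$class == "upunet")
    build_upunet(upunet_spec(header$spec$L, header$spec$f0), seed = 1)
  else
    build_baseline_unet(baseline_unet_spec(header$spec$depth,
                                           header$spec$f0,
                                           header$spec$dropout), seed = 1)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  for (nm in names(net$params)) {
    n <- length(net$params[[nm]])
    vals <- readBin(con, "numeric", n, size = 8, endian = "little")
    if (length(vals) != n) stop("checkpoint weight blob truncated at ", nm)
    net$params[[nm]][] <- vals
  }
  for (nm in names(net$running))
    net$running[[nm]][] <- unlist(header$running[[nm]])
  net
}

#' Load a pipeline configuration from YAML
#'
#' The file may contain the sections `dataset` (fields of
#' [dataset_spec()]; `vol`, `bg` and `noise` as nested maps), `model`
#' (fields of [upunet_spec()]), `train` (fields of [train_config()]),
#' `detector` (`threshold`, `min_area`, `d_match`, `r_link`), plus
#' top-level `seed` and `out_dir`.  Unknown keys anywhere are an error,
#' guarding against silent typos.
#'
#' @param path YAML file.
#' @return A named list with classed component objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path) %||% list()
  known <- c("dataset", "model", "train", "detector", "seed", "out_dir")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  check_keys(raw, known, "top level")
  seed <- raw$seed %||% 1L
  ds_args <- raw$dataset %||% list()
  check_keys(ds_args, c("n_images", "split", "count_range", "radius_spec",
                        "bead_value", "vol", "bg", "noise", "seed"),
             "dataset")
  if (!is.null(ds_args$vol)) {
    # the YAML 1.1 parser reads a bare key `n` as the boolean FALSE
    names(ds_args$vol)[names(ds_args$vol) == "FALSE"] <- "n"
    check_keys(ds_args$vol, c("Dx", "Dy", "Dz", "n", "nz"), "dataset$vol")
    ds_args$vol <- do.call(volume_spec, ds_args$vol)
  }
  if (!is.null(ds_args$bg)) {
    check_keys(ds_args$bg, c("octaves", "base_frequency", "base_amplitude",
                             "persistence", "beta", "seed"), "dataset$bg")
    ds_args$bg <- do.call(background_params, ds_args$bg)
  }
  if (!is.null(ds_args$noise)) {
    check_keys(ds_args$noise, c("psf_sigma", "gaussian_level",
                                "poisson_gamma", "noise_order", "seed"),
               "dataset$noise")
    ds_args$noise <- do.call(noise_params, ds_args$noise)
  }
  if (is.null(ds_args$seed)) ds_args$seed <- seed
  model_args <- raw$model %||% list()
  check_keys(model_args, c("L", "f0"), "model")
  train_args <- raw$train %||% list()
  check_keys(train_args, c("initial_lr", "drop_factor", "drop_period_epochs",
                           "batch_size", "max_epochs", "l2_lambda", "seed"),
             "train")
  if (is.null(train_args$seed)) train_args$seed <- seed
  det <- raw$detector %||% list()
  check_keys(det, c("threshold", "min_area", "d_match", "r_link"),
             "detector")
  list(dataset = do.call(dataset_spec, ds_args),
       model = do.call(upunet_spec, model_args),
       train = do.call(train_config, train_args),
       detector = list(threshold = det$threshold %||% (0.3 * 255),
                       min_area = det$min_area %||% 4,
                       d_match = det$d_match %||% 5,
                       r_link = det$r_link %||% 5),
       seed = seed, out_dir = raw$out_dir %||% ".")
}
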