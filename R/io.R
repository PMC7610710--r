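# Volume and table input/output. Volumes are NIfTI; the canonical in-memory
# orientation puts the left-right axis first, so "sagittal plane" is
# well-defined for mirroring. No registration is performed here: inputs are
# assumed already registered to a standard space upstream.

#' Load a 3D volume from a NIfTI file
#'
#' Reads a single-channel 3D NIfTI image into a plain array, reorienting to
#' the canonical left-right-first ("LAS") axis order when the file carries a
#' usable orientation. Intensities pass through unchanged unless
#' `standardize = TRUE`, which rescales to mean 0 / SD 1 over the nonzero
#' foreground.
#'
#' @param path path to a readable NIfTI file.
#' @param standardize logical; per-volume foreground standardization.
#' @param reorient logical; enforce the canonical orientation.
#' @return a 3D array with attribute `voxel_size` (mm).
#' @export
load_volume <- function(path, standardize = FALSE, reorient = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 4L)
    stop("4D input not supported: ", path,
         " (expected a single 3D volume, got ", dim(img)[4], " frames)")
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), " dimensions")
  hdr <- RNifti::niftiHeader(img)
  if (reorient && (hdr$qform_code > 0 || hdr$sform_code > 0)) {
    # only files carrying a usable xform can be reoriented; files without
    # one are taken to be in canonical order already
    ok <- tryCatch({
      RNifti::orientation(img) <- "LAS"
      TRUE
    }, error = function(e) FALSE)
    if (!ok) warning("could not reorient ", path, "; using stored axis order")
  }
  vox <- tryCatch(RNifti::pixdim(img), error = function(e) c(1, 1, 1))
  out <- array(as.numeric(img), dim(img))
  if (standardize) {
    fg <- out != 0
    if (any(fg)) out <- (out - mean(out[fg])) / sd(out[fg])
  }
  attr(out, "voxel_size") <- vox[seq_len(3)]
  out
}

#' Write a 3D volume to a NIfTI file
#'
#' @param volume a 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel size in mm.
#' @return the path, invisibly.
#' @export
save_volume <- function(volume, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3L)
  img <- RNifti::asNifti(volume, datatype = "double", pixdim = voxel_size)
  # record the canonical left-right-first orientation in the sform
  m <- diag(c(-voxel_size[1], voxel_size[2], voxel_size[3], 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Center-crop or zero-pad a volume to a target shape
#'
#' Each axis is handled independently and symmetrically; for odd remainders
#' the extra voxel is taken from (or added to) the high-index end. The 1 mm
#' MNI 182x218x182 grid center-crops to the network's 160x192x160 input
#' with little or no brain tissue loss. Deterministic; cropping then padding
#' back restores the original shape with zeros where voxels were removed.
#'
#' @param volume a 3D array.
#' @param target_shape three positive integers.
#' @return a 3D array of shape `target_shape`.
#' @export
crop_or_pad <- function(volume, target_shape) {
  d <- dim(volume)
  stopifnot(length(d) == 3L, length(target_shape) == 3L)
  target_shape <- as.integer(target_shape)
  out <- array(0, target_shape)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (target_shape[a] <= d[a]) {            # crop
      lo <- (d[a] - target_shape[a]) %/% 2L
      src[[a]] <- (lo + 1L):(lo + target_shape[a])
      dst[[a]] <- seq_len(target_shape[a])
    } else {                                  # pad
      lo <- (target_shape[a] - d[a]) %/% 2L
      src[[a]] <- seq_len(d[a])
      dst[[a]] <- (lo + 1L):(lo + d[a])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    volume[src[[1]], src[[2]], src[[3]]]
  out
}

#' Read and validate a participants table
#'
#' Tab-separated table with columns `participant_id`, `age`, `sex`, `path`
#' and optionally `split` (train/val/test) and `modality`. Identifiers must
#' be unique within each split, ages finite and positive.
#'
#' @param path path to a TSV file.
#' @param check_paths logical; verify that every `path` entry resolves to an
#'   existing file (relative paths are resolved against the table's
#'   directory).
#' @return a data frame.
#' @export
read_participants <- function(path, check_paths = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "age", "sex", "path")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("participants table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(tab$age)) || any(tab$age <= 0))
    stop("ages must be finite and positive")
  split <- if ("split" %in% names(tab)) tab$split else rep("all", nrow(tab))
  for (s in unique(split)) {
    ids <- tab$participant_id[split == s]
    if (anyDuplicated(ids))
      stop("duplicated participant_id within split '", s, "'")
  }
  if (check_paths) {
    p <- tab$path
    rel <- !file.exists(p)
    p[rel] <- file.path(dirname(path), p[rel])
    if (!all(file.exists(p)))
      stop("unresolvable volume path(s): ",
           paste(head(tab$path[!file.exists(p)], 3), collapse = ", "))
    tab$path <- p
  }
  tab
}

#' Write a participants table
#'
#' @param tab a participants data frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_participants <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML file mirroring [train_config()] (keys such as `lr_init`, `lr_step`,
#' `batch_size`, `age_min`, `age_max`, `bin_width`, `label_sigma`, augment
#' settings). Missing keys fall back to the defaults; unknown keys are
#' reported.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# MD5 of a config list (via its canonical JSON serialization on disk),
# recorded in run logs for provenance.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: the serialized object embeds the
#' architecture spec and task, so a checkpoint can be reloaded without the
#' original build call. Conventionally named `<run>_epoch<k>.ckpt`.
#'
#' @param net a `cnn_network`.
#' @param path output path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored network.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "cnn_network"))
  layers <- collect_param_layers(net)
  params <- snapshot_params(net)
  buffers <- lapply(layers, function(l)
    if (inherits(l, "norm3d_layer"))
      list(running_mean = l$running_mean, running_var = l$running_var))
  saveRDS(list(arch = net$arch, spec = net$spec, task = net$task,
               params = params, buffers = buffers,
               package_version = as.character(utils::packageVersion("sfcn"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- switch(ck$arch,
                sfcn = build_sfcn(ck$spec, seed = 0L),
                resnet3d = build_resnet3d(ck$spec, seed = 0L),
                stop("unknown architecture in checkpoint: ", ck$arch))
  net$task <- ck$task
  restore_params(net, ck$params)
  layers <- collect_param_layers(net)
  for (i in seq_along(layers)) {
    if (!is.null(ck$buffers[[i]])) {
      layers[[i]]$running_mean <- ck$buffers[[i]]$running_mean
      layers[[i]]$running_var <- ck$buffers[[i]]$running_var
    }
  }
  net
}
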