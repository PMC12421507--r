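# Readers and writers: multi-plane TIFF frames, 16-bit label TIFFs, JSON
# manifests and YAML configuration.

write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 instances per frame")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  m <- round(m * 65535)
  storage.mode(m) <- "integer"
  m
}

write_frame_tiff <- function(frame, path) {
  tiff::writeTIFF(
    list(frame$nuclei_plane, frame$ev_plane, frame$merge_plane),
    path, bits.per.sample = 16L
  )
  invisible(path)
}

#' Read a multi-channel frame from disk
#'
#' Accepts a TIFF with at least three planes (mapped to entity roles by
#' `channel_map`) or an RGB image (TIFF or PNG), whose channels follow the
#' staining convention red = EV (DiD), green = merge/membrane (WGA),
#' blue = nuclei (Hoechst).
#'
#' @param path image file.
#' @param channel_map named integer list/vector giving the plane index of
#'   `nuclei`, `ev` and `merge` for multi-plane TIFFs.
#' @param time acquisition time (minutes) to attach to the frame.
#' @param normalize min-max normalize each plane to `[0, 1]`.
#' @return A [multichannel_frame()].
#' @export
read_frame <- function(path, channel_map = c(nuclei = 1L, ev = 2L,
                                             merge = 3L),
                       time = 0, normalize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  planes <- NULL
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, all = TRUE)
    if (length(img) >= 3L) {
      pick <- function(role) {
        pl <- img[[channel_map[[role]]]]
        if (length(dim(pl)) == 3L) pl <- pl[, , 1]
        pl
      }
      planes <- list(nuclei = pick("nuclei"), ev = pick("ev"),
                     merge = pick("merge"))
    } else {
      a <- img[[1]]
      if (length(dim(a)) == 3L && dim(a)[3] >= 3L) {
        planes <- list(nuclei = a[, , 3], ev = a[, , 1], merge = a[, , 2])
      }
    }
  } else if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L && dim(a)[3] >= 3L) {
      planes <- list(nuclei = a[, , 3], ev = a[, , 1], merge = a[, , 2])
    }
  } else {
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
  if (is.null(planes)) {
    stop(sprintf(
      "'%s' has fewer than 3 planes/channels and no explicit mapping applies",
      path
    ))
  }
  planes <- lapply(planes, function(p) {
    p <- as.matrix(p)
    if (normalize) minmax_norm(p) else p
  })
  multichannel_frame(planes$nuclei, planes$ev, planes$merge, time)
}

#' Write a synthetic dataset to disk
#'
#' One 3-plane 16-bit TIFF per frame, one 16-bit label TIFF per entity
#' class per frame, and a JSON manifest listing files, acquisition times,
#' seed and generator parameters. The write/read round trip reproduces the
#' arrays exactly (intensities live on the 16-bit grid).
#'
#' @param frames list of [multichannel_frame()].
#' @param truths list of `scene_truth` (or lists with `cells`, `nuclei`,
#'   `evs` label images), parallel to `frames`.
#' @param dir output directory (created if needed).
#' @param params optional [scene_params()] recorded in the manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
write_dataset <- function(frames, truths, dir, params = NULL, seed = NULL) {
  if (length(frames) == 0L) stop("empty frame list; nothing to write")
  stopifnot(length(frames) == length(truths))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  entries <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    img <- sprintf("frame_%03d.tif", f)
    labs <- list(
      cells = sprintf("cells_%03d.tif", f),
      nuclei = sprintf("nuclei_%03d.tif", f),
      evs = sprintf("evs_%03d.tif", f)
    )
    write_frame_tiff(frames[[f]], file.path(dir, img))
    write_label_tiff(truths[[f]]$cells, file.path(dir, labs$cells))
    write_label_tiff(truths[[f]]$nuclei, file.path(dir, labs$nuclei))
    write_label_tiff(truths[[f]]$evs, file.path(dir, labs$evs))
    entries[[f]] <- list(image = img, labels = labs,
                         time = frames[[f]]$time)
  }
  manifest <- list(
    n_frames = length(frames),
    times = vapply(frames, function(fr) fr$time, numeric(1)),
    frames = entries,
    image_size = dim(frames[[1]]$nuclei_plane),
    seed = seed,
    params = if (!is.null(params)) unclass(params) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @param normalize min-max normalize intensity planes on read.
#' @return List with `frames`, `truths` (label images only) and `schedule`.
#' @export
read_dataset <- function(dir, normalize = FALSE) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json in '%s'", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  n <- manifest$n_frames
  manifest$times <- unlist(manifest$times)
  frames <- vector("list", n)
  truths <- vector("list", n)
  for (f in seq_len(n)) {
    entry <- manifest$frames[[f]]
    img <- tiff::readTIFF(file.path(dir, entry$image), all = TRUE)
    planes <- lapply(img[1:3], function(p) {
      p <- as.matrix(p)
      if (normalize) minmax_norm(p) else p
    })
    frames[[f]] <- multichannel_frame(planes[[1]], planes[[2]], planes[[3]],
                                      manifest$times[f])
    truths[[f]] <- list(
      cells = read_label_tiff(file.path(dir, entry$labels$cells)),
      nuclei = read_label_tiff(file.path(dir, entry$labels$nuclei)),
      evs = read_label_tiff(file.path(dir, entry$labels$evs))
    )
  }
  list(frames = frames, truths = truths, schedule = manifest$times)
}

# ---------------------------------------------------------------------------
# Pipeline configuration (YAML).

#' Default pipeline configuration
#'
#' @return A nested list of class `pipeline_config` holding the channel
#'   mapping, per-entity seed thresholds, fusion `tau`, border widths,
#'   number of tracked cells, augmentation probabilities, training
#'   hyperparameters and the global seed.
#' @export
pipeline_config <- function() {
  structure(list(
    channel_map = list(nuclei = 1L, ev = 2L, merge = 3L),
    seed_thresholds = list(cells = 0.5, nuclei = 0.5, evs = 0.3),
    fusion_tau = 0.5,
    border_widths = list(cells = 2L, nuclei = 2L, evs = 1L),
    n_tracked_cells = 5L,
    match_radius = 15,
    augmentation = list(p_flip = 0.3, p_contrast = 0.3, p_scale = 0.25,
                        p_blur = 0.25, p_noise = 0.25),
    training = list(depth = 2L, base_features = 16L, epochs = 50L,
                    lr = 1e-3, batch_size = 2L, cls_loss = "dice_ce"),
    seed = 1L
  ), class = "pipeline_config")
}

validate_config <- function(cfg) {
  ref <- unclass(pipeline_config())
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(ref[[k]]))
      if (length(bad) > 0) {
        stop(sprintf("unknown configuration key(s) under '%s': %s", k,
                     paste(bad, collapse = ", ")))
      }
    }
  }
  out <- ref
  for (k in names(cfg)) {
    if (is.list(ref[[k]])) {
      for (k2 in names(cfg[[k]])) out[[k]][[k2]] <- cfg[[k]][[k2]]
    } else {
      out[[k]] <- cfg[[k]]
    }
  }
  stopifnot(out$fusion_tau >= 0, out$fusion_tau <= 1,
            out$n_tracked_cells >= 0)
  class(out) <- "pipeline_config"
  out
}

#' Read / write a pipeline configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults. The
#' write/read round trip is lossless.
#'
#' @param path YAML file.
#' @param cfg a `pipeline_config`.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' not found", path))
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
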