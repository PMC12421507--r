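# Triple-prediction inference and fusion postprocessing. The single trained
# network is applied independently to the nuclei, EV and merge planes; each
# map pair is turned into instances by seeded watershed; the three label
# images are then reconciled by rule-based fusion controlled by one overlap
# hyperparameter.

#' Predict the distance and border maps for one image
#'
#' The image is zero-padded to a size divisible by the network stride and
#' the outputs are cropped back, so output shape always equals input shape.
#'
#' @param model a `unet_model` or `training_run`.
#' @param image numeric matrix normalized to `[0, 1]`.
#' @return List with `dmap` (matrix in `[0, 1]`) and `cmap` (array
#'   `H x W x n_classes` of per-pixel class probabilities).
#' @export
predict_maps <- function(model, image) {
  if (inherits(model, "training_run")) model <- model$model
  stopifnot(inherits(model, "unet_model"), is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  m <- 2^(model$cfg$depth - 1L)
  Hp <- ceiling(H / m) * m
  Wp <- ceiling(W / m) * m
  x <- matrix(0, Hp, Wp)
  x[seq_len(H), seq_len(W)] <- image
  out <- unet_forward(model, x)
  list(
    dmap = clamp(out$reg[seq_len(H), seq_len(W), drop = FALSE], 0, 1),
    cmap = out$cls[seq_len(H), seq_len(W), , drop = FALSE]
  )
}

#' Instances from a distance/border map pair
#'
#' The distance map is first rescaled to its nominal `[0, 1]` range within
#' each connected foreground component (foreground = `argmax` class interior
#' or border): trained regressors systematically shrink the per-instance
#' normalized target toward the mean, and the rescaling restores the peak
#' calibration per object group while being exactly the identity on ideal
#' maps, whose components already peak at 1. Seeds are the 8-connected
#' components of `{dmap >= seed_threshold}` united with the
#' interior-class regions: both lie strictly inside an instance on ideal
#' maps (and overlap at its core, so exact recovery is preserved), while on
#' predicted maps the interior class still separates clustered puncta when
#' the regression surface is flat. Labels grow from the seeds by watershed
#' flooding on the negated distance map (pixels claimed in order of
#' decreasing `dmap`), restricted to the foreground. Border pixels go to
#' whichever seed front reaches them first, so a border-class ridge between
#' two seeds splits touching instances.
#'
#' @param dmap numeric matrix in `[0, 1]`.
#' @param cmap class-probability array `H x W x 3`
#'   (background/interior/border), e.g. a one-hot encoding of a
#'   [border_target()].
#' @param seed_threshold seed level in `(0, 1)`.
#' @return Integer instance label matrix (0 = background).
#' @export
instances_from_maps <- function(dmap, cmap, seed_threshold = 0.5) {
  stopifnot(is.matrix(dmap), length(dim(cmap)) == 3L,
            identical(dim(cmap)[1:2], dim(dmap)),
            seed_threshold > 0, seed_threshold < 1)
  cls <- apply(cmap, c(1, 2), which.max)
  fg <- cls > 1L
  comp <- label_components(fg, 8L)
  for (k in seq_len(max(comp))) {
    sel <- comp == k
    mx <- max(dmap[sel])
    if (mx > 0) dmap[sel] <- pmin(dmap[sel] / mx, 1)
  }
  seeds <- label_components(
    (dmap >= seed_threshold & fg) | (cls == 2L & dmap > 0), 8L
  )
  if (max(seeds) == 0L) return(matrix(0L, nrow(dmap), ncol(dmap)))
  lab <- cpp_priority_flood(dmap, fg, seeds)
  relabel_dense(lab)
}

# One-hot encode an integer class matrix into H x W x n array.
one_hot_cmap <- function(cmap, n_classes = 3L) {
  out <- array(0, dim = c(nrow(cmap), ncol(cmap), n_classes))
  for (c in seq_len(n_classes)) out[, , c] <- (cmap == c - 1L) + 0
  out
}

#' Triple prediction over the three channels
#'
#' Applies the same trained network independently to the min-max-normalized
#' nuclei, EV and merge planes, converting each map pair into instances with
#' an entity-specific seed threshold (smaller objects have flatter
#' normalized distance peaks, so EVs use a lower threshold).
#'
#' @param model a `unet_model` or `training_run`.
#' @param frame a [multichannel_frame()].
#' @param seed_thresholds named numeric `(cells, nuclei, evs)`.
#' @return List of integer label matrices `cells`, `nuclei`, `evs`.
#' @export
triple_predict <- function(model, frame,
                           seed_thresholds = c(cells = 0.5, nuclei = 0.5,
                                               evs = 0.3)) {
  stopifnot(inherits(frame, "multichannel_frame"))
  seg_one <- function(plane, thr) {
    mp <- predict_maps(model, minmax_norm(plane))
    instances_from_maps(mp$dmap, mp$cmap, thr)
  }
  list(
    cells = seg_one(frame$merge_plane, seed_thresholds[["cells"]]),
    nuclei = seg_one(frame$nuclei_plane, seed_thresholds[["nuclei"]]),
    evs = seg_one(frame$ev_plane, seed_thresholds[["evs"]])
  )
}

#' Fusion postprocessing of the three channel segmentations
#'
#' Three repair rules, controlled by the single overlap hyperparameter
#' `tau`:
#' \enumerate{
#'   \item an EV instance whose pixel overlap with the nucleus foreground
#'     exceeds `tau` times its own area is deleted (nuclear bleed-through
#'     suppression);
#'   \item a nucleus with zero cell overlap is deleted;
#'   \item cell instances are repaired against sparse borders: first, a
#'     cell fragment containing no nucleus centroid is merged into the
#'     8-adjacent cell with which it shares the longest boundary (iterated
#'     to stability) -- the network splits cell bodies around the bright
#'     nuclei/EV puncta it was trained to treat as separate instances, and
#'     an anucleate fragment of contiguous cell matter is not a cell; then
#'     each cell mask is closed with a 3-px-radius disc and its enclosed
#'     holes are filled; where repaired cells collide, the larger cell
#'     wins.
#' }
#' Labels are re-issued densely (1..K).
#'
#' @param cells,nuclei,evs integer instance label matrices of one shape.
#' @param tau overlap fraction in `[0, 1]` (default 0.5).
#' @return An object of class `segmentation_result`: label images `cells`,
#'   `nuclei`, `evs`, the `fusion_tau` used, and a `report` list counting
#'   deletions per rule.
#' @export
fuse <- function(cells, nuclei, evs, tau = 0.5) {
  stopifnot(identical(dim(cells), dim(nuclei)),
            identical(dim(cells), dim(evs)))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    stop("tau must be a single value in [0, 1]")
  }
  nuc_fg <- nuclei > 0
  # rule (i): EV vs nucleus overlap
  ev_ids <- sort(unique(evs[evs > 0]))
  dropped_ev <- integer(0)
  for (k in ev_ids) {
    m <- evs == k
    if (sum(m & nuc_fg) > tau * sum(m)) dropped_ev <- c(dropped_ev, k)
  }
  evs2 <- evs
  evs2[evs2 %in% dropped_ev] <- 0L
  # rule (ii): nuclei must overlap some cell
  nuc_ids <- sort(unique(nuclei[nuclei > 0]))
  cell_fg <- cells > 0
  dropped_nuc <- integer(0)
  for (k in nuc_ids) {
    if (!any(nuclei == k & cell_fg)) dropped_nuc <- c(dropped_nuc, k)
  }
  nuclei2 <- nuclei
  nuclei2[nuclei2 %in% dropped_nuc] <- 0L
  # rule (iii): merge anucleate fragments, then close + fill each cell
  cells <- merge_anucleate_fragments(cells, nuclei2)
  cell_ids <- sort(unique(cells[cells > 0]))
  areas <- vapply(cell_ids, function(k) sum(cells == k), integer(1))
  ord <- cell_ids[order(-areas, cell_ids)]
  cells2 <- matrix(0L, nrow(cells), ncol(cells))
  brush <- disc_brush(3L)
  for (k in ord) {
    m <- cells == k
    m <- EBImage::closing(m + 0, brush) > 0
    m <- EBImage::fillHull(m + 0) > 0
    m <- m & (cells2 == 0L)
    cells2[m] <- k
  }
  structure(
    list(
      cells = relabel_dense(cells2),
      nuclei = relabel_dense(nuclei2),
      evs = relabel_dense(evs2),
      fusion_tau = tau,
      report = list(evs_deleted_overlap = length(dropped_ev),
                    nuclei_deleted_no_cell = length(dropped_nuc))
    ),
    class = "segmentation_result"
  )
}

# Merge cell labels that contain no nucleus centroid into the 8-adjacent
# cell sharing the longest boundary, iterating until stable. Fragments with
# no adjacent cell are left alone.
merge_anucleate_fragments <- function(cells, nuclei) {
  cents <- label_centroids(nuclei)
  repeat {
    ids <- sort(unique(cells[cells > 0]))
    if (length(ids) < 2L) return(cells)
    has_nuc <- rep(FALSE, length(ids))
    if (nrow(cents) > 0) {
      ri <- round(cents[, "row"]); ci <- round(cents[, "col"])
      for (q in seq_len(nrow(cents))) {
        lab <- cells[ri[q], ci[q]]
        if (lab > 0) has_nuc[match(lab, ids)] <- TRUE
      }
    }
    if (all(has_nuc)) return(cells)
    # shared 8-adjacency boundary lengths between label pairs
    contact <- matrix(0L, length(ids), length(ids))
    H <- nrow(cells); W <- ncol(cells)
    shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    for (s in shifts) {
      di <- s[1]; dj <- s[2]
      src_i <- max(1, 1 + di):min(H, H + di)
      src_j <- max(1, 1 + dj):min(W, W + dj)
      a <- cells[src_i - di, src_j - dj, drop = FALSE]
      b <- cells[src_i, src_j, drop = FALSE]
      sel <- a > 0 & b > 0 & a != b
      if (any(sel)) {
        pairs <- table(paste(a[sel], b[sel]))
        for (nm in names(pairs)) {
          kk <- as.integer(strsplit(nm, " ")[[1]])
          i1 <- match(kk[1], ids); i2 <- match(kk[2], ids)
          contact[i1, i2] <- contact[i1, i2] + as.integer(pairs[[nm]])
        }
      }
    }
    merged <- FALSE
    for (q in seq_along(ids)) {
      if (has_nuc[q]) next
      if (all(contact[q, ] == 0L)) next
      tgt <- which.max(contact[q, ])
      cells[cells == ids[q]] <- ids[tgt]
      merged <- TRUE
      break  # recompute adjacency after each merge
    }
    if (!merged) return(cells)
  }
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result %dx%d: %d cells, %d nuclei, %d EVs (tau = %g)>\n",
    nrow(x$cells), ncol(x$cells), max(x$cells), max(x$nuclei), max(x$evs),
    x$fusion_tau
  ))
  invisible(x)
}

#' Segment one frame end to end
#'
#' Convenience wrapper: [triple_predict()] then [fuse()].
#'
#' @inheritParams triple_predict
#' @inheritParams fuse
#' @return A `segmentation_result`.
#' @export
segment_frame <- function(model, frame,
                          seed_thresholds = c(cells = 0.5, nuclei = 0.5,
                                              evs = 0.3),
                          tau = 0.5) {
  raw <- triple_predict(model, frame, seed_thresholds)
  fuse(raw$cells, raw$nuclei, raw$evs, tau)
}
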