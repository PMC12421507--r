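# Training targets for the dual-branch network, built from an instance label
# image: a per-instance max-normalized Euclidean distance map (regression
# branch) and a 3-class background/interior/border map (classification
# branch).

#' Per-instance normalized Euclidean distance target
#'
#' For every instance independently, the Euclidean distance of each of its
#' pixels to the instance's complement is computed and divided by the
#' instance's maximum distance, so each instance peaks at exactly 1
#' regardless of its size. This keeps cell bodies (tens of pixels across)
#' and EV puncta (a few pixels) on a common target scale, which is what lets
#' one network segment both. Pixels outside the image grid count as
#' complement, so instances touching the border are inset like any others.
#' Background is exactly 0.
#'
#' @param labels integer instance label matrix (0 = background).
#' @return Numeric matrix in `[0, 1]` of the same shape.
#' @export
distance_target <- function(labels) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  out <- matrix(0, nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0]))
  for (k in ids) {
    mask <- labels == k
    bb <- mask_bbox(mask, pad = 0L)
    sub <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    d <- edt_ring(sub)
    mx <- max(d)
    if (mx > 0) {
      tmp <- out[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
      tmp[sub] <- d[sub] / mx
      out[bb[1]:bb[2], bb[3]:bb[4]] <- tmp
    }
  }
  out
}

# Euclidean distance of mask pixels to the mask's complement, with
# out-of-grid treated as complement (the mask is embedded in a 1-px
# background ring before the transform).
edt_ring <- function(sub) {
  h <- nrow(sub); w <- ncol(sub)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- sub
  d <- as.matrix(EBImage::distmap(pad + 0, metric = "euclidean"))
  d[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}

#' Categorical border/interior/background target
#'
#' Class 2 (border) marks instance pixels within `border_width` of the
#' instance boundary (a pixel adjacent to the complement is at boundary
#' distance 0) or 8-adjacent to a *different* instance; class 1 marks the
#' remaining instance pixels (interior); class 0 is background. Border and
#' interior together reconstruct the binary foreground exactly.
#'
#' @param labels integer instance label matrix (0 = background).
#' @param border_width border thickness in pixels (>= 1).
#' @return Integer matrix over `{0, 1, 2}` of the same shape.
#' @export
border_target <- function(labels, border_width = 2L) {
  stopifnot(is.matrix(labels), all(labels >= 0), border_width >= 1)
  H <- nrow(labels); W <- ncol(labels)
  out <- matrix(0L, H, W)
  out[labels > 0] <- 1L
  ids <- sort(unique(labels[labels > 0]))
  for (k in ids) {
    mask <- labels == k
    bb <- mask_bbox(mask, pad = 0L)
    sub <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    d <- edt_ring(sub)
    border <- sub & (d <= border_width)
    tmp <- out[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    tmp[border] <- 2L
    out[bb[1]:bb[2], bb[3]:bb[4]] <- tmp
  }
  # pixels 8-adjacent to a different instance are border regardless of width
  adj <- adjacent_to_other_instance(labels)
  out[adj] <- 2L
  out
}

# Logical matrix: instance pixels having an 8-neighbour belonging to a
# different (positive) instance.
adjacent_to_other_instance <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  adj <- matrix(FALSE, H, W)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (s in shifts) {
    di <- s[1]; dj <- s[2]
    src_i <- max(1, 1 + di):min(H, H + di)
    src_j <- max(1, 1 + dj):min(W, W + dj)
    dst_i <- src_i - di
    dst_j <- src_j - dj
    a <- labels[dst_i, dst_j, drop = FALSE]
    b <- labels[src_i, src_j, drop = FALSE]
    hit <- a > 0 & b > 0 & a != b
    cur <- adj[dst_i, dst_j, drop = FALSE]
    adj[dst_i, dst_j] <- cur | hit
  }
  adj
}

# Build the aggregated-channel training target pair from a scene truth:
# entity label images are overlaid with the smaller structures on top
# (EVs > nuclei > cells) to produce one instance labelling, then the
# distance target is computed per overlaid instance and the border target
# uses an entity-specific width (EV puncta are near the resolution limit).
build_training_targets <- function(truth, border_width_cells = 2L,
                                   border_width_nuclei = 2L,
                                   border_width_evs = 1L) {
  cells <- truth$cells; nuclei <- truth$nuclei; evs <- truth$evs
  n_c <- max(cells); n_n <- max(nuclei)
  lab <- cells
  lab[nuclei > 0] <- nuclei[nuclei > 0] + n_c
  lab[evs > 0] <- evs[evs > 0] + n_c + n_n
  dmap <- distance_target(lab)
  cmap_cells <- border_target(ifelse(lab >= 1 & lab <= n_c, lab, 0L),
                              border_width_cells)
  cmap_nuc <- border_target(ifelse(lab > n_c & lab <= n_c + n_n, lab, 0L),
                            border_width_nuclei)
  cmap_ev <- border_target(ifelse(lab > n_c + n_n, lab, 0L), border_width_evs)
  cmap <- pmax(cmap_cells, cmap_nuc, cmap_ev)
  # overlay may place an EV interior over a cell border pixel; the overlaid
  # entity owns the pixel
  owner_ev <- lab > n_c + n_n
  owner_nuc <- lab > n_c & lab <= n_c + n_n
  cmap[owner_ev] <- cmap_ev[owner_ev]
  cmap[owner_nuc] <- cmap_nuc[owner_nuc]
  cmap[adjacent_to_other_instance(lab)] <- 2L
  storage.mode(cmap) <- "integer"
  list(dmap = dmap, cmap = cmap, labels = lab)
}
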