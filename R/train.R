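# Training loop: one network, trained on the aggregated channel whose
# targets merge all entity instances (EVs drawn over nuclei over cells, so
# every particle contributes its own instance).

# Loss and output-gradients for one sample.
sample_loss <- function(model, out, dmap, cmap) {
  cfg <- model$cfg
  w <- cfg$loss_weights
  dice <- dice_loss(out$cls, cmap, cfg$eps)
  sl1 <- smooth_l1(out$reg, dmap, cfg$beta)
  g_cls <- dice_loss_grad(out$cls, cmap, cfg$eps)
  cls_extra <- 0
  if (cfg$cls_loss == "dice_ce") {
    cls_extra <- weighted_ce(out$cls, cmap)
    g_cls <- g_cls + weighted_ce_grad(out$cls, cmap)
  }
  list(
    total = unname(w["cls"] * (dice + cls_extra) + w["reg"] * sl1),
    dice = dice, sl1 = sl1,
    g_cls = w["cls"] * g_cls,
    g_reg = w["reg"] * smooth_l1_grad(out$reg, dmap, cfg$beta)
  )
}

#' Train the dual U-Net on synthetic (or annotated) frames
#'
#' Each sample is the aggregated channel of a frame paired with targets
#' built from the union of all entity instance labels. The total loss is
#' `w_cls * Dice (+ weighted CE if configured) + w_reg * smooth L1`,
#' minimized with Adam.
#'
#' @param dataset list of samples, each a list with elements `frame` (a
#'   [multichannel_frame()]) and `truth` (a `scene_truth` with `cells`,
#'   `nuclei`, `evs` label images).
#' @param model_cfg a [model_config()].
#' @param aug_cfg an [augment_config()], or `NULL` to disable augmentation.
#' @param epochs training epochs; `0` returns the initialized model with an
#'   empty history.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation.
#' @param lr Adam learning rate.
#' @param batch_size gradient-accumulation batch size.
#' @param border_widths named integer vector `(cells, nuclei, evs)` of
#'   border-target widths in pixels.
#' @param verbose print per-epoch losses.
#' @return An object of class `training_run`: `model`, per-epoch `history`
#'   (columns `epoch`, `total`, `dice`, `smooth_l1`), `seed`.
#' @export
train_model <- function(dataset, model_cfg = model_config(),
                        aug_cfg = augment_config(), epochs = 50L,
                        seed = 1L, lr = 1e-3, batch_size = 2L,
                        border_widths = c(cells = 2L, nuclei = 2L, evs = 1L),
                        verbose = FALSE) {
  stopifnot(length(dataset) >= 1L, epochs >= 0L, batch_size >= 1L)
  xs <- lapply(dataset, function(s) aggregate_channel(s$frame))
  tg <- lapply(dataset, function(s) {
    build_training_targets(
      s$truth,
      border_width_cells = border_widths[["cells"]],
      border_width_nuclei = border_widths[["nuclei"]],
      border_width_evs = border_widths[["evs"]]
    )
  })
  model <- init_model(model_cfg, seed = seed)
  history <- data.frame(epoch = integer(0), total = numeric(0),
                        dice = numeric(0), smooth_l1 = numeric(0))
  if (epochs == 0L) {
    return(structure(list(model = model, history = history,
                          seed = as.integer(seed)), class = "training_run"))
  }
  n <- length(dataset)
  opt <- adam_init(model$params)
  with_local_seed(seed + 1L, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- dice <- sl1 <- 0
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          x <- xs[[i]]; dmap <- tg[[i]]$dmap; cmap <- tg[[i]]$cmap
          if (!is.null(aug_cfg)) {
            au <- augment(x, dmap, cmap, aug_cfg)
            x <- au$image; dmap <- au$dmap; cmap <- au$cmap
          }
          out <- unet_forward(model, x, keep_cache = TRUE)
          ls <- sample_loss(model, out, dmap, cmap)
          if (!is.finite(ls$total)) {
            stop(sprintf("non-finite training loss at epoch %d", e))
          }
          tot <- tot + ls$total; dice <- dice + ls$dice; sl1 <- sl1 + ls$sl1
          gr <- unet_backward(model, out$cache, ls$g_reg, ls$g_cls)
          acc <- if (is.null(acc)) gr else param_add(acc, gr)
        }
        acc <- param_scale(acc, 1 / length(idx))
        st <- adam_step(model$params, acc, opt, lr = lr)
        model$params <- st$params
        opt <- st$state
      }
      history <- rbind(history, data.frame(
        epoch = e, total = tot / n, dice = dice / n, smooth_l1 = sl1 / n
      ))
      if (verbose) {
        message(sprintf("epoch %3d  total %.4f  dice %.4f  smoothL1 %.4f",
                        e, tot / n, dice / n, sl1 / n))
      }
    }
  })
  structure(list(model = model, history = history, seed = as.integer(seed)),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("<training_run: %d epochs, seed %d>\n",
              nrow(x$history), x$seed))
  if (nrow(x$history) > 0) {
    cat(sprintf("  final total loss %.4f (dice %.4f, smooth L1 %.4f)\n",
                x$history$total[nrow(x$history)],
                x$history$dice[nrow(x$history)],
                x$history$smooth_l1[nrow(x$history)]))
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The parameters go to a single binary file; a JSON sidecar
#' (`<path>.json`) records the configuration, seed and loss history.
#'
#' @param run a `training_run` (or a bare `unet_model`).
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `training_run`.
#' @export
save_checkpoint <- function(run, path) {
  if (inherits(run, "unet_model")) {
    run <- structure(list(model = run,
                          history = data.frame(), seed = run$seed),
                     class = "training_run")
  }
  stopifnot(inherits(run, "training_run"))
  saveRDS(run$model$params, path)
  sidecar <- list(
    config = unclass(run$model$cfg), seed = run$seed,
    history = run$history
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path))
  params <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$loss_weights <- unlist(cfg$loss_weights)
  names(cfg$loss_weights) <- c("reg", "cls")
  class(cfg) <- "model_config"
  model <- structure(list(cfg = cfg, params = params,
                          seed = as.integer(side$seed)),
                     class = "unet_model")
  structure(list(model = model,
                 history = as.data.frame(side$history),
                 seed = as.integer(side$seed)),
            class = "training_run")
}
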