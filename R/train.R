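# Model fitting surface: octdetect() trains the detector and returns a
# classed fit with the usual print/summary/coef/predict/plot methods.

#' Training control parameters
#'
#' @param learning_rate Adam step size (default 5e-4).
#' @param epochs training epochs (default 200).
#' @param batch_size images per optimizer step (default 4).
#' @param optimizer `"adam"` or `"adamw"` (decoupled weight decay).
#' @param weight_decay decay rate for `"adamw"` (ignored by `"adam"`).
#' @param seed one integer seeding every source of randomness:
#'   initialization, shuffling, augmentation draws and dropout.
#' @param augment an [augment_params] object, or `NULL` to train on the raw
#'   records.
#' @param augmentations_per_image augmented draws per record per epoch when
#'   `augment` is given (default 2; the draws replace the original).
#' @param loss_grid `c(height, width)` rasterization grid of the structural
#'   loss term (default 64 x 64).
#' @param checkpoint_dir optional directory; when set, the best-validation
#'   state is checkpointed there as `best.rds`.
#' @param verbose print a one-line summary every `verbose` epochs (0 = quiet).
#' @return an object of class `train_control`.
#' @export
train_control <- function(learning_rate = 5e-4, epochs = 200L, batch_size = 4L,
                          optimizer = c("adam", "adamw"), weight_decay = 1e-2,
                          seed = 1L, augment = NULL,
                          augmentations_per_image = 2L,
                          loss_grid = c(64L, 64L), checkpoint_dir = NULL,
                          verbose = 0L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 0L) stop("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment = augment,
                 augmentations_per_image = as.integer(augmentations_per_image),
                 loss_grid = as.integer(loss_grid),
                 checkpoint_dir = checkpoint_dir,
                 verbose = as.integer(verbose)),
            class = "train_control")
}

# ---- flat parameter traversal (shared by the optimizer and gradient checks)

flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nms <- names(x) %||% as.character(seq_along(x))
    if (is.null(names(x))) nms <- paste0("[", nms, "]")
    for (i in seq_along(x))
      out <- c(out, flatten_params(x[[i]], paste0(prefix, "/", nms[i])))
    out
  } else if (is.numeric(x)) {
    stats::setNames(list(x), prefix)
  } else list()
}

# Apply f(param, same-shaped companion values...) to every numeric leaf.
# Companion structures are matched by name where names exist (gradient lists
# may order their elements differently from the state), positionally
# otherwise.
map_params <- function(x, ..., f) {
  others <- list(...)
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      x[[i]] <- do.call(map_params,
                        c(list(x[[i]]), lapply(others, `[[`, key),
                          list(f = f)))
    }
    x
  } else if (is.numeric(x)) {
    do.call(f, c(list(x), others))
  } else x
}

zeros_like <- function(x) map_params(x, f = function(p) p * 0)

make_optimizer <- function(control) {
  t <- 0L
  m <- NULL; v <- NULL
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  wd <- if (control$optimizer == "adamw") control$weight_decay else 0
  lr <- control$learning_rate
  function(state, grads) {
    if (is.null(m)) { m <<- zeros_like(state); v <<- zeros_like(state) }
    t <<- t + 1L
    bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
    m <<- map_params(m, grads, f = function(mm, gg) b1 * mm + (1 - b1) * gg)
    v <<- map_params(v, grads, f = function(vv, gg) b2 * vv + (1 - b2) * gg^2)
    map_params(state, m, v, f = function(p, mm, vv) {
      step <- lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
      if (wd > 0 && length(dim(p)) == 2L) step <- step + lr * wd * p
      p - step
    })
  }
}

# mean loss (and optional gradient accumulation) of one record
sample_loss <- function(record, state, cfg, control, with_grad = TRUE) {
  fw <- detector_forward(record$image, state, cfg, train = with_grad)
  actual <- unclass(record$boxes)
  if (nrow(actual) != cfg$max_boxes)
    stop("record box array capacity does not match max_boxes")
  lb <- lloss(fw$boxes, actual, control$loss_grid)
  g <- NULL
  if (with_grad) {
    dbox <- lloss_grad(fw$boxes, actual, control$loss_grid)
    g <- detector_backward(state, cfg, fw, dbox)
  }
  list(loss = lb, grad = g)
}

split_loss_means <- function(records, state, cfg, control) {
  ls <- lapply(records, function(r)
    sample_loss(r, state, cfg, control, with_grad = FALSE)$loss)
  c(total = mean(vapply(ls, `[[`, 0, "l_total")),
    mse = mean(vapply(ls, `[[`, 0, "l_mse")),
    difference = mean(vapply(ls, `[[`, 0, "l_difference")),
    iou = mean(vapply(ls, `[[`, 0, "l_iou")))
}

#' Fit the transformer lesion detector
#'
#' Trains the attention-gated patch encoder + transformer trunk on a list of
#' annotated records by minimizing the composite loss (coordinate MSE,
#' structural mask difference, IOU) with Adam or AdamW. One seed controls
#' initialization, shuffling, augmentation and dropout, so identical calls
#' produce identical fits.
#'
#' @param records list of [annotated_record]s (the training split); every box
#'   array must have capacity `model$max_boxes`.
#' @param model a [model_config].
#' @param control a [train_control].
#' @param validation optional list of annotated records; when given, the
#'   state with the best validation loss is retained alongside the final one
#'   and used for prediction.
#' @return an object of class `octdetect` with components `state` (final
#'   parameters), `best_state`/`best_epoch` (when validated), `model`,
#'   `control` and `history` (per-epoch data frame of the loss components).
#' @examples
#' \donttest{
#' p <- synthetic_params(128, 128, lesion_count_range = c(1, 1), seed = 1)
#' recs <- generate_dataset(p, 8)
#' cfg <- model_config(n_blocks = 1, image_height = 128, image_width = 128)
#' fit <- octdetect(recs, cfg, train_control(epochs = 2, seed = 1))
#' predict(fit, recs[1:2])
#' }
#' @export
octdetect <- function(records, model = model_config(),
                      control = train_control(), validation = NULL) {
  stopifnot(inherits(model, "model_config"), inherits(control, "train_control"))
  if (!length(records)) stop("empty training split")
  set.seed(control$seed)
  state <- init_model_state(model, seed = control$seed)
  opt <- make_optimizer(control)
  hist <- list()
  best <- list(loss = Inf, state = NULL, epoch = NA_integer_)

  n_aug <- if (is.null(control$augment)) 0L else
    max(1L, control$augmentations_per_image)
  for (ep in seq_len(control$epochs)) {
    epoch_set <- if (n_aug == 0L) records else
      unlist(lapply(records, function(r)
        lapply(seq_len(n_aug), function(i) augment(r, control$augment))),
        recursive = FALSE)
    ord <- sample.int(length(epoch_set))
    comp <- c(total = 0, mse = 0, difference = 0, iou = 0)
    nb <- 0L
    for (start in seq(1L, length(ord), by = control$batch_size)) {
      bidx <- ord[start:min(start + control$batch_size - 1L, length(ord))]
      acc <- NULL
      bl <- c(total = 0, mse = 0, difference = 0, iou = 0)
      for (ri in bidx) {
        sl <- sample_loss(epoch_set[[ri]], state, model, control)
        if (!is.finite(sl$loss$l_total))
          stop(sprintf("non-finite loss at epoch %d (mse %g, diff %g, iou %g)",
                       ep, sl$loss$l_mse, sl$loss$l_difference, sl$loss$l_iou))
        bl <- bl + c(sl$loss$l_total, sl$loss$l_mse, sl$loss$l_difference,
                     sl$loss$l_iou)
        acc <- if (is.null(acc)) sl$grad else
          map_params(acc, sl$grad, f = `+`)
      }
      acc <- map_params(acc, f = function(g) g / length(bidx))
      state <- opt(state, acc)
      comp <- comp + bl / length(bidx)
      nb <- nb + 1L
    }
    row <- as.list(comp / nb)
    names(row) <- c("train_total", "train_mse", "train_difference", "train_iou")
    if (!is.null(validation) && length(validation)) {
      vl <- split_loss_means(validation, state, model, control)
      row$val_total <- vl[["total"]]
      row$val_mse <- vl[["mse"]]
      row$val_difference <- vl[["difference"]]
      row$val_iou <- vl[["iou"]]
      if (vl[["total"]] < best$loss)
        best <- list(loss = vl[["total"]], state = state, epoch = ep)
    }
    hist[[ep]] <- as.data.frame(c(list(epoch = ep), row))
    if (control$verbose > 0L && ep %% control$verbose == 0L)
      message(sprintf("epoch %3d  train %.5f%s", ep, row$train_total,
                      if (!is.null(row$val_total))
                        sprintf("  val %.5f", row$val_total) else ""))
  }
  fit <- structure(list(state = state, best_state = best$state,
                        best_epoch = best$epoch, model = model,
                        control = control,
                        history = if (length(hist)) do.call(rbind, hist) else
                          data.frame(),
                        n_train = length(records)),
                   class = "octdetect")
  if (!is.null(control$checkpoint_dir) && !is.null(best$state)) {
    dir.create(control$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(best$state, model,
                    file.path(control$checkpoint_dir, "best.rds"))
  }
  fit
}

# the state predictions use: best-validation when available, else final
inference_state <- function(fit) fit$best_state %||% fit$state

#' Predict bounding boxes for new scans
#'
#' Deterministic inference (dropout off). Predicted boxes with an area below
#' `min_area` of the unit square are reported as sentinels.
#'
#' @param object an `octdetect` fit.
#' @param newdata a list of [scan_image]s or [annotated_record]s (a single
#'   one, or a plain matrix, is also accepted).
#' @param min_area sentinel cutoff on normalized box area (default 1e-4).
#' @param ... unused.
#' @return list of `box_array` matrices, one per image.
#' @export
predict.octdetect <- function(object, newdata, min_area = 1e-4, ...) {
  if (inherits(newdata, c("scan_image", "annotated_record")) ||
      is.matrix(newdata)) newdata <- list(newdata)
  state <- inference_state(object)
  lapply(newdata, function(x) {
    img <- if (inherits(x, "annotated_record")) x$image else x
    fw <- detector_forward(img, state, object$model, train = FALSE)
    b <- fw$boxes
    b[box_area(b) < min_area, ] <- 0
    box_array(b, k = object$model$max_boxes)
  })
}

#' Evaluate a fit (or explicit state) on an annotated split
#'
#' Runs prediction, greedy box matching, the IOU-thresholded confusion
#' counts, and the single-class summary metrics.
#'
#' @param fit an `octdetect` fit (or a model state list, with `cfg` given;
#'   ignored when `predictions` is supplied).
#' @param records annotated evaluation split.
#' @param threshold IOU threshold for the TP rule (default 0.5).
#' @param cfg [model_config] when `fit` is a raw state.
#' @param predictions optional list of predicted box arrays (one per record)
#'   to score instead of running the model.
#' @return a `detection_report` (with per-image matched IOUs attached).
#' @export
evaluate_detections <- function(fit, records, threshold = 0.5, cfg = NULL,
                                predictions = NULL) {
  if (!length(records)) stop("empty evaluation split")
  preds <- if (!is.null(predictions)) predictions
  else if (inherits(fit, "octdetect")) predict(fit, records) else {
    stopifnot(!is.null(cfg))
    lapply(records, function(r) {
      fw <- detector_forward(r$image, fit, cfg, train = FALSE)
      b <- fw$boxes
      b[box_area(b) < 1e-4, ] <- 0
      box_array(b, k = cfg$max_boxes)
    })
  }
  per_image <- lapply(seq_along(records), function(i)
    match_boxes(preds[[i]], records[[i]]$boxes)$iou)
  ious <- unlist(per_image)
  cc <- confusion_counts(ious, threshold)
  summarize_detections(cc$tp, cc$fp, ious, per_image = per_image)
}

#' @export
print.octdetect <- function(x, ...) {
  m <- x$model
  np <- sum(vapply(flatten_params(x$state), length, 0L))
  cat("Transformer lesion detector (attention-gated patch encoder + ViT trunk)\n")
  cat(sprintf("  input %dx%d px, patch %d -> %d tokens, latent dim %d\n",
              m$image_height, m$image_width, m$patch_size, m$n_tokens,
              m$latent_dim))
  cat(sprintf("  %d transformer blocks, %d heads, box slots K = %d, %s parameters\n",
              m$n_blocks, m$n_heads, m$max_boxes, format(np, big.mark = ",")))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs on %d records; final train loss %.5f\n",
                nrow(x$history), x$n_train, last$train_total))
    if (!is.null(x$best_state))
      cat(sprintf("  best validation loss %.5f at epoch %d\n",
                  min(x$history$val_total), x$best_epoch))
  } else cat("  untrained (initialized parameters)\n")
  invisible(x)
}

#' @export
summary.octdetect <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nLoss components, last 5 epochs:\n")
    print(utils::tail(object$history, 5), row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
coef.octdetect <- function(object, ...) inference_state(object)

#' Plot training history
#'
#' Total (and validation, when present) loss per epoch plus the three
#' components.
#'
#' @param x an `octdetect` fit.
#' @param ... passed to [graphics::matplot].
#' @export
plot.octdetect <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  cols <- intersect(c("train_total", "val_total", "train_mse",
                      "train_difference", "train_iou"), names(h))
  graphics::matplot(h$epoch, as.matrix(h[cols]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
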