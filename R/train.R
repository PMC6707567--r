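# Training / evaluation / prediction orchestration: soft-Dice objective,
# Adam optimiser, per-epoch metric curves, best-validation-Dice checkpoint.

#' Run configuration for training
#'
#' @param model a [model_config()].
#' @param batch_size mini-batch size; defaults to 32 for input sides up to
#'   128 and 16 for 256 (the canonical protocol).
#' @param epochs training epochs, default 300 (desk-scale runs use far
#'   fewer).
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size, default 1e-4.
#' @param augment expand the training set with the four paired affine
#'   transforms before training.
#' @param threshold binarisation threshold for reported metrics.
#' @param seed seed for shuffling/augmentation (model init uses the model
#'   config's own seed).
#' @param out_dir optional directory; when set, the resolved config, the
#'   training history and the final report are written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(model = model_config(), batch_size = NULL,
                       epochs = 300L, optimizer = "adam",
                       learning_rate = 1e-4, augment = FALSE,
                       threshold = 0.5, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(model, "model_config"))
  optimizer <- match.arg(optimizer, "adam")
  if (is.null(batch_size))
    batch_size <- if (model$input_side <= 128L) 32L else 16L
  structure(list(model = model, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 learning_rate = learning_rate, augment = augment,
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

samples_to_tensor <- function(samples, side) {
  n <- length(samples)
  x <- array(0, dim = c(side, side, 1L, n))
  g <- array(0, dim = c(side, side, 1L, n))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    msk <- samples[[i]]$mask
    if (nrow(img) != side || ncol(img) != side) {
      img <- resize_bilinear(img, side)
      msk <- resize_nearest(msk, side)
    }
    x[, , 1L, i] <- img
    g[, , 1L, i] <- msk
  }
  list(x = x, gold = g)
}

#' Bilinear resize of a matrix to a square side
#' @param img numeric matrix.
#' @param side target side in pixels.
#' @return `side x side` matrix.
#' @export
resize_bilinear <- function(img, side) {
  sr <- nrow(img) / side
  sc <- ncol(img) / side
  rr <- matrix((seq_len(side) - 0.5) * sr + 0.5, side, side)
  cc <- matrix((seq_len(side) - 0.5) * sc + 0.5, side, side, byrow = TRUE)
  rr <- pmin(pmax(rr, 1), nrow(img))
  cc <- pmin(pmax(cc, 1), ncol(img))
  bilinear_sample(img, rr, cc)
}

#' Nearest-neighbour resize (mask-safe: output stays binary)
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(img, side) {
  ri <- pmin(pmax(round((seq_len(side) - 0.5) * nrow(img) / side + 0.5), 1),
             nrow(img))
  ci <- pmin(pmax(round((seq_len(side) - 0.5) * ncol(img) / side + 0.5), 1),
             ncol(img))
  img[ri, ci, drop = FALSE]
}

new_adam <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- collect_layers(model$net)
  state <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
                m = lapply(layers, function(l) lapply(l$par, function(p) p * 0)),
                v = lapply(layers, function(l) lapply(l$par, function(p) p * 0)))
  state
}

adam_step <- function(model, opt) {
  layers <- collect_layers(model$net)
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$par)) {
      g <- l$grd[[nm]]
      opt$m[[i]][[nm]] <- opt$beta1 * opt$m[[i]][[nm]] + (1 - opt$beta1) * g
      opt$v[[i]][[nm]] <- opt$beta2 * opt$v[[i]][[nm]] + (1 - opt$beta2) * g^2
      l$par[[nm]] <- l$par[[nm]] - opt$lr * (opt$m[[i]][[nm]] / bc1) /
        (sqrt(opt$v[[i]][[nm]] / bc2) + opt$eps)
    }
  }
  opt
}

# Forward a set in evaluation mode, in chunks, returning probability maps.
predict_probs <- function(model, samples, batch_size = 16L) {
  side <- model$config$input_side
  out <- vector("list", length(samples))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batch_size - 1L, length(samples))
    tb <- samples_to_tensor(samples[i:j], side)
    p <- forward(model, tb$x, training = FALSE)
    for (k in i:j) out[[k]] <- p[, , 1L, k - i + 1L]
    i <- j + 1L
  }
  out
}

eval_metrics <- function(model, samples, threshold = 0.5, batch_size = 16L) {
  side <- model$config$input_side
  gold <- lapply(samples, function(s)
    if (nrow(s$mask) == side) s$mask else resize_nearest(s$mask, side))
  prob <- predict_probs(model, samples, batch_size)
  metrics_report(gold, prob, threshold)
}

#' Train a segmentation network
#'
#' Minimises the mean per-image soft Dice loss with Adam. Each epoch logs
#' the training-batch average of the nine-score battery and the same scores
#' on the validation set (evaluation mode); the parameters achieving the
#' best validation Dice are restored into the returned model.
#'
#' @param config a [run_config()].
#' @param train_set,val_set non-empty sample lists (`image` + `mask`).
#' @param verbose print one line per epoch.
#' @return the trained `rdau_model`, with attributes `history` (per-epoch
#'   data.frame) and `best_epoch`.
#' @export
train_model <- function(config, train_set, val_set = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (length(train_set) == 0) stop("empty training set", call. = FALSE)
  if (config$augment)
    train_set <- expand_training_set(train_set, seed = config$seed)
  model <- build_model(config$model)
  opt <- new_adam(model, config$learning_rate)
  side <- config$model$input_side
  n <- length(train_set)
  history <- list()
  best_dice <- -Inf
  best_epoch <- NA_integer_
  best <- NULL
  with_seed(config$seed, function() {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      tr_gold <- list()
      tr_prob <- list()
      nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        tb <- samples_to_tensor(train_set[ord[i:j]], side)
        zero_grads(model$net)
        p <- forward(model, tb$x, training = TRUE)
        loss <- mean(vapply(seq_len(dim(p)[4]), function(k)
          dice_loss(tb$gold[, , , k], p[, , , k]), numeric(1)))
        dy <- dice_loss_grad(tb$gold, p)
        backward(model, p, dy)
        opt <<- adam_step(model, opt)
        tr_loss <- tr_loss + loss
        nb <- nb + 1L
        for (k in seq_len(dim(p)[4])) {
          tr_gold[[length(tr_gold) + 1L]] <- tb$gold[, , 1L, k]
          tr_prob[[length(tr_prob) + 1L]] <- p[, , 1L, k]
        }
        i <- j + 1L
      }
      tr <- metrics_report(tr_gold, tr_prob, config$threshold)
      row <- data.frame(epoch = epoch, train_loss = tr_loss / nb,
                        train_dc = tr$DC, train_acc = tr$Acc,
                        train_sen = tr$Sen, train_sp = tr$Sp, train_f1 = tr$F1,
                        train_pc = tr$Pc, train_miou = tr$`M-IOU`)
      if (!is.null(val_set) && length(val_set)) {
        vm <- eval_metrics(model, val_set, config$threshold)
        row <- cbind(row, data.frame(
          val_loss = vm$Loss, val_dc = vm$DC, val_acc = vm$Acc,
          val_sen = vm$Sen, val_sp = vm$Sp, val_f1 = vm$F1, val_pc = vm$Pc,
          val_miou = vm$`M-IOU`))
        if (vm$DC > best_dice) {
          best_dice <<- vm$DC
          best_epoch <<- epoch
          best <<- list(par = get_params(model), bn = get_bn_state(model))
        }
      }
      history[[epoch]] <<- row
      if (verbose)
        cat(sprintf("epoch %3d  train loss %.4f  dc %.4f%s\n", epoch,
                    row$train_loss, row$train_dc,
                    if (!is.null(row$val_dc)) sprintf("  val dc %.4f", row$val_dc)
                    else ""))
    }
  })
  if (!is.null(best)) {
    set_params(model, best$par)
    set_bn_state(model, best$bn)
  }
  history <- do.call(rbind, history)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(history, file.path(config$out_dir, "history.csv"),
              row.names = FALSE)
    writeLines(yaml::as.yaml(config_to_list(config)),
               file.path(config$out_dir, "run_config.yaml"))
  }
  structure(model, history = history, best_epoch = best_epoch,
            class = class(model))
}

#' Evaluate a trained model on a test set
#'
#' @param model a trained `rdau_model`.
#' @param test_set non-empty sample list.
#' @param threshold binarisation threshold, default 0.5.
#' @param out_dir optional directory for the aggregate CSV, the per-image
#'   CSV and the ROC/PR curve points.
#' @return a [metrics_report()] row.
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5, out_dir = NULL) {
  if (length(test_set) == 0) stop("empty test set", call. = FALSE)
  rep <- eval_metrics(model, test_set, threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(rep, file.path(out_dir, "metrics.csv"))
    write.csv(attr(rep, "per_image"), file.path(out_dir, "per_image.csv"),
              row.names = FALSE)
    curves <- attr(rep, "curves")
    if (!is.null(curves)) {
      write.csv(curves$roc, file.path(out_dir, "roc_curve.csv"),
                row.names = FALSE)
      write.csv(curves$pr, file.path(out_dir, "pr_curve.csv"),
                row.names = FALSE)
    }
  }
  rep
}

#' Predict binary lesion masks
#'
#' @param model a trained `rdau_model`.
#' @param images list of grayscale matrices in `[0, 1]` (resized to the
#'   model's input side if needed), or sample lists.
#' @param threshold probability cut, default 0.5.
#' @return list of binary mask matrices at the model's input resolution;
#'   attribute `"prob"` holds the probability maps.
#' @export
predict_masks <- function(model, images, threshold = 0.5) {
  samples <- lapply(images, function(im)
    if (is.list(im)) im else list(image = im, mask = im * 0))
  prob <- predict_probs(model, samples)
  masks <- lapply(prob, function(p) (p > threshold) * 1)
  attr(masks, "prob") <- prob
  masks
}

#' Train/evaluate one model per input resolution
#'
#' @param base_config a [run_config()]; its model config is rebuilt at each
#'   side (all other settings shared).
#' @param train_set,val_set,test_set sample lists (resized per run).
#' @param sides input resolutions to sweep.
#' @param verbose print per-epoch lines.
#' @return data.frame: one metrics row per resolution plus a wall-time
#'   column (reported, never asserted).
#' @export
resolution_sweep <- function(base_config, train_set, val_set, test_set,
                             sides = c(64L, 96L, 128L, 256L),
                             verbose = FALSE) {
  rows <- lapply(sides, function(side) {
    mc <- base_config$model
    mc$input_side <- as.integer(side)
    cfg <- run_config(model = structure(mc, class = "model_config"),
                      batch_size = NULL, epochs = base_config$epochs,
                      learning_rate = base_config$learning_rate,
                      augment = base_config$augment,
                      threshold = base_config$threshold,
                      seed = base_config$seed)
    t0 <- Sys.time()
    model <- train_model(cfg, train_set, val_set, verbose = verbose)
    rep <- evaluate_model(model, test_set, cfg$threshold)
    cbind(data.frame(input_size = sprintf("%d x %d", side, side)),
          as.data.frame(rep),
          data.frame(train_min = as.numeric(difftime(Sys.time(), t0,
                                                     units = "mins"))))
  })
  do.call(rbind, rows)
}

#' Train/evaluate the four ablation variants
#'
#' Sweeps RAU (no dilated bridge), DAU (no residual shortcuts), RDU (no
#' attention gates) and the full RDAU model under one shared protocol.
#'
#' @inheritParams resolution_sweep
#' @param variants variant names to run.
#' @return data.frame with one metrics row per variant plus parameter
#'   counts.
#' @export
ablation_sweep <- function(base_config, train_set, val_set, test_set,
                           variants = c("rau", "dau", "rdu", "rdau"),
                           verbose = FALSE) {
  rows <- lapply(variants, function(v) {
    mc <- base_config$model
    flags <- switch(v, rdau = c(TRUE, TRUE, TRUE), rau = c(TRUE, FALSE, TRUE),
                    dau = c(FALSE, TRUE, TRUE), rdu = c(TRUE, TRUE, FALSE))
    mc$use_residual <- flags[1]
    mc$use_dilated_bridge <- flags[2]
    mc$use_attention_gates <- flags[3]
    mc$variant <- v
    cfg <- run_config(model = structure(mc, class = "model_config"),
                      batch_size = base_config$batch_size,
                      epochs = base_config$epochs,
                      learning_rate = base_config$learning_rate,
                      augment = base_config$augment,
                      threshold = base_config$threshold,
                      seed = base_config$seed)
    model <- train_model(cfg, train_set, val_set, verbose = verbose)
    rep <- evaluate_model(model, test_set, cfg$threshold)
    cbind(data.frame(model = toupper(paste0(v, "-net")),
                     params = count_params(model)),
          as.data.frame(rep))
  })
  do.call(rbind, rows)
}
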