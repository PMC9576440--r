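#' Training configuration
#'
#' Defaults follow the reference training protocol: RMSprop with initial
#' learning rate 0.001, 10 epochs, combined loss, and a 0.9 image-level
#' train/validation split inside the non-test cases (the test split is
#' case-level, so no slice of a test case is ever seen in training).
#'
#' @param optimizer optimizer name (only `"rmsprop"` is implemented).
#' @param learning_rate initial learning rate (> 0).
#' @param epochs training epochs (>= 1).
#' @param batch_size slices per batch.
#' @param seed integer seed governing weight initialization, shuffling and
#'   dropout.
#' @param split train fraction of the image-level train/val split, in (0,1).
#' @param loss loss name: "dice", "focal" or "combined".
#' @param loss_cfg a [loss_config()].
#' @param model a [model_config()].
#' @param rho RMSprop decay of the squared-gradient average.
#' @param eps RMSprop denominator stabilizer.
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = "rmsprop", learning_rate = 0.001,
                         epochs = 10, batch_size = 8, seed = 1,
                         split = 0.9, loss = "combined",
                         loss_cfg = loss_config(), model = model_config(),
                         rho = 0.9, eps = 1e-8) {
  if (!identical(optimizer, "rmsprop"))
    stop_param("optimizer", "only 'rmsprop' is implemented")
  check_scalar(learning_rate, "learning_rate", lower = 0)
  check_scalar(epochs, "epochs", lower = 1, integer = TRUE)
  check_scalar(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(split, "split", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  if (!loss %in% c("dice", "focal", "combined"))
    stop_param("loss", "must be 'dice', 'focal' or 'combined'")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), split = split, loss = loss,
                 loss_cfg = loss_cfg, model = model, rho = rho, eps = eps),
            class = "train_config")
}

#' Split cases into train/validation images and test cases
#'
#' The test split is case-level: `n_test` whole cases are held out, so no
#' slice of a test case leaks into training. Within the remaining cases the
#' train/validation split is image-level with train fraction `split`.
#'
#' @param cases list of cases (anything with a slice count obtainable from
#'   `dim(case$image)[3]`, e.g. `phantom_case`s).
#' @param n_test number of held-out test cases.
#' @param split train fraction of the image-level split.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with `train` and `val` (data.frames with columns case,
#'   slice) and `test` (integer case indices).
#' @export
split_dataset <- function(cases, n_test = 12, split = 0.9, seed = 1) {
  n <- length(cases)
  if (n < 2) stop("need at least two cases to split", call. = FALSE)
  check_scalar(n_test, "n_test", lower = 1, upper = n - 1, integer = TRUE)
  check_scalar(split, "split", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  withr::with_seed(as.integer(seed), {
    test <- sort(sample.int(n, n_test))
    rest <- setdiff(seq_len(n), test)
    imgs <- do.call(rbind, lapply(rest, function(ci)
      data.frame(case = ci, slice = seq_len(dim(cases[[ci]]$image)[3]))))
    ord <- sample.int(nrow(imgs))
    n_train <- max(1L, round(split * nrow(imgs)))
    list(train = imgs[sort(ord[seq_len(n_train)]), , drop = FALSE],
         val = imgs[sort(ord[-seq_len(n_train)]), , drop = FALSE],
         test = test)
  })
}

#' Build the (image, mask) training tensors from phantom cases
#'
#' Preprocesses every case referenced by the split (Gaussian smoothing, body
#' crop, zoom to `cfg$out_size`), normalizes intensities, and collects the
#' requested slices. Targets are the pristine ground-truth masks.
#'
#' @param cases list of `phantom_case`s (or lists with `image` and `mask`).
#' @param split result of [split_dataset()].
#' @param cfg a [preprocess_config()] (its `out_size` sets the network input
#'   side).
#' @param hu_window HU normalization window.
#' @param crop if `FALSE`, skip body cropping and resize whole slices to
#'   `out_size` (ablation baseline).
#' @return list with `train` and `val`, each a list of `list(x, y)` slice
#'   pairs (matrices in \[0, 1\] / {0, 1}).
#' @export
make_training_set <- function(cases, split, cfg = preprocess_config(),
                              hu_window = c(-1000, 400), crop = TRUE) {
  used <- sort(unique(c(split$train$case, split$val$case)))
  prepped <- list()
  for (ci in used) {
    pc <- preprocess_for_model(cases[[ci]]$image, cases[[ci]]$mask, cfg,
                               crop = crop)
    prepped[[as.character(ci)]] <-
      list(x = normalize_hu(pc$image$voxels, hu_window),
           y = pc$mask$voxels)
  }
  pick <- function(df) lapply(seq_len(nrow(df)), function(i) {
    p <- prepped[[as.character(df$case[i])]]
    list(x = p$x[, , df$slice[i]], y = p$y[, , df$slice[i]])
  })
  list(train = pick(split$train), val = pick(split$val))
}

preprocess_for_model <- function(image, mask, cfg, crop = TRUE) {
  sm <- gaussian_smooth_volume(image, cfg$sigma)
  if (crop) {
    tf <- locate_body(sm, cfg)
    crop_and_zoom(sm, mask, tf)
  } else {
    d <- dim(as_voxels(sm))
    tf <- crop_transform(c(1L, d[1], 1L, d[2]), d[1:2], cfg$out_size)
    crop_and_zoom(sm, mask, tf)
  }
}

stack_batch <- function(slices, idx) {
  d <- dim(slices[[idx[1]]]$x)
  x <- array(0, c(d[1], d[2], 1L, length(idx)))
  y <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    x[, , 1L, j] <- slices[[idx[j]]]$x
    y[, , 1L, j] <- slices[[idx[j]]]$y
  }
  list(x = x, y = y)
}

rmsprop_step <- function(net, G, state, lr, rho, eps) {
  for (nm in ls(G)) {
    g <- G[[nm]]
    v <- state[[nm]]
    if (is.null(v)) v <- g * 0
    v <- rho * v + (1 - rho) * g * g
    state[[nm]] <- v
    net$P[[nm]] <- net$P[[nm]] - lr * g / (sqrt(v) + eps)
  }
}

#' Train the segmentation network
#'
#' RMSprop optimization of the configured loss over shuffled mini-batches of
#' (image, mask) slice pairs, with per-epoch validation loss and hard Dice
#' (predictions thresholded at 0.5). The parameters with the best validation
#' Dice are kept. Divergence (non-finite loss) aborts with a diagnostic
#' naming the epoch and batch.
#'
#' @param cfg a [train_config()].
#' @param data list with `train` and `val` slice lists, as produced by
#'   [make_training_set()].
#' @param verbose print a line per epoch.
#' @return object of class `resunet_fit`: list with `net` (best-validation
#'   weights), `log` (data.frame epoch/train_loss/val_loss/val_dice) and
#'   `cfg`.
#' @export
train_segmentation <- function(cfg, data, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(data$train) == 0) stop("empty training set", call. = FALSE)
  set.seed(cfg$seed)
  net <- build_resunet(cfg$model)
  lossfn <- loss_by_name(cfg$loss, cfg$loss_cfg)
  state <- new.env(parent = emptyenv())
  log <- data.frame()
  best <- list(dice = -Inf, params = NULL, buffers = NULL)
  n <- length(data$train)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tl <- 0; nb <- 0
    for (i0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[i0:min(n, i0 + cfg$batch_size - 1L)]
      b <- stack_batch(data$train, idx)
      fw <- resunet_forward(net, b$x, mode = "train", want_cache = TRUE)
      l <- lossfn$value(b$y, fw$prob)
      if (!is.finite(l))
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                     ep, nb + 1L), call. = FALSE)
      df <- lossfn$grad(b$y, fw$prob)
      dz <- df * fw$prob * (1 - fw$prob)
      G <- new.env(parent = emptyenv())
      resunet_backward(net, dz, fw$cache, G)
      rmsprop_step(net, G, state, cfg$learning_rate, cfg$rho, cfg$eps)
      tl <- tl + l; nb <- nb + 1L
    }
    val <- evaluate_slices(net, data$val, lossfn)
    log <- rbind(log, data.frame(epoch = ep, train_loss = tl / nb,
                                 val_loss = val$loss, val_dice = val$dice))
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  val dice %.4f",
                      ep, tl / nb, val$loss, val$dice))
    if (is.finite(val$dice) && val$dice >= best$dice) {
      best$dice <- val$dice
      best$params <- as.list(net$P)
      best$buffers <- as.list(net$B)
    }
  }
  if (!is.null(best$params)) {
    net$P <- list2env(best$params, parent = emptyenv())
    net$B <- list2env(best$buffers, parent = emptyenv())
  }
  structure(list(net = net, log = log, cfg = cfg), class = "resunet_fit")
}

evaluate_slices <- function(net, slices, lossfn, batch = 8L) {
  if (length(slices) == 0) return(list(loss = NA_real_, dice = NA_real_))
  tot <- 0; inter <- 0; esum <- 0; fsum <- 0
  for (i0 in seq(1L, length(slices), by = batch)) {
    idx <- i0:min(length(slices), i0 + batch - 1L)
    b <- stack_batch(slices, idx)
    pr <- resunet_forward(net, b$x, mode = "eval")$prob
    tot <- tot + lossfn$value(b$y, pr) * length(idx)
    hard <- as.numeric(pr > 0.5)
    inter <- inter + sum(hard * b$y)
    esum <- esum + sum(b$y); fsum <- fsum + sum(hard)
  }
  list(loss = tot / length(slices),
       dice = if (esum + fsum == 0) 1 else 2 * inter / (esum + fsum))
}

#' @export
print.resunet_fit <- function(x, ...) {
  lastrow <- x$log[nrow(x$log), ]
  cat(sprintf("<resunet_fit: %d epochs, final val loss %.4f, best val dice %.4f>\n",
              nrow(x$log), lastrow$val_loss, max(x$log$val_dice)))
  invisible(x)
}

#' Run the full segmentation pipeline on a set of cases
#'
#' For each case: Gaussian smoothing, body crop + zoom, slicewise network
#' prediction, optional case-based 3D component filtering, inverse transform
#' back to original coordinates, and (when ground truth is present) scoring
#' against it. Per-case failures are caught, recorded and skipped.
#'
#' @param cases list of cases, each with `image` (ct_volume) and optionally
#'   `mask` (gold-standard mask_volume).
#' @param fit a `resunet_fit` or `resunet`.
#' @param cfg a [preprocess_config()] whose `out_size` matches the network
#'   input side.
#' @param postprocess apply [case_filter()] to each predicted volume.
#' @param threshold probability binarization threshold.
#' @param crop apply body cropping (disable for ablation baselines).
#' @param location_prior central-region fraction for [case_filter()].
#' @return object of class `pipeline_result`: list with `metrics`
#'   (data.frame incl. Average row, NULL if no ground truth), `masks` (list
#'   of predicted mask_volumes in original coordinates), and `failures`
#'   (named list of error messages).
#' @export
run_pipeline <- function(cases, fit, cfg = preprocess_config(),
                         postprocess = TRUE, threshold = 0.5, crop = TRUE,
                         location_prior = 0.8) {
  net <- if (inherits(fit, "resunet_fit")) fit$net else fit
  masks <- list()
  scored <- list()
  failures <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    id <- if (inherits(case$image, "ct_volume")) case$image$case_id else
      sprintf("case-%d", i)
    res <- tryCatch({
      pp <- preprocess_for_model(case$image, NULL, cfg, crop = crop)
      pred <- predict_case(net, pp$image, threshold = threshold)
      if (postprocess)
        pred <- suppressWarnings(
          case_filter(pred, location_prior = location_prior))
      full <- invert_transform(pred, pp$transform)
      full$case_id <- id
      masks[[id]] <- full
      if (!is.null(case$mask))
        scored[[id]] <- score_case(case$mask, full, case_id = id)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[[id]] <- res
  }
  structure(list(
    metrics = if (length(scored)) metrics_table(scored) else NULL,
    masks = masks, failures = failures), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  if (!is.null(x$metrics)) {
    print(x$metrics, row.names = FALSE, digits = 4)
  }
  if (length(x$failures))
    cat(sprintf("failures: %s\n", paste(names(x$failures), collapse = ", ")))
  invisible(x)
}
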