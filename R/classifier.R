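# Stage 1: binary tumor-presence classifier trained on image-level labels.
# Its probabilities drive RISE seed extraction and the healthy-image
# overrides at training and inference time.

#' Classifier configuration
#'
#' Defaults follow the reference protocol: Adam (beta1 0.9, beta2 0.999,
#' eps 1e-8, weight decay 0.1), batch size 32, 100 epochs, initial learning
#' rate 5e-4 decreased by a factor of 10 whenever the validation loss fails
#' to improve by 1e-4 (at most `max_lr_decays` times), inputs bilinearly
#' upsampled by a factor of 2 before the network, decision threshold 0.5.
#'
#' @param backbone `"vgg16-bn"` (reference), `"resnet18"`, or `"small"`
#'   (desk-scale); any backbone mapping a 4-channel image to one logit
#'   trains through the same code path
#' @param width channel width of the `"small"` backbone
#' @param input_upsample_factor integer upsampling factor applied to inputs
#' @param epochs,batch_size training schedule
#' @param lr_init,lr_decay_factor,plateau_tol,max_lr_decays learning-rate
#'   schedule (reduce-on-plateau against the best validation loss so far)
#' @param weight_decay,adam_betas,adam_eps optimizer settings
#' @param decision_threshold probability cutoff for [classify()]
#' @param rng_seed seed controlling initialization and batch order
#' @return an object of class `classifier_config`
#' @export
classifier_config <- function(backbone = "vgg16-bn", width = 8L,
                              input_upsample_factor = 2L,
                              epochs = 100L, batch_size = 32L,
                              lr_init = 5e-4, lr_decay_factor = 10,
                              plateau_tol = 1e-4, max_lr_decays = 3L,
                              weight_decay = 0.1,
                              adam_betas = c(0.9, 0.999), adam_eps = 1e-8,
                              decision_threshold = 0.5, rng_seed = 1L) {
  stopifnot(lr_init > 0, decision_threshold > 0, decision_threshold < 1,
            epochs >= 1, batch_size >= 1)
  structure(as.list(environment()), class = "classifier_config")
}

upsample_input <- function(pixels, factor) {
  if (factor <= 1L) return(pixels)
  d <- dim(pixels)
  cpp_bilinear_resize(pixels, as.integer(d[1] * factor), as.integer(d[2] * factor))
}

# batched eval-mode probabilities for an (H,W,4,N) array
classifier_probs <- function(model, pixels, batch = 64L) {
  d <- dim(pixels)
  if (!identical(as.integer(d[1:2]), as.integer(model$input_size)))
    stop("slice shape ", d[1], "x", d[2], " does not match training shape ",
         model$input_size[1], "x", model$input_size[2])
  n <- d[4]
  probs <- numeric(n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    x <- upsample_input(pixels[, , , idx, drop = FALSE],
                        model$config$input_upsample_factor)
    z <- sx_no_grad(backbone_forward(model$module, sx_const(x), training = FALSE))
    probs[idx] <- 1 / (1 + exp(-as.vector(z$value)))
  }
  probs
}

#' Train the tumor-presence classifier
#'
#' Minimizes binary cross-entropy between the sigmoid output and the
#' image-level labels.  Both cohorts must contain both classes.
#'
#' @param train_ds,val_ds [slice_dataset()] cohorts with labels
#' @param config a [classifier_config()]
#' @return an object of class `tumor_classifier` with fields `module`,
#'   `config`, and a per-epoch `history` tibble (learning rate, train/val
#'   loss, val accuracy)
#' @export
train_classifier <- function(train_ds, val_ds, config = classifier_config()) {
  for (nm in c("train", "val")) {
    lab <- (if (nm == "train") train_ds else val_ds)$label
    if (length(unique(lab)) < 2L)
      stop(nm, " cohort contains a single class; both labels are required")
  }
  d <- dim(train_ds$pixels)
  module <- new_backbone(config$backbone, 4L, 1L, config$width, config$rng_seed)
  model <- structure(list(module = module, config = config,
                          input_size = d[1:2], history = NULL),
                     class = "tumor_classifier")
  params <- collect_params(module)
  opt <- adam_init(params)
  lr <- config$lr_init
  best_val <- Inf
  decays <- 0L
  n <- length(train_ds)
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$rng_seed + 1000L * epoch, sample.int(n))
    batch_losses <- c()
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      x <- upsample_input(train_ds$pixels[, , , idx, drop = FALSE],
                          config$input_upsample_factor)
      y <- train_ds$label[idx]
      sx_tape_reset()
      sx_zero_grads(params)
      z <- backbone_forward(module, sx_const(x), training = TRUE)
      # BCE with logits: mean(softplus(z) - y * z)
      loss <- sx_mean(sx_sub(sx_softplus(z), sx_mul(z, matrix(y, ncol = 1))))
      lv <- as.numeric(loss$value)
      if (!is.finite(lv))
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting ", s, "); lr=", lr)
      sx_backward(loss)
      opt <- adam_step(opt, params, lr, config$adam_betas[1],
                       config$adam_betas[2], config$adam_eps,
                       config$weight_decay)
      batch_losses <- c(batch_losses, lv)
    }
    sx_tape_reset()
    vp <- classifier_probs(model, val_ds$pixels)
    vp_cl <- pmin(pmax(vp, 1e-12), 1 - 1e-12)
    val_loss <- -mean(val_ds$label * log(vp_cl) + (1 - val_ds$label) * log(1 - vp_cl))
    val_acc <- mean((vp >= config$decision_threshold) == (val_ds$label == 1L))
    if (val_loss < best_val - config$plateau_tol) {
      best_val <- val_loss
    } else if (decays < config$max_lr_decays) {
      lr <- lr / config$lr_decay_factor
      decays <- decays + 1L
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    train_loss = mean(batch_losses),
                                    val_loss = val_loss, val_acc = val_acc)
  }
  model$history <- do.call(rbind, hist)
  model
}

#' @export
print.tumor_classifier <- function(x, ...) {
  h <- x$history
  cat(sprintf("<tumor_classifier> backbone=%s, input %dx%d (x%d upsampled)\n",
              x$config$backbone, x$input_size[1], x$input_size[2],
              x$config$input_upsample_factor))
  if (!is.null(h))
    cat(sprintf("  %d epochs; final train loss %.4f, val loss %.4f, val acc %.3f\n",
                nrow(h), h$train_loss[nrow(h)], h$val_loss[nrow(h)], h$val_acc[nrow(h)]))
  invisible(x)
}

#' Predict tumor probability for slices
#'
#' Deterministic in eval mode (batch-norm uses running statistics).
#'
#' @param model a trained [train_classifier()] model
#' @param x a single (H, W, 4) slice array, or a [slice_dataset()]
#' @return numeric vector of probabilities in \[0, 1\]
#' @export
predict_tumor_probability <- function(model, x) {
  px <- if (inherits(x, "slice_dataset")) x$pixels
        else if (is.array(x) && length(dim(x)) == 3L) array(x, c(dim(x), 1L))
        else stop("x must be a slice_dataset or an (H, W, 4) array")
  classifier_probs(model, px)
}

#' Binary tumor-presence decision
#'
#' Probability greater than or equal to the threshold counts as positive
#' (ties go to 1).
#'
#' @inheritParams predict_tumor_probability
#' @param threshold decision threshold (default 0.5)
#' @return integer vector of 0/1 decisions
#' @export
classify <- function(model, x, threshold = 0.5) {
  as.integer(predict_tumor_probability(model, x) >= threshold)
}
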