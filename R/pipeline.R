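# Orchestration: joint Stage-3 training and the resumable three-stage
# pipeline (classifier -> RISE seeds -> superpixel models -> threshold
# selection -> evaluation) driven by one run configuration.

#' Stage-3 training configuration
#'
#' Reference protocol: Adam (betas 0.9/0.999, eps 1e-8, weight decay 0.1),
#' 100 epochs, batch 32, learning rate 5e-4 halved every 25 epochs; one
#' optimizer over the union of both networks' parameters.
#'
#' @param epochs,batch_size training schedule
#' @param lr_init initial learning rate
#' @param halve_every halve the learning rate every this many epochs
#' @param weight_decay,adam_betas,adam_eps optimizer settings
#' @param loss a [loss_config()]
#' @param rng_seed seed controlling batch order
#' @return an object of class `spixel_train_config`
#' @export
spixel_train_config <- function(epochs = 100L, batch_size = 32L,
                                lr_init = 5e-4, halve_every = 25L,
                                weight_decay = 0.1,
                                adam_betas = c(0.9, 0.999), adam_eps = 1e-8,
                                loss = loss_config(), rng_seed = 3L) {
  stopifnot(lr_init > 0, epochs >= 1, halve_every >= 1)
  structure(as.list(environment()), class = "spixel_train_config")
}

#' Jointly train the superpixel generation and clustering models
#'
#' Both networks are optimized simultaneously against
#' `L_spixel + alpha * L_seed`; the seed loss gradient reaches the generator
#' both directly through the heatmap and through the clusterer's input
#' (which consumes the associations).  Training uses all images, including
#' predicted-healthy ones (whose seeds are all-negative).
#'
#' @param train_ds a [slice_dataset()]
#' @param seeds list of [seed_map()]s, one per training slice
#' @param gen a [new_superpixel_generator()]
#' @param clu a [new_superpixel_clusterer()]
#' @param config a [spixel_train_config()]
#' @return list with `gen`, `clu` (trained in place) and `history` tibble of
#'   per-epoch mean loss terms
#' @export
train_superpixel_stage <- function(train_ds, seeds, gen, clu,
                                   config = spixel_train_config()) {
  n <- length(train_ds)
  missing_ids <- which(vapply(seq_len(n), function(i)
    i > length(seeds) || !inherits(seeds[[i]], "seed_map"), TRUE))
  if (length(missing_ids))
    stop("missing seed maps for slices: ",
         paste(utils::head(missing_ids, 10L), collapse = ", "),
         if (length(missing_ids) > 10L) " ...")
  params <- c(collect_params(gen), collect_params(clu))
  opt <- adam_init(params)
  lc <- config$loss
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr_init * 0.5^((epoch - 1L) %/% config$halve_every)
    ord <- with_seed(config$rng_seed + 1000L * epoch, sample.int(n))
    ep <- c(total = 0, spixel = 0, seed = 0)
    nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      B <- length(idx)
      sx_tape_reset()
      sx_zero_grads(params)
      xt <- sx_const(train_ds$pixels[, , , idx, drop = FALSE])
      qt <- generator_forward_t(gen, xt, training = TRUE)
      rt <- clusterer_forward_t(clu, sx_concat_channels(xt, qt), training = TRUE)
      sp_sum <- sx_const(0); sd_sum <- sx_const(0)
      for (j in seq_len(B)) {
        ic <- img_consts(train_ds$pixels[, , , idx[j]])
        Qj <- sx_img_mat(qt, j)
        sp <- spixel_loss_core(ic, Qj, lc$m)
        rj <- sx_transpose(sx_row(rt, j))
        hj <- sx_matmul(sx_transpose(Qj), rj)
        sl <- seed_loss_core(hj, seeds[[idx[j]]], lc$eps)
        sp_sum <- sx_add(sp_sum, sp$total)
        sd_sum <- sx_add(sd_sum, sl)
      }
      loss <- sx_mul(sx_add(sp_sum, sx_mul(sd_sum, lc$alpha)), 1 / B)
      if (!is.finite(as.numeric(loss$value)))
        stop("non-finite stage-3 loss at epoch ", epoch)
      sx_backward(loss)
      opt <- adam_step(opt, params, lr, config$adam_betas[1],
                       config$adam_betas[2], config$adam_eps,
                       config$weight_decay)
      ep <- ep + c(as.numeric(loss$value), as.numeric(sp_sum$value) / B,
                   as.numeric(sd_sum$value) / B)
      nb <- nb + 1L
    }
    sx_tape_reset()
    ep <- ep / nb
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr, loss = ep[1],
                                    spixel = ep[2], seed = ep[3])
  }
  list(gen = gen, clu = clu, history = do.call(rbind, hist))
}

#' Pipeline run configuration
#'
#' `profile = "desk"` is the package's CPU-scale study design (32 x 32
#' phantoms, small backbones, 500 RISE masks, 16 superpixels, short
#' schedules); `profile = "paper"` carries the reference protocol (128 x 128
#' inputs, VGG-16-bn / ResNet-18, 4000 masks, 64 superpixels, 100 epochs)
#' and is practical only with far more compute.
#'
#' @param profile `"desk"` or `"paper"`
#' @param phantom_condition phantom difficulty name from
#'   [phantom_difficulty_suite()] used when no dataset paths are given
#' @param n_train,n_val,n_test cohort sizes for phantom data
#' @param data_dirs optional named list (train/val/test) of
#'   [write_slice_dataset()] directories to use instead of phantoms
#' @param rng_seed master seed; stage seeds derive from it
#' @param ... named overrides of individual fields (`classifier`, `rise`,
#'   `spixel`, `n_superpixels`, `gen_width`, `threshold_grid_step`)
#' @return an object of class `run_config`
#' @export
run_config <- function(profile = c("desk", "paper"),
                       phantom_condition = "easy",
                       n_train = 256L, n_val = 64L, n_test = 64L,
                       data_dirs = NULL, rng_seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(
      classifier = classifier_config(backbone = "small", width = 8L,
                                     epochs = 30L, rng_seed = rng_seed + 11L),
      rise = list(K = 500L, cell_grid = 4L, keep_prob = 0.5,
                  quantile = 0.2, rng_seed = rng_seed + 22L),
      n_superpixels = 16L, gen_width = 8L,
      clu_backbone = "small", clu_width = 8L,
      spixel = spixel_train_config(epochs = 15L, halve_every = 25L,
                                   rng_seed = rng_seed + 33L),
      threshold_grid_step = 0.1
    )
  } else {
    list(
      classifier = classifier_config(backbone = "vgg16-bn",
                                     rng_seed = rng_seed + 11L),
      rise = list(K = 4000L, cell_grid = 8L, keep_prob = 0.5,
                  quantile = 0.2, rng_seed = rng_seed + 22L),
      n_superpixels = 64L, gen_width = 16L,
      clu_backbone = "resnet18", clu_width = 8L,
      spixel = spixel_train_config(rng_seed = rng_seed + 33L),
      threshold_grid_step = 0.1
    )
  }
  cfg <- utils::modifyList(base, list(...))
  cfg$profile <- profile
  cfg$phantom_condition <- phantom_condition
  cfg$n_train <- as.integer(n_train)
  cfg$n_val <- as.integer(n_val)
  cfg$n_test <- as.integer(n_test)
  cfg$data_dirs <- data_dirs
  cfg$rng_seed <- as.integer(rng_seed)
  structure(cfg, class = "run_config")
}

stage_artifact <- function(run_dir, name) file.path(run_dir, name)

load_or <- function(path, compute) {
  if (file.exists(path)) return(readRDS(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  val <- compute()
  saveRDS(val, path)
  val
}

#' Run the full weakly supervised segmentation pipeline
#'
#' Executes data preparation, Stage 1 (classifier), Stage 2 (RISE seeds),
#' Stage 3 (joint superpixel training), validation threshold selection, and
#' test-cohort evaluation.  Every stage's artifacts are written under
#' `run_dir`; rerunning with an existing directory resumes after the last
#' completed stage (delete a stage file to re-train from that point).
#'
#' @param config a [run_config()]
#' @param run_dir output directory; a timestamped directory under `base_dir`
#'   is created when NULL
#' @param base_dir parent for timestamped run directories
#' @param quiet suppress progress messages
#' @return list with the run directory, trained models, selected threshold,
#'   and the test [evaluate_cohort()] result
#' @export
run_pipeline <- function(config, run_dir = NULL, base_dir = "runs",
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(run_dir))
    run_dir <- file.path(base_dir, format(Sys.time(), "run-%Y%m%d-%H%M%S"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[spixelseg] ", ...)
  writeLines(yaml::as.yaml(list(
    config = unclass(rapply(config, unclass, how = "replace")),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("spixelseg")))),
    file.path(run_dir, "config.yaml"))

  say("preparing data")
  data <- load_or(stage_artifact(run_dir, "data/cohorts.rds"), function() {
    if (!is.null(config$data_dirs)) {
      lapply(config$data_dirs, read_slice_dataset)
    } else {
      pc <- phantom_difficulty_suite()[[config$phantom_condition]]
      if (is.null(pc)) stop("unknown phantom condition: ", config$phantom_condition)
      list(train = generate_phantom(pc, config$n_train,
                                    rng_seed = pc$rng_seed + 7L * config$rng_seed),
           val = generate_phantom(pc, config$n_val,
                                  rng_seed = pc$rng_seed + 7L * config$rng_seed + 1L),
           test = generate_phantom(pc, config$n_test,
                                   rng_seed = pc$rng_seed + 7L * config$rng_seed + 2L))
    }
  })

  say("stage 1: training classifier (", config$classifier$backbone, ")")
  classifier <- load_or(stage_artifact(run_dir, "stage1/classifier.rds"),
    function() {
      m <- train_classifier(data$train, data$val, config$classifier)
      utils::write.csv(m$history,
                       stage_artifact(run_dir, "stage1/history.csv"),
                       row.names = FALSE)
      m
    })

  say("stage 2: RISE seeds (K=", config$rise$K, ")")
  seeds <- load_or(stage_artifact(run_dir, "stage2/seeds.rds"), function() {
    masks <- generate_masks(dim(data$train$pixels)[1:2], config$rise$K,
                            config$rise$cell_grid, config$rise$keep_prob,
                            config$rise$rng_seed)
    make_seeds(classifier, data$train, masks, config$rise$quantile,
               config$classifier$decision_threshold)
  })

  say("stage 3: joint superpixel training (N_S=", config$n_superpixels, ")")
  stage3 <- load_or(stage_artifact(run_dir, "stage3/models.rds"), function() {
    gen <- new_superpixel_generator(config$n_superpixels, config$gen_width,
                                    rng_seed = config$rng_seed + 44L)
    clu <- new_superpixel_clusterer(config$n_superpixels, config$clu_backbone,
                                    config$clu_width,
                                    rng_seed = config$rng_seed + 55L)
    out <- train_superpixel_stage(data$train, seeds$seeds, gen, clu,
                                  config$spixel)
    utils::write.csv(out$history,
                     stage_artifact(run_dir, "stage3/losses.csv"),
                     row.names = FALSE)
    out
  })

  say("selecting threshold on validation cohort")
  thr <- load_or(stage_artifact(run_dir, "threshold.rds"), function() {
    vs <- segment_dataset(data$val, stage3$gen, stage3$clu, classifier,
                          threshold = 0.5,
                          classifier_threshold = config$classifier$decision_threshold)
    select_threshold(vs$heatmaps, data$val$mask, config$threshold_grid_step)
  })

  say("evaluating test cohort (threshold ", thr, ")")
  eval_res <- load_or(stage_artifact(run_dir, "eval/result.rds"), function() {
    ts <- segment_dataset(data$test, stage3$gen, stage3$clu, classifier,
                          threshold = thr,
                          classifier_threshold = config$classifier$decision_threshold)
    correct <- ts$gate == data$test$label
    res <- evaluate_cohort(ts$masks, data$test$mask, correct,
                           id = data$test$patient_id)
    utils::write.csv(res$per_image, stage_artifact(run_dir, "eval/metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary, stage_artifact(run_dir, "eval/summary.csv"),
                     row.names = FALSE)
    res
  })

  list(run_dir = run_dir, data = data, classifier = classifier,
       seeds = seeds, gen = stage3$gen, clu = stage3$clu,
       threshold = thr, evaluation = eval_res)
}
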