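# Desk-scale end-to-end benchmark shared by the acceptance tests.
#
# One 200-image synthetic dataset (320x320 scenes, seeded) is shared by all
# runs. Four training arms are compared at a fixed desk profile (network
# input 160, 4 pretraining + 6 formal epochs, batch 10, no geometric
# augmentation) over three seeds each:
#   all_off   - no auxiliary task, no P2 scale, standard convolutions
#   no_D      - auxiliary task + dynamic conv, without the P2 scale
#   all_on    - auxiliary task + P2 + dynamic conv (the full architecture)
#   distilled - all_on plus masked generative distillation from a frozen
#               wider teacher
# The distillation weight for this profile is set by a gradient-magnitude
# rule (the distillation term contributes ~5% of the task parameter
# gradient), because the desk schedule is an order of magnitude shorter than
# the reference protocol; the teacher is 1.5x the student width and trained
# longer at a reduced input, which at desk scale yields a strictly stronger
# model than a 2x-width teacher trained under the same time budget.
# Everything is computed lazily once and cached for the test blocks.

DESK <- new.env(parent = emptyenv())

desk_profile <- list(
  n_images = 200L, image_size = 320L, data_seed = 42L,
  input = 160L, batch = 10L, lr0 = 0.02,
  epochs = 6L, pre_epochs = 4L,
  seeds = c(1L, 2L, 3L),
  distill_alpha = 2e-6, distill_lambda = 0.65,
  teacher_width = 0.1875, teacher_input = 128L,
  teacher_pre_epochs = 3L, teacher_epochs = 15L, teacher_seed = 11L,
  headline_input = 128L, headline_pre = 3L, headline_epochs = 15L,
  eval_conf = 0.005
)

desk_data_dir <- function() {
  d <- file.path(tempdir(), "desk_data")
  if (!dir.exists(d) || length(list.files(d, pattern = "\\.png$")) <
      desk_profile$n_images) {
    synth_dataset(d, desk_profile$n_images, seed = desk_profile$data_seed,
                  spec = scene_spec(width = desk_profile$image_size,
                                    height = desk_profile$image_size,
                                    n_cells = 4L,
                                    seed = desk_profile$data_seed))
  }
  d
}

desk_manifest <- function() {
  if (is.null(DESK$manifest)) {
    m <- build_manifest(desk_data_dir())
    DESK$manifest <- split_dataset(m, c(7, 2, 1), seed = desk_profile$data_seed)
  }
  DESK$manifest
}

desk_records <- function(split, input = desk_profile$input) {
  key <- paste0("rec_", split, "_", input)
  if (is.null(DESK[[key]]))
    DESK[[key]] <- stomadet:::load_split(desk_manifest(), split, input)
  DESK[[key]]
}

desk_pretrain_manifest <- function(seed) {
  key <- paste0("pre_", seed)
  if (is.null(DESK[[key]])) {
    pm <- make_pretrain_dataset(desk_manifest(), 0.5,
                                seed = stomadet:::sub_seed(seed, 35L),
                                out_dir = file.path(tempdir(),
                                                    paste0("pre_labels_", seed)))
    pm$items$split <- "train"
    DESK[[key]] <- pm
  }
  DESK[[key]]
}

desk_teacher <- function() {
  if (is.null(DESK$teacher)) {
    pr <- desk_profile
    teacher <- build_detector(detector_config(
      scales = c("P2", "P3", "P4", "P5"), width = pr$teacher_width,
      use_dynamic = TRUE, input_size = pr$teacher_input,
      seed = stomadet:::sub_seed(pr$teacher_seed, 30L)))
    pre_rec <- stomadet:::load_split(desk_pretrain_manifest(pr$teacher_seed),
                                     "train", pr$teacher_input)
    train_detector(teacher, pre_rec, pr$teacher_pre_epochs, 14L, pr$lr0,
                   mask_inner_only = FALSE,
                   seed = stomadet:::sub_seed(pr$teacher_seed, 37L),
                   phase = "teacher_pre", augment = FALSE)
    rec <- desk_records("train", pr$teacher_input)
    train_detector(teacher, rec, pr$teacher_epochs, 14L, pr$lr0,
                   mask_inner_only = TRUE,
                   seed = stomadet:::sub_seed(pr$teacher_seed, 36L),
                   phase = "teacher", augment = FALSE)
    # the network is fully convolutional; inference runs at the student input
    teacher$config$input_size <- pr$input
    DESK$teacher <- teacher
  }
  DESK$teacher
}

# teacher neck features over the training split (identical across seeds)
desk_teacher_feats <- function(teacher, input = desk_profile$input) {
  if (is.null(teacher)) return(NULL)
  key <- paste0("teacher_feats_", input)
  if (is.null(DESK[[key]])) {
    rec <- desk_records("train", input)
    scs <- names(teacher$neck_out)
    feats <- vector("list", length(rec))
    for (i in seq_along(rec)) {
      b <- stomadet:::make_batch(rec, i, input)
      tf <- stomadet:::graph_forward(teacher, b$x, train = FALSE)
      feats[[i]] <- lapply(scs, function(sc) tf$vals[[teacher$neck_out[[sc]]]])
      names(feats[[i]]) <- scs
    }
    DESK[[key]] <- feats
  }
  DESK[[key]]
}

# snapshot/restore of model state, so the all_on and distilled arms can share
# their (identical) pretraining phase per seed
snap_state <- function(model) {
  P <- model$graph$params; B <- model$graph$buffers
  list(p = mget(ls(P), envir = P), b = mget(ls(B), envir = B))
}
restore_state <- function(model, st) {
  for (nm in names(st$p)) model$graph$params[[nm]] <- st$p[[nm]]
  for (nm in names(st$b)) model$graph$buffers[[nm]] <- st$b[[nm]]
  invisible(model)
}

# one training arm; returns inner-class mAP@0.5, metrics, wall time
desk_arm <- function(seed, p2 = TRUE, dynamic = TRUE, aux = TRUE,
                     distill = FALSE, input = desk_profile$input,
                     epochs = desk_profile$epochs,
                     pre_epochs = desk_profile$pre_epochs) {
  pr <- desk_profile
  t0 <- proc.time()
  scales <- if (p2) c("P2", "P3", "P4", "P5") else c("P3", "P4", "P5")
  model <- build_detector(detector_config(
    scales = scales, width = 0.125, use_dynamic = dynamic,
    input_size = input, seed = stomadet:::sub_seed(seed, 31L)))
  if (aux) {
    full_arch <- p2 && dynamic && input == pr$input &&
      pre_epochs == pr$pre_epochs
    cache_key <- paste0("pretrained_", seed)
    if (full_arch && !is.null(DESK[[cache_key]])) {
      restore_state(model, DESK[[cache_key]])
    } else {
      pre_rec <- stomadet:::load_split(desk_pretrain_manifest(seed), "train",
                                       input)
      train_detector(model, pre_rec, pre_epochs, pr$batch, pr$lr0,
                     mask_inner_only = FALSE,
                     seed = stomadet:::sub_seed(seed, 32L), phase = "pretrain",
                     augment = FALSE)
      if (full_arch) DESK[[cache_key]] <- snap_state(model)
    }
  }
  teacher <- if (distill) desk_teacher() else NULL
  dcfg <- if (distill)
    distill_config(lambda = pr$distill_lambda, alpha = pr$distill_alpha,
                   seed = stomadet:::sub_seed(seed, 33L)) else NULL
  log <- train_detector(model, desk_records("train", input), epochs, pr$batch,
                        pr$lr0, mask_inner_only = aux, teacher = teacher,
                        distill = dcfg,
                        teacher_feats = desk_teacher_feats(teacher, input),
                        seed = stomadet:::sub_seed(seed, 34L),
                        phase = "formal", augment = FALSE)
  metrics <- evaluate_records(model, desk_records("val", input),
                              conf_threshold = pr$eval_conf)
  list(map = metrics$map_headline, metrics = metrics, log = log,
       minutes = (proc.time() - t0)[[3]] / 60)
}

# the full recipe at its own desk conditions (15 formal epochs), one seed
desk_headline <- function() {
  if (is.null(DESK$headline)) {
    pr <- desk_profile
    DESK$headline <- desk_arm(1L, p2 = TRUE, dynamic = TRUE, aux = TRUE,
                              distill = TRUE, input = pr$headline_input,
                              epochs = pr$headline_epochs,
                              pre_epochs = pr$headline_pre)
  }
  DESK$headline
}

# the full arm table (computed once, cached)
desk_results <- function() {
  if (!is.null(DESK$results)) return(DESK$results)
  rows <- list()
  for (s in desk_profile$seeds) {
    for (arm in c("all_off", "no_D", "all_on", "distilled")) {
      r <- switch(arm,
        all_off = desk_arm(s, p2 = FALSE, dynamic = FALSE, aux = FALSE),
        no_D = desk_arm(s, p2 = FALSE, dynamic = TRUE, aux = TRUE),
        all_on = desk_arm(s, p2 = TRUE, dynamic = TRUE, aux = TRUE),
        distilled = desk_arm(s, p2 = TRUE, dynamic = TRUE, aux = TRUE,
                             distill = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(arm = arm, seed = s,
                                              map = r$map,
                                              minutes = r$minutes)
    }
  }
  DESK$results <- do.call(rbind, rows)
  DESK$results
}

arm_median <- function(results, arm)
  stats::median(results$map[results$arm == arm])
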