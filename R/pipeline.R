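# ---------------------------------------------------------------------------
# End-to-end orchestration: synthesize -> split -> pretrain -> formal
# multi-task training -> distill -> evaluate -> profile, plus the ablation
# harness over the three toggles (T = auxiliary-task pretraining, D = the P2
# small-object scale, C = dynamic convolution).
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' @param out_dir output directory (logs, checkpoints, reports).
#' @param data_dir directory of an existing dataset; `NULL` synthesizes one.
#' @param n_images number of synthetic images when synthesizing.
#' @param image_size synthetic canvas side in pixels (square scenes).
#' @param preset synthetic preset (`"single"`, `"mosaic2"`, `"mosaic4"`).
#' @param scales detector scale set.
#' @param width detector width multiplier.
#' @param use_dynamic dynamic convolution on/off.
#' @param input_size network input side.
#' @param pretrain logical: run the outer-only auxiliary pretraining phase.
#' @param pretrain_epochs epochs of the pretraining phase (protocol default
#'   50).
#' @param pretrain_fraction fraction of train+val sampled for pretraining.
#' @param mask_inner_only mask the formal-training loss to the inner class.
#' @param epochs formal-training epochs (default 100; desk runs use 15).
#' @param batch_size,lr0 optimizer settings.
#' @param distill a [distill_config()] or `NULL`.
#' @param teacher_width width multiplier of the distillation teacher
#'   (default: twice the student width).
#' @param teacher_ckpt checkpoint path of a trained teacher; `NULL` trains
#'   one.
#' @param seed global seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("run"), data_dir = NULL,
                       n_images = 200L, image_size = 320L, preset = "single",
                       scales = c("P2", "P3", "P4", "P5"), width = 0.125,
                       use_dynamic = TRUE, input_size = 160L,
                       pretrain = TRUE, pretrain_epochs = 50L,
                       pretrain_fraction = 0.5, mask_inner_only = TRUE,
                       epochs = 100L, batch_size = 8L, lr0 = 0.01,
                       distill = NULL, teacher_width = NULL,
                       teacher_ckpt = NULL, seed = 0L) {
  structure(as.list(environment()), class = "run_config")
}

# scene spec scaled to a square synthetic canvas
desk_scene_spec <- function(image_size, seed = 0L) {
  scene_spec(width = image_size, height = image_size,
             n_cells = 4L, stomata_per_cell = c(1L, 3L), seed = seed)
}

# synthesize + split; reuses an existing directory when present
prepare_data <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- cfg$data_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(cfg$out_dir, "data")
    if (!dir.exists(data_dir) || !length(list.files(data_dir, pattern = "\\.png$"))) {
      synth_dataset(data_dir, cfg$n_images, seed = sub_seed(cfg$seed, 1L),
                    spec = desk_scene_spec(cfg$image_size))
    }
  }
  m <- build_manifest(data_dir)
  split_dataset(m, c(7, 2, 1), seed = sub_seed(cfg$seed, 2L))
}

#' Run the full training recipe
#'
#' Executes the configured phases and writes a JSON-lines log
#' (`train_log.jsonl`), a checkpoint (`model.rds`) and a YAML report
#' (`report.yaml`) under `out_dir`. Phase boundaries, per-epoch losses and
#' the final evaluation are all in the log; rebuilding from the checkpoint
#' reproduces the reported metrics.
#'
#' @param cfg a [run_config()].
#' @param manifest optional pre-built split manifest (overrides data config).
#' @return list: `model`, `metrics`, `log`, `manifest`, `params`, `gflops`.
#' @export
train_pipeline <- function(cfg, manifest = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(cfg$out_dir, "train_log.jsonl")
  if (file.exists(log_file)) unlink(log_file)
  if (is.null(manifest)) manifest <- prepare_data(cfg)

  dcfg <- detector_config(scales = cfg$scales, width = cfg$width,
                          use_dynamic = cfg$use_dynamic,
                          input_size = cfg$input_size,
                          seed = sub_seed(cfg$seed, 3L))
  model <- build_detector(dcfg)
  train_rec <- load_split(manifest, "train", cfg$input_size)
  val_rec <- load_split(manifest, "val", cfg$input_size)
  logs <- list()

  epoch0 <- 0L
  if (isTRUE(cfg$pretrain) && cfg$pretrain_epochs > 0) {
    pm <- make_pretrain_dataset(manifest, cfg$pretrain_fraction,
                                seed = sub_seed(cfg$seed, 4L),
                                out_dir = file.path(cfg$out_dir, "pretrain_labels"))
    pm$items$split <- "train"
    pre_rec <- load_split(pm, "train", cfg$input_size)
    logs <- c(logs, train_detector(
      model, pre_rec, cfg$pretrain_epochs, cfg$batch_size, cfg$lr0,
      mask_inner_only = FALSE, seed = sub_seed(cfg$seed, 5L),
      phase = "pretrain", log_file = log_file))
    epoch0 <- cfg$pretrain_epochs
  }

  teacher <- NULL
  if (!is.null(cfg$distill)) {
    if (!is.null(cfg$teacher_ckpt)) {
      teacher <- load_checkpoint(cfg$teacher_ckpt)
    } else {
      tw <- cfg$teacher_width %||% (2 * cfg$width)
      tcfg <- detector_config(scales = cfg$scales, width = tw,
                              use_dynamic = cfg$use_dynamic,
                              input_size = cfg$input_size,
                              seed = sub_seed(cfg$seed, 6L))
      teacher <- build_detector(tcfg)
      train_detector(teacher, train_rec, cfg$epochs, cfg$batch_size, cfg$lr0,
                     mask_inner_only = cfg$mask_inner_only,
                     seed = sub_seed(cfg$seed, 7L), phase = "teacher",
                     log_file = log_file)
      save_checkpoint(teacher, file.path(cfg$out_dir, "teacher.rds"))
    }
  }

  logs <- c(logs, train_detector(
    model, train_rec, cfg$epochs, cfg$batch_size, cfg$lr0,
    mask_inner_only = cfg$mask_inner_only,
    teacher = teacher, distill = cfg$distill,
    seed = sub_seed(cfg$seed, 8L), phase = "formal", log_file = log_file,
    epoch_offset = epoch0))

  metrics <- evaluate_records(model, val_rec)
  params <- count_parameters(model)
  gflops <- as.numeric(count_flops(model))
  save_checkpoint(model, file.path(cfg$out_dir, "model.rds"))
  report <- list(precision = metrics$precision, recall = metrics$recall,
                 map50_inner = metrics$map_headline, map50 = metrics$map,
                 parameters = params, gflops = gflops)
  yaml::write_yaml(report, file.path(cfg$out_dir, "report.yaml"))
  row <- c(list(phase = "eval"), report)
  cat(jsonlite::toJSON(row, auto_unbox = TRUE), "\n", file = log_file,
      append = TRUE)
  list(model = model, metrics = metrics, log = logs, manifest = manifest,
       params = params, gflops = gflops)
}

#' Ablation harness over the three architecture/training toggles
#'
#' Runs one training per requested toggle combination, sharing the data and
#' the global seed: `T` switches the auxiliary outer-cell pretraining phase
#' (with inner-masked formal training), `D` the P2 small-object scale, `C`
#' dynamic convolution. Returns one row per combination with precision,
#' recall, mAP@0.5 (inner class), parameters and GFLOPs.
#'
#' @param base a [run_config()] used as the template.
#' @param toggles character subset of `c("T", "D", "C")` to vary; the rest
#'   stay at the `base` setting.
#' @param combos optional list of named logical vectors to run instead of
#'   the full 2^k grid.
#' @return data.frame, one row per combination.
#' @export
run_ablation <- function(base, toggles = c("T", "D", "C"), combos = NULL) {
  stopifnot(all(toggles %in% c("T", "D", "C")))
  if (is.null(combos)) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(toggles)))
    names(grid) <- toggles
    combos <- lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
  }
  manifest <- prepare_data(base)
  rows <- list()
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    cfg <- base
    if ("T" %in% names(cb)) {
      cfg$pretrain <- cb[["T"]]
      cfg$mask_inner_only <- cb[["T"]]
    }
    if ("D" %in% names(cb))
      cfg$scales <- if (cb[["D"]]) c("P2", "P3", "P4", "P5") else c("P3", "P4", "P5")
    if ("C" %in% names(cb)) cfg$use_dynamic <- cb[["C"]]
    cfg$out_dir <- file.path(base$out_dir, paste0("ablate_",
      paste0(names(cb), ifelse(cb, "1", "0"), collapse = "")))
    res <- train_pipeline(cfg, manifest = manifest)
    rows[[i]] <- data.frame(
      t(as.data.frame(cb)),
      P = res$metrics$precision, R = res$metrics$recall,
      mAP = res$metrics$map_headline,
      parameters = res$params, gflops = res$gflops)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile a detector configuration
#'
#' Builds the model and reports trainable parameters, GFLOPs at the
#' configured input (convention: 1 MAC = 2 FLOPs) and the per-scale map
#' sides.
#'
#' @param config a [detector_config()].
#' @return list with `parameters`, `gflops`, `convention`, `maps`.
#' @export
profile_detector <- function(config) {
  model <- build_detector(config)
  gf <- count_flops(model)
  maps <- vapply(model$strides, function(s) config$input_size %/% s, integer(1))
  list(parameters = count_parameters(model), gflops = as.numeric(gf),
       convention = attr(gf, "convention"),
       maps = maps)
}
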