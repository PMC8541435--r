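# End-to-end orchestration: phantom generation (or dataset ingest) ->
# gradient preprocessing -> split -> training -> prediction -> morphological
# refinement -> thickness measurement -> evaluation, with one master seed
# feeding per-stage child seeds so each stage is independently reproducible.

#' Assemble a run configuration
#'
#' @param out_dir run output directory.
#' @param data_dir optional existing dataset directory (with `manifest.json`,
#'   see [write_dataset()]); when `NULL`, phantoms are generated.
#' @param n_phantoms number of phantoms to generate (default 30).
#' @param phantom_ranges per-field sampling intervals for [make_dataset()].
#' @param base_spec template `phantom_spec`.
#' @param model a `model_config` (default [desk_config()]).
#' @param aug an `augment_config` (or `NULL` for none).
#' @param morph_chain list of `morph_step`s.
#' @param train_frac train split fraction (default 0.8).
#' @param averaging metric averaging, `"macro"` or `"micro"`.
#' @param thickness_mode `"max"` or `"mean"`, see [image_thickness()].
#' @param pixel_density pixels/mm used for mm conversion.
#' @param experts optional list of `expert_reference`s.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir, data_dir = NULL, n_phantoms = 30L,
                       phantom_ranges = list(thickness_mm = c(0.4, 1.0)),
                       base_spec = phantom_spec(),
                       model = desk_config(), aug = augment_config(),
                       morph_chain = default_morph_chain(),
                       train_frac = 0.8, averaging = "macro",
                       thickness_mode = "max", pixel_density = 16.66,
                       experts = NULL, seed = 1L) {
  structure(list(out_dir = out_dir, data_dir = data_dir,
                 n_phantoms = as.integer(n_phantoms),
                 phantom_ranges = phantom_ranges, base_spec = base_spec,
                 model = model, aug = aug, morph_chain = morph_chain,
                 train_frac = train_frac, averaging = averaging,
                 thickness_mode = thickness_mode,
                 pixel_density = pixel_density, experts = experts,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`.
#' @return character vector of violations, empty iff the config is runnable.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir)) add("out_dir: missing")
  if (!is.null(cfg$data_dir) && !file.exists(file.path(cfg$data_dir, "manifest.json")))
    add(sprintf("data_dir: no manifest.json under %s", cfg$data_dir))
  if (is.null(cfg$data_dir) && cfg$n_phantoms < 2)
    add("n_phantoms: need at least 2 samples to split")
  if (!(cfg$train_frac > 0 && cfg$train_frac < 1))
    add(sprintf("train_frac: %.3f outside (0,1)", cfg$train_frac))
  if (!cfg$averaging %in% c("macro", "micro")) add("averaging: must be macro or micro")
  if (!cfg$thickness_mode %in% c("max", "mean")) add("thickness_mode: must be max or mean")
  if (cfg$pixel_density <= 0) add("pixel_density: must be positive")
  mc <- tryCatch({ validate_model_config(cfg$model); NULL },
                 error = function(e) conditionMessage(e))
  if (!is.null(mc)) add(paste0("model: ", mc))
  if (is.null(cfg$data_dir)) {
    pc <- tryCatch({ validate_phantom_spec(cfg$base_spec); NULL },
                   error = function(e) conditionMessage(e))
    if (!is.null(pc)) add(paste0("base_spec: ", pc))
    sh <- c(cfg$base_spec$height, cfg$base_spec$width)
    if (!identical(as.integer(sh), cfg$model$input_shape))
      add(sprintf("base_spec/model: phantom %dx%d vs model input %dx%d",
                  sh[1], sh[2], cfg$model$input_shape[1], cfg$model$input_shape[2]))
  }
  v
}

stage_log <- function(con, stage, msg, t0) {
  line <- sprintf("[%s] %s (%.1fs)", stage, msg,
                  as.numeric(proc.time()[3] - t0))
  writeLines(line, con)
  message(line)
}

#' Run the full pipeline
#'
#' Executes every stage, writes all artifacts under `cfg$out_dir` (config,
#' dataset manifest, training history CSV, predicted masks, metric and
#' thickness reports, per-stage log) and returns the key results invisibly.
#' A rerun with the same config reproduces the split, augmentation stream and
#' all reports.
#'
#' @param cfg a `run_config`.
#' @return invisibly, list with `metrics`, `thickness`, `history`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  viol <- validate_config(cfg)
  if (length(viol) > 0)
    stop_cfg("invalid run configuration:\n  %s", paste(viol, collapse = "\n  "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(cfg$out_dir, "run.log"), "w")
  on.exit(close(logcon))
  t0 <- proc.time()[3]

  # ingest / phantom
  if (is.null(cfg$data_dir)) {
    samples <- make_dataset(cfg$n_phantoms, cfg$phantom_ranges,
                            seed = derive_seed(cfg$seed, 11L),
                            base_spec = cfg$base_spec)
    write_dataset(samples, file.path(cfg$out_dir, "dataset"))
    stage_log(logcon, "phantom", sprintf("generated %d samples", length(samples)), t0)
  } else {
    samples <- read_dataset(cfg$data_dir)
    stage_log(logcon, "ingest", sprintf("read %d samples from %s", length(samples), cfg$data_dir), t0)
  }

  # preprocess: dual gradient inputs + label masks
  items <- lapply(samples, function(s) {
    mask <- if (!is.null(s$mask)) s$mask else rasterize_mask(s$annotation, dim(s$image$pixels))
    list(pair = make_pair(s$image), mask = mask,
         true_thickness_px = s$true_thickness_px)
  })
  stage_log(logcon, "preprocess", sprintf("built %d gradient pairs", length(items)), t0)

  sp <- split_dataset(items, cfg$train_frac, seed = derive_seed(cfg$seed, 13L))
  stage_log(logcon, "split", sprintf("%d train / %d test", length(sp$train), length(sp$test)), t0)

  model_cfg <- cfg$model
  model_cfg$seed <- derive_seed(cfg$seed, 17L)
  model <- build_model(model_cfg)
  aug <- cfg$aug
  if (!is.null(aug)) aug$seed <- derive_seed(cfg$seed, 19L)
  history <- if (model_cfg$epochs > 0) train_model(model, sp$train, aug)
             else data.frame(epoch = integer(0), loss = numeric(0))
  write.csv(history, file.path(cfg$out_dir, "history.csv"), row.names = FALSE)
  save_model(model, file.path(cfg$out_dir, "model.rds"))
  stage_log(logcon, "train", sprintf("%d epochs, final loss %s", nrow(history),
            if (nrow(history)) sprintf("%.4f", history$loss[nrow(history)]) else "NA"), t0)

  mask_dir <- file.path(cfg$out_dir, "pred_masks")
  dir.create(mask_dir, showWarnings = FALSE)
  preds <- vector("list", length(sp$test))
  for (i in seq_along(sp$test)) {
    preds[[i]] <- predict_mask(model, sp$test[[i]]$pair, cfg$morph_chain)
    write_mask(preds[[i]], file.path(mask_dir, sprintf("pred_%03d.pgm", i)))
  }
  stage_log(logcon, "predict+refine", sprintf("%d masks", length(preds)), t0)

  gts <- lapply(sp$test, `[[`, "mask")
  metrics <- evaluate_set(preds, gts, cfg$averaging)
  nonempty <- vapply(preds, function(m) any(m == 1L), logical(1))
  thickness <- if (any(nonempty)) {
    thickness_report(preds[nonempty], cfg$pixel_density, cfg$thickness_mode,
                     cfg$experts)
  } else NULL
  stage_log(logcon, "measure+evaluate",
            sprintf("Dice %.4f; mean cIMT %s mm", metrics$dice,
                    if (is.null(thickness)) "NA" else sprintf("%.3f", thickness$mean_mm)), t0)

  jsonlite::write_json(
    list(precision = metrics$precision, recall = metrics$recall,
         f1 = metrics$f1, dice = metrics$dice, jaccard = metrics$jaccard,
         averaging = metrics$averaging),
    file.path(cfg$out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(thickness)) {
    jsonlite::write_json(
      list(per_image_px = thickness$per_image_px, mean_px = thickness$mean_px,
           mean_mm = thickness$mean_mm, pixel_density = thickness$pixel_density),
      file.path(cfg$out_dir, "thickness.json"), auto_unbox = TRUE, digits = NA)
  }
  cfg_json <- cfg
  cfg_json$base_spec <- unclass(cfg_json$base_spec)
  cfg_json$model <- unclass(cfg_json$model)
  cfg_json$aug <- if (is.null(cfg$aug)) NULL else unclass(cfg_json$aug)
  cfg_json$morph_chain <- lapply(cfg$morph_chain, unclass)
  jsonlite::write_json(unclass(cfg_json), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(metrics = metrics, thickness = thickness, history = history,
                 test_items = sp$test, preds = preds, out_dir = cfg$out_dir))
}
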