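#' Default configuration of the miniature phantom study
#'
#' A desk-scale rendition of the full weak-supervision study: 30 synthetic
#' two-modality patients at 64x64 with the reduced-width network, split
#' patient-wise into 24 training patients (20 weakly labelled via ellipse
#' trimaps, 4 annotated) and 6 test patients, trained with the two-round
#' protocol and compared against the fully supervised baseline on the same
#' architecture.
#'
#' @param seed Integer master seed.
#' @return Nested configuration list accepted by [run_experiment()].
#' @export
phantom_study_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(n_patients = 30, image_size = 64, n_modalities = 2,
                   n_slices = 3),
    split = list(fractions = c(0.8, 0, 0.2)),
    n_annotated = 4,
    weak_labels = list(p1 = 0.9, p2 = 1.2, dilation = 1.05),
    net = list(channels = c(8, 16, 32, 64, 128)),
    train = list(learning_rate = 0.02, batch_size = 8,
                 epochs_round1 = 8, epochs_round2 = 12),
    baseline = TRUE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the weak-supervision experiment end to end
#'
#' Generates (or loads) phantom patients, derives ellipse-box trimaps,
#' splits patients strictly, trains the two-round weakly supervised model
#' and (optionally) the fully supervised baseline, evaluates both on the
#' held-out test patients and writes a degradation report.
#'
#' @param config Configuration list (see [phantom_study_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir Optional run directory; when given, checkpoints, the
#'   epoch history, the resolved configuration and `report.json` are written
#'   there.
#' @param quiet Suppress progress messages.
#' @return List with the trained models, their `metrics_report`s, the
#'   degradation tibble, the split and the slice tables.
#' @export
run_experiment <- function(config = phantom_study_config(), out_dir = NULL,
                           quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_io(sprintf("no config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(phantom_study_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- cfg$seed

  pc_args <- merge_config(cfg$phantom,
                          list(seed = derive_seed(seed, "phantom")))
  pcfg <- do.call(phantom_config, pc_args)
  say("generating %d phantom patients (%dx%d, %d modalities)",
      pcfg$n_patients, pcfg$image_size, pcfg$image_size, pcfg$n_modalities)
  slices <- generate_phantoms(pcfg)
  slices <- derive_weak_labels(slices, p1 = cfg$weak_labels$p1,
                               p2 = cfg$weak_labels$p2,
                               dilation = cfg$weak_labels$dilation)
  slices <- normalize_slices(slices, size = pcfg$image_size)

  split <- split_patients(slices, cfg$split$fractions,
                          seed = derive_seed(seed, "split"))
  slices <- apply_split(slices, split)
  train_slices <- dplyr::filter(slices, .data$subset == "train")
  test_slices <- dplyr::filter(slices, .data$subset == "test")
  train_slices <- mark_annotated(train_slices, cfg$n_annotated,
                                 seed = derive_seed(seed, "annot"))
  weak_set <- dplyr::filter(train_slices, !.data$annotated)
  annotated_set <- dplyr::filter(train_slices, .data$annotated)

  tq <- purrr::map2(weak_set$trimap, weak_set$mask, trimap_quality) |>
    dplyr::bind_rows() |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean))

  spec <- do.call(network_spec, merge_config(
    list(n_streams = pcfg$n_modalities, input_size = pcfg$image_size),
    cfg$net))
  tcfg <- do.call(train_config, merge_config(
    list(seed = derive_seed(seed, "train")), cfg$train))

  say("round 1/2: coarse training on %d weak slices, refining on %d annotated",
      nrow(weak_set), nrow(annotated_set))
  weak_model <- train_two_round(build_multistream(spec, seed = derive_seed(seed, "w")),
                                weak_set, annotated_set, tcfg)
  weak_report <- evaluate_runs(list(weak_model), test_set = test_slices)

  full_model <- NULL; full_report <- NULL; degr <- NULL
  if (isTRUE(cfg$baseline)) {
    say("baseline: fully supervised training on %d slices", nrow(train_slices))
    full_train <- dplyr::mutate(train_slices, annotated = TRUE)
    full_model <- train_fully_supervised(
      build_multistream(spec, seed = derive_seed(seed, "f")), full_train, tcfg)
    full_report <- evaluate_runs(list(full_model), test_set = test_slices)
    degr <- degradation_report(weak_report, full_report)
  }

  result <- list(config = cfg, split = split, slices = slices,
                 trimap_quality = tq,
                 weak_model = weak_model, weak_report = weak_report,
                 full_model = full_model, full_report = full_report,
                 degradation = degr)
  if (!is.null(out_dir)) write_run_dir(result, out_dir)
  result
}

write_run_dir <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(result$config, file.path(out_dir, "config.yaml"))
  write.csv(tidy(result$weak_model), file.path(out_dir, "history_weak.csv"),
            row.names = FALSE)
  save_msunet(result$weak_model, file.path(out_dir, "weak_model.rds"))
  if (!is.null(result$full_model)) {
    save_msunet(result$full_model, file.path(out_dir, "full_model.rds"))
    write.csv(tidy(result$full_model), file.path(out_dir, "history_full.csv"),
              row.names = FALSE)
  }
  report <- list(
    split = list(train = result$split$train_patients,
                 val = result$split$val_patients,
                 test = result$split$test_patients),
    trimap_quality = as.list(result$trimap_quality),
    weak = as.list(tidyr::pivot_wider(result$weak_report$summary[, 1:2],
                                      names_from = "metric",
                                      values_from = "mean")),
    full = if (!is.null(result$full_report))
      as.list(tidyr::pivot_wider(result$full_report$summary[, 1:2],
                                 names_from = "metric", values_from = "mean")),
    degradation = if (!is.null(result$degradation))
      purrr::transpose(as.list(result$degradation))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Repeat the weak-versus-full comparison over several seeds
#'
#' Each seed draws a new patient-wise phantom cohort and split (mirroring the
#' multiple-runs protocol of the full study), trains both protocols, and the
#' per-seed test metrics are aggregated into across-run reports plus a
#' degradation table.
#'
#' @param seeds Integer vector of master seeds.
#' @param config Base configuration (see [phantom_study_config()]).
#' @param quiet Suppress progress messages.
#' @return List with `weak`, `full` (`metrics_report`s across seeds),
#'   `degradation`, and the per-seed experiment results.
#' @export
compare_protocols <- function(seeds = 1:3, config = phantom_study_config(),
                              quiet = FALSE) {
  runs <- purrr::map(seeds, function(s) {
    cfgs <- merge_config(config, list(seed = derive_seed(s, "study"),
                                      baseline = TRUE))
    run_experiment(cfgs, quiet = quiet)
  })
  weak <- evaluate_runs(dplyr::bind_rows(purrr::map(runs, ~ .x$weak_report$per_run)))
  full <- evaluate_runs(dplyr::bind_rows(purrr::map(runs, ~ .x$full_report$per_run)))
  list(weak = weak, full = full,
       degradation = degradation_report(weak, full), runs = runs)
}
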