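# Run configuration and the end-to-end pipeline wiring all stages.

#' Default run configuration
#'
#' @return a nested list of defaults; override entries via
#'   [run_config()].
#' @export
default_run_config <- function() {
  list(
    paths = list(images = NULL, annotations = NULL, taxonomy = NULL,
                 output = NULL),
    generate = NULL,            # synth_spec() arguments, or NULL
    split = list(type = "holdout", fraction = 0.8, k = 7L, fold = 1L,
                 seed = 0L),
    trunk = "tiny",
    freeze = "all",             # flat-model freeze policy
    training = list(epochs = 30L, lr = 0.01, momentum = 0.9,
                    batch_size = 32L, weight_decay = 1e-4, seed = 0L),
    augmentation = list(flip_horizontal = TRUE,
                        scale_factors = c(0.75, 1.25),
                        crop_fraction_per_side = 0.25,
                        rotation_angles_deg = c(-20, -10, 10, 20)),
    monitor = list(threshold = 0.5, window = 5L, min_val_samples = 3L),
    confusable = "auto",        # "auto", list of pairs, or NULL
    confusable_fraction = 0.02,
    plots = FALSE,
    seed = 0L
  )
}

#' Build and validate a run configuration
#'
#' @param config a named list of overrides, or the path of a YAML file
#'   holding one; unknown keys are rejected before any stage runs.
#' @return the merged, validated configuration.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- default_run_config()
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(config, names(defaults), "config")
  for (section in c("paths", "split", "training", "augmentation",
                    "monitor")) {
    if (!is.null(config[[section]])) {
      check_keys(config[[section]], names(defaults[[section]]), section)
    }
  }
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$split$type %in% c("holdout", "kfold")) {
    stop("split$type must be 'holdout' or 'kfold'", call. = FALSE)
  }
  for (k in c("epochs", "batch_size", "seed")) {
    cfg$training[[k]] <- as.integer(cfg$training[[k]])
  }
  for (k in c("k", "fold", "seed")) {
    cfg$split[[k]] <- as.integer(cfg$split[[k]])
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

load_pipeline_data <- function(cfg) {
  if (!is.null(cfg$generate)) {
    spec <- do.call(synth_spec, cfg$generate)
    gen <- generate_synthetic(spec)
    list(records = standardize(gen$records), tree = gen$tree)
  } else {
    p <- cfg$paths
    if (is.null(p$images) || is.null(p$annotations) || is.null(p$taxonomy)) {
      stop("config must set paths$images/annotations/taxonomy or generate",
           call. = FALSE)
    }
    tree <- load_taxonomy(p$taxonomy)
    records <- read_annotations(p$images, p$annotations, tree)
    list(records = standardize(records), tree = tree)
  }
}

make_pipeline_split <- function(cfg, records) {
  if (cfg$split$type == "kfold") {
    stratified_kfold(records, k = cfg$split$k,
                     seed = cfg$split$seed)[[cfg$split$fold]]
  } else {
    holdout_split(records, train_fraction = cfg$split$fraction,
                  seed = cfg$split$seed)
  }
}

eval_partition <- function(split) {
  if (length(split$test)) split$test else split$validation
}

write_manifest <- function(out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
}

#' Run the full classification pipeline
#'
#' Modes: `"flat"` trains and evaluates the flat species classifier;
#' `"flat+augment"` runs the targeted-augmentation loop (train, inspect
#' per-class loss curves, flag, enlarge the train partition, retrain a
#' fresh model, evaluate both rounds); `"hier"` trains the hierarchical
#' model (root stage, optional automatic confusable-pair detection from
#' the root's validation confusions, leaf stage) and evaluates routed
#' predictions.
#'
#' @param config a [run_config()] (or list / YAML path passed to it).
#' @param mode one of `"flat"`, `"flat+augment"`, `"hier"`.
#' @param out_dir output directory; overrides `config$paths$output`.
#' @return invisibly, a list of stage results; reports, histories and
#'   the run manifest are written under the output directory.
#' @export
run_pipeline <- function(config = list(), mode = c("flat", "flat+augment", "hier"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  cfg <- run_config(config)
  out_dir <- out_dir %||% cfg$paths$output %||%
    stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  log_stage <- function(...) message("[finclass] ", ...)

  log_stage("loading data")
  data <- load_pipeline_data(cfg)
  records <- data$records
  tree <- data$tree
  split <- make_pipeline_split(cfg, records)
  write_split_manifest(split, vapply(records, function(r) r$source_id,
                                     character(1)),
                       file.path(out_dir, "split.csv"))
  hyper <- do.call(training_config, cfg$training)
  conv <- trunk_conv_features(build_trunk(cfg$trunk), records)
  eval_idx <- eval_partition(split)
  species <- record_species(records)
  result <- list(config = cfg, split = split)

  if (mode %in% c("flat", "flat+augment")) {
    log_stage("training flat model")
    model <- build_flat_model(cfg$trunk, sort(unique(species)),
                              freeze = cfg$freeze, seed = cfg$seed)
    fit <- train_flat(model, records, split, hyper, conv_cache = conv)
    write_loss_history(fit$history, file.path(out_dir, "loss_history.csv"))
    pred <- predict_flat(fit$model, records[eval_idx],
                         conv_cache = conv[eval_idx, , drop = FALSE])
    report <- metrics_report(species[eval_idx], pred$labels,
                             fit$model$class_order)
    write_metrics_report(report, file.path(out_dir, "flat"))
    result$flat <- list(model = fit$model, history = fit$history,
                        report = report)
    if (mode == "flat+augment") {
      log_stage("inspecting per-class loss curves")
      flags <- flag_classes(fit$history, threshold = cfg$monitor$threshold,
                            window = cfg$monitor$window,
                            min_val_samples = cfg$monitor$min_val_samples)
      utils::write.csv(
        data.frame(class = names(flags$per_class_score),
                   score = unname(flags$per_class_score),
                   flagged = names(flags$per_class_score) %in% flags$flagged),
        file.path(out_dir, "divergence_report.csv"), row.names = FALSE)
      log_stage("flagged: ", if (length(flags$flagged))
        paste(flags$flagged, collapse = ", ") else "(none)")
      plan <- do.call(augmentation_plan,
                      c(cfg$augmentation,
                        list(flagged_classes = flags$flagged)))
      enlarged <- enlarge_training_set(records[split$train], plan)
      combined <- fish_records(c(unclass(enlarged),
                                 unclass(records[-split$train])))
      n_new <- length(enlarged)
      split2 <- new_dataset_split(
        train = seq_len(n_new),
        validation = n_new + match(split$validation,
                                   seq_along(records)[-split$train]),
        test = n_new + match(split$test,
                             seq_along(records)[-split$train])
      )
      log_stage("retraining on enlarged set (", n_new, " train records)")
      model2 <- build_flat_model(cfg$trunk, sort(unique(species)),
                                 freeze = cfg$freeze, seed = cfg$seed)
      fit2 <- train_flat(model2, combined, split2, hyper)
      eval2 <- eval_partition(split2)
      pred2 <- predict_flat(fit2$model, combined[eval2])
      report2 <- metrics_report(record_species(combined[eval2]),
                                pred2$labels, fit2$model$class_order)
      write_metrics_report(report2, file.path(out_dir, "flat_augmented"))
      result$augmented <- list(model = fit2$model, history = fit2$history,
                               report = report2, flags = flags, plan = plan)
    }
  }

  if (mode == "hier") {
    log_stage("training root node")
    model <- build_tree_model(cfg$trunk, tree, confusable = list(),
                              seed = cfg$seed)
    root_fit <- train_root(model, records, split, hyper, conv_cache = conv)
    model <- root_fit$model
    fams <- record_family(records)
    root_val <- route_predict(model, records[split$validation],
                              conv_cache = conv[split$validation, ,
                                                drop = FALSE])
    root_cm <- confusion(fams[split$validation], root_val$predictions$family,
                         tree$family_labels)
    confusable <- cfg$confusable
    if (identical(confusable, "auto")) {
      confusable <- auto_confusable_pairs(root_cm, cfg$confusable_fraction)
      log_stage("auto-confusable pairs: ", length(confusable))
    }
    if (length(confusable %||% list())) {
      # rebuild leaf spaces with Others classes, keep the trained root
      rebuilt <- build_tree_model(model$trunk, tree, confusable,
                                  seed = cfg$seed)
      rebuilt$trunk <- model$trunk
      rebuilt$root_head <- model$root_head
      rebuilt$root_trained <- TRUE
      model <- rebuilt
    }
    write_loss_history(root_fit$history,
                       file.path(out_dir, "root_loss_history.csv"))
    log_stage("training leaf nodes")
    leaf_fit <- train_leaves(model, records, split, hyper, conv_cache = conv)
    model <- leaf_fit$model
    log_stage("routed evaluation")
    routed <- route_predict(model, records[eval_idx],
                            conv_cache = conv[eval_idx, , drop = FALSE])
    root_report <- metrics_report(fams[eval_idx], routed$predictions$family,
                                  tree$family_labels)
    write_metrics_report(root_report, file.path(out_dir, "root"))
    species_report <- metrics_report(species[eval_idx],
                                     routed$predictions$species,
                                     tree$species_labels)
    write_metrics_report(species_report, file.path(out_dir, "hier"))
    leaf_reports <- list()
    for (f in tree$family_labels) {
      if (model$leaf_heads[[f]]$type == "identity") next
      sub <- which(routed$predictions$family == f)
      if (!length(sub)) next
      truth <- species[eval_idx][sub]
      truth[!truth %in% model$spaces[[f]]$classes] <- others_label()
      pred_leaf <- routed$predictions$species[sub]
      pred_leaf[pred_leaf == reject_label()] <- others_label()
      leaf_reports[[f]] <- metrics_report(truth, pred_leaf,
                                          model$spaces[[f]]$classes)
      write_metrics_report(leaf_reports[[f]],
                           file.path(out_dir, paste0("leaf_", f)))
    }
    result$hier <- list(model = model, root_report = root_report,
                        species_report = species_report,
                        leaf_reports = leaf_reports,
                        confusable = confusable,
                        root_history = root_fit$history)
  }

  if (isTRUE(cfg$plots) && !is.null(result$flat)) {
    plot_curves(result$flat$history, "global", file.path(out_dir, "plots"))
  }
  write_manifest(out_dir)
  log_stage("done; outputs in ", out_dir)
  invisible(result)
}
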