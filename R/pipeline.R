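#' Pipeline configuration
#'
#' Validates a (possibly nested) configuration for [run_pipeline()]. Any
#' unknown key is an error, raised before any stage runs. A config can be
#' built in code or loaded from a YAML file.
#'
#' @param config A named list (or path to a YAML file) with any of the keys:
#'   `fixture` (arguments for [fixture_config()]), `registry_census`
#'   (named counts for [feature_registry()]), `auc_threshold`,
#'   `training` (arguments for [training_config()]), `gsla` (arguments for
#'   [gsla_config()]), `pr_cutoffs`, `n_all_pairs`, `seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c(
    "fixture", "registry_census", "auc_threshold", "training",
    "gsla", "pr_cutoffs", "n_all_pairs", "seed"
  )
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  check_args <- function(given, fn, what) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad)) {
      abort(sprintf(
        "unknown %s config key(s): %s", what,
        paste(bad, collapse = ", ")
      ))
    }
    given
  }
  out <- list(
    fixture = check_args(config$fixture %||% list(), fixture_config, "fixture"),
    registry_census = config$registry_census,
    auc_threshold = config$auc_threshold %||% 0.6,
    training = check_args(config$training %||% list(), training_config, "training"),
    gsla = check_args(config$gsla %||% list(), gsla_config, "gsla"),
    pr_cutoffs = config$pr_cutoffs %||% 10^seq(-10, 0, by = 0.5),
    n_all_pairs = config$n_all_pairs,
    seed = as.integer(config$seed %||% 1L)
  )
  structure(out, class = "pipeline_config")
}

stage_uptodate <- function(outputs, inputs) {
  if (!all(file.exists(outputs))) {
    return(FALSE)
  }
  if (!length(inputs)) {
    return(TRUE)
  }
  min(file.mtime(outputs)) >= max(file.mtime(inputs))
}

#' Run the end-to-end workflow
#'
#' Executes the requested stages of the full workflow on a synthetic bundle:
#' `simulate` (generate and write the fixture), `features` (pair features
#' for labeled pairs), `select` (AUC-gated feature selection), `train`
#' (CV grid search + refit), `predict` (score all candidate pairs and keep
#' the predicted associations), `assemble` (union with the gold
#' experimental edges), `estimate-size`, `gsla` (each module's first half as
#' query against all module sets) and `evaluate` (guilt-by-association PR
#' curve). Stages are resumable: a stage whose outputs are newer than its
#' inputs is skipped. A `summary.json` aggregating the headline numbers is
#' written last and returned.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory.
#' @param stages Character vector of stage names, or `"all"`.
#' @param force Re-run stages even when outputs are up to date.
#' @return The summary, invisibly (a named list).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = "all", force = FALSE) {
  config <- pipeline_config(unclass(config))
  all_stages <- c(
    "simulate", "features", "select", "train", "predict",
    "assemble", "estimate-size", "gsla", "evaluate"
  )
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  log_msg <- function(fmt, ...) inform(sprintf(paste0("[pipeline] ", fmt), ...))
  skipped <- character(0)

  run_stage <- function(name, outputs, inputs, fun) {
    if (!name %in% stages) {
      return(invisible(NULL))
    }
    if (!force && stage_uptodate(outputs, inputs)) {
      skipped <<- c(skipped, name)
      log_msg("stage %s up to date, skipped", name)
      return(invisible(NULL))
    }
    log_msg("running stage %s", name)
    tryCatch(fun(), error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  fix_args <- config$fixture
  fix_args$seed <- fix_args$seed %||% config$seed
  fcfg <- do.call(fixture_config, fix_args)
  registry <- if (is.null(config$registry_census)) {
    feature_registry()
  } else {
    feature_registry(unlist(config$registry_census))
  }

  run_stage(
    "simulate", p("bundle", "manifest.json"), character(0),
    function() write_fixture_bundle(generate_fixture(fcfg), p("bundle"))
  )
  bundle <- generate_fixture(fcfg) # in-memory twin of the written bundle

  run_stage(
    "features", p("labeled_pairs.tsv"), p("bundle", "manifest.json"),
    function() {
      lp <- labeled_pairs_from_bundle(bundle, registry,
        neg_ratio = config$training$neg_ratio %||% 100,
        seed = config$seed
      )
      readr::write_tsv(lp, p("labeled_pairs.tsv"), progress = FALSE)
    }
  )

  run_stage(
    "select", p("selected_features.tsv"), p("labeled_pairs.tsv"),
    function() {
      lp <- readr::read_tsv(p("labeled_pairs.tsv"), show_col_types = FALSE)
      aucs <- feature_aucs(lp[, setdiff(names(lp), "label")], lp$label)
      aucs$selected <- aucs$feature %in% select_features(aucs, config$auc_threshold)
      readr::write_tsv(aucs, p("selected_features.tsv"), progress = FALSE)
    }
  )

  model_env <- new.env()
  get_model <- function() {
    if (is.null(model_env$model)) {
      lp <- readr::read_tsv(p("labeled_pairs.tsv"), show_col_types = FALSE)
      sel <- readr::read_tsv(p("selected_features.tsv"), show_col_types = FALSE)
      keep <- sel$feature[sel$selected]
      if (!length(keep)) keep <- sel$feature # degenerate gate: keep all
      tr_args <- config$training
      tr_args$seed <- tr_args$seed %||% config$seed
      tcfg <- do.call(training_config, tr_args)
      model_env$model <- train_association_model(
        lp[, c("gene_a", "gene_b", "label", keep)], tcfg
      )
    }
    model_env$model
  }

  run_stage(
    "train", p("model_summary.tsv"), p("selected_features.tsv"),
    function() readr::write_tsv(glance(get_model()), p("model_summary.tsv"), progress = FALSE)
  )

  run_stage(
    "predict", p("predicted.tsv"), p("model_summary.tsv"),
    function() {
      model <- get_model()
      genes <- bundle$truth$genes
      idx <- which(upper.tri(matrix(0, length(genes), length(genes))),
        arr.ind = TRUE
      )
      pairs <- tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]])
      feats <- suppressWarnings(
        compute_features(pairs, bundle$evidence, registry)
      )
      pred <- predict(model, feats)
      net <- interactome(
        pred[pred$predicted, c("gene_a", "gene_b")] |>
          mutate(score = pred$confidence[pred$predicted]),
        genes = genes
      )
      write_edge_list(net, p("predicted.tsv"))
    }
  )

  run_stage(
    "assemble", p("assembled.tsv"), p("predicted.tsv"),
    function() {
      predicted <- read_edge_list(p("predicted.tsv"))
      experimental <- interactome(
        filter_gold_positives(bundle$gold)[, c("gene_a", "gene_b")]
      )
      asm <- assemble_interactome(predicted, experimental)
      write_edge_list(asm$net, p("assembled.tsv"))
      readr::write_tsv(asm$report, p("assembly_report.tsv"), progress = FALSE)
    }
  )

  run_stage(
    "estimate-size", p("size_estimate.json"), p("assembled.tsv"),
    function() {
      model <- get_model()
      n_predicted <- n_edges(read_edge_list(p("predicted.tsv")))
      n_g <- length(bundle$truth$genes)
      est <- estimate_interactome_size(
        n_predict = n_predicted,
        n_all_pairs = config$n_all_pairs %||% (n_g * (n_g - 1) / 2),
        sensitivity = min(model$cv_sensitivity, model$apparent_sensitivity),
        specificity = model$cv_specificity
      )
      jsonlite::write_json(as.list(est), p("size_estimate.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  )

  run_stage(
    "gsla", p("gsla_report.tsv"), p("assembled.tsv"),
    function() {
      net <- read_edge_list(p("assembled.tsv"))
      g_args <- config$gsla
      g_args$seed <- g_args$seed %||% config$seed
      gcfg <- do.call(gsla_config, g_args)
      query <- bundle$modules[[1]]
      query <- query[seq_len(ceiling(length(query) / 2))]
      res <- suppressWarnings(gsla_run(net, query, bundle$sets, gcfg))
      write_gsla_report(res, p("gsla_report.tsv"))
    }
  )

  run_stage(
    "evaluate", p("pr_curve.tsv"), p("assembled.tsv"),
    function() {
      net <- read_edge_list(p("assembled.tsv"))
      curve <- pr_eval(net, bundle$corpus, config$pr_cutoffs)
      out <- as_tibble(curve)
      readr::write_tsv(out, p("pr_curve.tsv"), progress = FALSE)
      jsonlite::write_json(list(pr_auc = pr_auc(curve)), p("pr_auc.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  )

  summary <- list(seed = config$seed, skipped_stages = skipped)
  if (file.exists(p("selected_features.tsv"))) {
    sel <- readr::read_tsv(p("selected_features.tsv"), show_col_types = FALSE)
    summary$n_features <- nrow(sel)
    summary$n_selected <- sum(sel$selected)
  }
  if (file.exists(p("predicted.tsv"))) {
    summary$n_predicted <- n_edges(read_edge_list(p("predicted.tsv")))
  }
  if (file.exists(p("assembly_report.tsv"))) {
    rep <- readr::read_tsv(p("assembly_report.tsv"), show_col_types = FALSE)
    summary$n_assembled <- rep$n_total
  }
  if (file.exists(p("gsla_report.tsv"))) {
    rep <- readr::read_tsv(p("gsla_report.tsv"),
      comment = "#", show_col_types = FALSE
    )
    summary$gsla_sets_reported <- sum(rep$passes_q1 & rep$passes_q2)
  }
  if (file.exists(p("pr_auc.json"))) {
    summary$pr_auc <- jsonlite::read_json(p("pr_auc.json"))$pr_auc
  }
  writeable <- summary
  writeable$skipped_stages <- NULL
  jsonlite::write_json(writeable, p("summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(summary)
}
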