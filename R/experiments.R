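#' Configuration for an end-to-end experiment
#'
#' Single seeded configuration driving generate -> label -> train ->
#' evaluate, and the weak-data-proportion ablation.
#'
#' @param task `"activity"` or `"diet"`.
#' @param n_sentences Size of the generated training-side corpus.
#' @param lexicon_profile `"extended"` (default) or `"strict"` rule lexicon
#'   for weak labeling.
#' @param models Character vector of classifier families (roster), or a
#'   named list mixing family names and plugin constructors
#'   `function(texts, labels, seed)` returning an object with a
#'   `predict(object, texts)` method.
#' @param split A [split_spec()] (90/10 split, seeds 24/48/128 by default).
#' @param ablation_fractions Ascending fractions in (0, 1] of the weak pool
#'   used by [run_ablation()] (default 0.1, 0.3, 0.5, 1).
#' @param weak_label_noise_rate Symmetric flip rate applied to the weak
#'   labels after rule labeling (default 0).
#' @param gsc_size Size of the gold-standard stand-in used for evaluation.
#' @param gsc_class_counts Optional exact class counts for the stand-in
#'   (e.g. the published 78/122 activity composition); default mirrors the
#'   corpus class mixture.
#' @param out_of_lexicon_fraction Paraphrase fraction in the training-side
#'   corpus (default 0).
#' @param gsc_out_of_lexicon_fraction Paraphrase fraction in the stand-in
#'   (default 0).
#' @param keyword_profile Generator keyword pool (default `"strict"`).
#' @param seed Global integer seed for corpus generation and noise.
#' @param out_dir Optional run directory; when given, labels, reports,
#'   manifest and logs are written there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(task = "activity",
                              n_sentences = 2000L,
                              lexicon_profile = c("extended", "strict"),
                              models = c("logistic_regression", "svm_linear",
                                         "random_forest"),
                              split = split_spec(),
                              ablation_fractions = c(0.1, 0.3, 0.5, 1),
                              weak_label_noise_rate = 0,
                              gsc_size = 500L,
                              gsc_class_counts = NULL,
                              out_of_lexicon_fraction = 0,
                              gsc_out_of_lexicon_fraction = 0,
                              keyword_profile = "strict",
                              seed = 1L,
                              out_dir = NULL) {
  task <- match.arg(task, c("activity", "diet"))
  lexicon_profile <- match.arg(lexicon_profile)
  stopifnot(length(models) >= 1L,
            all(ablation_fractions > 0), all(ablation_fractions <= 1),
            !is.unsorted(ablation_fractions))
  if (is.character(models)) {
    nms <- names(models)
    if (is.null(nms)) {
      nms <- unname(models)
    } else {
      nms[!nzchar(nms)] <- models[!nzchar(nms)]
    }
    models <- stats::setNames(as.list(unname(models)), nms)
  }
  stopifnot(!is.null(names(models)), all(nzchar(names(models))))
  structure(
    list(task = task, n_sentences = as.integer(n_sentences),
         lexicon_profile = lexicon_profile, models = models, split = split,
         ablation_fractions = ablation_fractions,
         weak_label_noise_rate = weak_label_noise_rate,
         gsc_size = as.integer(gsc_size),
         gsc_class_counts = gsc_class_counts,
         out_of_lexicon_fraction = out_of_lexicon_fraction,
         gsc_out_of_lexicon_fraction = gsc_out_of_lexicon_fraction,
         keyword_profile = keyword_profile,
         seed = as.integer(seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

new_run_log <- function(config) {
  env <- new.env(parent = emptyenv())
  env$events <- list()
  env$hash <- config_hash(config)
  env
}

log_event <- function(log, stage, message, seed = NA_integer_) {
  log$events[[length(log$events) + 1L]] <- list(
    stage = stage, message = message, seed = seed, config_hash = log$hash
  )
  invisible(NULL)
}

fit_roster_model <- function(spec, texts, labels, seed) {
  if (is.character(spec)) {
    train_text_classifier(texts, labels, family = spec, seed = seed)
  } else if (is.function(spec)) {
    spec(texts, labels, seed)
  } else {
    stop("roster entries must be family names or constructor functions",
         call. = FALSE)
  }
}

# Shared stages 1-3: generate the corpus, weak-label it, apply optional
# label noise, and build the held-out gold-standard stand-in.
prepare_pipeline_data <- function(config, log) {
  gen <- generator_config(
    task = config$task, n_sentences = config$n_sentences,
    out_of_lexicon_fraction = config$out_of_lexicon_fraction,
    keyword_profile = config$keyword_profile,
    template_split = "train", seed = config$seed
  )
  corpus <- generate_corpus(gen)
  log_event(log, "generate", paste("generated", nrow(corpus), "sentences"),
            config$seed)
  lex <- default_lexicon(config$task, config$lexicon_profile)
  labeled <- label_corpus(corpus, lex)
  log_event(log, "label", paste(nrow(labeled$labels), "labeled,",
                                nrow(labeled$excluded), "excluded"))
  pool <- labeled$labels[, c("sentence_id", "text", "label")]
  if (config$weak_label_noise_rate > 0) {
    noisy <- derive_weak_labels(
      tibble::tibble(task = config$task, gold_label = pool$label),
      epsilon = config$weak_label_noise_rate, seed = config$seed + 1L
    )
    pool$label <- noisy$weak_label
    log_event(log, "label", paste("flipped", sum(noisy$flipped),
                                  "weak labels (noise rate",
                                  config$weak_label_noise_rate, ")"))
  }
  gsc <- make_gsc_standin(
    config$task, n = config$gsc_size, class_counts = config$gsc_class_counts,
    seed = config$seed + 2L,
    out_of_lexicon_fraction = config$gsc_out_of_lexicon_fraction,
    keyword_profile = config$keyword_profile
  )
  corp_tmpl <- unique(corpus$template_id)
  if (length(intersect(corp_tmpl, unique(gsc$template_id))) ||
      length(intersect(corpus$note_id, gsc$note_id))) {
    stop("training corpus and GSC stand-in share templates or notes",
         call. = FALSE)
  }
  log_event(log, "gsc", paste("stand-in of", nrow(gsc), "sentences"))
  list(corpus = corpus, lexicon = lex, pool = pool, gsc = gsc)
}

#' Run the end-to-end weak-supervision pipeline
#'
#' Stages: (1) generate the synthetic corpus; (2) weak-label it with the
#' rule lexicon (plus optional label noise); (3) build the template-disjoint
#' gold-standard stand-in; (4) for each run seed, split the weak pool 90/10
#' and train every roster model on the training part; (5) evaluate all
#' models (and the rule labeler itself) on the stand-in and average the
#' metrics over seeds. Deterministic given the config.
#'
#' @param config An [experiment_config()].
#' @return A list of class `pipeline_result`: `config`, `config_hash`,
#'   `reports` (named list of seed-averaged `eval_report`s, including
#'   `rule_based`), `table` (comparison tibble), `pool_size`,
#'   `excluded` count, `log` (list of events), and `paths` when `out_dir`
#'   was set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log <- new_run_log(config)
  data <- prepare_pipeline_data(config, log)
  class_set <- task_classes(config$task)
  seeds <- config$split$seeds
  per_seed <- lapply(seeds, function(sd) {
    parts <- split_train_eval(data$pool, config$split$train_fraction, sd)
    log_event(log, "train", paste("split", nrow(parts$train), "/",
                                  nrow(parts$eval)), sd)
    fits <- lapply(config$models, fit_roster_model,
                   texts = parts$train$text, labels = parts$train$label,
                   seed = sd)
    ev <- evaluate_on_gsc(fits, data$gsc, class_set,
                          train_texts = parts$train$text)
    for (nm in names(ev$reports)) ev$reports[[nm]]$provenance$seed <- sd
    log_event(log, "evaluate", "evaluated roster on GSC stand-in", sd)
    ev$reports
  })
  reports <- lapply(names(config$models), function(nm) {
    average_over_seeds(lapply(per_seed, `[[`, nm))
  })
  names(reports) <- names(config$models)
  rule_ev <- evaluate_on_gsc(list(rule_based = rule_classifier(data$lexicon)),
                             data$gsc, class_set)
  reports$rule_based <- rule_ev$reports$rule_based
  tab <- tibble::tibble(
    model = names(reports),
    precision = vapply(reports, function(r) r$weighted_avg[["precision"]], 0),
    recall = vapply(reports, function(r) r$weighted_avg[["recall"]], 0),
    f1 = vapply(reports, function(r) r$weighted_avg[["f1"]], 0)
  )
  for (col in c("precision", "recall", "f1")) {
    tab[[paste0("best_", col)]] <- tab[[col]] == max(tab[[col]])
  }
  result <- structure(
    list(config = config, config_hash = log$hash, reports = reports,
         table = tab, pool_size = nrow(data$pool),
         excluded = config$n_sentences - nrow(data$pool),
         log = log$events),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    result$paths <- write_run_artifacts(config, data, result)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$config$task, "| pool:", x$pool_size,
      "| hash:", substr(x$config_hash, 1, 8), "\n")
  print(as.data.frame(x$table[, 1:4]), row.names = FALSE, digits = 3)
  invisible(x)
}

write_run_artifacts <- function(config, data, result) {
  dir <- config$out_dir
  for (sub in c("labels", "reports", "logs")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  paths <- list(
    manifest = file.path(dir, "manifest.json"),
    labels = file.path(dir, "labels", "weak_labels.jsonl"),
    report = file.path(dir, "reports", "report.json"),
    log = file.path(dir, "logs", "events.jsonl")
  )
  jsonlite::write_json(
    list(task = config$task, config_hash = result$config_hash,
         n_sentences = config$n_sentences, pool_size = result$pool_size,
         seeds = config$split$seeds),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE
  )
  write_jsonl(data$pool, paths$labels)
  report_json <- lapply(result$reports, function(r) {
    list(per_class = r$per_class, weighted_avg = as.list(r$weighted_avg),
         macro_avg = as.list(r$macro_avg), accuracy = r$accuracy,
         n_eval = r$n_eval)
  })
  jsonlite::write_json(report_json, paths$report, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_jsonl(do.call(rbind, lapply(result$log, function(e)
    data.frame(stage = e$stage, message = e$message,
               seed = e$seed, config_hash = e$config_hash))), paths$log)
  paths
}

#' Weak-data-proportion ablation
#'
#' Fixes the weak-labeled pool, then for each fraction trains every roster
#' model on a nested seeded subsample of each run's training split (the 10%
#' subsample is a subset of the 30% subsample, and so on, so curves reflect
#' data quantity rather than resampling variance). The evaluation stand-in
#' is held constant across fractions; metrics are averaged over the run
#' seeds.
#'
#' @param config An [experiment_config()]; `ablation_fractions` gives the
#'   proportions of the training split used.
#' @return A list of class `ablation_result`: `curve` (tibble with one row
#'   per model x fraction: weighted precision/recall/F1 and `n_train`),
#'   `reports` (nested list), `subsample_ids` (per seed, per fraction;
#'   demonstrates nesting), `gsc_fingerprint`, `config_hash`.
#' @export
run_ablation <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log <- new_run_log(config)
  data <- prepare_pipeline_data(config, log)
  class_set <- task_classes(config$task)
  fractions <- config$ablation_fractions
  gsc_fp <- rlang::hash(data$gsc)
  seeds <- config$split$seeds
  per_seed <- lapply(seeds, function(sd) {
    parts <- split_train_eval(data$pool, config$split$train_fraction, sd)
    n_tr <- nrow(parts$train)
    order_idx <- withr::with_seed(sd, sample.int(n_tr))
    sub_ids <- list()
    frac_reports <- lapply(fractions, function(f) {
      take <- order_idx[seq_len(ceiling(f * n_tr))]
      sub <- parts$train[take, , drop = FALSE]
      if (length(unique(sub$label)) < 2L) {
        stop("subsample at fraction ", f, " contains fewer than 2 classes",
             call. = FALSE)
      }
      sub_ids[[as.character(f)]] <<- sub$sentence_id
      fits <- lapply(config$models, fit_roster_model,
                     texts = sub$text, labels = sub$label, seed = sd)
      stopifnot(identical(rlang::hash(data$gsc), gsc_fp))
      ev <- evaluate_on_gsc(fits, data$gsc, class_set,
                            train_texts = sub$text)
      log_event(log, "ablate", paste0("fraction ", f, ": trained on ",
                                      nrow(sub), " sentences"), sd)
      lapply(ev$reports, function(r) { r$provenance$seed <- sd; r })
    })
    names(frac_reports) <- as.character(fractions)
    list(reports = frac_reports, sub_ids = sub_ids,
         n_train = vapply(fractions, function(f) ceiling(f * n_tr), 0))
  })
  rows <- list()
  reports <- list()
  for (f in as.character(fractions)) {
    reports[[f]] <- lapply(names(config$models), function(nm) {
      average_over_seeds(lapply(per_seed, function(ps) ps$reports[[f]][[nm]]))
    })
    names(reports[[f]]) <- names(config$models)
    for (nm in names(config$models)) {
      r <- reports[[f]][[nm]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = nm, fraction = as.numeric(f),
        precision = r$weighted_avg[["precision"]],
        recall = r$weighted_avg[["recall"]],
        f1 = r$weighted_avg[["f1"]],
        n_train = mean(vapply(per_seed, function(ps)
          ps$n_train[match(as.numeric(f), fractions)], 0))
      )
    }
  }
  structure(
    list(curve = do.call(rbind, rows), reports = reports,
         subsample_ids = lapply(per_seed, `[[`, "sub_ids"),
         gsc_fingerprint = gsc_fp, config_hash = log$hash,
         log = log$events),
    class = "ablation_result"
  )
}
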