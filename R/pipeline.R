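#' Hash an R object (MD5 of its canonical JSON form)
#'
#' Used to stamp every pipeline output with the configuration that produced
#' it, so artifacts are traceable to a run.
#'
#' @param x a serializable R object.
#' @return 32-character MD5 hex string.
#' @export
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Build a pipeline run configuration
#'
#' Defaults merged with an optional YAML file and with explicit overrides
#' (highest precedence). Fields: `seed`; `image` (height, width, noise_sd);
#' `rubric` (visibility_threshold, uniform_threshold); `training` (enabled,
#' hidden_size, epochs, learning_rate, batch_size, n_per_score); `images`
#' (materialize per-patient PNGs); `cohort` (NULL = the default reported
#' score distributions, or a `cohort_spec()`-shaped list); `out_dir`.
#'
#' @param path optional YAML config file.
#' @param ... named overrides of top-level fields (nested lists are merged).
#' @return a `run_config` list including its own `config_hash`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    out_dir = "elastoscore_run",
    images = FALSE,
    image = list(height = 64L, width = 64L, noise_sd = 0),
    rubric = list(visibility_threshold = 0.01, uniform_threshold = 0.95),
    training = list(enabled = FALSE, hidden_size = 8L, epochs = 200L,
                    learning_rate = 2, batch_size = 5L, n_per_score = 40L),
    cohort = NULL)
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        merge_into(base[[nm]], new[[nm]])
      } else new[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  cfg <- merge_into(cfg, list(...))
  # the hash covers everything that shapes the outputs' content; the output
  # location does not, so moving a run does not change its stamp
  cfg$config_hash <- hash_object(cfg[setdiff(names(cfg),
                                             c("config_hash", "out_dir"))])
  structure(cfg, class = "run_config")
}

spec_from_config <- function(cfg) {
  if (is.null(cfg$cohort)) return(default_cohort_spec())
  if (inherits(cfg$cohort, "cohort_spec")) return(cfg$cohort)
  cohort_spec(cfg$cohort$arms, printed_totals = cfg$cohort$printed_totals)
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

log_stage <- function(con, stage, detail) {
  line <- sprintf("[%s] %-9s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  detail)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(NULL)
}

#' Run the full elastogram-scoring pipeline
#'
#' Orchestrates simulate -> (segment -> score) -> (train -> predict) ->
#' analyze under one seed: generates the synthetic cohort, optionally
#' materializes per-patient elastogram PNGs with label maps and rubric
#' scores, optionally trains the LSTM scorer on a dedicated synthetic
#' training set and records its agreement with the rubric, and writes the
#' cohort summary. Re-running with the same configuration overwrites the
#' run directory with identical content; every output carries the config
#' hash.
#'
#' Outputs under `config$out_dir`: `scores.csv` (long patient scores),
#' `summary.csv`, `report.json` (totals, mean changes, audit, ANOVA, any
#' scorer agreement), `run.log`, and when enabled `images/*.png`,
#' `labels/*.png`, `image_scores.csv`, `model.json`.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly (with `paths` of written artifacts).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  hash <- config$config_hash
  t0 <- Sys.time()
  ok <- FALSE
  invalid_marker <- file.path(config$out_dir, "INVALID")
  file.create(invalid_marker)
  on.exit({
    if (ok) unlink(invalid_marker) else
      writeLines("run aborted before completion; outputs are partial",
                 invalid_marker)
  }, add = TRUE)

  stage <- "simulate"
  report <- tryCatch({
    spec <- spec_from_config(config)
    records <- generate_cohort(spec, rng_seed = config$seed,
                               images = isTRUE(config$images),
                               height = config$image$height,
                               width = config$image$width,
                               noise_sd = config$image$noise_sd)
    log_stage(logf, stage, sprintf("%d patients in %d arms", nrow(records),
                                   length(unique(records$arm))))
    scores_path <- file.path(config$out_dir, "scores.csv")
    long <- rbind(
      data.frame(patient_id = records$patient_id, arm = records$arm,
                 timepoint = "pre", score = records$score_pre),
      data.frame(patient_id = records$patient_id, arm = records$arm,
                 timepoint = "post", score = records$score_post))
    write_stamped_csv(long[order(long$patient_id), ], scores_path, hash)

    image_scores <- NULL
    if (isTRUE(config$images)) {
      stage <- "segment/score"
      imgs <- attr(records, "images")
      dir.create(file.path(config$out_dir, "images"), showWarnings = FALSE)
      dir.create(file.path(config$out_dir, "labels"), showWarnings = FALSE)
      image_scores <- data.frame(key = names(imgs),
                                 rubric_score = NA_integer_)
      for (k in seq_along(imgs)) {
        key <- names(imgs)[k]
        write_elastogram(imgs[[k]],
                         file.path(config$out_dir, "images",
                                   paste0(key, ".png")))
        labels <- classify_pixels(imgs[[k]])
        write_label_map(labels, file.path(config$out_dir, "labels",
                                          paste0(key, ".png")))
        image_scores$rubric_score[k] <- score_composition(
          compute_composition(labels),
          visibility_threshold = config$rubric$visibility_threshold,
          uniform_threshold = config$rubric$uniform_threshold)
      }
      write_stamped_csv(image_scores,
                        file.path(config$out_dir, "image_scores.csv"), hash)
      log_stage(logf, stage, sprintf("%d images scored", length(imgs)))
    }

    scorer_report <- NULL
    if (isTRUE(config$training$enabled)) {
      stage <- "train"
      tr <- config$training
      train_set <- scored_image_set(tr$n_per_score,
                                    noise_sd = config$image$noise_sd,
                                    height = config$image$height,
                                    width = config$image$width,
                                    rng_seed = child_seed(config$seed, 11L))
      model <- train_scorer(train_set$images, train_set$scores,
                            hidden_size = tr$hidden_size,
                            epochs = tr$epochs,
                            learning_rate = tr$learning_rate,
                            batch_size = tr$batch_size,
                            rng_seed = config$seed)
      write_scorer_json(model, file.path(config$out_dir, "model.json"))
      stage <- "predict"
      test_set <- scored_image_set(20L, noise_sd = config$image$noise_sd,
                                   height = config$image$height,
                                   width = config$image$width,
                                   rng_seed = child_seed(config$seed, 12L))
      pred <- vapply(test_set$images, function(im) predict_score(model, im),
                     integer(1))
      ct <- score_confusion(pred, test_set$scores)
      scorer_report <- list(final_loss = model$loss[length(model$loss)],
                            holdout_n = length(pred),
                            holdout_agreement = accuracy(ct))
      log_stage(logf, stage,
                sprintf("holdout agreement with rubric: %.3f",
                        scorer_report$holdout_agreement))
    }

    stage <- "analyze"
    summ <- summarize_cohort(records, spec$printed_totals)
    write_stamped_csv(summ$groups, file.path(config$out_dir, "summary.csv"),
                      hash)
    comparison <- if (length(unique(arm_group(records$arm))) >= 2L) {
      compare_groups(records)
    } else NULL
    report <- list(
      config_hash = hash,
      seed = config$seed,
      groups = summ$groups,
      audit = summ$audit,
      anova = comparison[c("means", "F", "df", "p_value", "significant")],
      scorer = scorer_report,
      paths = list(out_dir = config$out_dir, scores = scores_path))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE,
                         pretty = TRUE)
    log_stage(logf, stage,
              sprintf("done in %.1fs",
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    report
  }, error = function(e) {
    log_stage(logf, stage, paste("FAILED:", conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  ok <- TRUE
  invisible(report)
}

#' Generate a balanced set of rubric-scored synthetic elastograms
#'
#' Convenience builder for training / evaluation sets: `n_per_score` images
#' per score 1..5, each from [composition_for_score()] and
#' [generate_elastogram()] with per-image child seeds, labeled with its
#' generating score.
#'
#' @param n_per_score images per score class.
#' @param noise_sd,height,width image parameters.
#' @param rng_seed integer seed.
#' @return list with `images` (list of [elastogram()]) and `scores`
#'   (integer vector).
#' @export
scored_image_set <- function(n_per_score, noise_sd = 0, height = 64L,
                             width = 64L, rng_seed = 1L) {
  scores <- rep(1:5, each = n_per_score)
  images <- vector("list", length(scores))
  for (k in seq_along(scores)) {
    cs <- child_seed(rng_seed, k)
    comp <- composition_for_score(scores[k], rng_seed = cs)
    images[[k]] <- generate_elastogram(comp, height, width, noise_sd,
                                       rng_seed = cs)
  }
  list(images = images, scores = scores)
}
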