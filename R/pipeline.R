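# File formats, configuration and the end-to-end pipeline.

#' Read an RR-interval series from a text file
#'
#' Expects one positive interval in milliseconds per line. Subject and stage
#' labels are parsed from filenames of the form `subj{S}_stage{T}.rr` when
#' present. Non-numeric lines are reported with their line number; intervals
#' outside the 300-2000 ms plausibility window are rejected by name.
#'
#' @param path path to a `.rr` text file.
#' @return An [RRISeries-class].
#' @export
readRRI <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty RR file: %s", path), call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stop(sprintf("non-numeric RR value at line %d of %s: '%s'",
                 which(is.na(vals))[1], path, lines[which(is.na(vals))[1]]),
         call. = FALSE)
  bad <- which(vals < 300 | vals > 2000)
  if (length(bad))
    stop(sprintf(paste0("interval plausibility guard: line %d of %s has ",
                        "%.1f ms (allowed 300-2000 ms)"),
                 bad[1], path, vals[bad[1]]), call. = FALSE)
  m <- regmatches(basename(path),
                  regexec("subj([0-9]+)_stage([0-9]+)", basename(path)))[[1]]
  if (length(m) == 3)
    RRISeries(vals, subjectId = paste0("subj", m[2]), stage = as.integer(m[3]))
  else RRISeries(vals)
}

#' Write an RR-interval series to a text file
#'
#' One interval per line, milliseconds, full double precision. Round-trips
#' exactly through [readRRI()].
#'
#' @param series an [RRISeries-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeRRI <- function(series, path) {
  stopifnot(is(series, "RRISeries"))
  writeLines(format(series@intervals, digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' One global seed deterministically derives the seeds of every stage
#' (cohort simulation, clustering restarts, network initialization and the
#' cross-validation partition), so a pipeline run is reproducible from
#' (config, seed) alone.
#'
#' @param cohort a [protocolConfig()] (its own seed is overridden by `seed`).
#' @param k number of fatigue clusters (default 5).
#' @param replicates K-means restarts (default 10).
#' @param kRange candidate K values scanned by the silhouette selection.
#' @param train a [trainConfig()].
#' @param folds cross-validation folds (default 5).
#' @param nTest held-out samples of the single train/test split (default 4,
#'   the 19:2 ratio on 42 samples).
#' @param seed the global seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohort = protocolConfig(), k = 5, replicates = 10,
                           kRange = 2:10, train = trainConfig(), folds = 5,
                           nTest = 4, seed = 1) {
  assertScalarNumber(k, "k", lower = 2, integer = TRUE)
  assertScalarNumber(replicates, "replicates", lower = 1, integer = TRUE)
  assertScalarNumber(folds, "folds", lower = 2, integer = TRUE)
  assertScalarNumber(nTest, "nTest", lower = 1, integer = TRUE)
  assertScalarNumber(seed, "seed", integer = TRUE)
  structure(list(cohort = cohort, k = as.integer(k),
                 replicates = as.integer(replicates),
                 kRange = as.integer(kRange), train = train,
                 folds = as.integer(folds), nTest = as.integer(nTest),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys (all optional): `seed`, `k`, `replicates`,
#' `k_range` (two-element lo/hi), `folds`, `n_test`, plus nested `cohort`
#' (`n_subjects`, `n_stages`, `stage_minutes`, `start_speed`,
#' `speed_increment`, `noise_sd` with `borg`/`rt`/`hr`/`sdnn`) and `train`
#' (`learning_rate`, `max_epochs`, `goal_mse`, `hidden_nodes`). Anything
#' omitted keeps the package default.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  yml <- yaml::read_yaml(path)
  if (is.null(yml)) yml <- list()
  pick <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]
  co <- yml$cohort
  noiseDefault <- list(borg = 0.6, rt = 10, hr = 2, sdnn = 3)
  noise <- utils::modifyList(noiseDefault, as.list(pick(co, "noise_sd", list())))
  cohort <- protocolConfig(
    nSubjects = pick(co, "n_subjects", 6), nStages = pick(co, "n_stages", 7),
    stageMinutes = pick(co, "stage_minutes", 4),
    startSpeed = pick(co, "start_speed", 4),
    speedIncrement = pick(co, "speed_increment", 1),
    seed = pick(yml, "seed", 1), noiseSd = noise)
  tr <- yml$train
  train <- trainConfig(
    learningRate = pick(tr, "learning_rate", 0.01),
    maxEpochs = pick(tr, "max_epochs", 1000),
    goalMse = pick(tr, "goal_mse", 1e-5),
    hiddenNodes = pick(tr, "hidden_nodes", 8))
  kr <- pick(yml, "k_range", c(2, 10))
  pipelineConfig(cohort = cohort, k = pick(yml, "k", 5),
                 replicates = pick(yml, "replicates", 10),
                 kRange = seq(kr[1], kr[2]),
                 train = train, folds = pick(yml, "folds", 5),
                 nTest = pick(yml, "n_test", 4), seed = pick(yml, "seed", 1))
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full fatigue pipeline
#'
#' Simulates (or loads) a cohort, extracts the ten HRV features per
#' subject-stage, derives entropy weights and the composite fatigue index
#' from the normalized reaction times and Borg ratings, scans K by mean
#' silhouette, clusters at `config$k`, extracts and weight-combines the
#' per-cluster thresholds, consolidates them into the final grading, trains
#' the 10-8-1 network on the features with the composite index as target,
#' and evaluates it on a held-out split and by cross-validation.
#'
#' Artifacts written to `outDir`: `features.csv`, `weights.json`,
#' `indexed.csv`, `thresholds.json`, `model.json` and `report.json`. Every
#' artifact embeds the seed (and the report the full configuration), and a
#' rerun with the same configuration is byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @param cohort optionally, a pre-built [FatigueCohort-class] to use instead
#'   of simulating one.
#' @return Invisibly, the report list.
#' @examples
#' \donttest{
#' rep <- runPipeline(pipelineConfig(seed = 1), outDir = tempfile())
#' rep$evaluation$cv$pooled$r2
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, cohort = NULL) {
  if (!inherits(config, "PipelineConfig"))
    stop("'config' must come from pipelineConfig()", call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stageFail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  logStage <- function(...) message(sprintf("[hrvFatigue seed %d] ", config$seed),
                                    sprintf(...))

  # --- cohort -------------------------------------------------------------
  if (is.null(cohort)) {
    cc <- config$cohort
    cc$seed <- deriveSeed(config$seed, 1)
    class(cc) <- "ProtocolConfig"
    cohort <- stageFail("simulate", simulateCohort(cc))
  }
  obs <- observations(cohort)
  n <- nrow(obs)
  logStage("simulate: %d observations", n)

  # --- features -----------------------------------------------------------
  se <- stageFail("features", cohortFeatures(cohort))
  feat <- t(SummarizedExperiment::assay(se, "hrv"))
  logStage("features: %d x %d feature matrix", nrow(feat), ncol(feat))
  featDf <- data.frame(subject = obs$subject, stage = obs$stage, feat)
  utils::write.csv(format(featDf, digits = 15, trim = TRUE),
                   file.path(outDir, "features.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- entropy weights and composite index --------------------------------
  raw <- cbind(reaction_time = obs$rt_ms, borg = as.numeric(obs$borg))
  norm <- stageFail("index", minmaxNormalize(raw))
  ew <- stageFail("index", entropyWeights(shiftFeatures(norm)))
  fIdx <- compositeIndex(featureValues(norm)[, "reaction_time"],
                         featureValues(norm)[, "borg"], weights = ew)
  logStage("index: weights %s", paste(sprintf("%s=%.3f", names(ew@w), ew@w),
                                        collapse = ", "))
  indexed <- data.frame(obs,
                        reaction_time_norm = featureValues(norm)[, "reaction_time"],
                        borg_norm = featureValues(norm)[, "borg"],
                        F = fIdx)
  writeJson(list(seed = config$seed, n = ew@n,
                 entropy = as.list(ew@e), difference = as.list(ew@g),
                 weights = as.list(ew@w)),
            file.path(outDir, "weights.json"))

  # --- grading ------------------------------------------------------------
  silScan <- stageFail("grade",
    selectK(featureValues(norm), kRange = config$kRange,
            replicates = config$replicates, seed = deriveSeed(config$seed, 2)))
  km <- stageFail("grade",
    kmeansFit(featureValues(norm), config$k, replicates = config$replicates,
              seed = deriveSeed(config$seed, 3)))
  gt <- stageFail("grade",
    clusterThresholds(featureValues(norm), clusterLabels(km),
                      weights = featureWeights(ew)))
  gt <- weightedThresholds(gt, ew)
  bands5 <- fatigueBands(gt)
  gt3 <- consolidateLevels(gt)
  logStage("grade: best K by silhouette %d; %d consolidated levels",
           silScan$bestK, nrow(fatigueBands(gt3)))
  breaks <- c(0, fatigueBands(gt3)[-1, "lo"], 1)
  indexed$level <- classifyLevel(indexed$F, breaks = sort(breaks))
  utils::write.csv(format(indexed, digits = 15, trim = TRUE),
                   file.path(outDir, "indexed.csv"),
                   row.names = FALSE, quote = FALSE)
  asBands <- function(m) lapply(seq_len(nrow(m)), function(i)
    list(lo = m[i, 1], hi = m[i, 2]))
  writeJson(list(seed = config$seed, k = config$k,
                 silhouette_by_k = silScan$table, best_k = silScan$bestK,
                 levels5 = list(
                   reaction_time = asBands(levelIntervals(gt)$reaction_time),
                   borg = asBands(levelIntervals(gt)$borg),
                   F = asBands(bands5)),
                 consolidated = asBands(fatigueBands(gt3)),
                 consolidation_map = consolidationMap(gt3)),
            file.path(outDir, "thresholds.json"))

  # --- predictor ----------------------------------------------------------
  cfg <- config$train
  cfg$seed <- deriveSeed(config$seed, 4)
  class(cfg) <- "TrainConfig"
  ho <- stageFail("train",
    holdoutEvaluate(feat, indexed$F, config = cfg, nTest = config$nTest,
                    seed = deriveSeed(config$seed, 5)))
  cv <- stageFail("train",
    crossValidate(feat, indexed$F, folds = config$folds, config = cfg,
                  seed = deriveSeed(config$seed, 6)))
  fit <- ho$model
  writeJson(list(seed = config$seed, structure = c(ncol(feat),
                                                   cfg$hiddenNodes, 1),
                 W1 = apply(fit@W1, 1, as.list), b1 = as.list(fit@b1),
                 W2 = as.list(as.vector(fit@W2)), b2 = fit@b2,
                 x_scale = fit@xScale, y_scale = fit@yScale,
                 epochs = length(fit@history) - 1,
                 final_mse = fit@history[length(fit@history)],
                 config = unclass(cfg)),
            file.path(outDir, "model.json"))
  logStage("train: holdout test r2 %.4f; CV pooled r2 %.4f",
           ho$test$r2, cv$pooled$r2)

  report <- list(
    seed = config$seed,
    config = list(cohort = unclass(config$cohort)[
                    c("nSubjects", "nStages", "stageMinutes", "startSpeed",
                      "speedIncrement", "noiseSd")],
                  k = config$k, replicates = config$replicates,
                  kRange = config$kRange, train = unclass(config$train),
                  folds = config$folds, nTest = config$nTest),
    n_observations = n,
    weights = as.list(ew@w),
    silhouette_by_k = silScan$table,
    best_k = silScan$bestK,
    consolidated_bands = asBands(fatigueBands(gt3)),
    consolidation_map = consolidationMap(gt3),
    evaluation = list(holdout = list(train = ho$train, test = ho$test),
                      cv = list(folds = cv$folds, mean = cv$mean,
                                pooled = cv$pooled))
  )
  writeJson(report, file.path(outDir, "report.json"))
  invisible(report)
}
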