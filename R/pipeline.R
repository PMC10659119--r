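#' Define an end-to-end variability experiment
#'
#' A plan names one or more corpus configurations, the datasets derived
#' from them (each a corpus name plus an optional [DatasetSpec-class] and
#' split options), a shared model configuration, a transfer matrix of
#' source -> target dataset pairs, and the seeds to repeat everything over.
#'
#' @param corpusConfigs named list of [CorpusConfig-class] objects.
#' @param datasets named list; each element a list with `corpus` (a name in
#'   `corpusConfigs`), optional `spec` (a [DatasetSpec-class]) and optional
#'   `holdoutLevel` (`"auto"`, `"project"` or `"file"`).
#' @param modelConfig an [RTModelConfig-class] shared by all models.
#' @param transfers data.frame with `source` and `target` dataset names
#'   (zero rows for none).
#' @param seeds nonempty integer vector; the whole experiment is repeated
#'   per seed.
#' @param mcRepeats MC-dropout repeats per model (0 disables).
#' @return a list of class `ExperimentPlan`.
#' @export
experimentPlan <- function(corpusConfigs, datasets, modelConfig,
                           transfers = data.frame(source = character(),
                                                  target = character()),
                           seeds = 1L, mcRepeats = 25L) {
  stopifnot(length(seeds) >= 1, length(corpusConfigs) >= 1,
            length(datasets) >= 1)
  for (nm in names(datasets)) {
    if (!datasets[[nm]]$corpus %in% names(corpusConfigs)) {
      stop("dataset '", nm, "' references undefined corpus '",
           datasets[[nm]]$corpus, "'")
    }
  }
  bad <- setdiff(c(transfers$source, transfers$target), names(datasets))
  if (length(bad)) {
    stop("transfer matrix references undefined dataset(s): ",
         paste(bad, collapse = ", "))
  }
  out <- list(corpusConfigs = corpusConfigs, datasets = datasets,
              modelConfig = modelConfig, transfers = transfers,
              seeds = as.integer(seeds), mcRepeats = as.integer(mcRepeats))
  class(out) <- "ExperimentPlan"
  out
}

#' A ready-made desk-scale experiment plan
#'
#' Two structurally identical multi-project corpora (differing only in
#' seed, hence in their project-level effects) with between-project noise
#' three times the within-project noise, a reduced model, and a transfer
#' from the first dataset to the second — the miniature of the
#' single-versus-multi-project cross-evaluation design.
#'
#' @param seed base seed.
#' @param nProjects,filesPerProject,peptidesPerFile corpus dimensions.
#' @param epochs training epochs.
#' @return an `ExperimentPlan`.
#' @export
deskScalePlan <- function(seed = 1L, nProjects = 8L,
                          filesPerProject = c(4L, 4L),
                          peptidesPerFile = c(300L, 300L), epochs = 25L) {
  mk <- function(s) corpusConfig(
    nProjects = nProjects, filesPerProject = filesPerProject,
    peptidesPerFile = peptidesPerFile, seed = s,
    sigmaProject = 3, sigmaFile = 1, spectraPerFile = 2L)
  experimentPlan(
    corpusConfigs = list(corpusA = mk(seed), corpusB = mk(seed + 5000L)),
    datasets = list(
      dsA = list(corpus = "corpusA", holdoutLevel = "file"),
      dsB = list(corpus = "corpusB", holdoutLevel = "file")),
    modelConfig = rtModelConfig(embeddingDim = 16L, recurrentUnits = 32L,
                                denseUnits = 64L, batchSize = 256L,
                                maxEpochs = epochs, patience = 10L,
                                seed = seed),
    transfers = data.frame(source = "dsA", target = "dsB",
                           stringsAsFactors = FALSE),
    seeds = seed)
}

.logLine <- function(logFile, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  cat(line, "\n", sep = "", file = logFile, append = TRUE)
}

#' Run an experiment plan end to end
#'
#' Per seed: simulate the corpora, build each dataset (modification filter,
#' effective-gradient normalization, stratified filtering, hold-out and
#' sequence splits), train one model per dataset, cross-evaluate every
#' model on every dataset's hold-out test set, run the transfer matrix,
#' and estimate MC-dropout uncertainty on each model's own test set.
#' Everything is written under `outDir` (`corpora/`, `datasets/`,
#' `models/`, `metrics/`, `figures/`, plus `run.log`); any stage failure
#' aborts with the stage name, leaving earlier outputs in place. The whole
#' run is a deterministic function of the plan.
#'
#' @param plan an `ExperimentPlan`.
#' @param outDir output directory.
#' @param writeCorpora also persist the simulated corpora as text (can be
#'   large; default FALSE).
#' @param verbose log to console as well.
#' @return invisibly, a list with `metrics` (long data.frame: seed, model,
#'   dataset, split, metric columns, pretrained_from) and `uncertainty`.
#' @export
runExperiment <- function(plan, outDir, writeCorpora = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  for (d in c("", "corpora", "datasets", "models", "metrics", "figures")) {
    dir.create(file.path(outDir, d), showWarnings = FALSE, recursive = TRUE)
  }
  logFile <- file.path(outDir, "run.log")
  say <- function(...) {
    .logLine(logFile, ...)
    if (verbose) message(...)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      say("FAILED at stage '", name, "': ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs under ", outDir, ")", call. = FALSE)
    })
  }

  metricRows <- list()
  uncRows <- list()
  for (s in plan$seeds) {
    say("seed ", s)
    corpora <- stage(paste0("corpora[seed ", s, "]"), {
      lapply(plan$corpusConfigs, function(cfg) {
        cfg@seed <- cfg@seed + 7L * s
        simulateCorpus(cfg)
      })
    })
    if (writeCorpora) {
      for (nm in names(corpora)) {
        writeCorpus(corpora[[nm]],
                    file.path(outDir, "corpora", paste0(nm, "_seed", s)))
      }
    }
    bundles <- stage(paste0("datasets[seed ", s, "]"), {
      out <- list()
      for (nm in names(plan$datasets)) {
        d <- plan$datasets[[nm]]
        rec <- removeModified(corpusPeptides(corpora[[d$corpus]]))
        rec <- normalizeEffectiveGradient(rec)
        if (!is.null(d$spec)) {
          rec <- filterPeptides(rec, d$spec, corpusFiles(corpora[[d$corpus]]))
        }
        bundle <- buildSplitBundle(rec,
                                   holdoutLevel = d$holdoutLevel %||% "auto",
                                   seed = s, normalize = FALSE)
        writeSplitBundle(bundle, file.path(outDir, "datasets",
                                           paste0(nm, "_seed", s)))
        out[[nm]] <- bundle
      }
      out
    })
    models <- stage(paste0("training[seed ", s, "]"), {
      out <- list()
      for (nm in names(bundles)) {
        cfg <- plan$modelConfig
        cfg@seed <- cfg@seed + 13L * s
        model <- buildRTModel(cfg)
        model <- trainRTModel(model, trainSet(bundles[[nm]]),
                              validationSet(bundles[[nm]]), trainedOn = nm)
        writeRTModel(model, file.path(outDir, "models",
                                      paste0(nm, "_seed", s)))
        say("  trained ", nm, ": best val MSE ",
            signif(model@finalValLoss, 4))
        out[[nm]] <- model
      }
      out
    })
    stage(paste0("cross-evaluation[seed ", s, "]"), {
      for (mn in names(models)) {
        hist <- trainingHistory(models[[mn]])
        last <- hist[nrow(hist), ]
        metricRows[[length(metricRows) + 1]] <- cbind(
          data.frame(seed = s, model = mn, dataset = mn, split = "train",
                     pretrained_from = NA_character_),
          evaluateRt(predictRt(models[[mn]], trainSet(bundles[[mn]])),
                     trainSet(bundles[[mn]])$rt_normalized))
        metricRows[[length(metricRows) + 1]] <- cbind(
          data.frame(seed = s, model = mn, dataset = mn,
                     split = "validation",
                     pretrained_from = NA_character_),
          evaluateRt(predictRt(models[[mn]], validationSet(bundles[[mn]])),
                     validationSet(bundles[[mn]])$rt_normalized))
        for (dn in names(bundles)) {
          te <- testSet(bundles[[dn]])
          metricRows[[length(metricRows) + 1]] <- cbind(
            data.frame(seed = s, model = mn, dataset = dn, split = "test",
                       pretrained_from = NA_character_),
            evaluateRt(predictRt(models[[mn]], te), te$rt_normalized))
        }
      }
    })
    if (nrow(plan$transfers)) {
      stage(paste0("transfer[seed ", s, "]"), {
        for (k in seq_len(nrow(plan$transfers))) {
          src <- plan$transfers$source[k]
          tgt <- plan$transfers$target[k]
          tm <- transferRTModel(models[[src]], trainSet(bundles[[tgt]]),
                                validationSet(bundles[[tgt]]),
                                trainedOn = tgt)
          te <- testSet(bundles[[tgt]])
          metricRows[[length(metricRows) + 1]] <- cbind(
            data.frame(seed = s, model = paste0(src, "->", tgt),
                       dataset = tgt, split = "test",
                       pretrained_from = src),
            evaluateRt(predictRt(tm, te), te$rt_normalized))
          say("  transferred ", src, " -> ", tgt)
        }
      })
    }
    if (plan$mcRepeats > 0) {
      stage(paste0("uncertainty[seed ", s, "]"), {
        for (mn in names(models)) {
          est <- mcDropoutPredict(models[[mn]], testSet(bundles[[mn]]),
                                  nRepeats = plan$mcRepeats, seed = s + 31L)
          utils::write.csv(est, file.path(outDir, "metrics",
                                          sprintf("uncertainty_%s_seed%d.csv",
                                                  mn, s)),
                           row.names = FALSE)
          uncertaintyReport(est, file.path(outDir, "figures",
                                           sprintf("uncertainty_%s_seed%d.png",
                                                   mn, s)))
          uncRows[[length(uncRows) + 1]] <- cbind(
            data.frame(seed = s, model = mn), est)
        }
      })
    }
  }
  metrics <- do.call(rbind, metricRows)
  utils::write.csv(metrics, file.path(outDir, "metrics", "metrics_grid.csv"),
                   row.names = FALSE)
  metricGridReport(metrics, file.path(outDir, "figures"))
  say("done: ", nrow(metrics), " metric rows")
  invisible(list(metrics = metrics,
                 uncertainty = if (length(uncRows)) do.call(rbind, uncRows)))
}

#' Tables and figures from a metric grid
#'
#' Writes the long-format metric table and two grouped-bar figures: RTdelta
#' per model across train/validation/test splits, and fresh-versus-
#' transferred test RTdelta per dataset.
#'
#' @param metrics long metric data.frame from [runExperiment()].
#' @param outDir optional directory for the figure files.
#' @return list with `table` and ggplot objects `bySplit`, `transfer`.
#' @export
metricGridReport <- function(metrics, outDir = NULL) {
  stopifnot(nrow(metrics) >= 1)
  pSplit <- ggplot2::ggplot(
    metrics[is.na(metrics$pretrained_from), ],
    ggplot2::aes(x = model, y = rt_delta, fill = split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(y = "RTΔ (normalized gradient units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  tr <- metrics[metrics$split == "test", ]
  tr$origin <- ifelse(is.na(tr$pretrained_from), "fresh", "transferred")
  pTransfer <- ggplot2::ggplot(
    tr, ggplot2::aes(x = model, y = rt_delta, fill = origin)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dataset, scales = "free_x") +
    ggplot2::labs(y = "test RTΔ") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(file.path(outDir, "metrics_by_split.png"), pSplit,
                    width = 8, height = 5)
    ggplot2::ggsave(file.path(outDir, "transfer_comparison.png"), pTransfer,
                    width = 8, height = 5)
  }
  list(table = metrics, bySplit = pSplit, transfer = pTransfer)
}

#' Persist / load a trained model
#'
#' Writes `weights.rds` (the parameter list), `model_config.json` and
#' `history.csv`.
#'
#' @param model an [RTModel-class].
#' @param directory target directory.
#' @return invisibly, the directory.
#' @export
writeRTModel <- function(model, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@params, file.path(directory, "weights.rds"))
  cfg <- model@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  cfgList$vocab <- as.list(cfgList$vocab)
  jsonlite::write_json(
    c(cfgList, list(trained_on = model@trainedOn,
                    pretrained_from = model@pretrainedFrom,
                    final_val_loss = model@finalValLoss)),
    file.path(directory, "model_config.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  utils::write.csv(model@history, file.path(directory, "history.csv"),
                   row.names = FALSE)
  invisible(directory)
}

#' @rdname writeRTModel
#' @export
readRTModel <- function(directory) {
  cfgJson <- jsonlite::read_json(file.path(directory, "model_config.json"))
  config <- rtModelConfig(
    vocab = unlist(cfgJson$vocab), maxLength = cfgJson$maxLength,
    embeddingDim = cfgJson$embeddingDim,
    recurrentUnits = cfgJson$recurrentUnits,
    denseUnits = unlist(cfgJson$denseUnits),
    dropoutRate = cfgJson$dropoutRate, learningRate = cfgJson$learningRate,
    batchSize = cfgJson$batchSize, maxEpochs = cfgJson$maxEpochs,
    patience = cfgJson$patience, seed = cfgJson$seed)
  history <- utils::read.csv(file.path(directory, "history.csv"))
  new("RTModel", config = config,
      params = readRDS(file.path(directory, "weights.rds")),
      history = history,
      trainedOn = cfgJson$trained_on %||% NA_character_,
      pretrainedFrom = cfgJson$pretrained_from %||% NA_character_,
      finalValLoss = cfgJson$final_val_loss %||% NA_real_,
      trained = TRUE)
}
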