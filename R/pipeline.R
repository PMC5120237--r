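## End-to-end wiring: simulate a message world and pilot ratings, fit the
## recommender, run the two-arm trial, simulate follow-up, analyze. Every
## stage is seeded from the single run seed by fixed offsets and writes its
## artifacts to the output directory, so a rerun with the same configuration
## and seed is byte-identical and stages can be re-run individually.

#' Default pipeline configuration
#'
#' A demonstration-sized trial world: a 261-message library; a 300-user
#' pilot rating study (20 ratings each) in a two-dimensional latent
#' preference space with rating noise SD 0.5 and global offset 3.9 (daily
#' means then hover near the agreement threshold of 4, as in the trial this
#' emulates); a two-dimensional BPMF model; and a 120-participant cohort
#' block-randomized 7:3 in blocks of 10 rating 30 messages each.
#'
#' @return Nested named list with sections \code{library}, \code{pilot},
#'   \code{model}, \code{cohort}, \code{followup}, \code{analysis}.
#' @export
defaultPipelineConfig <- function() {
  list(
    library = list(nMessages = 261, stageProb = 0.4, peerProportion = 0.5,
                   motivationalProportion = 102 / 261,
                   behavioralProportion = 139 / 261),
    pilot = list(nUsers = 300, ratingsPerUser = 20, latentDim = 2,
                 factorScale = 0.8, noiseSd = 0.5, offset = 3.9),
    model = list(latentDim = 2, alpha = 2, nSamples = 30, burnIn = 20),
    cohort = list(nParticipants = 120, block = c(7, 3), nMessagesPerUser = 30,
                  followupRate = 0.79, armEffect = 0.25,
                  stageProbs = c(0.15, 0.45, 0.20, 0.10, 0.10)),
    followup = list(quitBase = 0.32, ladderUpBase = 0.30, influenceMu = 3.5,
                    influenceSd = 1),
    analysis = list(threshold = 4, windows = list(c(1, 12), c(13, 30)))
  )
}

#' Validate a pipeline configuration
#'
#' Checks the nested configuration against the default schema; unknown keys
#' (at either level) are rejected, and missing keys are filled from
#' [defaultPipelineConfig()].
#'
#' @param config Nested list (possibly partial).
#' @return The completed, validated configuration.
#' @export
validateRunConfig <- function(config = list()) {
  def <- defaultPipelineConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    def[[sec]] <- modifyList(def[[sec]], config[[sec]])
  }
  def
}

#' Run both arms of the messaging trial
#'
#' Every intervention participant is served by the recommender policy under
#' the fitted model; every comparison participant by the rule-based
#' stage-matched policy. Participants rate through a latent oracle built
#' from their true preference vector (intervention scores shifted by the
#' cohort's \code{prefShift}).
#'
#' @param cohort Result of [generateCohort()].
#' @param lib The [MessageLibrary-class] both arms draw from.
#' @param itemFactors True item factors of the simulated world (rownames =
#'   message ids).
#' @param model A fitted [BPMFFit-class] for the recommender arm.
#' @param offset,noiseSd The world's rating model.
#' @param nMessages Messages rated per participant (default 30).
#' @param seed Integer seed.
#' @return \code{data.frame} of session-log rows: user, arm, day, message,
#'   predicted, rating.
#' @export
runTrial <- function(cohort, lib, itemFactors, model, offset = 3, noiseSd = 0.5,
                     nMessages = 30, seed = 1) {
  part <- cohort$participants
  logs <- vector("list", nrow(part))
  for (i in seq_len(nrow(part))) {
    p <- part[i, ]
    policy <- if (p$arm == "INTERVENTION") perspectPolicy(model, seed + i)
      else ruleBasedPolicy(seed + 100000L + i)
    oracle <- latentRatingOracle(cohort$userFactors[p$user, ], itemFactors,
                                 offset = offset + p$prefShift,
                                 noiseSd = noiseSd, seed = seed + 200000L + i)
    state <- runSession(p$user, p$stage, policy, lib, oracle, n = nMessages)
    lg <- sessionLog(state)
    logs[[i]] <- data.frame(user = p$user, arm = p$arm, lg,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, logs)
}

## Strip a trialAnalysis object down to JSON-friendly plain structures.
analysisToList <- function(an) {
  tabList <- function(tab) list(counts = unname(apply(tab, 1, identity, simplify = FALSE)),
                                rows = rownames(tab), cols = colnames(tab))
  testList <- function(ts) if (is.null(ts)) NULL else
    list(statistic = ts$statistic, p = ts$p)
  out <- list(
    daysAgreed = list(
      INTERVENTION = an$daysAgreed$INTERVENTION,
      COMPARISON = an$daysAgreed$COMPARISON,
      table = tabList(an$daysAgreed$table),
      test = testList(an$daysAgreed$test)),
    windowTests = an$windowTests,
    dailySeries = lapply(an$dailySeries, function(s)
      list(day = s$day, mean = s$mean, n = s$n)))
  if (!is.null(an$quit))
    out$quit <- list(table = tabList(an$quit$table), test = testList(an$quit$test))
  if (!is.null(an$ladder))
    out$ladder <- list(table = tabList(an$ladder$table), test = testList(an$ladder$test))
  if (!is.null(an$influence))
    out$influence <- lapply(an$influence, function(q)
      list(table = tabList(q$table), test = testList(q$test)))
  if (!is.null(an$completers)) out$completers <- an$completers
  out
}

#' Run the full simulation-to-analysis pipeline
#'
#' Stages: \code{simulate} (library, pilot ratings, cohort), \code{fit}
#' (BPMF on the pilot), \code{sessions} (both trial arms), \code{followup}
#' (30-day outcomes), \code{analyze}. Stages not requested are loaded from
#' the artifacts of a previous run in \code{outDir}, so the pipeline is
#' re-entrant per stage. Every invocation writes its resolved configuration
#' and a manifest (seed, configuration hash, artifact list) next to the
#' outputs.
#'
#' @param config Pipeline configuration (see [validateRunConfig()]).
#' @param seed Integer run seed; per-stage seeds are derived by fixed offsets.
#' @param outDir Output directory (created if needed).
#' @param stages Character vector of stages to execute.
#' @param quiet Suppress the stage log on stderr.
#' @return Invisibly, a list with the analysis (class \code{"trialAnalysis"})
#'   and the artifact paths.
#' @export
runPipeline <- function(config = list(), seed = 1,
                        outDir = file.path(tempdir(), "perspectr-run"),
                        stages = c("simulate", "fit", "sessions", "followup",
                                   "analyze"),
                        quiet = FALSE) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[perspectr] ", sprintf(...))
  pathOf <- function(f) file.path(outDir, f)
  seeds <- list(library = seed + 11L, pilot = seed + 23L, model = seed + 37L,
                cohort = seed + 41L, sessions = seed + 53L, followup = seed + 67L)

  cfgPath <- pathOf("resolved_config.yaml")
  yaml::write_yaml(cfg, cfgPath)

  lib <- gen <- cohort <- model <- logs <- followup <- NULL
  if ("simulate" %in% stages) {
    say("simulate: library (%d messages), pilot (%d users), cohort (%d participants)",
        cfg$library$nMessages, cfg$pilot$nUsers, cfg$cohort$nParticipants)
    lib <- generateLibrary(cfg$library$nMessages,
                           tagProportions = c(MOTIVATIONAL_CONTENT = cfg$library$motivationalProportion,
                                              BEHAVIORAL_TREATMENT = cfg$library$behavioralProportion),
                           stageProb = cfg$library$stageProb,
                           peerProportion = cfg$library$peerProportion,
                           seed = seeds$library)
    writeMessageLibrary(lib, pathOf("library.csv"))
    gc0 <- generatorConfig(nUsers = cfg$pilot$nUsers,
                           nMessages = cfg$library$nMessages,
                           ratingsPerUser = cfg$pilot$ratingsPerUser,
                           latentDim = cfg$pilot$latentDim,
                           factorScale = cfg$pilot$factorScale,
                           noiseSd = cfg$pilot$noiseSd,
                           offset = cfg$pilot$offset, seed = seeds$pilot)
    gen <- generateRatings(gc0, lib)
    writeRatings(gen$data, pathOf("pilot_ratings.csv"))
    write.csv(data.frame(message = rownames(gen$itemFactors), gen$itemFactors),
              pathOf("item_factors_synthetic.csv"), row.names = FALSE)
    cc <- cohortConfig(nParticipants = cfg$cohort$nParticipants,
                       block = cfg$cohort$block,
                       nMessagesPerUser = cfg$cohort$nMessagesPerUser,
                       followupRate = cfg$cohort$followupRate,
                       armEffect = cfg$cohort$armEffect,
                       latentDim = cfg$pilot$latentDim,
                       factorScale = cfg$pilot$factorScale,
                       stageProbs = cfg$cohort$stageProbs, seed = seeds$cohort)
    cohort <- generateCohort(cc)
    write.csv(cohort$participants, pathOf("cohort.csv"), row.names = FALSE)
    write.csv(data.frame(user = rownames(cohort$userFactors), cohort$userFactors),
              pathOf("cohort_factors_synthetic.csv"), row.names = FALSE)
  }
  loadWorld <- function() {
    if (is.null(lib)) lib <<- readMessageLibrary(pathOf("library.csv"))
    if (is.null(gen)) {
      vf <- read.csv(pathOf("item_factors_synthetic.csv"), stringsAsFactors = FALSE)
      V <- as.matrix(vf[, -1, drop = FALSE]); rownames(V) <- vf$message
      gen <<- list(data = readRatings(pathOf("pilot_ratings.csv"),
                                      messageIds = messageIds(lib)),
                   itemFactors = V, offset = cfg$pilot$offset)
    }
    if (is.null(cohort)) {
      uf <- read.csv(pathOf("cohort_factors_synthetic.csv"), stringsAsFactors = FALSE)
      U <- as.matrix(uf[, -1, drop = FALSE]); rownames(U) <- uf$user
      cohort <<- list(participants = read.csv(pathOf("cohort.csv"),
                                              stringsAsFactors = FALSE),
                      userFactors = U)
    }
  }
  if ("fit" %in% stages) {
    loadWorld()
    say("fit: BPMF D=%d on %d pilot ratings", cfg$model$latentDim, nRatings(gen$data))
    model <- fitBPMF(gen$data, latentDim = cfg$model$latentDim,
                     alpha = cfg$model$alpha, nSamples = cfg$model$nSamples,
                     burnIn = cfg$model$burnIn, seed = seeds$model)
    saveBPMF(model, pathOf("model.json"))
  }
  if ("sessions" %in% stages) {
    loadWorld()
    if (is.null(model)) model <- readBPMF(pathOf("model.json"))
    say("sessions: %d participants x %d messages", nrow(cohort$participants),
        cfg$cohort$nMessagesPerUser)
    logs <- runTrial(cohort, lib, gen$itemFactors, model,
                     offset = cfg$pilot$offset, noiseSd = cfg$pilot$noiseSd,
                     nMessages = cfg$cohort$nMessagesPerUser,
                     seed = seeds$sessions)
    write.csv(logs, pathOf("session_logs.csv"), row.names = FALSE)
  }
  if ("followup" %in% stages) {
    loadWorld()
    say("followup: simulating 30-day outcomes")
    followup <- simulateFollowup(cohort,
                                 followupConfig(followupRate = cfg$cohort$followupRate,
                                                quitBase = cfg$followup$quitBase,
                                                ladderUpBase = cfg$followup$ladderUpBase,
                                                influenceMu = cfg$followup$influenceMu,
                                                influenceSd = cfg$followup$influenceSd),
                                 armEffect = cfg$cohort$armEffect,
                                 seed = seeds$followup)
    write.csv(followup, pathOf("followup.csv"), row.names = FALSE)
  }
  analysis <- NULL
  if ("analyze" %in% stages) {
    if (is.null(logs)) logs <- read.csv(pathOf("session_logs.csv"),
                                        stringsAsFactors = FALSE)
    if (is.null(followup) && file.exists(pathOf("followup.csv")))
      followup <- read.csv(pathOf("followup.csv"), stringsAsFactors = FALSE)
    say("analyze: %d log rows, %d follow-up records", nrow(logs),
        if (is.null(followup)) 0L else nrow(followup))
    nDays <- cfg$cohort$nMessagesPerUser
    ## clamp configured day windows to the session length
    windows <- Filter(function(w) w[1] <= nDays,
                      lapply(cfg$analysis$windows, function(w) pmin(w, nDays)))
    windows <- Filter(function(w) w[2] > w[1], windows)
    analysis <- analyzeTrial(logs, followup, threshold = cfg$analysis$threshold,
                             windows = windows, nDays = nDays)
    jsonlite::write_json(analysisToList(analysis), pathOf("analysis.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  artifacts <- list.files(outDir)
  artifacts <- setdiff(artifacts, "manifest.json")
  manifest <- list(seed = seed, configHash = unname(tools::md5sum(cfgPath)),
                   stages = stages, artifacts = artifacts)
  jsonlite::write_json(manifest, pathOf("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(analysis = analysis, outDir = outDir,
                 artifacts = file.path(outDir, artifacts)))
}
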