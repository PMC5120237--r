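## Synthetic-data generators: message libraries, sparse ordinal ratings with
## known latent structure, block-randomized trial cohorts and follow-up
## outcomes. Defaults emulate the pilot rating study (846 raters x 20 ratings
## over a 261-message library) and the 120-smoker 2:1 messaging trial.

#' Configuration for the rating-data generator
#'
#' @param nUsers,nMessages,ratingsPerUser Problem size; defaults are the pilot
#'   shape (846 users, 261 messages, 20 ratings each, i.e. 16,920 ratings).
#' @param latentDim True latent dimensionality of the simulated preference
#'   space (default 2: one "motivation" and one "treatment-information" axis
#'   is the simplest structure that makes ranking nontrivial).
#' @param factorScale Standard deviation of the latent user and item factor
#'   entries (default 0.8, which spreads ordinal ratings over the full 1..5
#'   range with only modest boundary clipping).
#' @param noiseSd Standard deviation of the Gaussian rating noise (default 0.5).
#' @param offset Global additive offset of the continuous score (default 3,
#'   the centre of the five-point scale).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A validated list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(nUsers = 846, nMessages = 261, ratingsPerUser = 20,
                            latentDim = 2, factorScale = 0.8, noiseSd = 0.5,
                            offset = 3, seed = 1) {
  assertCount(nUsers, "nUsers"); assertCount(nMessages, "nMessages")
  assertCount(ratingsPerUser, "ratingsPerUser"); assertCount(latentDim, "latentDim")
  if (ratingsPerUser > nMessages)
    stop("ratingsPerUser must not exceed nMessages", call. = FALSE)
  if (factorScale <= 0 || noiseSd < 0)
    stop("factorScale must be positive and noiseSd nonnegative", call. = FALSE)
  structure(list(nUsers = as.integer(nUsers), nMessages = as.integer(nMessages),
                 ratingsPerUser = as.integer(ratingsPerUser),
                 latentDim = as.integer(latentDim), factorScale = factorScale,
                 noiseSd = noiseSd, offset = offset, seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Generate a synthetic message library
#'
#' Builds a library with the canonical tag prevalences: the realized count of
#' messages carrying each tag equals \code{round(proportion * n)} exactly
#' (102/261 motivational content and 139/261 behavioral treatment at the
#' defaults). Each message is coded for a nonempty random subset of the five
#' readiness stages so that every stage has candidate messages.
#'
#' @param nMessages Library size (default 261, the canonical library).
#' @param tagProportions Named numeric vector of tag prevalences in [0, 1].
#' @param stageProb Probability that a message is coded for each given ladder
#'   level (independently; a message with no level drawn is assigned one at
#'   random, so stage sets are always nonempty).
#' @param peerProportion Fraction of peer-written (vs expert-written) messages.
#' @param seed Integer seed.
#' @return A [MessageLibrary-class].
#' @examples
#' lib <- generateLibrary(seed = 7)
#' tagProportions(lib)[c("MOTIVATIONAL_CONTENT", "BEHAVIORAL_TREATMENT")]
#' @export
generateLibrary <- function(nMessages = 261,
                            tagProportions = c(MOTIVATIONAL_CONTENT = 102 / 261,
                                               BEHAVIORAL_TREATMENT = 139 / 261),
                            stageProb = 0.4, peerProportion = 0.5, seed = 1) {
  assertCount(nMessages, "nMessages")
  if (length(tagProportions) && (any(tagProportions < 0) || any(tagProportions > 1)))
    stop("tag proportions must lie in [0, 1]", call. = FALSE)
  withSeed(seed, {
    ids <- sprintf("m%03d", seq_len(nMessages))
    stages <- lapply(seq_len(nMessages), function(i) {
      s <- readinessStages()[runif(5) < stageProb]
      if (!length(s)) s <- sample(readinessStages(), 1)
      s
    })
    tags <- vector("list", nMessages)
    for (tg in names(tagProportions)) {
      k <- round(tagProportions[[tg]] * nMessages)
      hit <- sample(nMessages, k)
      for (i in hit) tags[[i]] <- c(tags[[i]], tg)
    }
    tags <- lapply(tags, function(t) as.character(t %||% character(0)))
    nPeer <- round(peerProportion * nMessages)
    source <- rep("EXPERT", nMessages)
    source[sample(nMessages, nPeer)] <- "PEER"
    MessageLibrary(ids,
                   text = sprintf("Synthetic motivational message %03d", seq_len(nMessages)),
                   source = source, stages = stages, tags = tags)
  })
}

#' Generate a sparse ordinal rating dataset with known latent structure
#'
#' Latent user and item factors are drawn independently as
#' \eqn{N(0, \mathrm{factorScale}^2)} entries; the continuous score of a
#' (user, message) pair is the factor inner product plus the global offset
#' plus Gaussian noise; the ordinal rating is the score rounded to the nearest
#' integer and clipped to 1..5. Each user rates exactly
#' \code{ratingsPerUser} distinct messages sampled uniformly, so duplicates
#' are impossible by construction. The true factors are returned alongside
#' the data so parameter-recovery checks need no re-simulation.
#'
#' @param config A [generatorConfig()].
#' @param lib Optional [MessageLibrary-class] supplying message ids (its size
#'   must equal \code{config$nMessages}); synthetic ids are used otherwise.
#' @param ordinal If \code{FALSE}, return the continuous scores clipped to
#'   [1, 5] instead of rounded ordinal ratings (useful for noise-free
#'   recovery checks).
#' @return A list with elements \code{data} ([RatingDataset-class]),
#'   \code{userFactors} (\code{nUsers x D}), \code{itemFactors}
#'   (\code{nMessages x D}, rownames = message ids) and \code{offset}.
#' @examples
#' gen <- generateRatings(generatorConfig(nUsers = 20, nMessages = 15,
#'                                        ratingsPerUser = 5, seed = 2))
#' nRatings(gen$data)
#' @export
generateRatings <- function(config = generatorConfig(), lib = NULL, ordinal = TRUE) {
  stopifnot(inherits(config, "generatorConfig"))
  mids <- if (is.null(lib)) sprintf("m%03d", seq_len(config$nMessages)) else messageIds(lib)
  if (length(mids) != config$nMessages)
    stop("library size does not match config$nMessages", call. = FALSE)
  withSeed(config$seed, {
    D <- config$latentDim
    uids <- sprintf("u%04d", seq_len(config$nUsers))
    U <- matrix(rnorm(config$nUsers * D, 0, config$factorScale), ncol = D,
                dimnames = list(uids, NULL))
    V <- matrix(rnorm(config$nMessages * D, 0, config$factorScale), ncol = D,
                dimnames = list(mids, NULL))
    ui <- rep(seq_len(config$nUsers), each = config$ratingsPerUser)
    mi <- as.vector(vapply(seq_len(config$nUsers),
                           function(i) sample(config$nMessages, config$ratingsPerUser),
                           integer(config$ratingsPerUser)))
    score <- rowSums(U[ui, , drop = FALSE] * V[mi, , drop = FALSE]) +
      config$offset + rnorm(length(ui), 0, config$noiseSd)
    rating <- if (ordinal) clipRating(round(score)) else clipRating(score)
    triplets <- data.frame(user = uids[ui], message = mids[mi], rating = rating,
                           day = rep(seq_len(config$ratingsPerUser), config$nUsers),
                           stringsAsFactors = FALSE)
    list(data = RatingDataset(triplets, userIds = uids, messageIds = mids),
         userFactors = U, itemFactors = V, offset = config$offset)
  })
}

#' Configuration for the two-arm trial cohort generator
#'
#' @param nParticipants Cohort size (default 120).
#' @param block Length-2 integer composition of each randomization block:
#'   \code{c(intervention, comparison)} (default \code{c(7, 3)}; the trial
#'   used blocks of 10 with a 2:1 target allocation).
#' @param nMessagesPerUser Messages each participant rates (default 30).
#' @param followupRate Probability a participant completes follow-up
#'   (default 0.79, the trial's completion rate).
#' @param armEffect Additive shift applied to intervention participants'
#'   latent preference offset (rating-scale units); also used by
#'   [simulateFollowup()] as the log-odds shift of follow-up outcomes.
#' @param latentDim,factorScale Latent preference space of the cohort (must
#'   match the message world they will rate).
#' @param stageProbs Baseline distribution over the five ladder levels, in
#'   [readinessStages()] order.
#' @param seed Integer seed.
#' @return A validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nParticipants = 120, block = c(7, 3),
                         nMessagesPerUser = 30, followupRate = 0.79,
                         armEffect = 0.25, latentDim = 2, factorScale = 0.8,
                         stageProbs = c(0.15, 0.45, 0.20, 0.10, 0.10),
                         seed = 1) {
  assertCount(nParticipants, "nParticipants")
  if (length(block) != 2L || any(block < 0) || sum(block) < 1)
    stop("block must be a length-2 nonnegative composition", call. = FALSE)
  assertProb(followupRate, "followupRate")
  if (length(stageProbs) != 5L || any(stageProbs < 0) || abs(sum(stageProbs) - 1) > 1e-8)
    stop("stageProbs must be 5 probabilities summing to 1", call. = FALSE)
  structure(list(nParticipants = as.integer(nParticipants),
                 block = as.integer(block),
                 nMessagesPerUser = as.integer(nMessagesPerUser),
                 followupRate = followupRate, armEffect = armEffect,
                 latentDim = as.integer(latentDim), factorScale = factorScale,
                 stageProbs = stageProbs, seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Generate a block-randomized two-arm cohort
#'
#' Participants are allocated in registration order following the block
#' composition (each block is an independent random permutation of
#' \code{block[1]} intervention and \code{block[2]} comparison slots), so the
#' allocation ratio over any whole number of blocks equals the block
#' composition exactly. Baseline readiness stage and simple demographics
#' (sex, age group, education) are drawn from configurable marginals; each
#' participant receives a latent preference vector, with intervention
#' participants' preference offset shifted by \code{armEffect}.
#'
#' @param config A [cohortConfig()].
#' @return A list with \code{participants} (a \code{data.frame} with columns
#'   user, arm, stage, sex, ageGroup, education, prefShift) and
#'   \code{userFactors} (\code{nParticipants x latentDim} matrix, rownames =
#'   user ids).
#' @examples
#' coh <- generateCohort(cohortConfig(nParticipants = 20, block = c(2, 1)))
#' table(coh$participants$arm)
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  withSeed(config$seed, {
    n <- config$nParticipants
    bsize <- sum(config$block)
    nblock <- ceiling(n / bsize)
    alloc <- unlist(lapply(seq_len(nblock), function(b)
      sample(rep(c("INTERVENTION", "COMPARISON"), config$block))))[seq_len(n)]
    ids <- sprintf("p%03d", seq_len(n))
    stage <- sample(readinessStages(), n, replace = TRUE, prob = config$stageProbs)
    ## marginal demographics in the trial's observed proportions
    sex <- sample(c("FEMALE", "MALE"), n, replace = TRUE, prob = c(0.64, 0.36))
    ageGroup <- sample(c("19-34", "35-44", "45+"), n, replace = TRUE,
                       prob = c(0.30, 0.32, 0.38))
    education <- sample(c("LT_HIGH_SCHOOL", "HIGH_SCHOOL", "COLLEGE"), n,
                        replace = TRUE, prob = c(0.11, 0.30, 0.59))
    U <- matrix(rnorm(n * config$latentDim, 0, config$factorScale),
                ncol = config$latentDim, dimnames = list(ids, NULL))
    participants <- data.frame(
      user = ids, arm = alloc, stage = stage, sex = sex, ageGroup = ageGroup,
      education = education,
      prefShift = ifelse(alloc == "INTERVENTION", config$armEffect, 0),
      stringsAsFactors = FALSE)
    list(participants = participants, userFactors = U)
  })
}

#' Configuration for follow-up outcome simulation
#'
#' Base rates are the trial comparison arm's observed rates; the arm effect
#' enters every outcome on the log-odds scale.
#'
#' @param followupRate Completion probability (default 0.79).
#' @param quitBase Comparison-arm probability of a one-day quit (default 0.32).
#' @param ladderUpBase Comparison-arm probability of moving up the readiness
#'   ladder (default 0.30).
#' @param influenceMu Latent mean of the 5-level influence responses
#'   (default 3.5); responses are a rounded, clipped Gaussian.
#' @param influenceSd Latent SD of influence responses (default 1).
#' @param questions Names of the influence questions simulated.
#' @return A validated list of class \code{"followupConfig"}.
#' @export
followupConfig <- function(followupRate = 0.79, quitBase = 0.32,
                           ladderUpBase = 0.30, influenceMu = 3.5,
                           influenceSd = 1,
                           questions = c("quit_smoking", "use_nrt")) {
  assertProb(followupRate, "followupRate")
  assertProb(quitBase, "quitBase"); assertProb(ladderUpBase, "ladderUpBase")
  structure(list(followupRate = followupRate, quitBase = quitBase,
                 ladderUpBase = ladderUpBase, influenceMu = influenceMu,
                 influenceSd = influenceSd, questions = questions),
            class = "followupConfig")
}

#' Simulate 30-day follow-up outcomes for a cohort
#'
#' Each participant independently completes follow-up with probability
#' \code{followupRate}. For completers, the one-day-quit indicator and the
#' moved-up-the-ladder indicator are Bernoulli with probability
#' \code{plogis(qlogis(base) + armEffect)} in the intervention arm and
#' \code{base} in the comparison arm; influence responses are 5-level Likert
#' draws whose latent mean is shifted by \code{armEffect / 2} for
#' intervention completers. Deterministic for a fixed seed.
#'
#' @param cohort The result of [generateCohort()] (or its
#'   \code{participants} data.frame).
#' @param config A [followupConfig()].
#' @param armEffect Log-odds shift for intervention participants; defaults to
#'   the cohort's \code{prefShift} knob (0 gives an exact null).
#' @param seed Integer seed.
#' @return A \code{data.frame} with one row per participant: user, arm,
#'   completed, quitOneDay, baselineStage, followupStage, and one integer
#'   column per influence question (NA for non-completers).
#' @export
simulateFollowup <- function(cohort, config = followupConfig(),
                             armEffect = NULL, seed = 1) {
  stopifnot(inherits(config, "followupConfig"))
  part <- if (is.data.frame(cohort)) cohort else cohort$participants
  if (is.null(armEffect))
    armEffect <- max(part$prefShift %||% 0)
  withSeed(seed, {
    n <- nrow(part)
    int <- part$arm == "INTERVENTION"
    completed <- runif(n) < config$followupRate
    pQuit <- plogis(qlogis(config$quitBase) + armEffect * int)
    pUp <- plogis(qlogis(config$ladderUpBase) + armEffect * int)
    quit <- runif(n) < pQuit
    up <- runif(n) < pUp
    base <- stageIndex(part$stage)
    follow <- ifelse(up & base < 5L, base + 1L, base)
    out <- data.frame(user = part$user, arm = part$arm, completed = completed,
                      quitOneDay = ifelse(completed, quit, NA),
                      baselineStage = part$stage,
                      followupStage = ifelse(completed, readinessStages()[follow], NA),
                      stringsAsFactors = FALSE)
    for (q in config$questions) {
      resp <- clipRating(round(rnorm(n, config$influenceMu + (armEffect / 2) * int,
                                     config$influenceSd)))
      out[[q]] <- ifelse(completed, as.integer(resp), NA_integer_)
    }
    out
  })
}
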