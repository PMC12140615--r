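## End-to-end demonstration pipeline on a synthetic cohort with known ground
## truth: generate cohort -> observe -> preprocess -> fit -> classify ->
## reliability and clustering summaries.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a persons-by-sessions cohort of planted models, simulates a
#' BOLD-like observation for each, preprocesses (deconvolution, z-scoring,
#' derivative pairs), fits a MINDy model per session, classifies every
#' fitted model's attractor landscape, and summarizes: the taxonomy tally,
#' the within- versus between-person DAS table, and cosine K-means centroids
#' of all attractors with the instability-selected K. All randomness derives
#' from \code{seed}; the returned manifest records every derived seed and
#' configuration so a rerun reproduces the outputs exactly.
#'
#' @param seed Integer master seed.
#' @param nPersons Number of synthetic persons (default 4).
#' @param N Parcels (default 10).
#' @param T Frames per session (default 800).
#' @param nBatches Optimizer batches per fit (default 1500).
#' @param nInitClassify Initial conditions per landscape (default 200).
#' @param kCandidates Candidate cluster counts (default \code{2:6}).
#' @param verbose Print stage progress (default TRUE).
#' @return List: \code{taxonomy} (label tally of fitted models), \code{das}
#'   (pair table), \code{cluster} (selected K, centroids, instability
#'   curve), \code{landscapes}, \code{models}, \code{manifest}.
#' @export
runDemoPipeline <- function(seed = 1L, nPersons = 4L, N = 10L, T = 800L,
                            nBatches = 1500L, nInitClassify = 200L,
                            kCandidates = 2:6, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  cohort <- makeCohort(nPersons, N = N, seed = seed)
  say("cohort: %d models (%d persons x 2 sessions)",
      length(cohort$models), nPersons)
  cfg <- fitConfig(nBatches = nBatches, seed = seed)
  fitted <- vector("list", length(cohort$models))
  landscapes <- vector("list", length(cohort$models))
  for (i in seq_along(cohort$models)) {
    obs <- simulateObservation(cohort$models[[i]], T = T, nRuns = 2L,
                               seed = seed + 100L + i)
    prep <- preprocessTimeseries(obs)
    cfg$seed <- seed + 200L + i
    fitted[[i]] <- fitMindy(prep$samples, cfg,
                            tr = cohort$models[[i]]@tr)
    landscapes[[i]] <- classifyLandscape(
      fitted[[i]], nInit = nInitClassify,
      initData = prep$samples@states, seed = seed + 300L + i)
    say("model %d/%d: fitted (R^2 = %.2f), landscape %s", i,
        length(cohort$models), r2Derivatives(fitted[[i]], prep$samples),
        landscapes[[i]]@label)
  }
  tax <- table(vapply(landscapes, taxonomyLabel, character(1)))
  dasTab <- dasGroupTable(landscapes, cohort$info$person,
                          cohort$info$session)
  pats <- do.call(rbind, lapply(landscapes, attractorPatterns))
  cluster <- NULL
  if (!is.null(pats) && nrow(pats) >= 2 * max(kCandidates)) {
    sel <- selectK(pats, kCandidates, seed = seed)
    km <- cosineKmeans(pats, sel$K, seed = seed)
    cluster <- list(K = sel$K, curve = sel$curve,
                    centroids = km$centroids,
                    assignments = km$assignments)
    say("clustering: selected K = %d", sel$K)
  }
  manifest <- list(
    seed = seed, nPersons = nPersons, N = N, T = T,
    nBatches = nBatches, nInitClassify = nInitClassify,
    kCandidates = kCandidates,
    version = as.character(utils::packageVersion("mindyscapes")),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  list(taxonomy = tax, das = dasTab, cluster = cluster,
       landscapes = landscapes, models = fitted,
       trueInfo = cohort$info, manifest = manifest)
}
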