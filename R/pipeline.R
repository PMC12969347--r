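#' @include synthetic.R selection.R state-analysis.R arousal.R stats.R io.R
NULL

# Output-directory guard and manifest writer shared by the run* commands.
.prepare_out <- function(out, force = FALSE) {
  .stop_if(is.null(out), "config$out (output directory) is required")
  if (dir.exists(out) && length(list.files(out)) && !force)
    stop("output directory ", out, " exists; use force = TRUE",
         call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

.write_manifest <- function(out, command, config, seeds = list()) {
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    command = command,
    config = config[!vapply(config, is.null, logical(1))],
    seeds = seeds,
    files = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Pipeline commands
#'
#' Orchestration layer tying the pipeline stages together.  Each command
#' takes a plain config list, writes its reports into \code{config$out},
#' and finishes with a \code{manifest.json} recording the config, every
#' derived seed, and md5 hashes of all outputs, so identical configs give
#' identical results.
#'
#' \describe{
#'   \item{runSimulate}{config: \code{preset} (or \code{spec} path from
#'     [writeSpecConfig()]), \code{nFish}, \code{duration}, \code{seed},
#'     \code{out}, \code{force}.  Writes \code{traces.csv},
#'     \code{schedule.csv} and \code{truth.json}.}
#'   \item{runFit}{config: \code{traces} (CSV path), \code{states}
#'     (candidate K vector; a single value skips selection),
#'     \code{restarts}, \code{emission}, \code{seed}, \code{out},
#'     \code{force}.  Writes per-fish \code{fit_<id>.json} (BIC table,
#'     selected K, winning restart seed, parameters) and
#'     \code{selection.csv}.}
#'   \item{runAnalyze}{config: \code{traces}, \code{fits} (runFit output
#'     dir), \code{schedule} (CSV path), \code{out}, \code{force}.
#'     Writes \code{architecture.csv} (per fish/label/period proportions,
#'     minutes, bouts, occupancy), \code{conventional.csv} and
#'     \code{assignment.csv}.}
#'   \item{runCompare}{config: \code{fitsA}, \code{fitsB} (runFit output
#'     dirs), \code{nPerm}, \code{seed}, \code{out}, \code{force}.
#'     Permutation tests on label-aligned occupancies, rates and
#'     transition probabilities with family-wise Bonferroni factors 4 and
#'     16; writes \code{comparison.csv}.}
#'   \item{runArousal}{config: \code{preset}, \code{nFish},
#'     \code{nStimuli}, \code{restarts}, \code{seed}, \code{out},
#'     \code{force}.  Simulates the stimulus protocol, fits a pooled
#'     4-state model, excludes fish missing any state, and writes
#'     \code{arousal.csv} (per state: n, raw, baseline, corrected).}
#' }
#'
#' @param config named list of command parameters (see Details).
#' @return The written manifest, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config) {
  out <- .prepare_out(config$out, isTRUE(config$force))
  spec <- if (!is.null(config$spec)) readSpecConfig(config$spec)
          else sleepPreset(config$preset %||% "wt")
  seed <- as.integer(config$seed %||% 1L)
  sim <- generateCohort(spec, nFish = config$nFish %||% 10L,
                        duration = config$duration %||% 2880L,
                        seed = seed)
  writeTraces(sim$cohort, file.path(out, "traces.csv"))
  writeSchedule(sim$schedule, file.path(out, "schedule.csv"))
  jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(out, "simulate", config,
                  seeds = list(base = seed,
                               perFish = vapply(
                                 seq_len(config$nFish %||% 10L),
                                 function(i) deriveSeed(seed, i),
                                 integer(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_fit_dir <- function(dir) {
  files <- list.files(dir, pattern = "^fit_.*\\.json$",
                      full.names = TRUE)
  .stop_if(!length(files), "no fit files found in ", dir)
  fits <- lapply(files, function(f) {
    obj <- jsonlite::read_json(f, simplifyVector = TRUE)
    list(fish = obj$fish, selectedK = obj$selected_K,
         params = HMMParams(
           obj$params$initial,
           if (is.matrix(obj$params$transitions)) obj$params$transitions
           else matrix(unlist(obj$params$transitions),
                       nrow = obj$params$K, byrow = TRUE),
           obj$params$lambdas,
           if (is.null(obj$params$zero_weights)) numeric(0)
           else obj$params$zero_weights))
  })
  names(fits) <- vapply(fits, `[[`, character(1), "fish")
  fits
}

#' @rdname pipeline
#' @export
runFit <- function(config) {
  out <- .prepare_out(config$out, isTRUE(config$force))
  cohort <- readTraces(config$traces)
  states <- config$states %||% 2:6
  restarts <- config$restarts %||% 20L
  seed <- as.integer(config$seed %||% 1L)
  emission <- config$emission %||% "poisson"
  rows <- list()
  seeds <- list()
  for (i in seq_along(cohortTraces(cohort))) {
    tr <- cohortTraces(cohort)[[i]]
    fish_seed <- deriveSeed(seed, i)
    seeds[[fishId(tr)]] <- fish_seed
    if (length(states) == 1L) {
      fit <- fitMultistart(tr, states, nRestarts = restarts,
                           baseSeed = fish_seed, emission = emission)
      selK <- as.integer(states)
      tab <- data.frame(K = selK, logLik = fit@logLik,
                        bic = bic(fit, nBins(tr)))
    } else {
      sel <- suppressWarnings(
        optimalStateNumber(tr, kRange = states, nRestarts = restarts,
                           baseSeed = fish_seed, emission = emission))
      selK <- sel@selectedK
      fit <- sel@fits[[as.character(selK)]]
      tab <- sel@bicTable
    }
    p <- fit@params
    obj <- list(fish = fishId(tr), selected_K = selK,
                winning_seed = fit@seed, bic_table = tab,
                params = list(K = p@K, initial = p@initial,
                              transitions = apply(p@transitions, 1,
                                                  identity,
                                                  simplify = FALSE),
                              lambdas = p@lambdas,
                              zero_weights = if (length(p@zeroWeights))
                                p@zeroWeights else NULL))
    jsonlite::write_json(obj,
                         file.path(out, paste0("fit_", fishId(tr),
                                               ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    rows[[i]] <- data.frame(fish = fishId(tr), selected_K = selK,
                            logLik = fit@logLik,
                            winning_seed = fit@seed)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out, "selection.csv"), row.names = FALSE)
  .write_manifest(out, "fit", config, seeds = seeds)
}

#' @rdname pipeline
#' @export
runAnalyze <- function(config) {
  out <- .prepare_out(config$out, isTRUE(config$force))
  cohort <- readTraces(config$traces)
  fits <- .read_fit_dir(config$fits)
  schedule <- readSchedule(config$schedule)
  traces <- cohortTraces(cohort)
  arch <- list()
  seqs <- list()
  labs <- list()
  periods_list <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    fit <- fits[[fishId(tr)]]
    .stop_if(is.null(fit), "no fit for fish ", fishId(tr))
    lab <- withCallingHandlers(labelStates(fit$params),
      warning = function(w) {
        message("fish ", fishId(tr), ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    seq <- decodeStates(fit$params, tr, lab)
    periods <- labelBins(tr, schedule)
    props <- stateProportions(seq, lab, periods)
    bouts <- boutDurations(seq, lab, periods)
    occ <- occupancy(fit$params, lab,
                     fallbackStates = statePath(seq))
    m <- merge(props, bouts, by = c("period", "label"))
    m$occupancy <- occ[m$label]
    m <- cbind(fish = fishId(tr), m)
    arch[[i]] <- m
    seqs[[i]] <- seq
    labs[[i]] <- lab
    periods_list[[i]] <- periods
  }
  utils::write.csv(do.call(rbind, arch),
                   file.path(out, "architecture.csv"),
                   row.names = FALSE)
  if (all(vapply(labs, function(l) "S2" %in% l@labels, logical(1)))) {
    conv <- compareConventionalSleep(seqs, labs, traces, periods_list)
    utils::write.csv(conv$perFish, file.path(out, "conventional.csv"),
                     row.names = FALSE)
    if (!is.null(conv$fit))
      jsonlite::write_json(conv$fit,
                           file.path(out, "conventional_fit.json"),
                           auto_unbox = TRUE, digits = NA)
    same_labels <- all(vapply(labs, function(l)
      identical(sort(l@labels), sort(labs[[1L]]@labels)), logical(1)))
    if (same_labels) {
      asg <- assignmentByActivity(seqs, labs, traces, periods_list)
      utils::write.csv(asg, file.path(out, "assignment.csv"),
                       row.names = FALSE)
    }
  }
  .write_manifest(out, "analyze", config)
}

#' @rdname pipeline
#' @export
runCompare <- function(config) {
  out <- .prepare_out(config$out, isTRUE(config$force))
  fitsA <- .read_fit_dir(config$fitsA)
  fitsB <- .read_fit_dir(config$fitsB)
  KA <- unique(vapply(fitsA, function(f) f$params@K, integer(1)))
  KB <- unique(vapply(fitsB, function(f) f$params@K, integer(1)))
  .stop_if(length(KA) != 1L || !identical(KA, KB),
           "cohorts must share a single common K")
  nPerm <- config$nPerm %||% 2000L
  seed <- as.integer(config$seed %||% 1L)
  collect <- function(fits) {
    labs <- lapply(fits, function(f) labelStates(f$params))
    labels_ord <- labs[[1L]]@labels[order(fits[[1L]]$params@lambdas)]
    per_fish <- lapply(seq_along(fits), function(i) {
      perm <- match(labels_ord, labs[[i]]@labels)
      p <- fits[[i]]$params
      occ <- stationaryDistribution(p@transitions)[perm]
      A <- p@transitions[perm, perm]
      vals <- c(stats::setNames(occ, paste0("occ_", labels_ord)),
                stats::setNames(p@lambdas[perm],
                                paste0("lambda_", labels_ord)),
                stats::setNames(as.vector(t(A)),
                                paste0("A_", rep(labels_ord,
                                                 each = KA), "_",
                                       rep(labels_ord, KA))))
      vals
    })
    do.call(rbind, per_fish)
  }
  va <- collect(fitsA)
  vb <- collect(fitsB)
  .stop_if(!identical(colnames(va), colnames(vb)),
           "cohorts have incompatible label sets")
  rows <- lapply(seq_len(ncol(va)), function(j) {
    res <- permTest(va[, j], vb[, j], nPerm = nPerm,
                    seed = deriveSeed(seed, j))
    fam <- if (grepl("^A_", colnames(va)[j])) "transitions"
           else "occupancy_lambda"
    data.frame(parameter = colnames(va)[j],
               group_a_mean = mean(va[, j]),
               group_b_mean = mean(vb[, j]), diff = res$observed,
               ci_lo = res$ci[1L], ci_hi = res$ci[2L], p = res$p,
               family = fam)
  })
  tab <- do.call(rbind, rows)
  flags <- rbind(
    bonferroniFlags(tab$p[tab$family == "occupancy_lambda"],
                    "occupancy_lambda"),
    bonferroniFlags(tab$p[tab$family == "transitions"], "transitions"))
  tab <- tab[order(tab$family != "occupancy_lambda",
                   seq_len(nrow(tab))), ]
  tab$corrected_flag <- flags$stars
  tab$significant <- flags$significant
  utils::write.csv(tab, file.path(out, "comparison.csv"),
                   row.names = FALSE)
  .write_manifest(out, "compare", config, seeds = list(base = seed))
}

#' @rdname pipeline
#' @export
runArousal <- function(config) {
  out <- .prepare_out(config$out, isTRUE(config$force))
  spec <- sleepPreset(config$preset %||% "wt")
  seed <- as.integer(config$seed %||% 1L)
  sim <- generateArousalExperiment(spec, nFish = config$nFish %||% 20L,
                                   nStimuli = config$nStimuli %||% 99L,
                                   seed = seed)
  traces <- lapply(sim$raws, binActivity)
  fit <- concatenatedFit(traces, K = 4L,
                         nRestarts = config$restarts %||% 20L,
                         baseSeed = deriveSeed(seed, 10001L))
  lab <- labelStates(fit@params)
  seqs <- lapply(traces, function(tr)
    decodeStates(fit@params, tr, lab))
  keep <- excludeIncompleteFish(seqs, 4L)
  .stop_if(!length(keep$retained), "no fish occupied all four states")
  res <- responseFractions(sim$raws[keep$retained],
                           seqs[keep$retained], lab, sim$protocol)
  utils::write.csv(res, file.path(out, "arousal.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(retained = keep$retained,
                            excluded = keep$excluded),
                       file.path(out, "arousal_fish.json"),
                       auto_unbox = TRUE)
  .write_manifest(out, "arousal", config, seeds = list(base = seed))
}

#' Read a stimulus-time CSV
#'
#' Columns \code{fish_id} (optional; blank applies to all fish) and
#' \code{timestamp} (ISO-8601).
#'
#' @param path CSV path.
#' @param responseWindow,baselineOffset,interStimulus protocol settings
#'   (see [StimulusProtocol()]).
#' @return A [StimulusProtocol-class] built from the unique timestamps.
#' @export
readStimuli <- function(path, responseWindow = 2, baselineOffset = 120,
                        interStimulus = 300) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if(!"timestamp" %in% names(df),
           "stimulus CSV needs a timestamp column")
  ts <- sort(unique(as.POSIXct(df$timestamp, format = .TIME_FMT,
                               tz = "UTC")))
  StimulusProtocol(ts, responseWindow, baselineOffset, interStimulus)
}
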