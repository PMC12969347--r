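#' @include activity.R
NULL

.TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

#' Write a cohort of traces to CSV
#'
#' One row per bin with columns \code{fish_id}, \code{timestamp}
#' (ISO-8601 bin start, UTC) and \code{activity_sec}, sorted by fish then
#' time.  The written file round-trips losslessly through [readTraces()].
#'
#' @param cohort a [Cohort-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  rows <- lapply(cohort@traces, function(tr)
    data.frame(fish_id = tr@fishId,
               timestamp = format(binStarts(tr), .TIME_FMT, tz = "UTC"),
               activity_sec = tr@values, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort of traces from CSV
#'
#' Expects the format written by [writeTraces()].  Rows must form
#' contiguous 1-min series per fish; non-integer or out-of-range activity
#' values and time gaps are rejected with the offending row number.
#'
#' @param path CSV path.
#' @param label cohort label to attach.
#' @return A [Cohort-class].
#' @export
readTraces <- function(path, label = "cohort") {
  .stop_if(!file.exists(path), "trace CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "timestamp", "activity_sec")
  .stop_if(!all(need %in% names(df)),
           "trace CSV needs columns fish_id, timestamp, activity_sec")
  v <- suppressWarnings(as.numeric(df$activity_sec))
  bad <- which(is.na(v) | v < 0 | v > 60 | abs(v - round(v)) > 1e-9)
  .stop_if(length(bad) > 0,
           sprintf("row %d: activity_sec must be an integer in [0, 60]",
                   bad[1L] + 1L))  # +1 for the header line
  ts <- as.POSIXct(df$timestamp, format = .TIME_FMT, tz = "UTC")
  bad <- which(is.na(ts))
  .stop_if(length(bad) > 0,
           sprintf("row %d: malformed timestamp", bad[1L] + 1L))
  traces <- lapply(split(seq_len(nrow(df)), df$fish_id), function(i) {
    i <- i[order(ts[i])]
    gaps <- which(diff(as.numeric(ts[i])) != 60)
    .stop_if(length(gaps) > 0,
             sprintf("row %d: time gap in series for fish %s",
                     i[gaps[1L] + 1L] + 1L, df$fish_id[i[1L]]))
    ActivityTrace(df$fish_id[i[1L]], as.integer(v[i]), ts[i[1L]])
  })
  Cohort(unname(traces), label = label)
}

#' Write / read a light schedule CSV
#'
#' Columns \code{start}, \code{end} (ISO-8601, UTC) and \code{condition}.
#'
#' @param schedule a [LightSchedule-class].
#' @param path CSV path.
#' @return \code{writeSchedule}: \code{path} invisibly;
#'   \code{readSchedule}: a [LightSchedule-class].
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "LightSchedule"))
  iv <- schedule@intervals
  utils::write.csv(
    data.frame(start = format(iv$start, .TIME_FMT, tz = "UTC"),
               end = format(iv$end, .TIME_FMT, tz = "UTC"),
               condition = iv$condition),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if(!all(c("start", "end", "condition") %in% names(df)),
           "schedule CSV needs columns start, end, condition")
  LightSchedule(as.POSIXct(df$start, format = .TIME_FMT, tz = "UTC"),
                as.POSIXct(df$end, format = .TIME_FMT, tz = "UTC"),
                df$condition)
}

#' Loader stub for the published behavioral data deposit
#'
#' The behavioral recordings this package's models were designed around
#' are deposited on Figshare (doi:10.6084/m9.figshare.30727589).  This
#' optional convenience loader maps a locally downloaded per-fish activity
#' table onto [Cohort-class] objects; it is never required by any analysis
#' in the package, which operates on [ActivityTrace-class] objects from
#' any source.  Expected columns: a fish identifier, a bin timestamp (or a
#' bin index, resolved against \code{start}), and seconds-active-per-minute
#' activity; pass the actual column names via \code{columns}.
#'
#' @param path path to a downloaded CSV from the deposit.
#' @param columns named character vector mapping
#'   \code{c(fish, time, activity)} onto the file's column names.
#' @param start recording start used when \code{time} is a bin index.
#' @param label cohort label.
#' @return A [Cohort-class].
#' @export
readFigshareTraces <- function(path,
                               columns = c(fish = "fish_id",
                                           time = "timestamp",
                                           activity = "activity_sec"),
                               start = .default_start(),
                               label = "figshare") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if(!all(columns %in% names(df)),
           "columns mapping does not match the file; see ?readFigshareTraces")
  tcol <- df[[columns[["time"]]]]
  traces <- lapply(split(seq_len(nrow(df)), df[[columns[["fish"]]]]),
    function(i) {
      tt <- tcol[i]
      if (is.numeric(tt)) {
        i <- i[order(tt)]
        t0 <- .posixct(start)
      } else {
        tt <- as.POSIXct(tt, tz = "UTC")
        i <- i[order(tt)]
        t0 <- tt[order(tt)][1L]
      }
      ActivityTrace(df[[columns[["fish"]]]][i[1L]],
                    df[[columns[["activity"]]]][i], t0)
    })
  Cohort(unname(traces), label = label)
}

#' Write / read HMM parameters as JSON
#'
#' Round-trips \code{K}, \code{initial}, \code{transitions},
#' \code{lambdas} and \code{zero_weights} (null for plain Poisson) exactly
#' (to better than 1e-12).
#'
#' @param params an [HMMParams-class].
#' @param path JSON path.
#' @return \code{writeParams}: \code{path} invisibly; \code{readParams}:
#'   an [HMMParams-class].
#' @export
writeParams <- function(params, path) {
  stopifnot(is(params, "HMMParams"))
  obj <- list(K = params@K, initial = params@initial,
              transitions = apply(params@transitions, 1, identity,
                                  simplify = FALSE),
              lambdas = params@lambdas,
              zero_weights = if (length(params@zeroWeights))
                params@zeroWeights else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.matrix(obj$transitions)) obj$transitions
       else matrix(unlist(obj$transitions), nrow = obj$K, byrow = TRUE)
  HMMParams(initial = obj$initial, transitions = A,
            lambdas = obj$lambdas,
            zeroWeights = if (is.null(obj$zero_weights)) numeric(0)
                          else obj$zero_weights)
}
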