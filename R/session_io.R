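# Session directory reader/writer.
#
# One directory per participant/maneuver/repeat:
#   <channel>.csv      columns t_s,value ('.' decimal, LF, UTF-8)
#   bp_beats.csv       per-beat SBP/DBP/MAP events (t_s,sbp,dbp,map)
#   session.json       sidecar: devices, rates, units, maneuver, alignment
#   truth.json         ground truth (optional, simulator only)

sidecar_required_fields <- c("participant", "maneuver", "rep_idx",
                             "pre_aligned", "channels")

validate_sidecar <- function(meta) {
  missing <- setdiff(sidecar_required_fields, names(meta))
  if (length(missing))
    rlang::abort(sprintf("session.json is missing field(s): %s",
                         paste(missing, collapse = ", ")))
  ch <- meta$channels
  need <- c("device", "channel", "fs", "t0", "units", "file")
  if (!all(need %in% names(ch)))
    rlang::abort("session.json channel table lacks required columns")
  if (any(ch$fs <= 0)) rlang::abort("channel sampling rates must be > 0")
  invisible(meta)
}

channel_file_name <- function(device, channel) {
  ifelse(channel == "sync", paste0("sync_", device, ".csv"),
         paste0(channel, ".csv"))
}

#' Write a session directory
#'
#' @param session an `ortho_session`.
#' @param dir output directory (created if needed).
#' @param with_truth also write `truth.json` with the simulator ground truth.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, with_truth = FALSE) {
  stopifnot(inherits(session, "ortho_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ch <- session$channels
  if (!"t0" %in% names(ch)) ch$t0 <- 0
  files <- channel_file_name(ch$device, ch$channel)
  for (i in seq_len(nrow(ch))) {
    t_s <- ch$t0[i] + (seq_along(ch$samples[[i]]) - 1) / ch$fs[i]
    utils::write.csv(data.frame(t_s = t_s, value = ch$samples[[i]]),
                     file.path(dir, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(session$bp_beats))
    utils::write.csv(
      data.frame(t_s = session$bp_beats$t, sbp = session$bp_beats$sbp,
                 dbp = session$bp_beats$dbp, map = session$bp_beats$map),
      file.path(dir, "bp_beats.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(
    participant = session$participant,
    maneuver = session$maneuver,
    rep_idx = session$rep_idx,
    pre_aligned = isTRUE(session$pre_aligned),
    channels = data.frame(device = ch$device, channel = ch$channel,
                          fs = ch$fs, t0 = ch$t0, units = ch$units,
                          file = files)
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (with_truth && !is.null(session$truth)) {
    tr <- session$truth
    jsonlite::write_json(
      list(onset = tr$onset, brs_true = tr$brs_true,
           car_true = tr$car_true, age = tr$age,
           beats = as.data.frame(tr$beats)),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a session directory
#'
#' Validates the `session.json` sidecar (shipped schema:
#' `system.file("extdata", "session.schema.json", package = "orthomon")`)
#' and loads all channel CSVs, the per-beat BP event table and, when
#' present, the ground truth.
#'
#' @param dir session directory written by [write_session()] (or any tool
#'   emitting the same dialect).
#' @return an `ortho_session`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path))
    rlang::abort(sprintf("no session.json in '%s'", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  validate_sidecar(meta)
  chm <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  samples <- vector("list", nrow(chm))
  for (i in seq_len(nrow(chm))) {
    df <- utils::read.csv(file.path(dir, chm$file[i]))
    samples[[i]] <- df$value
  }
  channels <- tibble::tibble(device = chm$device, channel = chm$channel,
                             fs = chm$fs, t0 = chm$t0, units = chm$units,
                             samples = samples)
  bp_beats <- NULL
  if (file.exists(file.path(dir, "bp_beats.csv"))) {
    df <- utils::read.csv(file.path(dir, "bp_beats.csv"))
    bp_beats <- tibble::tibble(t = df$t_s, sbp = df$sbp, dbp = df$dbp,
                               map = df$map)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    truth <- list(onset = tr$onset, brs_true = tr$brs_true,
                  car_true = tr$car_true, age = tr$age,
                  beats = tibble::as_tibble(tr$beats))
  }
  session <- list(
    participant = meta$participant,
    maneuver = meta$maneuver,
    rep_idx = meta$rep_idx,
    channels = channels,
    bp_beats = bp_beats,
    pre_aligned = isTRUE(meta$pre_aligned),
    truth = truth,
    meta = list()
  )
  class(session) <- "ortho_session"
  session
}
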