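# On-disk formats. The big trace matrix goes in a plain CSV (roi_id first
# column, one column per frame, header carries 0-based frame indices);
# acquisition metadata lives in a JSON sidecar next to it so the CSV stays
# tool-agnostic. Events and ground truth are TSV.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a trace set to CSV (+ JSON sidecar)
#'
#' @param traces a `trace_set`.
#' @param path CSV path; metadata (frame rate, dimensions) is written to
#'   `<path>.json`.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- data.frame(roi_id = traces$roi_ids, traces$fluorescence,
                   check.names = FALSE)
  names(df) <- c("roi_id", sprintf("f%d", seq_len(ncol(traces$fluorescence)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(frame_rate_hz = traces$frame_rate_hz,
               n_rois = nrow(traces$fluorescence),
               n_frames = ncol(traces$fluorescence),
               duration_s = ncol(traces$fluorescence) / traces$frame_rate_hz)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace set from CSV (+ JSON sidecar)
#'
#' @param path CSV written by [write_traces()]; the `<path>.json` sidecar
#'   must be present (it carries the frame rate).
#' @return a `trace_set`.
#' @export
read_traces <- function(path) {
  if (!file.exists(sidecar_path(path)))
    stop("missing metadata sidecar ", sidecar_path(path), call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop("malformed trace CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L || names(df)[1] != "roi_id")
    stop("malformed trace CSV ", path, ": first column must be roi_id",
         call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  if (!is.numeric(mat) || anyNA(mat))
    stop("malformed trace CSV ", path, ": non-numeric or missing values",
         call. = FALSE)
  if (!is.null(meta$n_frames) && ncol(mat) != meta$n_frames)
    stop("trace CSV ", path, " is truncated: expected ", meta$n_frames,
         " frames, found ", ncol(mat), call. = FALSE)
  trace_set(mat, meta$frame_rate_hz, roi_ids = as.character(df$roi_id))
}

#' Write ground truth as TSV (+ config sidecar)
#'
#' Long format: one row per true event (`roi_id`, `event_time_s`); the
#' generating configuration goes to `<path>.json`.
#'
#' @param truth a `ground_truth`.
#' @param path TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  roi_ids <- sprintf("roi%03d", seq_along(truth$event_times_s))
  df <- data.frame(
    roi_id = rep(roi_ids, lengths(truth$event_times_s)),
    event_time_s = unlist(truth$event_times_s, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- truth$config
  cfg$drug_time_s <- if (is.null(cfg$drug_time_s)) NULL else cfg$drug_time_s
  jsonlite::write_json(
    c(unclass(cfg), list(network_times_s = truth$network_times_s)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read ground truth from TSV (+ config sidecar)
#'
#' @param path TSV written by [write_ground_truth()].
#' @return a `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  network <- as.numeric(meta$network_times_s)
  meta$network_times_s <- NULL
  cfg <- do.call(sim_config, meta)
  roi_ids <- sprintf("roi%03d", seq_len(cfg$n_rois))
  ev <- lapply(roi_ids, function(id) sort(df$event_time_s[df$roi_id == id]))
  structure(list(event_times_s = ev, network_times_s = network,
                 config = cfg),
            class = "ground_truth")
}

#' Write detected events as TSV
#'
#' Columns: roi_id, onset_frame, onset_time_s, peak_frame, peak_time_s,
#' peak_dff. ROI labels and the frame rate go to a `<path>.json` sidecar
#' so the full ROI set (including event-free ROIs) survives the round
#' trip.
#'
#' @param events a `ca_events`.
#' @param path TSV path.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "ca_events"))
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = attr(events, "frame_rate_hz"),
         roi_ids = attr(events, "roi_ids")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detected events from TSV
#'
#' @param path TSV written by [write_events()].
#' @return a `ca_events`.
#' @export
read_events <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", rep("numeric", 5)))
  ca_events(df, meta$frame_rate_hz, roi_ids = as.character(meta$roi_ids))
}

#' Write per-ROI preprocessing statistics as TSV
#'
#' @param dffset a `dff_traces`.
#' @param path TSV path (columns roi_id, f0, sigma_dff, sigma_deriv).
#' @export
write_roi_stats <- function(dffset, path) {
  stopifnot(inherits(dffset, "dff_traces"))
  df <- data.frame(roi_id = dffset$roi_ids,
                   f0 = unname(dffset$f0),
                   sigma_dff = unname(dffset$sigma_dff),
                   sigma_deriv = unname(dffset$sigma_deriv))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
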