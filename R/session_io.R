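#' Write a recording session to disk (JSON header + binary payload)
#'
#' The session format is a versioned JSON header (`<base>.json`) holding
#' the schedule, channel names, rates, sync events and ground truth, plus
#' a little-endian float64 payload (`<base>.dat`) containing, for each
#' block in schedule order, the LFP matrix then the EEG matrix, each in
#' column (channel) order. Parsing the proprietary device export is
#' explicitly not attempted.
#'
#' @param session a [generate_session()] output
#' @param base path prefix (without extension)
#' @return `base`, invisibly
#' @export
write_session <- function(session, base) {
  counts <- lapply(seq_len(nrow(session$schedule)), function(i) {
    e <- session$data[[i]]
    list(lfp = if (is.null(e$lfp)) 0L else nrow(e$lfp),
         eeg = if (is.null(e$eeg)) 0L else nrow(e$eeg))
  })
  header <- list(
    format = "betalens-session", version = 1L,
    lfp_channels = session$lfp_channels, lfp_rate = session$lfp_rate,
    eeg_channels = session$eeg_channels, eeg_rate = session$eeg_rate,
    schedule = session$schedule,
    sample_counts = counts,
    sync = session$sync,
    ground_truth = if (!is.null(session$ground_truth))
      list(blocks = session$ground_truth$blocks,
           gains = session$ground_truth$gains,
           days = session$ground_truth$days) else NULL)
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(session$schedule))) {
    e <- session$data[[i]]
    if (!is.null(e$lfp)) writeBin(as.numeric(e$lfp), con, size = 8,
                                  endian = "little")
    if (!is.null(e$eeg)) writeBin(as.numeric(e$eeg), con, size = 8,
                                  endian = "little")
  }
  invisible(base)
}

#' Read a recording session written by [write_session()]
#'
#' @param base path prefix used when writing
#' @return a `recording_session`
#' @export
read_session <- function(base) {
  jp <- paste0(base, ".json"); dp <- paste0(base, ".dat")
  if (!file.exists(jp)) abort_invalid(paste0("missing header file: ", jp))
  h <- jsonlite::read_json(jp, simplifyVector = TRUE)
  if (!identical(h$format, "betalens-session"))
    abort_invalid("not a betalens session header (field 'format')")
  for (fld in c("lfp_channels", "eeg_channels", "lfp_rate", "eeg_rate",
                "schedule", "sample_counts"))
    if (is.null(h[[fld]]))
      abort_invalid(paste0("session header missing field '", fld, "'"))
  lay <- channel_layout()
  miss <- setdiff(names(lay$lfp), h$lfp_channels)
  if (length(miss))
    abort_invalid(paste0("session missing required LFP channel(s): ",
                         paste(miss, collapse = ", ")))
  sched <- as.data.frame(h$schedule)
  nb <- nrow(sched)
  counts <- as.data.frame(h$sample_counts)
  need <- 0
  for (i in seq_len(nb))
    need <- need + counts[i, "lfp"][[1]] * length(h$lfp_channels) +
      counts[i, "eeg"][[1]] * length(h$eeg_channels)
  if (!file.exists(dp)) abort_invalid(paste0("missing payload file: ", dp))
  have <- file.info(dp)$size / 8
  if (have != need)
    abort_invalid(sprintf(
      "payload length mismatch: %d samples on disk, header requires %d",
      have, need))
  con <- file(dp, "rb")
  on.exit(close(con))
  data <- vector("list", nb)
  for (i in seq_len(nb)) {
    e <- list()
    nl <- counts[i, "lfp"][[1]]; ne <- counts[i, "eeg"][[1]]
    if (nl > 0) {
      v <- readBin(con, "numeric", nl * length(h$lfp_channels), size = 8,
                   endian = "little")
      e$lfp <- matrix(v, nl, length(h$lfp_channels),
                      dimnames = list(NULL, h$lfp_channels))
    }
    if (ne > 0) {
      v <- readBin(con, "numeric", ne * length(h$eeg_channels), size = 8,
                   endian = "little")
      e$eeg <- matrix(v, ne, length(h$eeg_channels),
                      dimnames = list(NULL, h$eeg_channels))
    }
    data[[i]] <- e
  }
  gt <- NULL
  if (!is.null(h$ground_truth))
    gt <- list(blocks = as.data.frame(h$ground_truth$blocks),
               gains = h$ground_truth$gains, days = h$ground_truth$days)
  structure(list(schedule = sched, data = data, sync = h$sync,
                 lfp_channels = h$lfp_channels, lfp_rate = h$lfp_rate,
                 eeg_channels = h$eeg_channels, eeg_rate = h$eeg_rate,
                 ground_truth = gt, spec = NULL),
            class = "recording_session")
}
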