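# Delimited-text import/export for the portable session pieces. Times are
# seconds from session start throughout.

#' Write / read a trial table as delimited text
#'
#' Two tab-separated tables, `<prefix>_trials.tsv` (one row per trial) and
#' `<prefix>_stimuli.tsv` (one row per stimulus presentation).
#'
#' @param trialTable a [TrialTable-class].
#' @param prefix file path prefix.
#' @return `writeTrialTable` returns the two paths invisibly;
#'   `readTrialTable` returns the [TrialTable-class].
#' @export
writeTrialTable <- function(trialTable, prefix) {
  pt <- paste0(prefix, "_trials.tsv")
  ps <- paste0(prefix, "_stimuli.tsv")
  write.table(trialTable@trials, pt, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(trialTable@stimuli, ps, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(trials = pt, stimuli = ps))
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(prefix) {
  tr <- read.table(paste0(prefix, "_trials.tsv"), header = TRUE,
                   sep = "\t", colClasses = NA)
  st <- read.table(paste0(prefix, "_stimuli.tsv"), header = TRUE,
                   sep = "\t", colClasses = NA)
  st$label <- as.character(st$label)
  new("TrialTable", trials = tr, stimuli = st, sessionEnd = max(tr$end))
}

#' Export spike events as delimited text
#'
#' One event per row (`unit`, `trial`, `time_s`), expanding binned counts
#' into per-spike rows at the bin start time.
#'
#' @param spikes a [BinnedSpikes-class].
#' @param path output file.
#' @export
writeSpikeEvents <- function(spikes, path) {
  cnt <- spikeCounts(spikes)
  bi <- binInfo(spikes)
  rows <- which(cnt > 0, arr.ind = TRUE)
  ev <- data.frame(unit = rownames(cnt)[rows[, 1L]],
                   trial = bi$trial[rows[, 2L]],
                   time_s = bi$time[rows[, 2L]],
                   count = cnt[rows])
  ev <- ev[rep(seq_len(nrow(ev)), ev$count), c("unit", "trial", "time_s")]
  ev <- ev[order(ev$time_s, ev$unit), ]
  write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a frame stack
#'
#' R-native serialized array container for video frame stacks (frames,
#' frame rate and view label).
#'
#' @param frames a [FrameStack-class].
#' @param path output file.
#' @export
writeFrameStack <- function(frames, path) {
  saveRDS(list(frames = frames@frames, frameRate = frames@frameRate,
               view = frames@view), path)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  x <- readRDS(path)
  new("FrameStack", frames = x$frames, frameRate = x$frameRate,
      view = x$view)
}

#' Export a design matrix: column metadata plus values
#'
#' Writes `<prefix>_columns.tsv` (group, source, shift, center, scale,
#' zero-variance flag per column) and `<prefix>_values.tsv` (the z-scored
#' design, bins in rows).
#'
#' @param design a [DesignMatrix-class].
#' @param prefix file path prefix.
#' @export
writeDesign <- function(design, prefix) {
  meta <- cbind(design@columnMeta,
                center = design@center, scale = design@scale,
                zeroVar = design@zeroVar)
  pm <- paste0(prefix, "_columns.tsv")
  pv <- paste0(prefix, "_values.tsv")
  write.table(meta, pm, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(design@X, pv, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(c(columns = pm, values = pv))
}
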