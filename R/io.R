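#' Read and write recordings and epoch sets
#'
#' On-disk container: a plain CSV holding the samples plus a JSON sidecar
#' holding everything else (sampling rate, channel names, events or labels,
#' seed). `path` is a basename; `<path>.csv` and `<path>.json` are written.
#'
#' For a recording the CSV is time x channels (one column per channel). For
#' an epoch set the CSV is long-ish: one row per (trial, channel) with the
#' time samples as remaining columns.
#'
#' @param x a `subject_recording` or [epoch_set()].
#' @param path basename (without extension) for the CSV/JSON pair.
#' @return `write_*` return `path` invisibly; `read_*` return the
#'   reconstructed object.
#' @name container_io
NULL

#' @rdname container_io
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "subject_recording"))
  df <- as.data.frame(t(x$samples))
  names(df) <- x$montage$channel_names
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(kind = "subject_recording", rate = x$rate,
               channel_names = x$montage$channel_names,
               montage_name = x$montage$name,
               frontocentral_weights = x$montage$frontocentral_weights,
               events = x$events, seed = x$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname container_io
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "subject_recording"))
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  m <- montage(if (meta$montage_name %in% c("gel64", "gel16", "dry20"))
                 meta$montage_name else "custom",
               channel_names = meta$channel_names,
               sampling_rate = meta$rate,
               frontocentral_weights = meta$frontocentral_weights)
  samples <- t(as.matrix(df))
  rownames(samples) <- meta$channel_names
  structure(list(samples = samples,
                 events = data.frame(sample = as.integer(meta$events$sample),
                                     label = meta$events$label,
                                     stringsAsFactors = FALSE),
                 montage = m, rate = meta$rate, seed = meta$seed,
                 errp = NULL),
            class = "subject_recording")
}

#' @rdname container_io
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(x$channel_names, d[1]))
  df <- cbind(df, as.data.frame(flat))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(kind = "epoch_set", rate = x$rate,
               channel_names = x$channel_names, labels = x$labels,
               onset_index = x$onset_index, n_time = d[3])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname container_io
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "epoch_set"))
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  nc <- length(meta$channel_names)
  nt <- length(meta$labels)
  flat <- as.matrix(df[, -(1:2), drop = FALSE])
  dat <- aperm(array(t(flat), dim = c(meta$n_time, nc, nt)), c(3, 2, 1))
  epoch_set(dat, meta$labels, meta$rate, meta$channel_names,
            meta$onset_index)
}
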