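#' Write / read a hypnogram CSV
#'
#' Columns: `epoch_index` (1-based), `zt_hours` (epoch midpoint ZT) and
#' `state`. The epoch length and ZT anchor are recovered from the
#' `zt_hours` column on read.
#'
#' @param h a [hypnogram].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  utils::write.csv(data.frame(epoch_index = seq_along(h$states),
                              zt_hours = epoch_zt(h), state = h$states),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @param source label source recorded in the hypnogram object.
#' @export
read_hypnogram <- function(path, source = "human") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "zt_hours", "state") %in% names(d)))
  if (nrow(d) < 2) stop("hypnogram CSV needs at least 2 epochs")
  epoch_s <- round((d$zt_hours[2] - d$zt_hours[1]) * 3600, 6)
  start_zt <- d$zt_hours[1] - epoch_s / 7200
  hypnogram(d$state, epoch_s = epoch_s, start_zt = start_zt,
            source = source)
}

#' Write / read a partial label CSV
#'
#' Same columns as the hypnogram CSV but with only the labelled
#' fraction of rows present.
#'
#' @param labels data.frame with `epoch`, `state` (as produced by
#'   [sample_labels()]).
#' @param h the [hypnogram] grid the labels refer to (supplies ZT).
#' @param path CSV path.
#' @export
write_labels <- function(labels, h, path) {
  zt <- epoch_zt(h)
  utils::write.csv(data.frame(epoch_index = labels$epoch,
                              zt_hours = zt[labels$epoch],
                              state = labels$state),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "state") %in% names(d)))
  data.frame(epoch = d$epoch_index, state = d$state)
}
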