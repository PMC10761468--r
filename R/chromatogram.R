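#' Chromatogram container
#'
#' A chromatogram is a data frame with a strictly increasing `time_s` column
#' followed by one numeric column per species (or signal channel).
#'
#' @param time_s Time grid in seconds, strictly increasing.
#' @param ... Named numeric vectors, one per species/channel, same length as
#'   `time_s`.
#' @return A data frame of class `chromatogram`.
#' @examples
#' chromatogram(time_s = 0:5, tris = c(0, 0, 1, 2, 1, 0))
#' @export
chromatogram <- function(time_s, ...) {
  chans <- list(...)
  if (length(chans) == 0) stop("at least one signal channel required", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (!all(vapply(chans, length, 1L) == length(time_s)))
    stop("all channels must match the time grid length", call. = FALSE)
  if (!all(vapply(chans, function(x) all(is.finite(x)), TRUE)))
    stop("chromatogram values must be finite", call. = FALSE)
  out <- data.frame(time_s = time_s, chans, check.names = FALSE)
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Names of the signal channels in a chromatogram
#' @param chrom A [chromatogram()].
#' @return Character vector of channel (species) names.
#' @export
chrom_channels <- function(chrom) setdiff(names(chrom), "time_s")

#' First temporal moment of a chromatographic trace
#'
#' Mean residence time of a pulse: integral(t c dt) / integral(c dt) by
#' trapezoidal quadrature. Optionally corrects for the injection plug width
#' (subtracting half of it), which matters when pulses are wide relative to
#' retention.
#'
#' @param chrom A [chromatogram()].
#' @param channel Channel name; defaults to the first channel.
#' @param injection_width Rectangular injection width in s to correct for
#'   (half is subtracted). Default 0 (no correction).
#' @return First moment in seconds.
#' @export
first_moment <- function(chrom, channel = chrom_channels(chrom)[1],
                         injection_width = 0) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time_s
  c <- chrom[[channel]]
  if (is.null(c)) stop("unknown channel: ", channel, call. = FALSE)
  area <- trapz(t, c)
  if (area <= 0)
    stop("undefined moment: trace '", channel, "' has nonpositive integral",
         call. = FALSE)
  trapz(t, t * c) / area - injection_width / 2
}

#' Trapezoidal quadrature
#' @param x Abscissae (increasing).
#' @param y Ordinates.
#' @return The trapezoidal integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Write / read a chromatogram as CSV
#'
#' Plain CSV with a `time_s` column followed by one column per channel;
#' round-trips exactly at full double precision.
#'
#' @param chrom A [chromatogram()].
#' @param path File path.
#' @return `read_chromatogram` returns a [chromatogram()];
#'   `write_chromatogram` returns `path` invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  df <- as.data.frame(chrom)
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("malformed chromatogram CSV (no time_s column): ", path, call. = FALSE)
  do.call(chromatogram, c(list(time_s = df$time_s),
                          as.list(df[setdiff(names(df), "time_s")])))
}
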