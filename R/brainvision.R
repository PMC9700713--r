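# Minimal BrainVision (.vhdr / .vmrk / .eeg) reader for continuous input.
# Supports the common configuration: multiplexed binary data in
# IEEE_FLOAT_32 or INT_16 with per-channel resolution, and stimulus markers.

parse_vhdr_sections <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("\\[|\\]", "", ln)
      out[[sec]] <- character(0)
    } else if (!is.null(sec)) out[[sec]] <- c(out[[sec]], ln)
  }
  out
}

kv <- function(section) {
  eqs <- grepl("=", section, fixed = TRUE)
  keys <- sub("=.*$", "", section[eqs])
  vals <- sub("^[^=]*=", "", section[eqs])
  stats::setNames(vals, keys)
}

#' Read a BrainVision recording
#'
#' Reads the text header (.vhdr), binary data file (.eeg; multiplexed
#' IEEE_FLOAT_32 or INT_16), and marker file (.vmrk). Stimulus markers
#' become events; channel roles default to `"scalp"` except names matching
#' `eog_pattern`.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @param montage optional montage data.frame supplying 2D positions by
#'   channel name (default [montage_1020()]).
#' @param eog_pattern regex marking EOG channels (default `"EOG"`).
#' @param deviant_marker marker description treated as deviant (label 1);
#'   all other stimulus markers get label 0. Default `"S  2"`.
#' @return a `continuous_recording`.
#' @export
read_brainvision <- function(vhdr, montage = montage_1020(),
                             eog_pattern = "EOG", deviant_marker = "S  2") {
  hdr <- parse_vhdr_sections(readLines(vhdr, warn = FALSE))
  ci <- kv(hdr[["Common Infos"]])
  bi <- kv(hdr[["Binary Infos"]])
  if (!identical(toupper(ci[["DataOrientation"]]), "MULTIPLEXED"))
    stop("only multiplexed BrainVision data supported", call. = FALSE)
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  fmt <- toupper(bi[["BinaryFormat"]])

  chl <- kv(hdr[["Channel Infos"]])
  parts <- strsplit(unname(chl), ",")
  names_ch <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r) || length(p) < 3 || p[3] == "") 1 else r
  }, 0)

  dirn <- dirname(vhdr)
  datafile <- file.path(dirn, ci[["DataFile"]])
  raw_n <- file.info(datafile)$size
  if (fmt == "IEEE_FLOAT_32") {
    x <- readBin(datafile, "numeric", n = raw_n / 4, size = 4)
  } else if (fmt == "INT_16") {
    x <- readBin(datafile, "integer", n = raw_n / 2, size = 2, signed = TRUE)
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  n_s <- length(x) / n_ch
  data <- matrix(x, nrow = n_ch)          # multiplexed: channel fastest
  data <- data * res                      # resolution to microvolts

  events <- data.frame(sample = integer(0), label = integer(0))
  if (!is.null(ci[["MarkerFile"]])) {
    mrk <- parse_vhdr_sections(readLines(file.path(dirn, ci[["MarkerFile"]]),
                                         warn = FALSE))
    mk <- kv(mrk[["Marker Infos"]])
    mp <- strsplit(unname(mk), ",")
    is_stim <- vapply(mp, function(p) identical(p[1], "Stimulus"), TRUE)
    if (any(is_stim)) {
      desc <- vapply(mp[is_stim], `[`, "", 2)
      samp <- as.integer(vapply(mp[is_stim], `[`, "", 3))
      events <- data.frame(sample = samp,
                           label = as.integer(desc == deviant_marker))
    }
  }
  channels <- data.frame(
    name = names_ch,
    x = montage$x[match(names_ch, montage$name)],
    y = montage$y[match(names_ch, montage$name)],
    role = ifelse(grepl(eog_pattern, names_ch, ignore.case = TRUE),
                  "eog", "scalp"),
    stringsAsFactors = FALSE)
  continuous_recording(data, srate, events, channels)
}
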