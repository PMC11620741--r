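# Minimal reader for Axon Binary Format version 1 (pre-ABF2) episodic files,
# the vendor format of Digidata/Axoclamp acquisition systems. Covers the
# header subset needed to recover per-sweep voltage traces: signature,
# episodic layout, data section pointer, int16/float32 data, per-channel
# scaling and unit strings. ABF2 ("ABF2" signature) is not supported.

abf1_offsets <- list(
  signature = 0L,          # char[4], "ABF " for version 1
  file_version = 4L,       # float
  operation_mode = 8L,     # int16, 5 = episodic
  actual_acq_length = 10L, # int32, total samples across channels
  actual_episodes = 16L,   # int32
  data_section_ptr = 40L,  # int32, 512-byte blocks
  data_format = 100L,      # int16, 0 = int16, 1 = float32
  adc_num_channels = 120L, # int16
  adc_sample_interval = 122L, # float, us per multiplexed sample
  samples_per_episode = 138L, # int32, across channels
  adc_range = 244L,        # float
  adc_resolution = 252L,   # int32
  sampling_seq = 378L,     # int16[16]
  channel_names = 410L,    # char[16][10]
  channel_units = 602L,    # char[16][8]
  programmable_gain = 922L,   # float[16]
  instrument_scale = 1050L,   # float[16]
  instrument_offset = 1114L,  # float[16]
  signal_gain = 1178L         # float[16]
)

read_at <- function(con, offset, what, n = 1L, size = NA_integer_) {
  seek(con, where = offset, origin = "start")
  readBin(con, what = what, n = n, size = size, endian = "little")
}

read_strings_at <- function(con, offset, n_strings, width) {
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, "raw", n = n_strings * width)
  vapply(seq_len(n_strings), function(i) {
    chunk <- raw[((i - 1) * width + 1):(i * width)]
    chunk <- chunk[chunk != as.raw(0)]
    trimws(rawToChar(chunk))
  }, "")
}

# "mV", "V", "uV", optionally with a numeric prefix like "0.1 mV" -> factor
# converting recorded values to mV
unit_to_mv_factor <- function(unit, path, channel) {
  m <- regmatches(unit, regexec("^\\s*([0-9.eE+-]*)\\s*(uV|mV|V)\\s*$", unit))[[1]]
  if (length(m) == 0)
    stop(sprintf("import error [%s, channel '%s']: unknown unit '%s'",
                 path, channel, unit), call. = FALSE)
  prefix <- if (nzchar(m[2])) as.numeric(m[2]) else 1
  base <- switch(m[3], uV = 1e-3, mV = 1, V = 1e3)
  prefix * base
}

#' Import an Axon Binary Format (ABF1) recording
#'
#' Reads an episodic ABF version-1 file and returns one [trial_recording()]
#' per sweep, with voltages converted to mV (per-channel scale factors, gains,
#' offsets and unit strings applied) and the sampling rate taken from the file
#' header. Sweeps without a protocol mapping are skipped, never silently
#' dropped: the count of skipped sweeps is attached as `attr(x, "skipped")`.
#'
#' @param path ABF file path.
#' @param channel_map name of the membrane-potential channel as recorded in
#'   the file's channel-name table (or `list(voltage = <name>)`).
#' @param protocol_map a single [stimulus_protocol()] applied to every sweep,
#'   or a list with one entry per sweep (`NULL` entries skip the sweep). The
#'   deposit's internal condition encoding is not standardized, so this
#'   mapping is caller-supplied.
#' @param t0_ms time of each sweep's first sample relative to the first
#'   stimulus event (negative for pre-stimulus padding).
#' @param cell a [cell_meta()] for the recordings (default: unknown cell).
#' @return list of [trial_recording()]s with attribute `skipped`.
#' @export
import_abf <- function(path, channel_map, protocol_map, t0_ms = -50,
                       cell = NULL) {
  if (!file.exists(path)) stop("import error: no such file: ", path, call. = FALSE)
  chan_name <- if (is.list(channel_map)) channel_map$voltage else channel_map
  if (is.null(chan_name)) stop("channel_map must name a voltage channel", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  o <- abf1_offsets
  sig <- rawToChar(read_at(con, o$signature, "raw", 4L))
  if (identical(sig, "ABF2"))
    stop("import error [", path, "]: ABF2 files are not supported", call. = FALSE)
  if (!identical(sig, "ABF "))
    stop("import error [", path, "]: not an ABF file (signature '", sig, "')",
         call. = FALSE)
  n_chan <- read_at(con, o$adc_num_channels, "integer", size = 2L)
  n_episodes <- read_at(con, o$actual_episodes, "integer", size = 4L)
  acq_len <- read_at(con, o$actual_acq_length, "integer", size = 4L)
  per_episode <- read_at(con, o$samples_per_episode, "integer", size = 4L)
  data_format <- read_at(con, o$data_format, "integer", size = 2L)
  data_ptr <- read_at(con, o$data_section_ptr, "integer", size = 4L)
  interval_us <- read_at(con, o$adc_sample_interval, "numeric", size = 4L)
  adc_range <- read_at(con, o$adc_range, "numeric", size = 4L)
  adc_res <- read_at(con, o$adc_resolution, "integer", size = 4L)
  seq16 <- read_at(con, o$sampling_seq, "integer", n = 16L, size = 2L)
  names16 <- read_strings_at(con, o$channel_names, 16L, 10L)
  units16 <- read_strings_at(con, o$channel_units, 16L, 8L)
  pgain <- read_at(con, o$programmable_gain, "numeric", n = 16L, size = 4L)
  iscale <- read_at(con, o$instrument_scale, "numeric", n = 16L, size = 4L)
  ioffset <- read_at(con, o$instrument_offset, "numeric", n = 16L, size = 4L)
  sgain <- read_at(con, o$signal_gain, "numeric", n = 16L, size = 4L)

  active <- seq16[seq_len(n_chan)] + 1L  # ADC numbers of multiplexed channels
  pos <- which(names16[active] == chan_name)
  if (length(pos) != 1)
    stop(sprintf("import error [%s]: channel '%s' not found (channels: %s)",
                 path, chan_name, paste(names16[active], collapse = ", ")),
         call. = FALSE)
  adc <- active[pos]
  mv_factor <- unit_to_mv_factor(units16[adc], path, chan_name)
  fs_hz <- 1e6 / (interval_us * n_chan)  # per-channel rate

  seek(con, where = data_ptr * 512, origin = "start")
  raw_data <- if (data_format == 0L) {
    readBin(con, "integer", n = acq_len, size = 2L, endian = "little")
  } else if (data_format == 1L) {
    readBin(con, "numeric", n = acq_len, size = 4L, endian = "little")
  } else {
    stop("import error [", path, "]: unsupported data format ", data_format,
         call. = FALSE)
  }
  if (length(raw_data) < acq_len)
    stop("import error [", path, "]: truncated data section", call. = FALSE)

  if (is.null(cell)) cell <- cell_meta("unknown", "left", NA_real_)
  single_protocol <- inherits(protocol_map, "stimulus_protocol")
  if (!single_protocol)
    stopifnot(is.list(protocol_map), length(protocol_map) >= n_episodes)

  per_chan <- per_episode %/% n_chan
  out <- list()
  skipped <- 0L
  for (ep in seq_len(n_episodes)) {
    proto <- if (single_protocol) protocol_map else protocol_map[[ep]]
    if (is.null(proto)) { skipped <- skipped + 1L; next }
    block <- raw_data[((ep - 1) * per_episode + 1):(ep * per_episode)]
    chan_samples <- block[seq(pos, length(block), by = n_chan)]
    v <- if (data_format == 0L) {
      chan_samples * adc_range / adc_res /
        (iscale[adc] * pgain[adc] * sgain[adc]) + ioffset[adc]
    } else {
      chan_samples
    }
    v <- v * mv_factor
    out[[length(out) + 1L]] <-
      trial_recording(mcell_trace(v, fs_hz, t0_ms), proto, cell,
                      fired = FALSE, trial_index = ep)
  }
  stopifnot(length(out) + skipped == n_episodes)
  attr(out, "skipped") <- skipped
  out
}
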