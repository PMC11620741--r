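# Neutral plain-text trial-bundle format: a directory with
#   trials.csv                 per-trial metadata table
#   traces/trial_<k>.csv       one two-column CSV (time_ms, voltage_mV) each
#   protocols/<label>.json     one protocol document per condition label
#   manifest.json              file list with md5 content hashes
# CSVs are RFC-4180, "." decimal, UTF-8; voltages are absolute membrane
# potential in mV; t = 0 is the first stimulus event.

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

# label -> filesystem-safe token (labels themselves may be unicode; the
# mapping is recorded in trials.csv so it need not be invertible)
safe_token <- function(label, idx) {
  tok <- gsub("[^A-Za-z0-9._-]", "_", label)
  if (nchar(tok) == 0) tok <- sprintf("protocol_%d", idx)
  tok
}

#' Write a trial bundle
#'
#' Writes a collection of [trial_recording()]s as a diffable plain-text
#' directory bundle with a JSON manifest of md5 content hashes.
#'
#' @param trials non-empty list of [trial_recording()]s.
#' @param path directory to create (must not be an existing non-empty file).
#' @return (invisibly) the manifest as a list.
#' @export
write_bundle <- function(trials, path) {
  stopifnot(is.list(trials))
  if (length(trials) == 0) stop("empty trial collection", call. = FALSE)
  stopifnot(all(vapply(trials, inherits, TRUE, "trial_recording")))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path, call. = FALSE)
  dir.create(file.path(path, "traces"), showWarnings = FALSE)
  dir.create(file.path(path, "protocols"), showWarnings = FALSE)

  labels <- vapply(trials, function(tr) tr$protocol$label, "")
  ulab <- unique(labels)
  ptok <- vapply(seq_along(ulab), function(i) safe_token(ulab[i], i), "")
  # disambiguate clashing tokens
  ptok <- make.unique(ptok, sep = "_")
  names(ptok) <- ulab
  for (lab in ulab) {
    write_protocol_json(trials[[match(lab, labels)]]$protocol,
                        file.path(path, "protocols", paste0(ptok[[lab]], ".json")))
  }

  meta <- data.frame(
    trial_index = vapply(trials, `[[`, 1L, "trial_index"),
    fish_id = vapply(trials, function(tr) tr$cell$fish_id, ""),
    cell_side = vapply(trials, function(tr) tr$cell$cell_side, ""),
    condition_label = labels,
    resting_potential_mV = vapply(trials, function(tr) tr$cell$resting_potential_mV, 1),
    fired = vapply(trials, `[[`, TRUE, "fired"),
    fs_hz = vapply(trials, function(tr) tr$trace$fs_hz, 1),
    trace_file = sprintf("traces/trial_%04d.csv", seq_along(trials)),
    protocol_file = file.path("protocols", paste0(ptok[labels], ".json")),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    d <- data.frame(time_ms = fmt_num(trace_time_ms(tr$trace)),
                    voltage_mV = fmt_num(tr$trace$samples_mV))
    utils::write.csv(d, file.path(path, meta$trace_file[i]),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  utils::write.csv(meta, file.path(path, "trials.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")

  files <- c("trials.csv", meta$trace_file,
             unique(as.character(meta$protocol_file)))
  hashes <- unname(tools::md5sum(file.path(path, files)))
  manifest <- list(format = "mcellmsi-bundle", version = 1L,
                   n_trials = length(trials),
                   files = data.frame(file = files, md5 = hashes,
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a trial bundle
#'
#' Lossless inverse of [write_bundle()]: verifies every manifest hash before
#' reading (any mismatch or missing file raises a corrupt-bundle error) and
#' rebuilds the [trial_recording()]s. Trials whose resting potential falls
#' outside the inclusion interval \[-90, -70\] mV are loaded but carry
#' `cell$included = FALSE`.
#'
#' @param path bundle directory.
#' @return list of [trial_recording()]s.
#' @export
read_bundle <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("corrupt bundle: manifest.json missing", call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- manifest$files
  for (i in seq_len(nrow(files))) {
    f <- file.path(path, files$file[i])
    if (!file.exists(f))
      stop("corrupt bundle: missing file ", files$file[i], call. = FALSE)
    h <- unname(tools::md5sum(f))
    if (!identical(h, files$md5[i]))
      stop("corrupt bundle: hash mismatch for ", files$file[i], call. = FALSE)
  }
  meta <- utils::read.csv(file.path(path, "trials.csv"),
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  protocols <- new.env()
  lapply(seq_len(nrow(meta)), function(i) {
    pf <- meta$protocol_file[i]
    if (is.null(protocols[[pf]]))
      protocols[[pf]] <- read_protocol_json(file.path(path, pf))
    d <- utils::read.csv(file.path(path, meta$trace_file[i]),
                         stringsAsFactors = FALSE)
    trace <- mcell_trace(d$voltage_mV, meta$fs_hz[i], t0_ms = d$time_ms[1])
    cell <- cell_meta(meta$fish_id[i], meta$cell_side[i],
                      meta$resting_potential_mV[i])
    trial_recording(trace, protocols[[pf]], cell, fired = meta$fired[i],
                    trial_index = meta$trial_index[i])
  })
}
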