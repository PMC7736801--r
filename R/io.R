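#' Read a reference sequence from FASTA
#'
#' @param path FASTA file (single or multi-record).
#' @param record Record to use (index or name); default the first.
#' @return Character string (upper case), named by the record id.
#' @export
read_fasta <- function(path, record = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in ", path)
  s <- seqs[[record]]
  out <- toupper(as.character(s))
  names(out) <- names(seqs)[if (is.numeric(record)) record
                            else match(record, names(seqs))]
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

droplet_channels <- function(df) {
  grep("^ch", names(df), value = TRUE)
}

#' Read a droplet-array table
#'
#' Accepts the four-colour sequencing dialect
#' (`index,diameter_um,ch532,ch594,ch655,ch701`) and the two-channel
#' methylation-plate dialect (`index,diameter_um,ch1,ch2`), auto-detected
#' from the header.
#'
#' @param path CSV path.
#' @return Data frame with an attribute `dialect` (`"sequencing"` or
#'   `"methylation"`).
#' @export
read_droplet_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("index", "diameter_um"))
    if (!col %in% names(df))
      stop("droplet table is missing required column '", col, "'")
  chans <- droplet_channels(df)
  if (length(chans) == 0L)
    stop("droplet table has no channel ('ch*') columns")
  for (ch in chans) {
    bad <- which(!is.finite(df[[ch]]) | df[[ch]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive intensity in column '%s' at line %d",
                   ch, bad[1] + 1L)) # +1 for the header line
  }
  if (anyDuplicated(df$index))
    stop("droplet indices must be unique")
  attr(df, "dialect") <- if (setequal(chans, c("ch1", "ch2")))
    "methylation" else "sequencing"
  df
}

#' Write a droplet-array table
#' @param records Droplet record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the droplet truth sidecar
#'
#' `index,captured,contaminants`, multisets as sorted base strings.
#'
#' @param truths A `droplet_truth` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truths, path) {
  write.csv(truths[, c("index", "captured", "contaminants")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-channel mixture-fit reports as JSON
#' @param fits Named list of `mixture_fit`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rep <- lapply(fits, function(f) list(
    weights = f$weights, location = f$location, scale = f$scale,
    family = f$family, crossing_point = f$crossing_point,
    crossing_intensity = f$crossing_intensity,
    fp_overlap = f$fp_overlap, fn_overlap = f$fn_overlap,
    loglik = f$loglik, n_iter = f$n_iter, converged = f$converged,
    n_obs = f$n_obs))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write occupancy calls as CSV (`index,channel,occupied,posterior`)
#' @param calls Call data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a set-read as CSV (`position,index,bases`)
#' @param read A `set_read`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_set_read <- function(read, path) {
  df <- data.frame(position = seq_along(read$droplets) - 1L,
                   index = read$index,
                   bases = vapply(read$droplets, paste, character(1),
                                  collapse = ""))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a set-read back from its CSV serialization
#' @param path CSV path written by [write_set_read()].
#' @return A `set_read`.
#' @export
read_set_read <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(bases = "character"))
  set_read(strsplit(df$bases, "", fixed = TRUE), df$index)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file mirrors the [sim_config()] field names; `intensity_model` is
#' given as lists `unoccupied`/`occupied` of `(location, scale)` plus
#' `occupied_weight` (omitted fields fall back to package defaults).
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  as_sim_config(raw)
}

as_sim_config <- function(raw) {
  im <- if (is.null(raw$intensity_model)) default_intensity_model()
  else do.call(intensity_model, raw$intensity_model[
    intersect(names(raw$intensity_model),
              c("unoccupied", "occupied", "occupied_weight", "family", "df"))])
  args <- raw[intersect(names(raw),
                        c("n_droplets", "capture_rate", "sampling_rate_hz",
                          "contamination_rate", "misidentify_rate", "seed"))]
  if (!is.null(raw$channel_map)) args$channel_map <- unlist(raw$channel_map)
  args$intensity_model <- im
  do.call(sim_config, args)
}
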