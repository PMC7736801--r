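#' Classify two-channel droplets into empty / dCTP / 5mdCTP
#'
#' In the two-channel 5-methylcytosine assay, channel 1 fluoresces when
#' either dCTP or 5mdCTP is captured while channel 2 fluoresces only for
#' unmethylated dCTP (its recognition step is blocked by the methyl
#' mark). Occupancy is called per channel from the fitted intensity
#' mixtures and combined by truth table: both unoccupied = `empty`, both
#' occupied = `dCTP`, channel 1 only = `5mdCTP`, channel 2 only =
#' `inconsistent` (flagged and retained — these events estimate the
#' modification-call error rate).
#'
#' @param records Data frame with `index` and two intensity columns named
#'   as in `fits` (typically `ch1`, `ch2`).
#' @param fits Named list of two converged `mixture_fit`s.
#'
#' @return Data frame `index`, `ch1_posterior`, `ch2_posterior`, `label`
#'   (factor with levels `empty`, `dCTP`, `5mdCTP`, `inconsistent`).
#' @export
classify_two_channel <- function(records, fits) {
  stopifnot(is.data.frame(records), "index" %in% names(records))
  if (length(fits) != 2L || is.null(names(fits)))
    stop("fits must be a named list of two mixture fits")
  missing <- setdiff(names(fits), names(records))
  if (length(missing))
    stop("missing channel column: ", paste(missing, collapse = ", "))
  ch <- names(fits)
  p1 <- occupancy_posterior(records[[ch[1]]], fits[[ch[1]]])
  p2 <- occupancy_posterior(records[[ch[2]]], fits[[ch[2]]])
  occ1 <- is_occupied(p1)
  occ2 <- is_occupied(p2)
  label <- ifelse(occ1 & occ2, "dCTP",
                  ifelse(occ1, "5mdCTP",
                         ifelse(occ2, "inconsistent", "empty")))
  data.frame(index = records$index,
             ch1_posterior = p1, ch2_posterior = p2,
             label = factor(label, levels = c("empty", "dCTP", "5mdCTP",
                                              "inconsistent")),
             stringsAsFactors = FALSE)
}
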