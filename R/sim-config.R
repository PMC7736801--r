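#' Default base-to-channel assignment
#'
#' Four detection channels named by fluorophore emission wavelength.
#' dATP reports in the 532 nm channel and dGTP in the 655 nm channel;
#' the dCTP and dTTP assignments are instrument conventions and can be
#' remapped freely.
#'
#' @return Named character vector mapping base (`A`, `C`, `G`, `T`) to
#'   channel column name.
#' @export
default_channel_map <- function() {
  c(A = "ch532", C = "ch594", G = "ch655", T = "ch701")
}

#' Two-component intensity model for one detection channel
#'
#' Describes the fluorescence intensity distribution of unoccupied and
#' occupied droplets as a two-component heavy-tailed mixture. The default
#' family is log-normal: location and scale are the mean and standard
#' deviation of log10 intensity, so both components are heavy-tailed on
#' the linear intensity scale.
#'
#' @param unoccupied,occupied Numeric length-2 vectors `c(location, scale)`
#'   on the log10-intensity scale.
#' @param occupied_weight Prior fraction of occupied droplets used for
#'   calibration and density weighting (default 0.30).
#' @param family Component family tag. `"lognormal"` (Gaussian on log10
#'   intensity) is fully supported; `"student"` adds location-scale
#'   Student-t log10 intensities for simulation only.
#' @param df Degrees of freedom, used only by the `"student"` family.
#'
#' @return An object of class `intensity_model`.
#' @seealso [default_intensity_model()], [calibrate_intensity_model()]
#' @export
intensity_model <- function(unoccupied, occupied, occupied_weight = 0.30,
                            family = c("lognormal", "student"), df = 5) {
  family <- match.arg(family)
  stopifnot(length(unoccupied) == 2, length(occupied) == 2,
            is.finite(unoccupied), is.finite(occupied))
  if (unoccupied[2] <= 0 || occupied[2] <= 0)
    stop("component scales must be > 0")
  if (occupied[1] <= unoccupied[1])
    stop("occupied location must exceed unoccupied location")
  if (occupied_weight <= 0 || occupied_weight >= 1)
    stop("occupied_weight must lie strictly in (0, 1)")
  structure(list(unoccupied = as.numeric(unoccupied),
                 occupied = as.numeric(occupied),
                 occupied_weight = occupied_weight,
                 family = family, df = df),
            class = "intensity_model")
}

#' Calibrate a log-normal intensity model to target overlap error rates
#'
#' Solves for the component scales of a two-component log-normal intensity
#' mixture such that, at the crossing point of the weighted densities, the
#' upper tail mass of the unoccupied component equals `fp` and the lower
#' tail mass of the occupied component equals `fn`. With the component
#' locations and occupancy weight fixed, the two conditions plus the
#' crossing-point identity give a closed form: writing `z_fp = qnorm(1-fp)`
#' and `z_fn = qnorm(fn)`, equality of the weighted densities at the
#' crossing forces `scale_occ / scale_unocc = w1 dnorm(z_fn) / (w0
#' dnorm(z_fp))`, and the crossing location pins `scale_unocc`.
#'
#' @param fp Target fraction of the unoccupied component above the
#'   crossing point (per droplet per colour).
#' @param fn Target fraction of the occupied component below the crossing
#'   point (per base per colour).
#' @param loc_unoccupied,loc_occupied Component locations on log10
#'   intensity.
#' @param occupied_weight Occupied mixture weight.
#'
#' @return An `intensity_model` whose crossing-point overlap reproduces
#'   `fp` and `fn` exactly.
#' @export
calibrate_intensity_model <- function(fp = 0.001, fn = 0.016,
                                      loc_unoccupied = 2.0,
                                      loc_occupied = 3.2,
                                      occupied_weight = 0.30) {
  stopifnot(fp > 0, fp < 0.5, fn > 0, fn < 0.5,
            loc_occupied > loc_unoccupied)
  w0 <- 1 - occupied_weight
  w1 <- occupied_weight
  z_fp <- qnorm(1 - fp)
  z_fn <- qnorm(fn)
  ratio <- w1 * dnorm(z_fn) / (w0 * dnorm(z_fp)) # scale_occ / scale_unocc
  s0 <- (loc_occupied - loc_unoccupied) / (z_fp - z_fn * ratio)
  s1 <- ratio * s0
  intensity_model(unoccupied = c(loc_unoccupied, s0),
                  occupied = c(loc_occupied, s1),
                  occupied_weight = occupied_weight)
}

#' Default intensity model
#'
#' The package default, calibrated so that the crossing-point overlap of
#' the weighted densities yields a false-positive rate of 0.1% per droplet
#' per colour (unoccupied mass above the crossing) and a false-negative
#' rate of 1.6% per base per colour (occupied mass below the crossing),
#' at 30% occupancy with component locations 2.0 and 3.2 log10 units.
#'
#' @return An `intensity_model`.
#' @export
default_intensity_model <- function() {
  calibrate_intensity_model()
}

#' Simulation configuration for a droplet sequencing run
#'
#' @param n_droplets Number of droplets passed over the DNA.
#' @param capture_rate Poisson mean of the number of released bases
#'   captured per droplet. The default 0.455 is calibrated so that, under
#'   truncated-Poisson occupancy, 21% of occupied droplets capture more
#'   than one base (the exact root of
#'   `(1 - exp(-x)(1+x)) / (1 - exp(-x)) = 0.21` is 0.45428; 0.455
#'   matches the target at its printed precision).
#' @param sampling_rate_hz Droplet passage rate over the template
#'   (default 0.5 Hz); metadata only, the capture statistics are governed
#'   by `capture_rate`.
#' @param contamination_rate Per-droplet per-colour probability that a
#'   contaminant dNTP is present (default 0.031; 0.040 is a typical
#'   run-to-run alternative).
#' @param misidentify_rate Probability that a present dNTP reports in a
#'   wrong channel (default 0.001, i.e. capture specificity 99.9%).
#' @param channel_map Named character vector, base to channel column.
#' @param intensity_model An [intensity_model()] shared by all channels.
#' @param seed Integer seed making the run reproducible.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_droplets,
                       capture_rate = 0.455,
                       sampling_rate_hz = 0.5,
                       contamination_rate = 0.031,
                       misidentify_rate = 0.001,
                       channel_map = default_channel_map(),
                       intensity_model = default_intensity_model(),
                       seed = 1L) {
  n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets < 1L)
    stop("n_droplets must be >= 1")
  if (capture_rate <= 0) stop("capture_rate must be > 0")
  for (p in c(contamination_rate, misidentify_rate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  bases <- sort(names(channel_map))
  if (!identical(bases, c("A", "C", "G", "T")) ||
      anyDuplicated(channel_map) > 0)
    stop("channel_map must be a bijection over {A, C, G, T}")
  if (!inherits(intensity_model, "intensity_model"))
    stop("intensity_model must be built with intensity_model()")
  structure(list(n_droplets = n_droplets,
                 capture_rate = capture_rate,
                 sampling_rate_hz = sampling_rate_hz,
                 contamination_rate = contamination_rate,
                 misidentify_rate = misidentify_rate,
                 channel_map = channel_map,
                 intensity_model = intensity_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Droplet run configuration\n")
  cat(sprintf("  droplets: %d, capture rate: %.4g dNTP/droplet, %g Hz\n",
              x$n_droplets, x$capture_rate, x$sampling_rate_hz))
  cat(sprintf("  contamination: %.4g /droplet/colour, misidentify: %.4g\n",
              x$contamination_rate, x$misidentify_rate))
  cat("  channels:", paste(names(x$channel_map), x$channel_map,
                           sep = "->", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf(
    "Intensity model (%s): unoccupied (%.4g, %.4g), occupied (%.4g, %.4g), P(occ) = %.3g\n",
    x$family, x$unoccupied[1], x$unoccupied[2],
    x$occupied[1], x$occupied[2], x$occupied_weight))
  invisible(x)
}
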