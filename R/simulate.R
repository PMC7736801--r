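BASES <- c("A", "C", "G", "T")

#' Generate a random reference sequence
#'
#' Draws bases independently with P(G) = P(C) = `gc_target / 2` and
#' P(A) = P(T) = `(1 - gc_target) / 2`, optionally embedding a single
#' homopolymer run (of dA, mirroring templates whose start contains a
#' long adenine stretch) at a random position recorded in the result.
#'
#' @param length Sequence length (>= 1).
#' @param gc_target Target GC fraction in \[0, 1\]; the realized fraction
#'   fluctuates within binomial sampling error.
#' @param homopolymer_len If > 0, overwrite a run of this length with a
#'   single base (`homopolymer_base`).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param homopolymer_base Base used for the embedded run.
#'
#' @return A single character string with attributes `homopolymer_start`
#'   (0-based) and `homopolymer_len` when a run was embedded.
#' @export
make_reference <- function(length, gc_target, homopolymer_len = 0L,
                           seed = 1L, homopolymer_base = "A") {
  stopifnot(length >= 1, gc_target >= 0, gc_target <= 1)
  homopolymer_len <- as.integer(homopolymer_len)
  if (homopolymer_len > length)
    stop("homopolymer_len must not exceed the sequence length")
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, T = (1 - gc_target) / 2)
  withr::with_seed(seed, {
    chars <- sample(BASES, length, replace = TRUE, prob = probs)
    start <- NA_integer_
    if (homopolymer_len > 0L) {
      start <- sample.int(length - homopolymer_len + 1L, 1L)
      chars[start:(start + homopolymer_len - 1L)] <- homopolymer_base
    }
    structure(paste(chars, collapse = ""),
              homopolymer_start = if (is.na(start)) NULL else start - 1L,
              homopolymer_len = if (is.na(start)) NULL else homopolymer_len)
  })
}

seq_chars <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

sort_collapse <- function(x) {
  vapply(x, function(b) paste(sort(b), collapse = ""), character(1))
}

## Report channels for a long vector of present dNTPs, flipping each to a
## uniformly chosen wrong channel with probability misidentify_rate.
## Returns an n x length(channel_map) logical matrix.
report_channels <- function(droplet, base, n, cfg) {
  channels <- cfg$channel_map
  reported <- matrix(FALSE, nrow = n, ncol = length(channels),
                     dimnames = list(NULL, unname(channels)))
  if (length(base) == 0L) return(reported)
  chan_idx <- match(base, names(channels))
  flip <- runif(length(base)) < cfg$misidentify_rate
  if (any(flip)) {
    shift <- sample.int(length(channels) - 1L, sum(flip), replace = TRUE)
    chan_idx[flip] <- 1L + (chan_idx[flip] - 1L + shift) %% length(channels)
  }
  reported[cbind(droplet, chan_idx)] <- TRUE
  reported
}

## Per-droplet contaminant dNTPs: each colour independently present with
## probability contamination_rate. Returns list(droplet=, base=).
draw_contaminants <- function(n, cfg) {
  present <- matrix(runif(n * 4L) < cfg$contamination_rate, nrow = n)
  idx <- which(present, arr.ind = TRUE)
  list(droplet = idx[, 1L], base = names(cfg$channel_map)[idx[, 2L]])
}

#' Simulate droplet-ordered release and capture of template bases
#'
#' Each droplet captures `k ~ Poisson(capture_rate)` consecutive bases of
#' the reference, truncated so the cumulative total never exceeds the
#' reference length; within-droplet order is lost (bases are stored as a
#' sorted multiset). Contaminant dNTPs are added independently per colour
#' with probability `contamination_rate`, and every present dNTP reports
#' its own channel except with probability `misidentify_rate`, when it
#' reports a uniformly chosen wrong channel.
#'
#' @param reference Reference sequence (non-empty character string over
#'   A/C/G/T).
#' @param cfg A [sim_config()].
#'
#' @return A data frame of class `droplet_truth` with one row per droplet:
#'   `index` (0-based acquisition order), `captured` and `contaminants`
#'   (sorted base strings), and one logical column per channel holding the
#'   reported flag.
#' @export
simulate_release <- function(reference, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nchar(reference) >= 1)
  ref <- seq_chars(reference)
  bad <- which(!ref %in% BASES)
  if (length(bad))
    stop(sprintf("invalid reference symbol '%s' at position %d",
                 ref[bad[1]], bad[1]))
  n <- cfg$n_droplets
  withr::with_seed(cfg$seed, {
    k <- rpois(n, cfg$capture_rate)
    # truncate so cumulative captures never exceed the reference length
    cum <- cumsum(k)
    over <- cum > length(ref)
    if (any(over)) {
      first <- which.max(over)
      prev <- if (first == 1L) 0L else cum[first - 1L]
      k[first] <- length(ref) - prev
      if (first < n) k[(first + 1L):n] <- 0L
    }
    cap_droplet <- rep.int(seq_len(n), k)
    cap_base <- ref[seq_len(sum(k))]
    captured <- character(n)
    captured[] <- ""
    if (length(cap_base)) {
      agg <- vapply(split(cap_base, cap_droplet),
                    function(b) paste(sort(b), collapse = ""), character(1))
      captured[as.integer(names(agg))] <- agg
    }
    cont <- draw_contaminants(n, cfg)
    contaminants <- character(n)
    contaminants[] <- ""
    if (length(cont$droplet)) {
      agg <- vapply(split(cont$base, cont$droplet),
                    function(b) paste(sort(b), collapse = ""), character(1))
      contaminants[as.integer(names(agg))] <- agg
    }
    reported <- report_channels(c(cap_droplet, cont$droplet),
                                c(cap_base, cont$base), n, cfg)
    out <- data.frame(index = seq_len(n) - 1L, captured = captured,
                      contaminants = contaminants,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(reported))
    class(out) <- c("droplet_truth", "data.frame")
    out
  })
}

#' Simulate blank droplets (never passed over the DNA)
#'
#' Blanks carry no released bases; any reported channel originates from
#' stochastic dNTP contamination (plus channel misidentification). Arrays
#' of blanks measure the stochastic false-positive rate of the assay.
#'
#' @param cfg A [sim_config()]; `capture_rate` is ignored.
#' @return A `droplet_truth` data frame with empty `captured` columns.
#' @export
simulate_blanks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_droplets
  withr::with_seed(cfg$seed, {
    cont <- draw_contaminants(n, cfg)
    contaminants <- character(n)
    contaminants[] <- ""
    if (length(cont$droplet)) {
      agg <- vapply(split(cont$base, cont$droplet),
                    function(b) paste(sort(b), collapse = ""), character(1))
      contaminants[as.integer(names(agg))] <- agg
    }
    reported <- report_channels(cont$droplet, cont$base, n, cfg)
    out <- data.frame(index = seq_len(n) - 1L, captured = "",
                      contaminants = contaminants,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(reported))
    class(out) <- c("droplet_truth", "data.frame")
    out
  })
}

draw_component <- function(n, location, scale, family, df) {
  y <- switch(family,
              lognormal = rnorm(n, location, scale),
              student = location + scale * stats::rt(n, df),
              stop("unsupported intensity family: ", family))
  10^y
}

## Droplet diameters: unimodal around 10 um, truncated to (4, 15) um
## (droplets above 15 um are removed upstream of detection).
draw_diameters <- function(n, mean = 10, sd = 1.5, lo = 4, hi = 15) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Render fluorescence intensities for simulated droplets
#'
#' For every droplet and channel, the intensity is drawn from the occupied
#' component when that channel's reported flag is set and from the
#' unoccupied component otherwise. Channels holding more than one dNTP of
#' the same colour draw from the same occupied component: occupied
#' droplets form a single "one or more" intensity population.
#'
#' @param truths A `droplet_truth` data frame from [simulate_release()] or
#'   [simulate_blanks()].
#' @param model An [intensity_model()].
#' @param seed Integer seed.
#'
#' @return A data frame of droplet records: `index`, `diameter_um`, and
#'   one positive intensity column per channel.
#' @export
render_intensities <- function(truths, model, seed = 1L) {
  stopifnot(inherits(truths, "droplet_truth"),
            inherits(model, "intensity_model"))
  chan_cols <- setdiff(names(truths), c("index", "captured", "contaminants"))
  n <- nrow(truths)
  withr::with_seed(seed, {
    out <- data.frame(index = truths$index,
                      diameter_um = draw_diameters(n))
    for (ch in chan_cols) {
      occ <- truths[[ch]]
      x <- numeric(n)
      x[!occ] <- draw_component(sum(!occ), model$unoccupied[1],
                                model$unoccupied[2], model$family, model$df)
      x[occ] <- draw_component(sum(occ), model$occupied[1],
                               model$occupied[2], model$family, model$df)
      out[[ch]] <- x
    }
    out
  })
}

#' Simulate a two-channel 5-methylcytosine detection plate
#'
#' Emulates a plate of droplets spiked with dCTP and 5mdCTP. Channel 1
#' fluoresces when either nucleotide is captured; channel 2 is generated
#' by a modification-sensitive restriction step and fluoresces only for
#' unmethylated dCTP. Empty droplets are unoccupied in both channels,
#' dCTP droplets occupied in both, 5mdCTP droplets occupied in channel 1
#' only.
#'
#' @param n Number of droplets.
#' @param fractions Numeric length 3, `c(empty, dCTP, 5mdCTP)`; must be
#'   non-negative and sum to 1.
#' @param model An [intensity_model()] shared by both channels.
#' @param seed Integer seed.
#'
#' @return A list with `records` (data frame `index`, `diameter_um`,
#'   `ch1`, `ch2`) and `truth` (factor of generating labels, levels
#'   `empty`, `dCTP`, `5mdCTP`).
#' @export
simulate_methyl_plate <- function(n, fractions, model = default_intensity_model(),
                                  seed = 1L) {
  stopifnot(n >= 1, length(fractions) == 3)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  labels <- c("empty", "dCTP", "5mdCTP")
  withr::with_seed(seed, {
    truth <- factor(sample(labels, n, replace = TRUE, prob = fractions),
                    levels = labels)
    occ1 <- truth %in% c("dCTP", "5mdCTP")
    occ2 <- truth == "dCTP"
    draw <- function(occ) {
      x <- numeric(n)
      x[!occ] <- draw_component(sum(!occ), model$unoccupied[1],
                                model$unoccupied[2], model$family, model$df)
      x[occ] <- draw_component(sum(occ), model$occupied[1],
                               model$occupied[2], model$family, model$df)
      x
    }
    records <- data.frame(index = seq_len(n) - 1L,
                          diameter_um = draw_diameters(n),
                          ch1 = draw(occ1), ch2 = draw(occ2))
    list(records = records, truth = truth)
  })
}
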