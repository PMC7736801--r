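#' Configuration for an end-to-end droplet sequencing analysis
#'
#' Composes the simulator configuration, alignment scoring and the
#' analysis settings of a full run. All stochastic stages derive their
#' seeds from the single `seed`, so a configuration reproduces its run
#' exactly.
#'
#' @param sim A [sim_config()].
#' @param reference Reference sequence; `NULL` generates one with
#'   [make_reference()] (`ref_length`, `gc_target`).
#' @param ref_length,gc_target Used only when `reference` is `NULL`.
#' @param scoring A [scoring_scheme()].
#' @param n_draws Permutation draws for the mean-identity summary.
#' @param n_restarts Restarts for the best-order search.
#' @param n_blanks Blank droplets simulated for the stochastic
#'   false-positive estimate.
#' @param seed Master seed of the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, reference = NULL, ref_length = 2000L,
                            gc_target = 0.5, scoring = scoring_scheme(),
                            n_draws = 20L, n_restarts = 20L,
                            n_blanks = 10000L, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(scoring, "scoring_scheme"),
            n_draws >= 1, n_restarts >= 1, n_blanks >= 0)
  structure(list(sim = sim, reference = reference,
                 ref_length = as.integer(ref_length), gc_target = gc_target,
                 scoring = scoring, n_draws = as.integer(n_draws),
                 n_restarts = as.integer(n_restarts),
                 n_blanks = as.integer(n_blanks), seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full droplet sequencing analysis pipeline
#'
#' Simulate (release, contamination, intensities) -> fit per-channel
#' intensity mixtures -> call occupancy -> reconstruct the set-read ->
#' align (permutation-averaged and best-order identity), plus a blank
#' array analysed with the run's fits for the stochastic false-positive
#' estimate. With `out_dir` set, every intermediate artifact is written
#' (droplet table, truth sidecar, fit report JSON, calls CSV, set-read
#' CSV, resolved read FASTA, report JSON), so each report value can be
#' recomputed from the persisted intermediates.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return The run report, a list: reference, per-channel fits, occupancy
#'   and multi-base statistics, stochastic false-positive estimate,
#'   per-draw identities with their mean, and the best-order identity.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  s <- cfg$seed

  reference <- stage("reference", {
    if (is.null(cfg$reference))
      make_reference(cfg$ref_length, cfg$gc_target, seed = s + 101L)
    else check_alphabet(cfg$reference, "reference")
  })

  sim <- cfg$sim
  sim$seed <- s + 202L
  truths <- stage("simulate", simulate_release(reference, sim))
  records <- stage("render",
                   render_intensities(truths, sim$intensity_model,
                                      seed = s + 303L))

  channels <- unname(sim$channel_map)
  fits <- stage("fit", {
    fits <- lapply(channels, function(ch) fit_mixture(records[[ch]]))
    names(fits) <- channels
    fits
  })

  calls <- stage("call", call_occupancy(records, fits))

  blank_fp <- NULL
  if (cfg$n_blanks > 0L) {
    blank_fp <- stage("blanks", {
      bsim <- sim
      bsim$n_droplets <- cfg$n_blanks
      bsim$seed <- s + 404L
      btruth <- simulate_blanks(bsim)
      brec <- render_intensities(btruth, sim$intensity_model,
                                 seed = s + 505L)
      estimate_stochastic_fp(call_occupancy(brec, fits))
    })
  }

  read <- stage("reconstruct", droplets_to_read(calls, sim$channel_map))
  if (length(read) == 0L)
    stop("pipeline stage 'reconstruct' failed: no occupied droplets")
  multibase_fraction <- mean(lengths(read$droplets) > 1L)

  ids <- stage("align", mean_identity(read, reference, cfg$scoring,
                                      n_draws = cfg$n_draws, seed = s + 606L))
  best <- stage("best_order",
                best_order_search(read, reference, cfg$scoring,
                                  n_restarts = cfg$n_restarts,
                                  seed = s + 707L))

  report <- list(
    seed = s,
    reference_length = nchar(reference),
    n_droplets = sim$n_droplets,
    n_occupied = length(read),
    multibase_fraction = multibase_fraction,
    fits = fits,
    stochastic_fp = blank_fp,
    stochastic_fp_mean = if (is.null(blank_fp)) NULL
      else attr(blank_fp, "mean_rate"),
    identity = ids,
    best_order_identity = best$identity,
    best_order_sequence = best$sequence)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(c(reference = reference), p("reference.fasta"))
    write_droplet_table(records, p("droplets.csv"))
    write_truth_table(truths, p("truth.csv"))
    write_fit_report(fits, p("fits.json"))
    write_calls(calls, p("calls.csv"))
    write_set_read(read, p("setread.csv"))
    write_fasta(c(best_order = best$sequence), p("resolved_read.fasta"))
    write_run_report(report, p("report.json"))
  }
  report
}

#' Write a pipeline run report as JSON
#' @param report A report from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- report
  out$fits <- lapply(report$fits, function(f) list(
    weights = f$weights, location = f$location, scale = f$scale,
    crossing_point = f$crossing_point, fp_overlap = f$fp_overlap,
    fn_overlap = f$fn_overlap, converged = f$converged,
    n_iter = f$n_iter))
  out$identity <- list(per_draw = report$identity$identities,
                       mean = report$identity$mean,
                       sd = report$identity$sd,
                       n_draws = report$identity$n_draws)
  if (!is.null(out$stochastic_fp)) {
    out$stochastic_fp <- as.list(out$stochastic_fp)
    out$stochastic_fp_mean <- report$stochastic_fp_mean
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
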