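#' Smith-Waterman scoring parameters
#'
#' Defaults are the common scheme: match +2, mismatch -2, gap opening -3,
#' gap extension -1. A gap of length L costs
#' `|gap_open| + (L - 1) * |gap_extend|`: the first gap symbol pays the
#' opening penalty, each further one the extension penalty.
#'
#' @param match Positive match score.
#' @param mismatch,gap_open,gap_extend Negative penalties.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -2L,
                           gap_open = -3L, gap_extend = -1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (is.na(match) || match <= 0L) stop("match score must be > 0")
  if (anyNA(c(mismatch, gap_open, gap_extend)) ||
      any(c(mismatch, gap_open, gap_extend) >= 0L))
    stop("mismatch, gap_open and gap_extend must be < 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

check_alphabet <- function(x, what) {
  chars <- seq_chars(x)
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("invalid symbol '%s' in %s at position %d",
                 chars[bad[1]], what, bad[1]))
  paste(chars, collapse = "")
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Finds the optimal local alignment of `query` against `reference` under
#' an affine gap model where a gap of length L costs
#' `|gap_open| + (L-1) * |gap_extend|`. `N` scores as a mismatch against
#' every symbol. Traceback is deterministic, preferring diagonal over up
#' (gap in reference) over left (gap in query); when no positive-scoring
#' pair exists the empty alignment (score 0) is returned.
#'
#' @param query,reference Non-empty sequences over A/C/G/T/N.
#' @param scoring A [scoring_scheme()].
#'
#' @return An object of class `alignment_result`: `score`,
#'   `query_aligned` / `ref_aligned` (gapped strings), 0-based half-open
#'   coordinates `query_start`/`query_end`/`ref_start`/`ref_end`,
#'   `matches`, `columns` (alignment length including gap columns),
#'   `identity` = matches / columns (0 for an empty alignment), a
#'   SAM-style `cigar` for the local segment, and the scheme used.
#' @export
smith_waterman <- function(query, reference, scoring = scoring_scheme()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  if (nchar(query) < 1 || nchar(reference) < 1)
    stop("query and reference must be non-empty")
  query <- check_alphabet(query, "query")
  reference <- check_alphabet(reference, "reference")
  raw <- .sw_align(query, reference, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  qa <- strsplit(raw$query_aligned, "", fixed = TRUE)[[1]]
  ra <- strsplit(raw$ref_aligned, "", fixed = TRUE)[[1]]
  columns <- length(qa)
  matches <- sum(qa == ra & qa != "-" & qa != "N")
  res <- list(score = raw$score,
              query_aligned = raw$query_aligned,
              ref_aligned = raw$ref_aligned,
              query_start = raw$query_start, query_end = raw$query_end,
              ref_start = raw$ref_start, ref_end = raw$ref_end,
              matches = matches, columns = columns,
              identity = if (columns == 0L) 0 else matches / columns,
              cigar = alignment_cigar(qa, ra),
              scoring = scoring,
              identity_convention = "matches / alignment columns (gap-inclusive)")
  class(res) <- "alignment_result"
  res
}

alignment_cigar <- function(qa, ra) {
  if (length(qa) == 0L) return("")
  op <- ifelse(qa == "-", "D", ifelse(ra == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

## Recompute the alignment score from the gapped strings; used as an
## internal consistency invariant in the tests.
rescore_alignment <- function(result) {
  qa <- strsplit(result$query_aligned, "", fixed = TRUE)[[1]]
  ra <- strsplit(result$ref_aligned, "", fixed = TRUE)[[1]]
  s <- result$scoring
  gap <- qa == "-" | ra == "-"
  sub <- sum(ifelse(qa[!gap] == ra[!gap] & qa[!gap] != "N",
                    s$match, s$mismatch))
  runs <- rle(ifelse(qa == "-", "q", ifelse(ra == "-", "r", "m")))
  gap_runs <- runs$lengths[runs$values != "m"]
  as.integer(sub + sum(vapply(gap_runs, function(L)
    s$gap_open + (L - 1L) * s$gap_extend, numeric(1))))
}

#' @export
print.alignment_result <- function(x, width = 60L, ...) {
  cat(sprintf("Local alignment: score %d, identity %.3f (%d/%d columns), CIGAR %s\n",
              x$score, x$identity, x$matches, x$columns,
              if (nzchar(x$cigar)) x$cigar else "*"))
  if (x$columns == 0L) {
    cat("  (empty alignment)\n")
    return(invisible(x))
  }
  qa <- strsplit(x$query_aligned, "", fixed = TRUE)[[1]]
  ra <- strsplit(x$ref_aligned, "", fixed = TRUE)[[1]]
  marks <- ifelse(qa == ra & qa != "-" & qa != "N", "|", " ")
  for (s in seq(1L, x$columns, by = width)) {
    e <- min(s + width - 1L, x$columns)
    cat(sprintf("  query %5d %s\n", x$query_start + 1L,
                paste(qa[s:e], collapse = "")))
    cat(sprintf("        %5s %s\n", "", paste(marks[s:e], collapse = "")))
    cat(sprintf("  ref   %5d %s\n\n", x$ref_start + 1L,
                paste(ra[s:e], collapse = "")))
  }
  invisible(x)
}

#' Permutation-averaged alignment identity of a set-read
#'
#' Draws `n_draws` random linearizations of the set-read (each multi-base
#' droplet permuted uniformly over its distinct orderings), aligns each
#' against the reference and summarizes the per-draw identities. This is
#' the fair headline accuracy of a droplet run when multi-base order is
#' unknown.
#'
#' @param read A `set_read`.
#' @param reference Reference sequence.
#' @param scoring A [scoring_scheme()].
#' @param n_draws Number of permutation draws (default 20).
#' @param seed Integer seed.
#'
#' @return An object of class `identity_summary`: per-draw `identities`,
#'   their `mean` and `sd`, `n_draws` and `seed`.
#' @export
mean_identity <- function(read, reference, scoring = scoring_scheme(),
                          n_draws = 20L, seed = 1L) {
  stopifnot(inherits(read, "set_read"), n_draws >= 1)
  if (length(read) == 0L) stop("empty set-read")
  draws <- sample_orderings(read, n_draws, seed)
  ids <- vapply(draws, function(s)
    smith_waterman(s, reference, scoring)$identity, numeric(1),
    USE.NAMES = FALSE)
  structure(list(identities = ids, mean = mean(ids),
                 sd = if (n_draws > 1L) sd(ids) else 0,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "identity_summary")
}

#' @export
print.identity_summary <- function(x, ...) {
  cat(sprintf("Mean identity over %d permutation draws: %.4f (sd %.4f)\n",
              x$n_draws, x$mean, x$sd))
  invisible(x)
}
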