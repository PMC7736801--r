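#' Local GC-content profile by Gaussian filtering
#'
#' Convolves the binary G/C indicator of a sequence with a discrete
#' Gaussian kernel (standard deviation `sigma` bases, truncated at 4
#' sigma and renormalized), reflecting the sequence at its ends. `N`
#' positions contribute neither to the numerator nor to the normalizing
#' weight, so the profile is the locally weighted GC fraction of the
#' informative bases.
#'
#' @param sequence Non-empty sequence over A/C/G/T/N.
#' @param sigma Filter standard deviation in bases (default 20).
#'
#' @return Object of class `gc_profile`: `sigma`, `values` (per-position
#'   local GC fraction in \[0, 1\]) and `mean` (unweighted region mean
#'   from [mean_gc()]).
#' @export
local_gc <- function(sequence, sigma = 20) {
  if (sigma <= 0) stop("sigma must be > 0")
  chars <- seq_chars(check_alphabet(sequence, "sequence"))
  n <- length(chars)
  gc <- as.numeric(chars %in% c("G", "C"))
  informative <- as.numeric(chars != "N")
  gc[chars == "N"] <- 0

  h <- ceiling(4 * sigma)
  kernel <- dnorm(-h:h, 0, sigma)
  kernel <- kernel / sum(kernel)

  reflect_pad <- function(x) {
    # whole-sample reflection (no edge repeat): position p maps to the
    # triangle wave of period 2n - 2 over 0..n-1
    pos <- (-h):(n - 1 + h)
    per <- 2 * n - 2
    if (per <= 0) pos <- rep(0L, length(pos)) else {
      pos <- pos %% per
      pos[pos >= n] <- per - pos[pos >= n]
    }
    x[pos + 1]
  }
  num <- stats::filter(reflect_pad(gc), kernel, sides = 2)
  den <- stats::filter(reflect_pad(informative), kernel, sides = 2)
  keep <- (h + 1):(h + n)
  values <- as.numeric(num[keep] / pmax(den[keep], .Machine$double.eps))
  values[den[keep] < .Machine$double.eps] <- NA_real_
  structure(list(sigma = sigma, values = values, mean = mean_gc(sequence)),
            class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("GC profile: %d positions, sigma = %g bases, region mean %.3f\n",
              length(x$values), x$sigma, x$mean))
  invisible(x)
}

#' Mean GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` positions are excluded from
#' both counts.
#'
#' @param sequence Non-empty sequence over A/C/G/T/N.
#' @return GC fraction in \[0, 1\].
#' @export
mean_gc <- function(sequence) {
  chars <- seq_chars(check_alphabet(sequence, "sequence"))
  informative <- chars != "N"
  if (!any(informative)) stop("sequence contains no informative (non-N) bases")
  sum(chars %in% c("G", "C")) / sum(informative)
}

#' Write a GC profile as BedGraph-style TSV
#'
#' One row per position: `seqid`, `start`, `end` (0-based half-open) and
#' the local GC fraction.
#'
#' @param profile A `gc_profile`.
#' @param seqid Sequence name for the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gc_bedgraph <- function(profile, seqid, path) {
  stopifnot(inherits(profile, "gc_profile"))
  n <- length(profile$values)
  df <- data.frame(seqid = seqid, start = seq_len(n) - 1L,
                   end = seq_len(n), gc = profile$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
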