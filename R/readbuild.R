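#' Construct a set-read
#'
#' A set-read is the natural read type of droplet-ordered sequencing: an
#' ordered list of unordered base multisets, one per occupied droplet.
#' Droplet order carries the sequence order; order *within* a multi-base
#' droplet is lost.
#'
#' @param droplets List of non-empty character vectors of bases.
#' @param index Integer acquisition index per droplet (same length).
#' @return An object of class `set_read`.
#' @export
set_read <- function(droplets, index = seq_along(droplets) - 1L) {
  stopifnot(is.list(droplets), length(index) == length(droplets))
  if (any(lengths(droplets) == 0L))
    stop("set-read droplets must be non-empty multisets")
  droplets <- lapply(droplets, function(b) sort(as.character(b)))
  structure(list(droplets = droplets, index = as.integer(index)),
            class = "set_read")
}

#' @export
length.set_read <- function(x) length(x$droplets)

#' @export
print.set_read <- function(x, ...) {
  n_multi <- sum(lengths(x$droplets) > 1L)
  cat(sprintf("Set-read: %d occupied droplets, %d bases, %d multi-base\n",
              length(x$droplets), sum(lengths(x$droplets)), n_multi))
  shown <- vapply(head(x$droplets, 20L), paste, character(1), collapse = "")
  cat(" ", paste0("{", shown, "}", collapse = " "),
      if (length(x$droplets) > 20L) "..." else "", "\n")
  invisible(x)
}

#' Total number of bases in a set-read
#' @param read A `set_read`.
#' @return Integer base count.
#' @export
n_bases <- function(read) sum(lengths(read$droplets))

#' Convert occupancy calls to a set-read
#'
#' Per droplet, collects the bases whose channels were called occupied
#' into a multiset; droplets with no occupied channel are skipped;
#' acquisition order is preserved.
#'
#' @param calls Long occupancy-call data frame from [call_occupancy()].
#' @param channel_map Named character vector, base to channel.
#' @return A `set_read`.
#' @export
droplets_to_read <- function(calls, channel_map = default_channel_map()) {
  stopifnot(all(c("index", "channel", "occupied") %in% names(calls)))
  unknown <- setdiff(unique(calls$channel), unname(channel_map))
  if (length(unknown))
    stop("unknown channel in calls: ", paste(unknown, collapse = ", "))
  occ <- calls[calls$occupied, , drop = FALSE]
  if (nrow(occ) == 0L) return(set_read(list(), integer(0)))
  base_of <- names(channel_map)[match(occ$channel, unname(channel_map))]
  by_drop <- split(base_of, occ$index)
  idx <- as.integer(names(by_drop))
  ord <- order(idx)
  set_read(unname(by_drop[ord]), idx[ord])
}

## All distinct arrangements of a small multiset of bases, as strings in
## deterministic (lexicographic) order.
distinct_perms <- function(bases) {
  bases <- sort(bases)
  if (length(bases) <= 1L) return(paste(bases, collapse = ""))
  out <- character(0)
  recurse <- function(prefix, rest) {
    if (length(rest) == 0L) {
      out[[length(out) + 1L]] <<- paste(prefix, collapse = "")
      return(invisible())
    }
    for (b in unique(rest)) {
      i <- match(b, rest)
      recurse(c(prefix, b), rest[-i])
    }
  }
  recurse(character(0), bases)
  out
}

## Number of distinct arrangements of each droplet's multiset.
n_arrangements <- function(read) {
  vapply(read$droplets, function(b) {
    tab <- table(b)
    exp(lfactorial(length(b)) - sum(lfactorial(tab)))
  }, numeric(1))
}

#' Sample random linearizations of a set-read
#'
#' Each draw independently permutes every multi-base droplet uniformly
#' over its *distinct* arrangements (duplicated bases carry no order
#' information) and concatenates the droplets in acquisition order.
#'
#' @param read A `set_read`.
#' @param n_draws Number of draws (default 20).
#' @param seed Integer seed; the same seed reproduces the same draws.
#' @return Character vector of `n_draws` candidate sequences.
#' @export
sample_orderings <- function(read, n_draws = 20L, seed = 1L) {
  stopifnot(inherits(read, "set_read"), n_draws >= 1)
  multi <- lengths(read$droplets) > 1L
  fixed <- vapply(read$droplets, paste, character(1), collapse = "")
  withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      parts <- fixed
      parts[multi] <- vapply(read$droplets[multi], function(b)
        paste(sample(b), collapse = ""), character(1))
      paste(parts, collapse = "")
    }, character(1))
  })
}

#' Resolve multi-base droplet order against a reference
#'
#' Searches the space of valid linearizations of a set-read for the one
#' whose local alignment identity against the reference is highest. When
#' the number of joint orderings is at most `exhaustive_limit` the search
#' enumerates the full product of per-droplet arrangements exactly;
#' otherwise it hill-climbs from `n_restarts` random linearizations,
#' sweeping droplets and trying every arrangement of each multi-base
#' droplet while the rest is held fixed, accepting strict identity
#' improvements until a full sweep yields no change. The result is always
#' at least as good as every ordering evaluated along the way.
#'
#' @param read A `set_read`.
#' @param reference Reference sequence (non-empty string).
#' @param scoring A [scoring_scheme()].
#' @param n_restarts Hill-climbing restarts (default 20).
#' @param seed Integer seed for the restart draws.
#' @param exhaustive_limit Enumerate exactly when the joint ordering count
#'   does not exceed this (default 1e4).
#'
#' @return List with `sequence` (best linearization), `alignment` (its
#'   [smith_waterman()] result), `identity`, `n_evaluated`, and
#'   `exhaustive` (logical).
#' @export
best_order_search <- function(read, reference, scoring = scoring_scheme(),
                              n_restarts = 20L, seed = 1L,
                              exhaustive_limit = 1e4) {
  stopifnot(inherits(read, "set_read"), nchar(reference) >= 1)
  if (length(read) == 0L) stop("empty set-read")
  perms <- lapply(read$droplets, distinct_perms)
  counts <- lengths(perms)
  joint <- prod(counts)
  n_eval <- 0L
  best_seq <- NULL
  best_id <- -1
  memo <- new.env(parent = emptyenv()) # restarts revisit many orderings
  identity_of <- function(s) {
    hit <- memo[[s]]
    if (!is.null(hit)) return(hit)
    n_eval <<- n_eval + 1L
    id <- smith_waterman(s, reference, scoring)$identity
    memo[[s]] <- id
    id
  }

  if (is.finite(joint) && joint <= exhaustive_limit) {
    multi_idx <- which(counts > 1L)
    parts <- vapply(perms, `[`, character(1), 1L)
    recurse <- function(d) {
      if (d > length(multi_idx)) {
        s <- paste(parts, collapse = "")
        id <- identity_of(s)
        if (id > best_id) { best_id <<- id; best_seq <<- s }
        return(invisible())
      }
      for (p in perms[[multi_idx[d]]]) {
        parts[multi_idx[d]] <<- p
        recurse(d + 1L)
      }
    }
    recurse(1L)
    exhaustive <- TRUE
  } else {
    starts <- sample_orderings(read, n_restarts, seed)
    multi_idx <- which(counts > 1L)
    blocks <- c(0L, cumsum(lengths(read$droplets)))
    for (s0 in starts) {
      parts <- substring(s0, blocks[-length(blocks)] + 1L, blocks[-1L])
      cur_id <- identity_of(paste(parts, collapse = ""))
      repeat {
        improved <- FALSE
        for (d in multi_idx) {
          for (p in perms[[d]]) {
            if (p == parts[d]) next
            cand <- parts
            cand[d] <- p
            id <- identity_of(paste(cand, collapse = ""))
            if (id > cur_id) {
              parts <- cand
              cur_id <- id
              improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      if (cur_id > best_id) {
        best_id <- cur_id
        best_seq <- paste(parts, collapse = "")
      }
    }
    exhaustive <- FALSE
  }
  list(sequence = best_seq,
       alignment = smith_waterman(best_seq, reference, scoring),
       identity = best_id, n_evaluated = n_eval, exhaustive = exhaustive)
}
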