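#' Retweet record
#'
#' The propagation footprint of one tweet: the originating organization and
#' the set of accounts that retweeted it.
#'
#' @param tweet_id opaque tweet identifier.
#' @param org_id originating organization's account id.
#' @param retweeter_ids character vector of retweeting account ids (must not
#'   include the organization itself).
#' @return An object of class `retweet_record` with `n_retweets =
#'   length(retweeter_ids)`.
#' @export
retweet_record <- function(tweet_id, org_id, retweeter_ids = character()) {
  retweeter_ids <- unique(as.character(retweeter_ids))
  org_id <- as.character(org_id)
  if (org_id %in% retweeter_ids) {
    stop("the originating organization cannot retweet its own tweet",
         call. = FALSE)
  }
  structure(list(tweet_id = as.character(tweet_id), org_id = org_id,
                 retweeter_ids = retweeter_ids,
                 n_retweets = length(retweeter_ids)),
            class = "retweet_record")
}

#' @export
print.retweet_record <- function(x, ...) {
  cat(sprintf("<retweet_record> %s from %s: %d retweeters\n",
              x$tweet_id, x$org_id, x$n_retweets))
  invisible(x)
}

#' Actual dissemination (retweeter network size)
#'
#' The combined audience of the accounts that retweeted one tweet: the sum
#' of the retweeters' declared follower counts. No deduplication is applied
#' across retweeters' audiences, and neither the organization's own
#' first-hop audience nor the retweeter count itself is added — this is the
#' measured second-hop audience, directly comparable to
#' [dissemination_potential()] via [fraction_of_potential()].
#'
#' @param graph a [follow_graph()].
#' @param record a [retweet_record()] whose retweeters are registered.
#' @return A single number.
#' @export
actual_dissemination <- function(graph, record) {
  stopifnot(inherits(record, "retweet_record"))
  check_ids(graph, record$retweeter_ids, "retweeter")
  if (record$n_retweets == 0) return(0)
  sum(declared_follower_count(graph, record$retweeter_ids))
}

#' Fraction of dissemination potential
#'
#' How close a tweet's actual dissemination came to the theoretical best:
#' `actual / potential`, at full precision. Use [format_fraction()] for
#' display at printed precision.
#'
#' @param actual measured dissemination, `>= 0`.
#' @param potential theoretical potential, `> 0`.
#' @return A ratio.
#' @export
fraction_of_potential <- function(actual, potential) {
  if (!is.numeric(potential) || length(potential) != 1 || potential <= 0) {
    stop("potential must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(actual) || length(actual) != 1 || actual < 0) {
    stop("actual must be a single non-negative number", call. = FALSE)
  }
  actual / potential
}

#' Printed-precision formatter for small fractions
#'
#' Renders a fraction with 3 significant figures, or 2 significant figures
#' below 1e-4, in plain decimal notation — the mixed precision convention
#' used when reporting tiny dissemination fractions.
#'
#' @param x numeric vector of fractions.
#' @return Character vector.
#' @examples
#' format_fraction(c(9558 / 6959092, 489 / 11228160))
#' @export
format_fraction <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    digits <- if (abs(v) < 1e-4 && v != 0) 2L else 3L
    format(signif(v, digits), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Retweet-count distribution over tweets
#'
#' Sorts per-tweet retweet counts in descending order and summarizes them.
#'
#' @param records list of [retweet_record()]s.
#' @return A list with `counts` (descending integer vector, one entry per
#'   tweet), `max`, `n_zero` (tweets never retweeted) and `n_tweets`.
#' @export
retweet_distribution <- function(records) {
  counts <- vapply(records, function(r) r$n_retweets, numeric(1))
  counts <- sort(counts, decreasing = TRUE)
  list(counts = counts,
       max = if (length(counts) > 0) max(counts) else 0,
       n_zero = sum(counts == 0),
       n_tweets = length(counts))
}

# Core BFS diffusion engine. `resends` is a named logical over all account
# ids saying whether a node forwards the message upon first reception
# (one coin per node); the source always sends.
run_cascade <- function(graph, source, resends) {
  reached <- character()
  hop_of <- integer()
  frontier <- followers_of(graph, source)
  hop <- 1L
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, c(reached, source))
    if (length(frontier) == 0) break
    reached <- c(reached, frontier)
    hop_of[frontier] <- hop
    forwarders <- frontier[resends[frontier]]
    frontier <- unique(unlist(lapply(forwarders, followers_of, graph = graph)))
    hop <- hop + 1L
  }
  senders <- c(source, reached[resends[reached]])
  messages_sent <- sum(structural_follower_count(graph, senders))
  redundant <- 0L
  if (length(reached) > 0) {
    e <- graph$edges
    recv <- e[e$from %in% senders & e$to %in% reached, , drop = FALSE]
    redundant <- nrow(recv) - length(reached)
  }
  list(reached = reached, hop_of = hop_of, messages_sent = messages_sent,
       redundant_receptions = redundant)
}

new_cascade_result <- function(source, p, run, seed) {
  structure(list(source = source, resend_probability = p,
                 reached = run$reached, hop_of = run$hop_of,
                 messages_sent = run$messages_sent,
                 redundant_receptions = run$redundant_receptions,
                 seed = seed),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  mh <- if (length(x$hop_of) > 0) max(x$hop_of) else 0L
  cat(sprintf(
    "<cascade_result> source %s, p = %g: reached %d (max hop %d), %d messages, %d redundant\n",
    x$source, x$resend_probability, length(x$reached), mh,
    x$messages_sent, x$redundant_receptions))
  invisible(x)
}

#' Deterministic flood diffusion
#'
#' Breadth-first flood from a source under the information-flow direction:
#' every node that receives the message forwards it (resend probability 1).
#' Hop numbers start at 1 for the source's direct followers. Redundant
#' receptions count every delivery beyond a node's first;
#' `messages_sent` totals the out-degrees of the source and of every
#' reached node, since all of them forward.
#'
#' @param graph a [follow_graph()].
#' @param source a registered account id.
#' @return A `cascade_result` with `resend_probability = 1`.
#' @export
flood_diffusion <- function(graph, source) {
  source <- as.character(source)
  check_ids(graph, source, "source")
  resends <- stats::setNames(rep(TRUE, n_accounts(graph)), account_ids(graph))
  new_cascade_result(source, 1, run_cascade(graph, source, resends), NA_integer_)
}

#' Independent cascade simulation
#'
#' The independent cascade model of message diffusion: the source sends its
#' message to all followers; each newly reached node forwards it once with
#' fixed independent probability `p` (a single coin per node), and the
#' process continues hop by hop until no new node is reached. Coins are
#' drawn per node from the seed alone, so runs with the same seed but
#' different `p` are coupled: the reached set at a lower `p` is a subset of
#' the reached set at a higher `p`, and `p = 1` coincides exactly with
#' [flood_diffusion()].
#'
#' @param graph a [follow_graph()].
#' @param source a registered account id.
#' @param p resend probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A `cascade_result`.
#' @export
independent_cascade <- function(graph, source, p, seed) {
  source <- as.character(source)
  check_ids(graph, source, "source")
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("resend probability p must lie in [0, 1]", call. = FALSE)
  }
  coins <- cascade_coins(graph, seed)
  new_cascade_result(source, p, run_cascade(graph, source, coins < p), seed)
}

# One uniform per node, in sorted id order, drawn from the seed alone —
# the coupling device shared by all p values at a fixed seed.
cascade_coins <- function(graph, seed) {
  ids <- sort(account_ids(graph))
  with_seed(seed, stats::setNames(stats::runif(length(ids)), ids))
}

#' Monte-Carlo cascade experiment grid
#'
#' Runs [independent_cascade()] for every combination of source and resend
#' probability over `reps` replicates, with per-replicate derived seeds.
#' Within a replicate the same coins are used across the whole `p` grid
#' (monotone coupling), so mean reach is non-decreasing in `p` by
#' construction, not just in expectation.
#'
#' @param graph a [follow_graph()].
#' @param sources character vector of source account ids.
#' @param p_values numeric vector of resend probabilities in `[0, 1]`.
#' @param reps number of replicates, `>= 1`.
#' @param seed integer base seed; replicate `r` uses `seed + r - 1`.
#' @return Data frame sorted by `(source, p)` with columns `source`, `p`,
#'   `mean_reach`, `sd_reach`, `mean_max_hop`.
#' @export
cascade_experiment <- function(graph, sources, p_values, reps, seed) {
  if (!is_count(reps) || reps < 1) stop("reps must be >= 1", call. = FALSE)
  sources <- as.character(sources)
  check_ids(graph, sources, "source")
  if (any(p_values < 0 | p_values > 1)) {
    stop("resend probabilities must lie in [0, 1]", call. = FALSE)
  }
  sources <- sort(sources)
  p_values <- sort(p_values)
  reach <- array(0, dim = c(reps, length(sources), length(p_values)))
  maxhop <- array(0, dim = dim(reach))
  for (r in seq_len(reps)) {
    coins <- cascade_coins(graph, seed + r - 1L)
    for (si in seq_along(sources)) {
      for (pi in seq_along(p_values)) {
        run <- run_cascade(graph, sources[si], coins < p_values[pi])
        reach[r, si, pi] <- length(run$reached)
        maxhop[r, si, pi] <- if (length(run$hop_of) > 0) max(run$hop_of) else 0
      }
    }
  }
  grid <- expand.grid(pi = seq_along(p_values), si = seq_along(sources))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    si <- grid$si[k]; pi <- grid$pi[k]
    data.frame(source = sources[si], p = p_values[pi],
               mean_reach = mean(reach[, si, pi]),
               sd_reach = stats::sd(c(reach[, si, pi], recursive = TRUE)),
               mean_max_hop = mean(maxhop[, si, pi]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sd_reach[is.na(out$sd_reach)] <- 0
  out[order(out$source, out$p), , drop = FALSE]
}
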