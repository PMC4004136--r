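#' Organization profile
#'
#' An organization account together with its follower set, the accounts it
#' follows, and its tweet volume. The organization is never a member of its
#' own follower set.
#'
#' @param org_id account id of the organization.
#' @param follower_ids character vector of follower account ids.
#' @param following_ids character vector of accounts the organization
#'   follows (its information sources).
#' @param tweet_count non-negative tweet volume.
#' @return An object of class `org_profile`.
#' @export
org_profile <- function(org_id, follower_ids = character(),
                        following_ids = character(), tweet_count = 0) {
  org_id <- as.character(org_id)
  follower_ids <- unique(as.character(follower_ids))
  if (org_id %in% follower_ids) {
    stop("an organization cannot be its own follower", call. = FALSE)
  }
  if (!is_count(tweet_count)) stop("tweet_count must be a non-negative count",
                                   call. = FALSE)
  structure(list(org_id = org_id,
                 follower_ids = follower_ids,
                 following_ids = unique(as.character(following_ids)),
                 tweet_count = as.numeric(tweet_count)),
            class = "org_profile")
}

#' @export
print.org_profile <- function(x, ...) {
  cat(sprintf("<org_profile> %s: %d followers, following %d, %g tweets\n",
              x$org_id, length(x$follower_ids), length(x$following_ids),
              x$tweet_count))
  invisible(x)
}

#' Level-2 follower sum
#'
#' Total audience of an organization's followers: the sum over followers of
#' their follower counts. This is the second hop of potential reach under
#' the assumption that followers' audiences do not overlap; no
#' deduplication is performed (see [unique_reach()] for the exact 2-hop
#' set size). By default the declared (global) follower counts are summed,
#' because the graph at hand is usually a sample; `mode = "structural"`
#' sums in-graph out-degrees instead.
#'
#' @param graph a [follow_graph()].
#' @param org an [org_profile()] whose followers are registered in `graph`.
#' @param mode `"declared"` (default) or `"structural"`.
#' @return A single number.
#' @export
level2_follower_sum <- function(graph, org, mode = c("declared", "structural")) {
  mode <- match.arg(mode)
  stopifnot(inherits(org, "org_profile"))
  check_ids(graph, org$follower_ids, "follower")
  if (length(org$follower_ids) == 0) return(0)
  if (mode == "declared") {
    sum(declared_follower_count(graph, org$follower_ids))
  } else {
    sum(structural_follower_count(graph, org$follower_ids))
  }
}

#' Information dissemination potential
#'
#' The theoretical audience if every follower retweets once and audiences
#' are disjoint: the organization's follower count plus its Level-2
#' follower sum. The organization's own account is never counted.
#'
#' @inheritParams level2_follower_sum
#' @return A single number, `>= length(org$follower_ids)`.
#' @export
dissemination_potential <- function(graph, org,
                                    mode = c("declared", "structural")) {
  length(org$follower_ids) + level2_follower_sum(graph, org, mode)
}

#' Exact unique two-hop reach
#'
#' The number of distinct accounts within two information-flow hops of the
#' organization in the structural graph: its followers plus their in-graph
#' followers, deduplicated, the organization itself excluded. This is the
#' exact counterpart of the no-overlap [dissemination_potential()].
#'
#' @param graph a [follow_graph()].
#' @param org an [org_profile()].
#' @return A single integer.
#' @export
unique_reach <- function(graph, org) {
  check_ids(graph, org$follower_ids, "follower")
  hop2 <- unlist(lapply(org$follower_ids, followers_of, graph = graph))
  length(setdiff(unique(c(org$follower_ids, hop2)), org$org_id))
}

#' Pairwise follower overlap percentage
#'
#' Overlap between two follower sets as a percentage of the smaller set:
#' `|A intersect B| / min(|A|, |B|) * 100`. Equals 100 exactly when one set
#' contains the other.
#'
#' @param followers_a,followers_b non-empty character vectors of account ids.
#' @return A percentage in `[0, 100]`.
#' @export
overlap_percentage <- function(followers_a, followers_b) {
  a <- unique(as.character(followers_a))
  b <- unique(as.character(followers_b))
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap percentage is undefined for empty follower sets",
         call. = FALSE)
  }
  100 * length(intersect(a, b)) / min(length(a), length(b))
}

#' Multi-group follower membership
#'
#' For a set of organizations, counts how many accounts follow exactly
#' `k` of them, for each `k`, and returns the set of accounts following
#' all of them. The counts over `k` partition the union of the follower
#' sets.
#'
#' @param profiles list of at least two [org_profile()]s with distinct ids.
#' @return A list with `counts` (named integer vector over `k = 1..n_orgs`),
#'   `intersection` (character vector of ids following every group), and
#'   `union_size`.
#' @export
multi_group_membership <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  ids <- vapply(profiles, function(p) p$org_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate organization ids", call. = FALSE)
  sets <- lapply(profiles, function(p) p$follower_ids)
  all_ids <- unique(unlist(sets))
  k_of <- rowSums(vapply(sets, function(s) all_ids %in% s,
                         logical(length(all_ids))))
  counts <- vapply(seq_along(profiles), function(k) sum(k_of == k), integer(1))
  names(counts) <- as.character(seq_along(profiles))
  list(counts = counts,
       intersection = all_ids[k_of == length(profiles)],
       union_size = length(all_ids))
}

#' Cumulative distribution of followers' audience sizes
#'
#' Right-continuous empirical CDF of the declared follower counts of an
#' organization's followers: at threshold `x`, the fraction of followers
#' whose own audience is `<= x`. Suitable for plotting on a log x-axis; the
#' final cumulative fraction is 1.
#'
#' @param graph a [follow_graph()].
#' @param org an [org_profile()] with at least one follower.
#' @return An object of class `follower_cdf`: a list with `table` (data
#'   frame of `threshold`, `cum_fraction` at each distinct count) and `fun`
#'   (a step function usable as `fun(x)`).
#' @export
follower_cdf <- function(graph, org) {
  if (length(org$follower_ids) == 0) {
    stop("follower CDF is undefined for an organization with no followers",
         call. = FALSE)
  }
  counts <- declared_follower_count(graph, org$follower_ids)
  f <- stats::ecdf(counts)
  thr <- sort(unique(counts))
  structure(list(table = data.frame(threshold = thr, cum_fraction = f(thr)),
                 fun = f, n = length(counts), org_id = org$org_id),
            class = "follower_cdf")
}

#' @export
print.follower_cdf <- function(x, ...) {
  cat(sprintf("<follower_cdf> %s: %d followers, %d distinct audience sizes\n",
              x$org_id, x$n, nrow(x$table)))
  invisible(x)
}

#' @export
plot.follower_cdf <- function(x, log = "x", ...) {
  tab <- x$table
  graphics::plot(pmax(tab$threshold, 1), tab$cum_fraction, type = "s", log = log,
       xlab = "audience size (declared followers)",
       ylab = "cumulative fraction of followers",
       main = x$org_id, ...)
  invisible(x)
}

#' Tweet-activity histogram of an organization's followers
#'
#' Fractions of followers falling in tweet-volume bins. The zero bin
#' isolates exactly the followers who have never tweeted; positive volumes
#' are binned either in powers of ten (`log_bins = TRUE`, matching a log
#' x-axis) or in unit-width bins.
#'
#' @param graph a [follow_graph()].
#' @param org an [org_profile()] with at least one follower.
#' @param log_bins logical; decade bins for positive counts?
#' @return Data frame with columns `bin` (label), `lower`, `upper`
#'   (inclusive bounds) and `fraction`; fractions sum to 1.
#' @export
activity_histogram <- function(graph, org, log_bins = TRUE) {
  if (length(org$follower_ids) == 0) {
    stop("activity histogram is undefined for an organization with no followers",
         call. = FALSE)
  }
  tw <- account_tweet_count(graph, org$follower_ids)
  n <- length(tw)
  pos <- tw[tw > 0]
  if (log_bins) {
    if (length(pos) > 0) {
      top <- max(1, ceiling(log10(max(pos) + 1)))
      lower <- c(0, 10^(seq_len(top) - 1))
      upper <- c(0, 10^seq_len(top) - 1)
    } else {
      lower <- 0; upper <- 0
    }
  } else {
    mx <- if (length(pos) > 0) max(pos) else 0
    lower <- 0:mx
    upper <- 0:mx
  }
  frac <- vapply(seq_along(lower), function(i) {
    sum(tw >= lower[i] & tw <= upper[i]) / n
  }, numeric(1))
  lab <- ifelse(lower == upper, as.character(lower),
                paste0(lower, "-", upper))
  data.frame(bin = lab, lower = lower, upper = upper, fraction = frac)
}

#' Prune inactive followers from the dissemination potential
#'
#' Removes every follower whose tweet count is `<= max_tweets`, together
#' with its Level-2 contribution, and reports the pruned potential and the
#' percentage reduction relative to the unpruned potential. The threshold
#' semantics is inclusive ("only t or fewer tweets"); `max_tweets = NULL`
#' prunes nothing, and `max_tweets = 0` removes exactly the never-tweeted
#' followers.
#'
#' @param graph a [follow_graph()].
#' @param org an [org_profile()].
#' @param max_tweets inclusive activity threshold `t >= 0`, or `NULL` for
#'   no pruning.
#' @param mode passed to [level2_follower_sum()].
#' @return A list with `pruned_potential`, `percent_reduction` (in
#'   `[0, 100]`, `NA` and flagged `defined = FALSE` when the original
#'   potential is 0), `n_removed`, and `threshold`.
#' @export
prune_inactive <- function(graph, org, max_tweets,
                           mode = c("declared", "structural")) {
  mode <- match.arg(mode)
  original <- dissemination_potential(graph, org, mode)
  if (is.null(max_tweets)) {
    keep <- org$follower_ids
  } else {
    if (!is_count(max_tweets)) stop("max_tweets must be >= 0 or NULL",
                                    call. = FALSE)
    tw <- account_tweet_count(graph, org$follower_ids)
    keep <- org$follower_ids[tw > max_tweets]
  }
  pruned_org <- org_profile(org$org_id, keep, org$following_ids,
                            org$tweet_count)
  pruned <- dissemination_potential(graph, pruned_org, mode)
  list(
    pruned_potential = pruned,
    percent_reduction = if (original > 0) 100 * (1 - pruned / original)
                        else NA_real_,
    defined = original > 0,
    n_removed = length(org$follower_ids) - length(keep),
    threshold = if (is.null(max_tweets)) NA_real_ else max_tweets
  )
}

#' Pruning sweep over activity thresholds
#'
#' Applies [prune_inactive()] at each threshold and tabulates the results;
#' the percent reduction is monotone non-decreasing in the threshold.
#'
#' @inheritParams prune_inactive
#' @param thresholds numeric vector of inclusive thresholds; `NA` entries
#'   mean "prune nothing".
#' @return Data frame with one row per threshold: `threshold`,
#'   `pruned_potential`, `percent_reduction`, `n_removed`.
#' @export
prune_sweep <- function(graph, org, thresholds = c(NA, 0, 10),
                        mode = c("declared", "structural")) {
  mode <- match.arg(mode)
  rows <- lapply(thresholds, function(t) {
    r <- prune_inactive(graph, org, if (is.na(t)) NULL else t, mode)
    data.frame(threshold = t, pruned_potential = r$pruned_potential,
               percent_reduction = r$percent_reduction,
               n_removed = r$n_removed)
  })
  do.call(rbind, rows)
}

#' Data-cleaning report
#'
#' Tallies retained versus ignored account records (accounts that were
#' disabled, private, or unrecognizable are typically flagged for
#' exclusion) and reports the ignored percentage of the total.
#'
#' @param records data frame of raw account rows with a logical `ignored`
#'   column, or a `status` column where values in `ignore_status` mark
#'   rows to drop.
#' @param ignore_status statuses treated as ignored when no `ignored`
#'   column is present.
#' @return A list with `retained`, `ignored`, and `ignored_pct`
#'   (`100 * ignored / (retained + ignored)`; 0 for an empty table).
#' @export
data_cleaning_report <- function(records,
                                 ignore_status = c("disabled", "private",
                                                   "unrecognizable", "ignored")) {
  records <- as.data.frame(records)
  if (!is.null(records$ignored)) {
    ign <- as.logical(records$ignored)
  } else if (!is.null(records$status)) {
    ign <- tolower(as.character(records$status)) %in% ignore_status
  } else {
    ign <- rep(FALSE, nrow(records))
  }
  n_ign <- sum(ign, na.rm = TRUE)
  n_keep <- nrow(records) - n_ign
  total <- n_keep + n_ign
  list(retained = n_keep, ignored = n_ign,
       ignored_pct = if (total > 0) 100 * n_ign / total else 0)
}

#' Organization characterization table
#'
#' One row per organization with its follower count, following count, tweet
#' volume, Level-2 follower sum and dissemination potential — the standard
#' per-group summary of a follower-network characterization.
#'
#' @param graph a [follow_graph()].
#' @param profiles list of [org_profile()]s.
#' @param mode passed to [level2_follower_sum()].
#' @return Data frame with columns `org_id`, `followers`, `following`,
#'   `tweets`, `level2_followers`, `potential`.
#' @export
characterize_orgs <- function(graph, profiles,
                              mode = c("declared", "structural")) {
  mode <- match.arg(mode)
  rows <- lapply(profiles, function(p) {
    l2 <- level2_follower_sum(graph, p, mode)
    data.frame(org_id = p$org_id,
               followers = length(p$follower_ids),
               following = length(p$following_ids),
               tweets = p$tweet_count,
               level2_followers = l2,
               potential = length(p$follower_ids) + l2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract organization profiles from a graph
#'
#' Builds one [org_profile()] per account flagged `is_organization`, taking
#' its follower set and following set from the graph structure and its
#' tweet count from the account record. This is how profiles are recovered
#' from a network read off disk.
#'
#' @param graph a [follow_graph()].
#' @return A list of [org_profile()]s, in sorted org-id order.
#' @export
org_profiles_from_graph <- function(graph) {
  org_ids <- sort(graph$accounts$id[graph$accounts$is_organization])
  lapply(org_ids, function(id) {
    org_profile(id,
                follower_ids = followers_of(graph, id),
                following_ids = following_of(graph, id),
                tweet_count = unname(account_tweet_count(graph, id)))
  })
}
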