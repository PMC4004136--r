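# Independent oracles and small graph builders used across the suite.
# Everything here works directly on edge data frames, never through the
# package's adjacency structures, so oracle and implementation stay on
# separate routes.

path_graph <- function(ids) {
  follow_graph(
    accounts = data.frame(id = ids, stringsAsFactors = FALSE),
    edges = data.frame(from = ids[-length(ids)], to = ids[-1],
                       stringsAsFactors = FALSE)
  )
}

triangle_graph <- function() {
  follow_graph(
    accounts = data.frame(id = c("a", "b", "c")),
    edges = data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
  )
}

# Random small test graph (distinct from the package generators only in
# usage: tests treat its edge list as ground truth for brute-force scans).
random_test_graph <- function(n, mean_degree = 3, seed = 1) {
  make_random(n, mean_degree, seed)
}

# Brute-force follower lookup by scanning the edge list.
bf_followers <- function(graph, id) {
  sort(graph$edges$to[graph$edges$from == id])
}

# Brute-force two-loop dissemination potential: walk the follower list and
# sum declared counts straight out of the accounts table.
bf_potential <- function(graph, org) {
  total <- length(org$follower_ids)
  for (f in org$follower_ids) {
    total <- total + graph$accounts[graph$accounts$id == f,
                                    "declared_follower_count"]
  }
  total
}

# Independent BFS reach under a fixed per-node resend assignment.
bf_reach <- function(edges, source, fires) {
  reached <- character()
  frontier <- edges$to[edges$from == source]
  repeat {
    frontier <- setdiff(frontier, c(reached, source))
    if (length(frontier) == 0) break
    reached <- c(reached, frontier)
    senders <- frontier[fires[frontier]]
    frontier <- unique(edges$to[edges$from %in% senders])
  }
  reached
}

# Exact expected cascade reach by exhaustive enumeration over all per-node
# coin outcomes (2^k assignments; requires few enough potential firers).
enum_expected_reach <- function(graph, source, p) {
  ids <- setdiff(account_ids(graph), source)
  k <- length(ids)
  stopifnot(k <= 12)
  total <- 0
  for (m in 0:(2^k - 1)) {
    bits <- bitwAnd(m, 2^(seq_len(k) - 1)) > 0
    fires <- stats::setNames(bits, ids)
    fires[source] <- TRUE
    weight <- prod(ifelse(bits, p, 1 - p))
    total <- total + weight * length(bf_reach(graph$edges, source, fires))
  }
  total
}

# Deterministically spread a total audience over n followers (used to build
# organizations whose Level-2 sum matches a printed table value exactly).
spread_counts <- function(total, n) {
  base <- total %/% n
  counts <- rep(base, n)
  extra <- total - base * n
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}

# Build a graph holding one organization with n followers whose declared
# counts sum to level2_sum, plus optional retweeter accounts with given
# declared counts.
build_org_fixture <- function(n_followers, level2_sum,
                              retweeter_counts = numeric(),
                              follower_tweets = NULL,
                              follower_declared = NULL) {
  f_ids <- sprintf("f%06d", seq_len(n_followers))
  declared <- follower_declared %||% spread_counts(level2_sum, n_followers)
  tweets <- follower_tweets %||% rep(1, n_followers)
  r_ids <- if (length(retweeter_counts) > 0) {
    sprintf("r%03d", seq_along(retweeter_counts))
  } else character()
  accounts <- data.frame(
    id = c("org", f_ids, r_ids),
    declared_follower_count = c(n_followers, declared, retweeter_counts),
    tweet_count = c(0, tweets, rep(1, length(r_ids))),
    is_organization = c(TRUE, rep(FALSE, n_followers + length(r_ids))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = "org", to = c(f_ids, r_ids),
                      stringsAsFactors = FALSE)
  list(graph = follow_graph(accounts, edges),
       org = org_profile("org", f_ids),
       retweeter_ids = r_ids)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
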