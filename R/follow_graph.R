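#' Directed follower graph with account attributes
#'
#' A `follow_graph` stores a directed graph whose edge direction encodes
#' information flow: an edge `u -> v` means `v` follows `u`, so a message
#' posted by `u` is seen by `v`. Each node is an account carrying a declared
#' (global) follower count, a tweet count, and an organization flag. The
#' declared follower count of an account may exceed its structural out-degree
#' in the graph, because a harvested graph is typically a sample of the full
#' platform; the two are never conflated (see [declared_follower_count()] and
#' [structural_follower_count()]).
#'
#' @param accounts data frame with column `id` (unique character ids) and
#'   optional columns `declared_follower_count`, `tweet_count`
#'   (non-negative numbers, default 0) and `is_organization` (logical,
#'   default `FALSE`). Extra columns are preserved.
#' @param edges two-column data frame (or matrix) of character ids,
#'   `from` and `to`, in information-flow direction. Self-loops are an
#'   error; duplicate edges are collapsed.
#'
#' @return An object of class `follow_graph`.
#' @examples
#' g <- follow_graph(
#'   accounts = data.frame(id = c("org", "a", "b")),
#'   edges = data.frame(from = c("org", "org"), to = c("a", "b"))
#' )
#' followers_of(g, "org")
#' @export
follow_graph <- function(accounts, edges = NULL) {
  if (is.null(accounts) || !"id" %in% names(accounts)) {
    stop("`accounts` must be a data frame with an `id` column", call. = FALSE)
  }
  accounts <- as.data.frame(accounts, stringsAsFactors = FALSE)
  accounts$id <- as.character(accounts$id)
  if (anyDuplicated(accounts$id)) {
    stop("account ids must be unique", call. = FALSE)
  }
  n <- nrow(accounts)
  if (is.null(accounts$declared_follower_count)) {
    accounts$declared_follower_count <- rep(0, n)
  }
  if (is.null(accounts$tweet_count)) accounts$tweet_count <- rep(0, n)
  if (is.null(accounts$is_organization)) accounts$is_organization <- rep(FALSE, n)
  accounts$declared_follower_count <- as.numeric(accounts$declared_follower_count)
  accounts$tweet_count <- as.numeric(accounts$tweet_count)
  accounts$is_organization <- as.logical(accounts$is_organization)
  if (any(is.na(accounts$declared_follower_count)) ||
      any(accounts$declared_follower_count < 0)) {
    stop("declared_follower_count must be non-negative", call. = FALSE)
  }
  if (any(is.na(accounts$tweet_count)) || any(accounts$tweet_count < 0)) {
    stop("tweet_count must be non-negative", call. = FALSE)
  }

  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 && nrow(edges) > 0) {
    stop("`edges` needs two columns: from, to", call. = FALSE)
  }
  if (ncol(edges) >= 2) {
    edges <- data.frame(from = as.character(edges[[1]]),
                        to = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed in a follow_graph", call. = FALSE)
    }
    unknown <- setdiff(unique(c(edges$from, edges$to)), accounts$id)
    if (length(unknown) > 0) {
      stop("edge endpoints not registered as accounts: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    edges <- unique(edges)
  }
  rownames(accounts) <- accounts$id
  g <- list(accounts = accounts, edges = edges)
  g$adj_out <- split(edges$to, factor(edges$from, levels = accounts$id))
  g$adj_in <- split(edges$from, factor(edges$to, levels = accounts$id))
  class(g) <- "follow_graph"
  g
}

#' @export
print.follow_graph <- function(x, ...) {
  cat(sprintf("<follow_graph> %d accounts, %d edges (%d organizations)\n",
              nrow(x$accounts), nrow(x$edges), sum(x$accounts$is_organization)))
  invisible(x)
}

#' @rdname follow_graph
#' @param graph a `follow_graph`.
#' @export
n_accounts <- function(graph) nrow(graph$accounts)

#' @rdname follow_graph
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @rdname follow_graph
#' @export
account_ids <- function(graph) graph$accounts$id

check_ids <- function(graph, ids, what = "account") {
  missing <- setdiff(as.character(ids), graph$accounts$id)
  if (length(missing) > 0) {
    stop("unknown ", what, " id(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Account attribute accessors
#'
#' `declared_follower_count()` returns the account's platform-reported global
#' follower count; `structural_follower_count()` returns its out-degree in
#' this (possibly sampled) graph. The two differ whenever the graph does not
#' contain the account's full audience, so every metric documents which one
#' it consumes.
#'
#' @param graph a [follow_graph()].
#' @param ids character vector of account ids (default: all accounts).
#' @return Named numeric vector.
#' @export
declared_follower_count <- function(graph, ids = account_ids(graph)) {
  ids <- as.character(ids)
  check_ids(graph, ids)
  stats::setNames(graph$accounts[ids, "declared_follower_count"], ids)
}

#' @rdname declared_follower_count
#' @export
structural_follower_count <- function(graph, ids = account_ids(graph)) {
  ids <- as.character(ids)
  check_ids(graph, ids)
  stats::setNames(lengths(graph$adj_out[ids]), ids)
}

#' @rdname declared_follower_count
#' @export
account_tweet_count <- function(graph, ids = account_ids(graph)) {
  ids <- as.character(ids)
  check_ids(graph, ids)
  stats::setNames(graph$accounts[ids, "tweet_count"], ids)
}

#' Followers of an account
#'
#' Out-neighbors under the information-flow convention: the accounts that
#' receive `id`'s messages directly.
#'
#' @param graph a [follow_graph()].
#' @param id a registered account id.
#' @return Character vector of follower ids (possibly empty).
#' @export
followers_of <- function(graph, id) {
  id <- as.character(id)
  check_ids(graph, id)
  as.character(graph$adj_out[[id]] %||% character())
}

#' @rdname followers_of
#' @export
following_of <- function(graph, id) {
  id <- as.character(id)
  check_ids(graph, id)
  as.character(graph$adj_in[[id]] %||% character())
}

#' Degree distribution
#'
#' Tabulates node degrees (in, out, or total) over all accounts.
#'
#' @param graph a [follow_graph()].
#' @param mode one of `"out"` (audience size), `"in"` (sources followed) or
#'   `"total"`.
#' @return Data frame with columns `degree` and `count`; counts sum to the
#'   number of accounts.
#' @export
degree_distribution <- function(graph, mode = c("out", "in", "total")) {
  mode <- match.arg(mode)
  d_out <- lengths(graph$adj_out)
  d_in <- lengths(graph$adj_in)
  deg <- switch(mode, out = d_out, `in` = d_in, total = d_out + d_in)
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

# Internal: igraph views of the graph (directed, and simple undirected
# projection) for shortest-path and clustering computations.
as_igraph <- function(graph, directed = TRUE) {
  ig <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                      vertices = graph$accounts["id"])
  if (!directed) {
    ig <- igraph::as_undirected(ig, mode = "collapse")
  }
  ig
}

#' Graph diameter
#'
#' Longest shortest-path length over ordered node pairs, using unweighted
#' breadth-first search. When some pair is mutually unreachable the result
#' depends on `unreachable`: `"inf"` (the default, strict mode) returns
#' `Inf` to flag the disconnection explicitly, `"drop"` returns the longest
#' finite distance.
#'
#' @param graph a non-empty [follow_graph()].
#' @param directed respect edge direction (information flow)?
#' @param unreachable `"inf"` or `"drop"` (see above).
#' @return A single number, possibly `Inf`.
#' @export
graph_diameter <- function(graph, directed = TRUE,
                           unreachable = c("inf", "drop")) {
  unreachable <- match.arg(unreachable)
  if (n_accounts(graph) == 0) {
    stop("diameter of an empty graph is undefined", call. = FALSE)
  }
  if (n_accounts(graph) == 1) return(0)
  ig <- as_igraph(graph, directed = directed)
  if (unreachable == "inf") {
    connected <- igraph::is_connected(ig, mode = if (directed) "strong" else "weak")
    if (!connected) return(Inf)
  }
  igraph::diameter(ig, directed = directed, unconnected = TRUE)
}

#' Local clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected
#' (triangle density around the node), computed on the simple undirected
#' projection of the graph. Nodes with fewer than two neighbors have
#' coefficient 0.
#'
#' @param graph a [follow_graph()].
#' @param ids account ids (default: all).
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_clustering <- function(graph, ids = account_ids(graph)) {
  ids <- as.character(ids)
  check_ids(graph, ids)
  ig <- as_igraph(graph, directed = FALSE)
  cc <- igraph::transitivity(ig, type = "local", vids = ids, isolates = "zero")
  cc[is.nan(cc)] <- 0
  stats::setNames(cc, ids)
}

# Undirected neighbor set of one node (union of in- and out-neighbors).
neighbors_undirected <- function(graph, id) {
  unique(c(graph$adj_out[[id]] %||% character(),
           graph$adj_in[[id]] %||% character()))
}

#' Group cohesion
#'
#' Cohesion of a set of accounts: the number of neighbors common to every
#' member divided by the total number of distinct neighbors of any member.
#' Neighbor sets are taken on the undirected projection and exclude the
#' members themselves, so mutual follows among members do not inflate the
#' score. When the members have no neighbors at all the ratio is undefined
#' and flagged (`defined = FALSE`, `cohesion = NA`).
#'
#' @param graph a [follow_graph()].
#' @param member_ids at least two registered account ids.
#' @return An object of class `group_cohesion` with fields `member_ids`,
#'   `common_neighbors`, `total_neighbors`, `cohesion`, `defined`.
#' @export
group_cohesion <- function(graph, member_ids) {
  member_ids <- unique(as.character(member_ids))
  if (length(member_ids) < 2) {
    stop("group cohesion needs at least two members", call. = FALSE)
  }
  check_ids(graph, member_ids)
  nbrs <- lapply(member_ids, function(m) {
    setdiff(neighbors_undirected(graph, m), member_ids)
  })
  common <- Reduce(intersect, nbrs)
  total <- unique(unlist(nbrs))
  res <- list(
    member_ids = member_ids,
    common_neighbors = length(common),
    total_neighbors = length(total),
    cohesion = if (length(total) > 0) length(common) / length(total) else NA_real_,
    defined = length(total) > 0
  )
  class(res) <- "group_cohesion"
  res
}

#' @export
print.group_cohesion <- function(x, ...) {
  cat(sprintf("<group_cohesion> %d members: %d common / %d total neighbors",
              length(x$member_ids), x$common_neighbors, x$total_neighbors))
  if (x$defined) cat(sprintf(" = %.4f\n", x$cohesion)) else cat(" (undefined)\n")
  invisible(x)
}

#' Pairwise Jaccard similarity of two accounts' neighborhoods
#'
#' Convenience companion to [group_cohesion()]: intersection over union of
#' the two accounts' undirected neighbor sets (the accounts themselves
#' excluded). For a two-member group this coincides with group cohesion.
#'
#' @param graph a [follow_graph()].
#' @param id_a,id_b registered account ids.
#' @return A number in `[0, 1]`, or `NA` if both neighborhoods are empty.
#' @export
pairwise_jaccard <- function(graph, id_a, id_b) {
  gc <- group_cohesion(graph, c(id_a, id_b))
  gc$cohesion
}
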