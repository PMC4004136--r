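#' Star topology
#'
#' One center (node `"0"`) with out-edges to all periphery nodes and no other
#' edges: every message from the center reaches everyone in one hop, while a
#' message from the periphery reaches nobody.
#'
#' @param n total number of nodes, `n >= 2`.
#' @return A [follow_graph()] with ids `"0"` (center) to `as.character(n-1)`.
#' @export
make_star <- function(n) {
  if (!is_count(n) || n < 2) stop("star needs n >= 2 nodes", call. = FALSE)
  ids <- as.character(seq_len(n) - 1L)
  follow_graph(
    accounts = data.frame(id = ids, stringsAsFactors = FALSE),
    edges = data.frame(from = "0", to = ids[-1], stringsAsFactors = FALSE)
  )
}

#' Random (Erdos-Renyi) directed topology
#'
#' Each ordered pair of distinct nodes receives an edge independently with
#' probability `mean_degree / (n - 1)`, so out-degrees follow a
#' Binomial(n-1, p) law — approximately normal, the hallmark of a random
#' network with no hubs.
#'
#' @param n number of nodes.
#' @param mean_degree target mean out-degree, `0 < mean_degree < n - 1`
#'   (the boundary values 0 and n-1 give the edgeless and complete graphs).
#' @param seed integer seed; same seed and parameters give identical edges.
#' @return A [follow_graph()].
#' @export
make_random <- function(n, mean_degree, seed) {
  if (!is_count(n) || n < 2) stop("need n >= 2", call. = FALSE)
  if (!is.numeric(mean_degree) || mean_degree < 0 || mean_degree > n - 1) {
    stop("mean_degree must lie in [0, n-1]", call. = FALSE)
  }
  p <- mean_degree / (n - 1)
  ids <- as.character(seq_len(n) - 1L)
  with_seed(seed, {
    d <- stats::rbinom(n, n - 1L, p)
    from <- rep(ids, d)
    to <- unlist(lapply(seq_len(n), function(i) {
      if (d[i] == 0) return(character())
      sample(ids[-i], d[i])
    }))
    follow_graph(
      accounts = data.frame(id = ids, stringsAsFactors = FALSE),
      edges = data.frame(from = from, to = to, stringsAsFactors = FALSE)
    )
  })
}

# Discrete power-law sampler, P(X = k) ~ k^-alpha for k >= xmin, via the
# continuous-inverse-transform approximation of Clauset et al.
rpowerlaw <- function(n, exponent, xmin = 1) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (exponent - 1)) + 0.5)
}

#' Power-law (small-world) topology
#'
#' Out-degrees (audience sizes) are drawn from a discrete power law with the
#' given exponent and minimum, then each node is wired to a uniform random
#' set of targets of that size (configuration-model style pairing). The
#' result has a few highly connected hubs, many low-degree nodes, and the
#' low diameter characteristic of small-world networks. Degrees are capped
#' at `n - 1` (a node cannot address more distinct targets than exist).
#'
#' @param n number of nodes.
#' @param exponent power-law exponent `> 1` (Twitter-like graphs are
#'   typically near 2-2.5).
#' @param min_degree minimum out-degree, `>= 1`.
#' @param seed integer seed.
#' @return A [follow_graph()].
#' @export
make_power_law <- function(n, exponent, min_degree = 1L, seed = 1L) {
  if (!is_count(n) || n < 2) stop("need n >= 2", call. = FALSE)
  if (!is.numeric(exponent) || exponent <= 1) {
    stop("exponent must exceed 1", call. = FALSE)
  }
  if (!is_count(min_degree) || min_degree < 1) {
    stop("min_degree must be >= 1", call. = FALSE)
  }
  ids <- as.character(seq_len(n) - 1L)
  with_seed(seed, {
    d <- pmin(rpowerlaw(n, exponent, min_degree), n - 1L)
    from <- rep(ids, d)
    to <- unlist(lapply(seq_len(n), function(i) {
      if (d[i] == 0) return(character())
      sample(ids[-i], d[i])
    }))
    follow_graph(
      accounts = data.frame(id = ids, stringsAsFactors = FALSE),
      edges = data.frame(from = from, to = to, stringsAsFactors = FALSE)
    )
  })
}

#' Configuration for multi-organization fixtures
#'
#' Describes a synthetic multi-organization follower network: how many
#' organization accounts, how many followers each has, the pairwise follower
#' overlap between organizations, the law of followers' declared (global)
#' follower counts, and the law of followers' tweet activity.
#'
#' The defaults emulate the follower populations of three mid-sized US
#' physician-association Twitter accounts circa 2012: follower-set sizes
#' 7546, 5955 and 11,768; follower audience-size medians of 120, 165 and 81;
#' zero-activity masses of 6.92%, 7.22% and 8.17%; and 25% pairwise follower
#' overlap, inside the 13%-55% band observed for such communities.
#'
#' @param n_orgs number of organization accounts.
#' @param followers_per_org integer vector of follower-set sizes, one per
#'   organization.
#' @param pairwise_overlap_fraction either a single fraction applied to every
#'   pair or a symmetric `n_orgs x n_orgs` matrix; the overlap between groups
#'   i and j is realized as `round(f * min(size_i, size_j))` shared
#'   followers (diagonal ignored).
#' @param follower_degree_law list with `family` (`"power-law"` or
#'   `"lognormal"`), `minimum` (smallest declared count), and either
#'   `exponent` / `sdlog` (shape) or `target_median` (per-organization
#'   medians; when given, the shape is kept and the scale is solved so the
#'   law's median hits the target).
#' @param activity_law list with `zero_fraction` (per-organization
#'   probability a follower has never tweeted) and `meanlog`, `sdlog` for
#'   the discrete-lognormal positive part.
#' @param org_tweet_counts tweet volume of each organization account.
#' @param seed integer seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_orgs = 3L,
                           followers_per_org = c(7546L, 5955L, 11768L),
                           pairwise_overlap_fraction = 0.25,
                           follower_degree_law = list(
                             family = "power-law",
                             exponent = 2.0,
                             minimum = 1L,
                             target_median = c(120, 165, 81)
                           ),
                           activity_law = list(
                             zero_fraction = c(0.0692, 0.0722, 0.0817),
                             meanlog = log(200),
                             sdlog = 1.5
                           ),
                           org_tweet_counts = c(2788L, 2979L, 1184L),
                           seed = 1L) {
  if (!is_count(n_orgs) || n_orgs < 1) stop("n_orgs must be >= 1", call. = FALSE)
  followers_per_org <- rep_len(as.integer(followers_per_org), n_orgs)
  if (any(followers_per_org < 1)) {
    stop("followers_per_org must be positive", call. = FALSE)
  }
  if (is.matrix(pairwise_overlap_fraction)) {
    ov <- pairwise_overlap_fraction
    if (!all(dim(ov) == n_orgs) || any(abs(ov - t(ov)) > 1e-12)) {
      stop("overlap matrix must be symmetric n_orgs x n_orgs", call. = FALSE)
    }
  } else {
    ov <- matrix(pairwise_overlap_fraction[1], n_orgs, n_orgs)
  }
  diag(ov) <- 0
  if (any(ov < 0 | ov > 1)) stop("overlap fractions must lie in [0,1]", call. = FALSE)
  follower_degree_law$family <- match.arg(follower_degree_law$family,
                                          c("power-law", "lognormal"))
  zf <- rep_len(activity_law$zero_fraction, n_orgs)
  if (any(zf < 0 | zf > 1)) stop("zero_fraction must lie in [0,1]", call. = FALSE)
  activity_law$zero_fraction <- zf
  cfg <- list(
    n_orgs = as.integer(n_orgs),
    followers_per_org = followers_per_org,
    pairwise_overlap_fraction = ov,
    follower_degree_law = follower_degree_law,
    activity_law = activity_law,
    org_tweet_counts = rep_len(as.integer(org_tweet_counts), n_orgs),
    seed = as.integer(seed)
  )
  class(cfg) <- "fixture_config"
  cfg
}

# Per-org sampler for declared follower counts, solving the scale so the
# law's median hits the configured target when one is given.
sample_declared_counts <- function(n, law, org_index) {
  med <- law$target_median
  if (!is.null(med)) med <- rep_len(med, max(org_index, length(med)))[org_index]
  if (law$family == "power-law") {
    a <- law$exponent %||% 2.0
    xmin <- law$minimum %||% 1L
    if (!is.null(med)) {
      # continuous Pareto median = xmin * 2^(1/(a-1))
      xmin <- max(1, med / 2^(1 / (a - 1)))
    }
    counts <- rpowerlaw(n, a, xmin)
  } else {
    sdlog <- law$sdlog %||% 1.5
    meanlog <- if (!is.null(med)) log(med) else law$meanlog %||% log(100)
    counts <- pmax(law$minimum %||% 0, round(stats::rlnorm(n, meanlog, sdlog)))
  }
  counts
}

#' Generate a multi-organization Twitter-like fixture
#'
#' Builds a [follow_graph()] containing `n_orgs` organization accounts and
#' their follower populations with the configured pairwise overlaps, plus
#' one [org_profile()] per organization. Shared followers are drawn from a
#' common pool before group-specific remainders are filled, so requested
#' pairwise intersections are realized exactly. Each follower carries a
#' declared follower count drawn from the configured audience-size law and
#' a tweet count drawn from the zero-inflated activity law. Output is
#' deterministic under a fixed seed.
#'
#' @param config a [fixture_config()].
#' @return A list with elements `graph` (the [follow_graph()]), `profiles`
#'   (list of [org_profile()]), and `config`.
#' @export
make_twitter_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  k <- config$n_orgs
  sizes <- config$followers_per_org
  ov <- config$pairwise_overlap_fraction
  shared_n <- matrix(0L, k, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      shared_n[i, j] <- as.integer(round(ov[i, j] * min(sizes[i], sizes[j])))
    }
  }
  committed <- rowSums(shared_n) + colSums(shared_n)
  if (any(committed > sizes)) {
    stop("requested pairwise overlaps exceed follower-set sizes", call. = FALSE)
  }

  org_ids <- paste0("org", seq_len(k))
  with_seed(config$seed, {
    member_sets <- vector("list", k)  # follower ids per org
    counter <- 0L
    new_ids <- function(m) {
      ids <- sprintf("u%07d", counter + seq_len(m))
      counter <<- counter + m
      ids
    }
    primary_org <- character()  # which org's laws a follower draws from
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (shared_n[i, j] > 0) {
          ids <- new_ids(shared_n[i, j])
          member_sets[[i]] <- c(member_sets[[i]], ids)
          member_sets[[j]] <- c(member_sets[[j]], ids)
          primary_org[ids] <- org_ids[i]
        }
      }
    }
    for (i in seq_len(k)) {
      need <- sizes[i] - length(member_sets[[i]])
      if (need > 0) {
        ids <- new_ids(need)
        member_sets[[i]] <- c(member_sets[[i]], ids)
        primary_org[ids] <- org_ids[i]
      }
    }

    follower_ids <- sprintf("u%07d", seq_len(counter))
    org_of <- match(primary_org[follower_ids], org_ids)
    declared <- numeric(counter)
    tweets <- numeric(counter)
    for (i in seq_len(k)) {
      idx <- which(org_of == i)
      if (length(idx) == 0) next
      declared[idx] <- sample_declared_counts(length(idx),
                                              config$follower_degree_law, i)
      zf <- config$activity_law$zero_fraction[i]
      active <- stats::runif(length(idx)) >= zf
      pos <- pmax(1, round(stats::rlnorm(sum(active),
                                         config$activity_law$meanlog %||% log(200),
                                         config$activity_law$sdlog %||% 1.5)))
      tweets[idx[active]] <- pos
    }

    accounts <- data.frame(
      id = c(org_ids, follower_ids),
      declared_follower_count = c(sizes, declared),
      tweet_count = c(config$org_tweet_counts, tweets),
      is_organization = c(rep(TRUE, k), rep(FALSE, counter)),
      stringsAsFactors = FALSE
    )
    edges <- data.frame(
      from = rep(org_ids, lengths(member_sets)),
      to = unlist(member_sets) %||% character(),
      stringsAsFactors = FALSE
    )
    graph <- follow_graph(accounts, edges)
    # post-generation check: realized pairwise overlap within 2 percentage
    # points of the request (exact by construction, up to rounding)
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        realized <- length(intersect(member_sets[[i]], member_sets[[j]])) /
          min(sizes[i], sizes[j])
        if (abs(realized - ov[i, j]) > 0.02) {
          stop("realized overlap for orgs ", i, ",", j,
               " deviates from request by more than 2 percentage points",
               call. = FALSE)
        }
      }
    }
    profiles <- lapply(seq_len(k), function(i) {
      org_profile(org_ids[i], follower_ids = member_sets[[i]],
                  tweet_count = config$org_tweet_counts[i])
    })
    list(graph = graph, profiles = profiles, config = config)
  })
}
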