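test_that("Level-2 sums add followers' declared audiences without deduplication", {
  fx <- build_org_fixture(3, 0, follower_declared = c(0, 0, 0))
  expect_equal(level2_follower_sum(fx$graph, fx$org), 0)

  fx <- build_org_fixture(3, 60, follower_declared = c(10, 20, 30))
  expect_equal(level2_follower_sum(fx$graph, fx$org), 60)
  expect_equal(dissemination_potential(fx$graph, fx$org), 63)

  # an organization shaped like a mid-sized professional society: 7546
  # followers whose audiences sum to 6,951,546
  aafp <- build_org_fixture(7546, 6951546)
  expect_equal(level2_follower_sum(aafp$graph, aafp$org), 6951546)
  expect_equal(dissemination_potential(aafp$graph, aafp$org), 6959092)

  orphan <- org_profile("org", "ghost")
  expect_error(level2_follower_sum(fx$graph, orphan), "unknown")
})

test_that("dissemination potential matches a brute-force two-loop oracle", {
  expect_equal(
    dissemination_potential(build_org_fixture(1, 0)$graph,
                            org_profile("lonely")), 0)
  for (seed in 1:3) {
    g <- random_test_graph(80, 3, seed = seed)
    set.seed(seed)
    acc <- g$accounts
    acc$declared_follower_count <- sample(0:500, nrow(acc), replace = TRUE)
    g <- follow_graph(acc, g$edges)
    org <- org_profile(account_ids(g)[1], followers_of(g, account_ids(g)[1]))
    expect_equal(dissemination_potential(g, org), bf_potential(g, org))
    expect_gte(dissemination_potential(g, org), length(org$follower_ids))
  }
})

test_that("structural mode and unique reach give the exact in-graph variants", {
  # org -> {a, b}; a -> {x, y}, b -> {y}: declared counts deliberately stale
  g <- follow_graph(
    data.frame(id = c("org", "a", "b", "x", "y"),
               declared_follower_count = c(2, 99, 99, 0, 0)),
    data.frame(from = c("org", "org", "a", "a", "b"),
               to = c("a", "b", "x", "y", "y"))
  )
  org <- org_profile("org", c("a", "b"))
  expect_equal(level2_follower_sum(g, org, mode = "structural"), 3)
  expect_equal(dissemination_potential(g, org, mode = "structural"), 5)
  expect_equal(unique_reach(g, org), 4)  # {a, b, x, y}, y deduplicated
  expect_equal(level2_follower_sum(g, org), 198)
})

test_that("overlap percentage is intersection over the smaller set", {
  expect_equal(overlap_percentage(letters[1:5], letters[1:5]), 100)
  expect_equal(overlap_percentage(letters[1:5], letters[6:10]), 0)
  expect_equal(overlap_percentage(c("1", "2", "3"), c("2", "3", "4", "5")),
               100 * 2 / 3)
  # symmetry and containment
  expect_equal(overlap_percentage(letters[1:3], letters[1:10]), 100)
  expect_equal(overlap_percentage(letters[1:10], letters[1:3]), 100)
  expect_error(overlap_percentage(character(), letters[1:3]), "empty")
})

test_that("multi-group membership partitions the union of follower sets", {
  p1 <- org_profile("o1", c("1", "2"))
  p2 <- org_profile("o2", c("2", "3"))
  p3 <- org_profile("o3", c("2", "4"))
  mm <- multi_group_membership(list(p1, p2, p3))
  expect_equal(unname(mm$counts), c(3L, 0L, 1L))
  expect_identical(mm$intersection, "2")
  expect_equal(sum(mm$counts), mm$union_size)

  disj <- multi_group_membership(list(org_profile("a", c("x", "y")),
                                      org_profile("b", c("z"))))
  expect_equal(unname(disj$counts), c(3L, 0L))
  expect_length(disj$intersection, 0)

  same <- multi_group_membership(list(org_profile("a", c("s1", "s2")),
                                      org_profile("b", c("s1", "s2")),
                                      org_profile("c", c("s1", "s2"))))
  expect_equal(unname(same$counts), c(0L, 0L, 2L))
  expect_setequal(same$intersection, c("s1", "s2"))

  expect_error(multi_group_membership(list(p1, org_profile("o1", "9"))),
               "duplicate")
  # partition property on generated fixtures
  fx <- make_twitter_fixture(fixture_config(n_orgs = 3,
                                            followers_per_org = c(200, 150, 180),
                                            pairwise_overlap_fraction = 0.3,
                                            seed = 6))
  mm2 <- multi_group_membership(fx$profiles)
  expect_equal(sum(mm2$counts), mm2$union_size)
})

test_that("follower CDF is a right-continuous step function ending at 1", {
  same <- build_org_fixture(4, 40, follower_declared = rep(10, 4))
  cdf <- follower_cdf(same$graph, same$org)
  expect_identical(cdf$table,
                   data.frame(threshold = 10, cum_fraction = 1))

  quart <- build_org_fixture(4, 1110, follower_declared = c(0, 10, 100, 1000))
  cdf <- follower_cdf(quart$graph, quart$org)
  expect_equal(cdf$table$cum_fraction, c(0.25, 0.5, 0.75, 1))
  expect_equal(cdf$fun(99), 0.5)   # right-continuity between steps
  expect_equal(cdf$fun(100), 0.75)

  # agrees with naive recomputation on a generated fixture
  fx <- make_twitter_fixture(fixture_config(n_orgs = 1,
                                            followers_per_org = 500,
                                            seed = 4))
  counts <- declared_follower_count(fx$graph, fx$profiles[[1]]$follower_ids)
  cdf2 <- follower_cdf(fx$graph, fx$profiles[[1]])
  for (x in c(0, 10, 50, 120, 1000)) {
    expect_equal(cdf2$fun(x), mean(counts <= x))
  }
  expect_error(follower_cdf(fx$graph, org_profile("empty")), "no followers")
})

test_that("activity histogram isolates the zero bin and sums to 1", {
  idle <- build_org_fixture(5, 0, follower_tweets = rep(0, 5))
  h <- activity_histogram(idle$graph, idle$org)
  expect_equal(h$fraction[h$lower == 0], 1)

  # 522 of 7546 never tweeted -> zero bin 6.92%
  tweets <- c(rep(0, 522), rep(5, 7546 - 522))
  soc <- build_org_fixture(7546, 7546, follower_tweets = tweets)
  h2 <- activity_histogram(soc$graph, soc$org)
  expect_equal(round(100 * h2$fraction[h2$lower == 0], 2), 6.92)
  expect_equal(sum(h2$fraction), 1)

  # arbitrary fixture: every bin fraction equals brute-force counting
  fx <- make_twitter_fixture(fixture_config(n_orgs = 1,
                                            followers_per_org = 400,
                                            seed = 12))
  tw <- account_tweet_count(fx$graph, fx$profiles[[1]]$follower_ids)
  h3 <- activity_histogram(fx$graph, fx$profiles[[1]])
  for (i in seq_len(nrow(h3))) {
    expect_equal(h3$fraction[i],
                 mean(tw >= h3$lower[i] & tw <= h3$upper[i]))
  }
  expect_equal(sum(h3$fraction), 1)
})

test_that("pruning inactive followers behaves at the threshold extremes", {
  fx <- build_org_fixture(20, 2000,
                          follower_tweets = rep(c(0, 5, 20, 100), 5))
  none <- prune_inactive(fx$graph, fx$org, NULL)
  expect_equal(none$percent_reduction, 0)
  expect_equal(none$n_removed, 0)

  all_gone <- prune_inactive(fx$graph, fx$org, 100)
  expect_equal(all_gone$percent_reduction, 100)
  expect_equal(all_gone$pruned_potential, 0)

  empty <- org_profile("org")
  flagged <- prune_inactive(fx$graph, empty, 0)
  expect_false(flagged$defined)
  expect_true(is.na(flagged$percent_reduction))
})

test_that("pruning reduction is monotone and equals the subgraph recomputation", {
  fx <- make_twitter_fixture(fixture_config(n_orgs = 1,
                                            followers_per_org = 600,
                                            seed = 21))
  g <- fx$graph; org <- fx$profiles[[1]]
  sweep <- prune_sweep(g, org, thresholds = c(NA, 0, 1, 10, 100, 1000))
  red <- sweep$percent_reduction
  expect_true(all(diff(red) >= -1e-12))
  expect_true(all(red >= 0 & red <= 100))

  for (t in c(0, 10, 100)) {
    res <- prune_inactive(g, org, t)
    tw <- account_tweet_count(g, org$follower_ids)
    keep <- org$follower_ids[tw > t]
    # second route: delete the pruned followers and recompute from scratch
    sub_acc <- g$accounts[!g$accounts$id %in% setdiff(org$follower_ids, keep), ]
    sub_edges <- g$edges[g$edges$from %in% sub_acc$id &
                           g$edges$to %in% sub_acc$id, ]
    sub <- follow_graph(sub_acc, sub_edges)
    expect_equal(res$pruned_potential,
                 dissemination_potential(sub, org_profile(org$org_id, keep)))
  }
})

test_that("zero-activity followers with tiny audiences barely dent the potential", {
  # followers who never tweet hold < 1% of the Level-2 mass
  n <- 1000
  tweets <- c(rep(0, 70), rep(50, n - 70))
  declared <- c(rep(1, 70), rep(500, n - 70))
  fx <- build_org_fixture(n, sum(declared), follower_tweets = tweets,
                          follower_declared = declared)
  res <- prune_inactive(fx$graph, fx$org, 0)
  expect_lt(res$percent_reduction, 1)
})

test_that("data-cleaning report tallies ignored records", {
  clean <- data_cleaning_report(data.frame(id = 1:10, status = "ok"))
  expect_equal(clean$ignored_pct, 0)

  recs <- data.frame(id = seq_len(238853),
                     status = c(rep("disabled", 1257), rep("ok", 237596)))
  rep9 <- data_cleaning_report(recs)
  expect_equal(rep9$ignored, 1257)
  expect_equal(rep9$retained, 237596)
  expect_lt(rep9$ignored_pct, 1)
  expect_equal(round(rep9$ignored_pct, 2), 0.53)

  set.seed(99)
  flags <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  r <- data_cleaning_report(data.frame(id = 1:500, ignored = flags))
  expect_equal(r$ignored, sum(flags))
  expect_equal(r$ignored_pct, 100 * sum(flags) / 500)
})

test_that("characterization table reproduces per-organization statistics", {
  fx <- make_twitter_fixture(fixture_config(n_orgs = 2,
                                            followers_per_org = c(100, 80),
                                            pairwise_overlap_fraction = 0.1,
                                            seed = 31))
  tab <- characterize_orgs(fx$graph, fx$profiles)
  expect_equal(tab$followers, c(100, 80))
  expect_equal(tab$potential, tab$followers + tab$level2_followers)
  expect_equal(tab$potential[1], dissemination_potential(fx$graph, fx$profiles[[1]]))
})
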