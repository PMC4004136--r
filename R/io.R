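#' Write and read edge lists
#'
#' The canonical on-disk graph format: one edge per line in information-flow
#' direction (`from` = followee, `to` = follower), tab-delimited with a
#' header, `#`-prefixed comment lines allowed. The reader auto-detects the
#' delimiter (tab, comma, or whitespace) and an optional header, and
#' round-trips anything the writer emits. Writers sort rows so output is
#' byte-identical across runs and platforms.
#'
#' @param graph a [follow_graph()].
#' @param path file path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns a data frame with character columns `from` and `to`.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  e <- e[order(e$from, e$to), , drop = FALSE]
  lines <- c("from\tto", if (nrow(e) > 0) paste(e$from, e$to, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  sep <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else "[[:space:]]+"
  parts <- strsplit(lines, sep)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop("malformed edge at line ", bad[1], " of ", path, call. = FALSE)
  }
  from <- trimws(vapply(parts, `[[`, character(1), 1))
  to <- trimws(vapply(parts, `[[`, character(1), 2))
  hdr <- tolower(c(from[1], to[1]))
  if (all(hdr %in% c("from", "to", "source", "target"))) {
    from <- from[-1]; to <- to[-1]
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# Strip thousands separators ("213,122") from count-like columns on read.
parse_count_col <- function(x) {
  as.numeric(gsub(",", "", as.character(x), fixed = TRUE))
}

#' Write and read account tables
#'
#' RFC-4180 CSV with columns `id`, `declared_follower_count`, `tweet_count`,
#' `is_organization`; extra columns (for example a `status` column marking
#' disabled or private accounts) are preserved on round-trip. Thousands
#' separators in count columns are accepted on read and never written.
#' Rows are written in sorted id order.
#'
#' @param accounts data frame of accounts (e.g. `graph$accounts`).
#' @param path file path.
#' @return `write_accounts()` returns `path` invisibly; `read_accounts()`
#'   returns a data frame with `id` as character and counts numeric.
#' @export
write_accounts <- function(accounts, path) {
  accounts <- as.data.frame(accounts)
  accounts <- accounts[order(accounts$id), , drop = FALSE]
  utils::write.csv(accounts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_accounts
#' @export
read_accounts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  if (!"id" %in% names(df)) stop("account table needs an `id` column",
                                 call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate account ids in ", path,
                                 call. = FALSE)
  for (col in intersect(c("declared_follower_count", "tweet_count"), names(df))) {
    df[[col]] <- parse_count_col(df[[col]])
    if (any(is.na(df[[col]])) || any(df[[col]] < 0)) {
      stop("column ", col, " must parse as non-negative numbers", call. = FALSE)
    }
  }
  if ("is_organization" %in% names(df)) {
    df$is_organization <- as.logical(df$is_organization)
  }
  df
}

#' Read a follower network from disk
#'
#' Assembles a [follow_graph()] from an edge-list file and an account table.
#' Rows whose `ignored` flag is set (or whose `status` is disabled, private,
#' or unrecognizable) are excluded from the graph and tallied; the tally is
#' attached as attribute `"cleaning"` (see [data_cleaning_report()]). In
#' strict mode every edge endpoint must appear in the account table; in
#' lenient mode unknown endpoints are auto-registered with zeroed
#' attributes and a message reports how many.
#'
#' @param edge_list_path path to an edge-list file.
#' @param account_table_path path to an account CSV.
#' @param strict logical; error on unknown edge endpoints?
#' @return A [follow_graph()] with a `"cleaning"` attribute.
#' @export
read_network <- function(edge_list_path, account_table_path, strict = TRUE) {
  accounts <- read_accounts(account_table_path)
  cleaning <- data_cleaning_report(accounts)
  if (!is.null(accounts$ignored)) {
    accounts <- accounts[!as.logical(accounts$ignored), , drop = FALSE]
  } else if (!is.null(accounts$status)) {
    drop <- tolower(as.character(accounts$status)) %in%
      c("disabled", "private", "unrecognizable", "ignored")
    accounts <- accounts[!drop, , drop = FALSE]
  }
  edges <- read_edge_list(edge_list_path)
  unknown <- setdiff(unique(c(edges$from, edges$to)), accounts$id)
  if (length(unknown) > 0) {
    if (strict) {
      stop("edge endpoints missing from account table: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    message(length(unknown), " unknown endpoint(s) auto-registered with zeroed attributes")
    extra <- data.frame(id = unknown, declared_follower_count = 0,
                        tweet_count = 0, is_organization = FALSE,
                        stringsAsFactors = FALSE)
    for (col in setdiff(names(accounts), names(extra))) extra[[col]] <- NA
    accounts <- rbind(accounts[names(accounts)],
                      extra[names(accounts)])
  }
  g <- follow_graph(accounts, edges)
  attr(g, "cleaning") <- cleaning
  g
}

#' Write a follower network to disk
#'
#' Inverse of [read_network()]: emits the sorted edge list and account CSV.
#' `read_network(write_network(g))` preserves node count, edge count, and
#' every account attribute.
#'
#' @param graph a [follow_graph()].
#' @param edge_list_path,account_table_path output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_network <- function(graph, edge_list_path, account_table_path) {
  write_edge_list(graph, edge_list_path)
  write_accounts(graph$accounts, account_table_path)
  invisible(c(edge_list_path, account_table_path))
}

#' Export a graph as GraphML
#'
#' Interoperability export (Gephi, Cytoscape, etc.); the edge list remains
#' the canonical format.
#'
#' @param graph a [follow_graph()].
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write and read retweet-record tables
#'
#' CSV with columns `tweet_id`, `org_id`, `retweeter_ids`, the last a
#' comma-separated id list inside one quoted field.
#'
#' @param records list of [retweet_record()]s.
#' @param path file path.
#' @return `write_retweets()` returns `path` invisibly; `read_retweets()`
#'   returns a list of [retweet_record()]s.
#' @export
write_retweets <- function(records, path) {
  df <- data.frame(
    tweet_id = vapply(records, function(r) r$tweet_id, character(1)),
    org_id = vapply(records, function(r) r$org_id, character(1)),
    retweeter_ids = vapply(records, function(r) {
      paste(sort(r$retweeter_ids), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$tweet_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_retweets
#' @export
read_retweets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    ids <- strsplit(df$retweeter_ids[i], ",", fixed = TRUE)[[1]]
    retweet_record(df$tweet_id[i], df$org_id[i], trimws(ids[nzchar(ids)]))
  })
}

#' Export overlap and membership tables
#'
#' Writes two CSVs summarizing follower overlap across organizations: a
#' per-account membership table (one logical column per organization plus
#' the number of groups followed) and a pairwise matrix of
#' [overlap_percentage()] values. Together these are sufficient input for
#' any external network-visualization tool.
#'
#' @param profiles list of at least two [org_profile()]s.
#' @param membership_path,overlap_path output CSV paths.
#' @return Invisibly, a list with the two data frames.
#' @export
export_overlap_tables <- function(profiles, membership_path, overlap_path) {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  org_ids <- vapply(profiles, function(p) p$org_id, character(1))
  all_ids <- sort(unique(unlist(lapply(profiles, function(p) p$follower_ids))))
  membership <- data.frame(account_id = all_ids, stringsAsFactors = FALSE)
  for (i in seq_along(profiles)) {
    membership[[org_ids[i]]] <- all_ids %in% profiles[[i]]$follower_ids
  }
  membership$n_groups <- rowSums(membership[org_ids])
  ov <- matrix(100, length(profiles), length(profiles),
               dimnames = list(org_ids, org_ids))
  for (i in seq_along(profiles)) for (j in seq_along(profiles)) {
    if (i != j) {
      ov[i, j] <- overlap_percentage(profiles[[i]]$follower_ids,
                                     profiles[[j]]$follower_ids)
    }
  }
  utils::write.csv(membership, membership_path, row.names = FALSE)
  utils::write.csv(as.data.frame(ov), overlap_path, row.names = TRUE)
  invisible(list(membership = membership, overlap = as.data.frame(ov)))
}

#' Read a fixture configuration file
#'
#' Parses a YAML file into a [fixture_config()]. Recognized keys mirror the
#' constructor arguments: `n_orgs`, `followers_per_org`,
#' `pairwise_overlap_fraction` (scalar or matrix as list of rows),
#' `follower_degree_law`, `activity_law`, `org_tweet_counts`, `seed`;
#' missing keys take the constructor defaults.
#'
#' @param path path to a YAML file.
#' @return A [fixture_config()].
#' @export
read_fixture_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(fixture_config)))
  if (length(unknown) > 0) {
    stop("unknown fixture-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.list(raw$pairwise_overlap_fraction) &&
      !is.null(raw$n_orgs)) {
    raw$pairwise_overlap_fraction <-
      matrix(unlist(raw$pairwise_overlap_fraction), nrow = raw$n_orgs,
             byrow = TRUE)
  }
  do.call(fixture_config, raw)
}
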