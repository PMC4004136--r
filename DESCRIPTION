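Package: disseminet
Title: Dissemination Potential and Message Diffusion on Directed Follower Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing information dissemination on directed
    follower networks such as Twitter. Implements audience-size metrics
    (followers, Level-2 followers, dissemination potential), follower overlap
    and group cohesion, activity-based pruning of inactive followers,
    per-tweet propagation measurement (retweeter network size and fraction of
    potential), deterministic flood diffusion and seeded independent-cascade
    simulation, and generators for star, random, and power-law (small-world)
    reference topologies plus realistic multi-organization fixtures. Includes
    readers and writers for edge-list, account-table, and retweet-record
    files and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
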