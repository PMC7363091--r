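Package: injurynet
Title: Bipartite Network Analysis of Serious Sports-Injury Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing serious-injury surveillance registries as
    bipartite networks. Cross-tabulates categorical injury records (player
    group by injury type or cause of play), builds weighted bipartite
    graphs from the contingency tables, detects communities by divisive
    edge-betweenness (Girvan-Newman) clustering with modularity-based cut
    selection, scores subgroup cohesion, and computes reproducible
    force-directed (Fruchterman-Reingold) layouts. Ships the printed
    tables of a 14-year Japanese youth-rugby head and spinal-cord injury
    registry as plain-text fixtures, and a synthetic registry generator
    with planted group-by-injury associations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
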