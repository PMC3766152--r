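Package: hgclust
Title: Hospital Grouping from Patient-Origin Utilization Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters health-care facilities into planning regions from
    origin-destination patient-day data and inter-facility travel distances.
    Facilities are described by Commitment Index profiles (the share of a
    facility's patient days drawn from each areal unit) joined with
    max-rescaled travel distances, clustered with a deterministic
    Ward-seeded K-means sweep over all group counts, and the final number
    of groups chosen by an incremental-F candidate heuristic with
    user-configurable decision rules. Includes geographic assignment of new
    facilities to an existing solution, partition comparison statistics
    (pseudo-F, cross-solution agreement, adjusted Rand index), and a
    gravity-model synthetic patient-flow generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    mclust,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
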