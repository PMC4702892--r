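Package: svhotspot
Title: Somatic Structural-Variant Breakpoint Hotspot Detection by
    Permutation Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recurrence analysis of somatic structural-variant
    breakpoints across cancer genome cohorts. Reads per-sample breakpoint
    profiles in a BED dialect, applies read-support, size, matched-normal
    and population-variant (blacklist) filters, and detects breakpoint
    hotspots by extending breakpoints into flanking windows, segmenting
    the genome at window boundaries into unequal bins, scoring each bin
    by the number of distinct samples hitting it, and testing enrichment
    against a permutation null with uniform genome-wide breakpoint
    relocation and Benjamini-Hochberg (or Bonferroni) correction.
    Includes profile-versus-hotspot overlap comparison, cohort summary
    tables, a synthetic-profile simulator with planted hotspot loci and
    germline sharing for ground-truth evaluation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
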