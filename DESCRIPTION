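Package: slabrelease
Title: Intermittent Diffusive Release of Chemicals from Slab Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the diffusion-controlled release of a chemical species
    from a homogeneous slab whose interface alternates between release
    (absorbing boundary) and pause (reflecting boundary) states, as in
    repeated skin contacts with a consumer article. Provides a spectral
    finite-difference solver for the switching-boundary diffusion equation
    on non-uniform grids, a priori lower and upper bounds on the released
    mass, an empirical estimator that needs only the number of contacts and
    the mean contact duration, a finite-thickness correction with bound
    classification, and the Monte-Carlo ensemble pipeline that calibrates
    the empirical envelope function. Includes random schedule generation,
    CSV/JSON input and output, and a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
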