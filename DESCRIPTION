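Package: disksearch
Title: Two-State Active-Particle Search on a Disk with an Absorbing Boundary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates constant-speed active particles with angular diffusion
    (a minimal model of sperm motility) searching a disk with an absorbing
    rim, including two-state protocols in which the persistence length drops
    irreversibly either at an exponentially distributed time or when a given
    radius is first crossed (a model of hyperactivation). Provides the search
    statistics used to judge coverage efficiency (annulus dwell-time
    densities, coverage uniformity, escape times, tangent-correlation
    persistence-length estimation, freely-jointed-chain algebra, outer-rim
    slope fits), closed-form radial-diffusion theory for the small
    persistence-length limit, a conservative finite-volume solver for the
    radial diffusion equation, and a command-line interface for reproducing
    the reference experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
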