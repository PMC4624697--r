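Package: spindlesim
Title: Stochastic Simulation of Motor-Driven Chromosome Congression and
    Bi-Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional agent-based simulator of mitotic chromosome
    congression and bi-orientation in mammalian cells. Microtubules emanate
    from two fixed spindle poles and follow dynamic instability with
    force-dependent catastrophe and rescue; chromosomes are transported by
    polar ejection forces, kinetochore dynein and CENP-E along microtubule
    tracks, and form slot-limited end-on kinetochore attachments with
    slip-bond/catch-bond detachment kinetics. Includes ensemble drivers for
    motor-knockdown phenotypes, microtubule-number and catastrophe-rate
    sweeps, first-passage observables, and closed-form fitting of the
    microtubule population kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
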