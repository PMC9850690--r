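Package: unitfindr
Title: Untargeted Detection of Repeating Chemical Units in High-Resolution Mass Spectra
Version: 0.1.0
Authors@R: person("Dane", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for finding chemically meaningful repeating ("changing")
    units in centroided high-resolution mass spectrometry peak lists.
    Generates a valence-validated molecular formula library for candidate
    repeat units, screens candidates with elemental-ratio, mass and
    double-bond-equivalent filters, and detects repeating units either by a
    local chain search (sequential homologous ladders) or by a global search
    over the multiset of pairwise m/z differences. Includes Kendrick mass
    defect transformation, peak-list data-reduction filters, a deterministic
    synthetic-spectrum generator for testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
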