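Package: opmnull
Title: Biplanar Nulling-Coil Design for OPM-MEG on Printed Circuit Boards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design pipeline for biplanar background-field nulling coils used
    with optically pumped magnetometers (OPM-MEG). Optimizes surface-current
    stream functions on a pair of square planes for target uniform and
    gradient fields, discretizes them into current loops, connects the loops
    into a continuous two-layer printed-circuit-board conducting path,
    predicts coil resistance and efficiency with and without a
    high-permeability shielded room, exports manufacturable Gerber/Excellon
    files, and computes the coil currents that null a measured background
    field from per-coil sensor activations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
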