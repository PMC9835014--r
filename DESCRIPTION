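Package: bladdergr
Title: Constrained-Mixture Simulation of Bladder Micturition, Growth and
    Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the urinary bladder as a spherical constrained-mixture
    membrane. A short-timescale micturition component models filling and
    voiding mechanics (triangular collagen recruitment distributions, a
    neo-Hookean ground matrix, length-tension active smooth-muscle stress and
    a linear urethral pressure-flow resistance). A long-timescale growth and
    remodeling component adapts collagen recruitment, smooth-muscle
    recruitment and smooth-muscle mass in response to partial bladder outlet
    obstruction under three selectable growth hypotheses. Includes a
    calibration pipeline that fits recruitment distributions and passive
    constitutive parameters to biaxial stress-stretch data, estimates void
    stretch via the law of Laplace, and a synthetic-data generator for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
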