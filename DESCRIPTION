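Package: caninebsp
Title: Body Segment Parameters and Inertial Properties of the German Shepherd Dog
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring, packaging and predicting body segment
    parameters (BSPs) of the German Shepherd dog. Implements closed-form and
    voxel-quadrature inertia tensors for five candidate geometric solids,
    compound-pendulum moment-of-inertia inversion including product-of-inertia
    recovery from coplanar skew axes, a transcribed reference parameter set for
    a 17-segment rigid-body model of the German Shepherd, 44 morphometric
    regression equations for predicting segment masses and moments of inertia,
    a whole-dog model builder with JSON/YAML export, and a synthetic cadaver/
    pendulum data generator with known ground truth for validating the entire
    measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
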