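Package: paleomech
Title: Musculoskeletal Biomechanics of Extinct Archosaurs from Bone Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for whole-body and hindlimb musculoskeletal modeling of
    fossil archosaurs. Computes exact rigid-body mass properties of watertight
    triangle meshes by divergence-theorem integration, builds body-segment
    solids from serial octagonal hoops with internal air cavities, fits
    geometric primitives (spheres, cylinders, ellipsoids, planes) to articular
    surfaces to derive anatomical and joint coordinate systems, poses skeletal
    chains by Euler-angle forward kinematics, scans joint range of motion via
    collision and disarticulation proxies, represents 3D muscle-tendon paths
    with via points and wrapping surfaces, computes signed muscle moment arms
    by the tendon-excursion method, estimates body mass allometrically from
    stylopodial circumferences, tests static bipedal feasibility from the
    whole-body centre of mass, and classifies posture (bipedal versus
    quadrupedal) with a pooled-covariance linear discriminant voting harness.
    Includes seeded synthetic-skeleton generators with closed-form ground
    truth, so every stage is testable without fossil scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
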