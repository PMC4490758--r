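Package: rearfootkin
Title: In Vivo Rearfoot Kinematics from Single-Plane Radiographic Bone Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for talocrural and subtalar joint
    kinematics measured by single-plane cineradiography. Provides a synthetic
    study generator (parametric bone meshes, ground-truth stance trajectories,
    rendered projection images, static lateral-radiograph scenes), anatomical
    coordinate-system construction for the tibia, talus and calcaneus,
    silhouette-based 3D-to-2D pose registration, Grood-Suntay joint angle
    decomposition with stance-phase normalization, static alignment measures
    (calcaneal pitch, navicular height change), and the group-level statistical
    battery (pooled t tests with effect sizes, mixed-design ANOVA over stance
    bins, intraclass correlation, Lilliefors-type normality checks).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    generics
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
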