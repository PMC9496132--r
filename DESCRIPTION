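Package: enose
Title: Electronic-Nose Sensor-Array Classification with Swarm-Tuned Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for classifying gas-sensor array (electronic nose) response
    curves, built around the pipeline used for detecting fungal infection in
    fruit: k-point linear smoothing, dead-channel exclusion, a duplicated-sensor
    consistency rule, Mahalanobis-distance outlier removal, six transient-response
    descriptors per channel, PCA/FA/LDA dimensionality reduction, a
    back-propagation neural network classifier, and sparrow search, particle
    swarm and grey wolf metaheuristics for tuning the network's hidden-layer
    sizes. Includes a seeded class-conditioned synthetic curve generator,
    stratified k-fold cross-validation with macro TPR and F1 reporting, CSV/YAML
    serialization for every artifact, and a subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    class,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    MASS,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
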