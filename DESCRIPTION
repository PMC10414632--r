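Package: squatmon
Title: IMU-Based Squat Technique Monitoring and Execution-Error Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring resistance exercise with body-worn inertial
    measurement units (IMUs). Implements the full processing chain for a
    six-sensor squat-monitoring system: quaternion orientation estimation with
    the Mahony complementary filter, gravity compensation yielding
    "microgravity-simulated" (0g) acceleration signals, Butterworth low-pass
    filtering, automatic repetition segmentation from peaks, valleys and zero
    crossings, a 2250-feature time/frequency feature bank (375 per sensor),
    robust scaling and recursive feature elimination, five supervised
    classifiers of execution technique (correct plus five common errors) with
    stratified cross-validation and macro-averaged metrics, paired-sensor
    agreement statistics (Pearson correlation and magnitude squared
    coherence), a simulated real-time monitoring loop with mixed-error
    feedback, and an articulated kinematic squat simulator that generates
    labelled six-sensor trials with ground-truth orientations and repetition
    boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml,
    e1071,
    rpart,
    randomForest,
    nnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
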