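Package: deepens
Title: Deep Ensemble Learning with Pluggable Neural Core Learning Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deep ensemble learning for binary classification on tabular,
    image and minute-level sequential health data. Provides three ensemble
    meta-algorithms over trainable neural core learning units (CLUs): deep
    aggregated learning (bagging with mean-aggregated member probabilities),
    gradient deep-learning boosting (neural regression boosters fitted to
    residuals with per-booster learning rates), and deep stacked
    generalization (level-0 neural classifiers feeding a level-1
    meta-classifier). Includes a compact deterministic neural engine (MLP,
    convolutional, and gated-recurrent-with-attention units with step-decay
    learning-rate scheduling and best-validation-loss checkpointing),
    leakage-free preprocessing chains (mean and time-of-day imputation,
    standard scaling, random-forest feature ranking, image resizing,
    convolutional-autoencoder feature extraction, seven-day moving-window
    sample generation), confusion-matrix metrics including the Matthews
    correlation coefficient and rank-based AUC, repeated-experiment
    summaries, synthetic benchmark-shaped data generators, and a three-phase
    experiment workflow with classical comparators and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ranger,
    randomForest,
    xgboost,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
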