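Package: mealdetectr
Title: Personalized Meal-Event Detection from Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meal events in continuous glucose monitoring (CGM) signals
    from per-individual glucose response patterns. Meal responses observed after
    logged meals are clustered into a small set of archetypal response patterns;
    z-normalized Euclidean distance profiles locate pattern occurrences across
    the signal; a cutoff/valley/temporal-grouping procedure selects candidate
    responses; candidates are featurized and classified Meal versus Non-Meal by
    per-participant model selection with the F2 score; detections are evaluated
    against the event log by margin-based one-to-one matching. Includes a seeded
    synthetic CGM simulator so the full pipeline is testable without access to
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    rpart,
    randomForest,
    nnet,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
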