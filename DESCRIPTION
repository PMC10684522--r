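Package: ventlstm
Title: Ventilator Airway-Pressure Prediction with Metaheuristic-Tuned LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the airway pressure delivered by a mechanical
    ventilator from the valve-control time series of a respiratory circuit.
    Implements a long short-term memory (LSTM) sequence regressor from its gate
    equations with exact backpropagation through time, the Chimp Optimization
    Algorithm (ChoA) together with particle swarm (PSO), grey wolf (GWO) and
    whale (WOA) baselines for hyperparameter search, a single-compartment
    lung-mechanics simulator that emulates the public ventilator-pressure
    dataset schema, respiratory-circuit feature engineering (lung setting
    delta = R*C, cumulative inspiratory-valve opening, inter-sample time and
    valve differences), Spearman and Pearson exploratory correlation summaries,
    and a repeated-run one-way ANOVA protocol for comparing optimizers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
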