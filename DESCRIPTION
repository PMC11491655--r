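Package: fedgap
Title: Simulated Distributed Learning for Retinal Age Prediction from
    Foundation-Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of distributed training of retinal age
    prediction models on foundation-model image embeddings. Generates
    synthetic cohorts of per-eye feature vectors with an age signal, site
    effects and within-subject correlation; trains linear and multilayer
    perceptron regression heads with hand-written analytic gradients and
    an Adam optimizer under centralized, federated (FedAvg) and
    traveling-model protocols with early stopping and a compute/transfer
    cost ledger; provides an analytic parameter/FLOP/quantized-size model
    of a vision-transformer encoder together with 8-bit quantize-dequantize
    emulation of feature vectors; and computes retinal age gap (RAG) group
    statistics with histogram-ratio importance weights and one-tailed
    weighted-bootstrap hypothesis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
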