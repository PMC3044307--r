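Package: GORpred
Title: Information-Theoretic Three-State Protein Secondary Structure
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trainer, predictor and post-processing passes for GOR-style
    three-state (helix/strand/coil) protein secondary structure prediction
    from single sequences.  Directional and pairwise information-difference
    tables are estimated over 17-residue windows from a database of
    sequences with known structure, applied by a streaming window engine
    with lookup instrumentation, smoothed by two scanning correction
    passes, and driven through a three-stage pipeline with parallel
    correction channels.  Includes table segmentation and int32
    quantization of the parameter tables, a binary model format, a
    synthetic Markov-chain sequence generator for end-to-end testing, Q3
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'GORpred-package.R'
    'alphabet.R'
    'io.R'
    'counts.R'
    'tables.R'
    'model-io.R'
    'predict.R'
    'correct.R'
    'pipeline.R'
    'synthetic.R'
    'evaluate.R'
    'cli.R'
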