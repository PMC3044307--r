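# Shared fixture builders.  Everything is generated in code; no data
# files are read from disk.

STATES <- c("H", "E", "C")

# An InformationTables object with every entry zero.
zeroTables <- function() {
  new("InformationTables",
      dir = array(0, dim = c(3, 17, 21)),
      pair = array(0, dim = c(3, 136, 21, 21)),
      quantized = FALSE, scale = NA_real_)
}

# Small i.i.d. normal tables; deterministic given seed.
randomTables <- function(seed = 1, sd = 0.5) {
  set.seed(seed)
  new("InformationTables",
      dir = array(rnorm(3 * 17 * 21, sd = sd), dim = c(3, 17, 21)),
      pair = array(rnorm(3 * 136 * 21 * 21, sd = sd),
                   dim = c(3, 136, 21, 21)),
      quantized = FALSE, scale = NA_real_)
}

# A training record from raw strings.
record <- function(seq, states, id = "rec") {
  list(sequence = encodeSequence(seq, id = id),
       structure = strsplit(states, "")[[1]])
}

# Random sequence of n residues (codes 0..20 via letters), deterministic.
randomSequence <- function(n, seed = 1, id = "rnd") {
  set.seed(seed)
  new("ProteinSequence", id = id,
      codes = sample(0:20, n, replace = TRUE))
}

# Small synthetic train/test split used by several suites.
smallSplit <- function(nTrain = 60, nTest = 30, contrast = 0.8,
                       seedTrain = 42, seedTest = 4242) {
  list(train = generateDataset(generatorConfig(nSequences = nTrain,
                                               contrast = contrast,
                                               seed = seedTrain)),
       test = generateDataset(generatorConfig(nSequences = nTest,
                                              contrast = contrast,
                                              seed = seedTest),
                              prefix = "tst"))
}

# Serial reference path: predict + correct each record, returning
# prediction blocks for datasetQ3().
serialPredict <- function(records, tables, ccfg = correctionConfig()) {
  lapply(records, function(rec) {
    p <- predictSequence(rec$sequence, tables)
    list(id = seqId(rec$sequence),
         states = applyCorrections(p$states, p$probs, ccfg),
         probs = p$probs)
  })
}
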