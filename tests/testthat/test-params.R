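test_that("pairIndex is the lexicographic bijection with a working inverse", {
  expect_identical(pairIndex(0, 1), 0L)
  expect_identical(pairIndex(15, 16), 135L)
  expect_identical(pairIndex(0, 16), 15L)
  seen <- integer(0)
  for (j1 in 0:15) for (j2 in (j1 + 1):16) {
    p <- pairIndex(j1, j2)
    seen <- c(seen, p)
    expect_identical(unname(pairPositions(p)[1, ]), c(j1, j2))
  }
  expect_identical(sort(seen), 0:135)
  expect_error(pairIndex(3, 3))
  expect_error(pairIndex(5, 2))
  expect_error(pairIndex(0, 17))
  expect_error(pairPositions(136))
})

test_that("a lone residue contributes full padding counts", {
  counts <- accumulateCounts(list(record("A", "H")))
  expect_identical(unname(stateTotals(counts)), c(1, 0, 0))
  singlet <- counts@singlet
  expect_identical(singlet[1, 9, 1], 1)      # center offset holds code 0 ('A')
  for (m in setdiff(1:17, 9))
    expect_identical(singlet[1, m, 21], 1)   # all other offsets read 'X'
  # one increment per pair index: 136 in total, all involving the pad or center
  expect_identical(sum(counts@pair[1, , , ]), 136)
})

test_that("counts satisfy the per-offset and per-pair conservation laws and additivity", {
  set.seed(21)
  recs <- generateDataset(generatorConfig(nSequences = 4, meanLength = 30,
                                          seed = 13))
  counts <- accumulateCounts(recs)
  nTot <- sum(sapply(recs, function(r) length(r$sequence)))
  expect_equal(sum(stateTotals(counts)), nTot)
  for (s in 1:3) {
    ns <- unname(stateTotals(counts)[s])
    for (m in c(1, 9, 17))
      expect_identical(sum(counts@singlet[s, m, ]), ns)
    for (p in c(1, 68, 136))
      expect_identical(sum(counts@pair[s, p, , ]), ns)
  }
  # additivity: counts over a concatenated db equal the sum of the parts
  c1 <- accumulateCounts(recs[1:2])
  c2 <- accumulateCounts(recs[3:4])
  expect_equal(counts@singlet, c1@singlet + c2@singlet)
  expect_equal(counts@pair, c1@pair + c2@pair)
  expect_error(accumulateCounts(list()), "empty")
})

test_that("symmetric evidence between a state and its complement carries zero information", {
  # identical counts for H and for the pooled others, equal totals
  counts <- accumulateCounts(list(record("A", "H")))
  counts@singlet[2, , ] <- counts@singlet[1, , ]
  counts@singlet[3, , ] <- 0
  counts@pair[2, , , ] <- counts@pair[1, , , ]
  counts@pair[3, , , ] <- 0
  counts@nState <- c(H = 1, E = 1, C = 0)
  tables <- countsToInformation(counts)
  expect_true(all(dirInformation(tables)[1, , ] == 0))
  expect_true(all(pairInformation(tables)[1, , , ] == 0))
})

test_that("a 2:1 count ratio with equal class totals approaches ln 2 as smoothing vanishes", {
  k <- 1000
  counts <- accumulateCounts(list(record("A", "H")))
  counts@singlet[1, , ] <- 2 * k
  counts@singlet[2, , ] <- k
  counts@singlet[3, , ] <- 0
  counts@pair[1, , , ] <- 2 * k
  counts@pair[2, , , ] <- k
  counts@pair[3, , , ] <- 0
  counts@nState <- c(H = 1, E = 1, C = 0) * k
  tables <- countsToInformation(counts, pseudocount = 1e-9)
  expect_equal(dirInformation(tables)[1, 5, 7], log(2), tolerance = 1e-8)
  expect_equal(pairInformation(tables)[1, 70, 3, 12], log(2), tolerance = 1e-8)
})

test_that("zero counts stay finite under default smoothing", {
  counts <- accumulateCounts(list(record("ACDEFGHIKLMNPQRSTVWY", paste(rep("H", 20), collapse = ""))))
  tables <- countsToInformation(counts)  # E and C never observed
  expect_true(all(is.finite(dirInformation(tables))))
  expect_true(all(is.finite(pairInformation(tables))))
  expect_error(countsToInformation(counts, pseudocount = 0), "positive")
})

test_that("swapping a state with its complement negates every entry", {
  set.seed(31)
  for (i in 1:5) {
    a <- array(rpois(3 * 17 * 21, 5), dim = c(3, 17, 21))
    ap <- array(rpois(3 * 136 * 21 * 21, 5), dim = c(3, 136, 21, 21))
    base <- accumulateCounts(list(record("A", "H")))
    # put all complement mass in E so H-vs-notH and E-vs-notE are mirrors
    base@singlet[1, , ] <- a[1, , ]
    base@singlet[2, , ] <- a[2, , ]
    base@singlet[3, , ] <- 0
    base@pair[1, , , ] <- ap[1, , , ]
    base@pair[2, , , ] <- ap[2, , , ]
    base@pair[3, , , ] <- 0
    base@nState <- c(H = 100, E = 100, C = 0)
    swapped <- base
    swapped@singlet[1, , ] <- base@singlet[2, , ]
    swapped@singlet[2, , ] <- base@singlet[1, , ]
    swapped@pair[1, , , ] <- base@pair[2, , , ]
    swapped@pair[2, , , ] <- base@pair[1, , , ]
    t1 <- countsToInformation(base)
    t2 <- countsToInformation(swapped)
    expect_equal(dirInformation(t2)[1, , ], -dirInformation(t1)[1, , ])
    expect_equal(pairInformation(t2)[1, , , ], -pairInformation(t1)[1, , , ])
  }
})

test_that("quantization stores round-to-nearest int32 within the error bound", {
  tables <- randomTables(8, sd = 1)
  tables@dir[1, 1, 1] <- 1.0
  qt <- quantizeTables(tables, scale = 65536)
  expect_true(isQuantized(qt))
  expect_identical(quantScale(qt), 65536)
  expect_identical(dirInformation(qt)[1, 1, 1], 65536L)
  expect_true(max(abs(dirInformation(qt) / 65536 - dirInformation(tables))) <= 0.5 / 65536)
  expect_true(max(abs(pairInformation(qt) / 65536 - pairInformation(tables))) <= 0.5 / 65536)
  back <- dequantizeTables(qt)
  expect_false(isQuantized(back))
  # overflow is reported with the offending magnitude
  big <- tables
  big@pair[2, 3, 4, 5] <- 1e6
  expect_error(quantizeTables(big, scale = 65536), "overflow")
  expect_error(quantizeTables(qt), "already quantized")
})

test_that("rounding is half-away-from-zero", {
  tables <- zeroTables()
  tables@dir[1, 1, 1] <- 1.5
  tables@dir[2, 1, 1] <- -1.5
  tables@dir[3, 1, 1] <- 2.5
  qt <- quantizeTables(tables, scale = 1)
  expect_identical(dirInformation(qt)[1, 1, 1], 2L)
  expect_identical(dirInformation(qt)[2, 1, 1], -2L)
  expect_identical(dirInformation(qt)[3, 1, 1], 3L)
})

test_that("segmentation yields 136 exact, independently addressable parts", {
  tables <- randomTables(9)
  seg <- segmentPairTable(tables)
  expect_length(seg@segments, 136L)
  expect_identical(unname(fetchSegment(seg, 0, 20, 20)),
                   pairInformation(tables)[, 1, 21, 21])
  expect_identical(unname(fetchSegment(seg, 135, 0, 7)),
                   pairInformation(tables)[, 136, 1, 8])
  back <- reassembleTables(seg)
  expect_identical(pairInformation(back), pairInformation(tables))
  expect_identical(dirInformation(back), dirInformation(tables))
  expect_error(fetchSegment(seg, 136, 0, 0))
})

test_that("the per-state pairwise table occupies 468 KB at double precision", {
  tables <- zeroTables()
  expect_identical(pairTableBytes(tables), 21L * 21L * 136L * 8L)
  expect_identical(pairTableBytes(tables), 479808L)
  expect_identical(pairTableBytes(tables) %/% 1024L, 468L)
  expect_identical(pairTableBytes(tables, perState = FALSE),
                   3L * pairTableBytes(tables))
})

test_that("model files round-trip bit-exactly and fail loudly when damaged", {
  for (quant in c(FALSE, TRUE)) {
    tables <- randomTables(10)
    if (quant) tables <- quantizeTables(tables)
    path <- withr::local_tempfile(fileext = ".gor4")
    saveModel(tables, path)
    back <- loadModel(path)
    expect_identical(dirInformation(back), dirInformation(tables))
    expect_identical(pairInformation(back), pairInformation(tables))
    expect_identical(isQuantized(back), quant)
    if (quant) expect_identical(quantScale(back), quantScale(tables))
  }

  path <- withr::local_tempfile(fileext = ".gor4")
  saveModel(randomTables(11), path)
  full <- readBin(path, "raw", n = file.size(path))

  trunc <- withr::local_tempfile(fileext = ".gor4")
  writeBin(full[1:5000], trunc)
  expect_error(loadModel(trunc), "unexpected end of model file")

  bad <- withr::local_tempfile(fileext = ".gor4")
  corrupt <- full; corrupt[1] <- as.raw(0x58)
  writeBin(corrupt, bad)
  expect_error(loadModel(bad), "bad magic")

  vers <- withr::local_tempfile(fileext = ".gor4")
  bumped <- full; bumped[9] <- as.raw(9)  # little-endian version field
  writeBin(bumped, vers)
  expect_error(loadModel(vers), "version 9 not supported.*version 1")
})
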