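test_that("extractWindow pads beyond the sequence ends with the boundary code", {
  s1 <- encodeSequence("A", id = "one")
  expect_identical(extractWindow(s1, 0), c(rep(20L, 8), 0L, rep(20L, 8)))

  s17 <- randomSequence(17, seed = 2)
  expect_identical(extractWindow(s17, 8), residueCodes(s17))

  s10 <- randomSequence(10, seed = 3)
  expect_identical(extractWindow(s10, 9),
                   c(residueCodes(s10)[2:10], rep(20L, 8)))

  expect_error(extractWindow(s10, 10), "out of range")
  expect_error(extractWindow(s10, -1), "out of range")
})

test_that("informationSum isolates single table entries with the documented weights", {
  win <- extractWindow(randomSequence(17, seed = 4), 8)
  expect_identical(informationSum(win, zeroTables(), "H"), 0)

  v <- 1.7
  dirOnly <- zeroTables()
  dirOnly@dir[1, 9, win[9] + 1] <- v
  expect_equal(informationSum(win, dirOnly, "H"), -(15 / 17) * v)
  expect_identical(informationSum(win, dirOnly, "E"), 0)

  pairOnly <- zeroTables()
  p <- pairIndex(2, 11)
  pairOnly@pair[2, p + 1, win[3] + 1, win[12] + 1] <- v
  expect_equal(informationSum(win, pairOnly, "E"), (2 / 17) * v)
})

test_that("normalizeInformation is a shift-invariant softmax", {
  expect_equal(unname(normalizeInformation(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(unname(normalizeInformation(5.5, 5.5, 5.5)), rep(1 / 3, 3))
  expect_equal(unname(normalizeInformation(log(2), 0, 0)),
               c(0.5, 0.25, 0.25))
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(3, sd = 10)
    p <- normalizeInformation(x[1], x[2], x[3])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    # shift invariance
    c0 <- rnorm(1, sd = 100)
    expect_equal(p, normalizeInformation(x[1] + c0, x[2] + c0, x[3] + c0),
                 tolerance = 1e-9)
    # permutation equivariance
    perm <- sample(3)
    expect_equal(unname(normalizeInformation(x[perm[1]], x[perm[2]], x[perm[3]])),
                 unname(p)[perm], tolerance = 1e-12)
  }
  # extreme inputs do not overflow
  expect_equal(unname(normalizeInformation(1e4, 0, -1e4)), c(1, 0, 0))
  expect_error(normalizeInformation(Inf, 0, 0), "finite")
})

test_that("pH increases strictly with I_H when the other sums are fixed", {
  base <- c(-2, 0.3, 1.1)
  prev <- -1
  for (iH in seq(-3, 3, by = 0.5)) {
    p <- normalizeInformation(iH, base[2], base[3])
    expect_gt(p[["H"]], prev)
    prev <- p[["H"]]
  }
})

test_that("selectState takes the argmax with H > E > C tie priority", {
  expect_identical(selectState(c(0.5, 0.25, 0.25)), "H")
  expect_identical(selectState(c(1, 1, 1) / 3), "H")
  expect_identical(selectState(c(0.2, 0.4, 0.4)), "E")
  expect_identical(selectState(c(0.1, 0.2, 0.7)), "C")
})

test_that("zero tables give uniform probabilities and all-H states", {
  seq <- randomSequence(30, seed = 6)
  pred <- predictSequence(seq, zeroTables())
  expect_true(all(abs(pred$probs - 1 / 3) < 1e-15))
  expect_true(all(pred$states == "H"))
  expect_error(predictSequence(encodeSequence("A"), zeroTables(),
                               stats = "not stats"), "newLookupStats")
})

test_that("the streaming engine issues exactly 272 pair and 17 dir reads per residue", {
  tables <- randomTables(12)
  for (n in c(1, 9, 200)) {
    stats <- newLookupStats()
    predictSequence(randomSequence(n, seed = n), tables, stats = stats)
    expect_identical(stats$pair_reads, 272 * n)
    expect_identical(stats$dir_reads, 17 * n)
    expect_identical(stats$residues_processed, n)
  }
  # counters are cumulative across runs
  stats <- newLookupStats()
  predictSequence(randomSequence(10, seed = 1), tables, stats = stats)
  predictSequence(randomSequence(5, seed = 2), tables, stats = stats)
  expect_identical(stats$pair_reads, 272 * 15)
})

test_that("streaming (ordered-pair) and naive (unordered-pair) engines agree to 1e-12", {
  worst <- 0
  for (i in 1:10) {
    tables <- randomTables(100 + i, sd = 1)
    for (j in 1:2) {
      seq <- randomSequence(20, seed = 1000 * i + j)
      a <- predictSequence(seq, tables, engine = "streaming")
      b <- predictSequence(seq, tables, engine = "naive")
      worst <- max(worst, max(abs(a$probs - b$probs)))
      expect_identical(a$states, b$states)
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("per-residue probabilities match the window-by-window reference path", {
  tables <- randomTables(14)
  seq <- randomSequence(12, seed = 15)
  pred <- predictSequence(seq, tables)
  for (t in c(0, 5, 11)) {
    win <- extractWindow(seq, t)
    ref <- normalizeInformation(informationSum(win, tables, "H"),
                                informationSum(win, tables, "E"),
                                informationSum(win, tables, "C"))
    expect_equal(unname(pred$probs[t + 1, ]), unname(ref), tolerance = 1e-12)
    expect_identical(pred$states[t + 1], selectState(ref))
  }
})

test_that("residues outside the 17-residue window cannot affect a prediction", {
  tables <- randomTables(16)
  seq1 <- randomSequence(40, seed = 17)
  codes2 <- residueCodes(seq1)
  codes2[30] <- (codes2[30] + 1L) %% 21L  # 21 positions right of center 9
  seq2 <- new("ProteinSequence", id = "mut", codes = codes2)
  p1 <- predictSequence(seq1, tables)
  p2 <- predictSequence(seq2, tables)
  expect_equal(p1$probs[9, ], p2$probs[9, ], tolerance = 0)
})
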