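test_that("smilesToGraph builds correct graphs for known molecules", {
  g <- smilesToGraph("C")
  expect_equal(numNodes(g), 1)
  expect_equal(nrow(edgeList(g)), 0)
  expect_equal(ncol(nodeFeatures(g)), 78)

  g <- smilesToGraph("CC")
  expect_equal(numNodes(g), 2)
  expect_equal(nrow(edgeList(g)), 1)

  g <- smilesToGraph("c1ccccc1")
  expect_equal(numNodes(g), 6)
  expect_equal(nrow(edgeList(g)), 6)
  expect_equal(unname(nodeFeatures(g)[, 78]), rep(1, 6))

  # cyclohexane is not aromatic
  g <- smilesToGraph("C1CCCCC1")
  expect_equal(unname(nodeFeatures(g)[, 78]), rep(0, 6))
})

test_that("atom feature rows have valid one-hot block structure", {
  mols <- c("CC(=O)O", "c1ccncc1", "CC(C)(C)C", "C[NH3+]", "CC(=O)[O-]",
            "ClCCl", "O=S(=O)(O)O")
  for (s in mols) {
    f <- nodeFeatures(smilesToGraph(s))
    expect_equal(ncol(f), 78)
    expect_true(all(f %in% c(0, 1)))
    expect_true(all(rowSums(f[, 1:44, drop = FALSE]) == 1))
    for (block in list(45:55, 56:66, 67:77)) {
      expect_true(all(rowSums(f[, block, drop = FALSE]) == 1))
    }
  }
})

test_that("hydrogen counts follow standard valence rules", {
  f <- nodeFeatures(smilesToGraph("C"))
  expect_equal(which(f[1, 56:66] == 1) - 1, 4)  # methane: 4 H
  f <- nodeFeatures(smilesToGraph("CO"))
  expect_equal(which(f[2, 56:66] == 1) - 1, 1)  # hydroxyl O: 1 H
  # charged: ammonium N carries 4 bonds worth of valence
  f <- nodeFeatures(smilesToGraph("C[NH3+]"))
  expect_equal(which(f[2, 56:66] == 1) - 1, 3)
})

test_that("unparsable and empty SMILES raise informative errors", {
  expect_error(smilesToGraph("zz((["), "unparsable SMILES.*zz")
  expect_error(smilesToGraph(""), "non-empty")
  expect_error(smilesToGraph(c("C", "CC")), "single")
})

test_that("distance maps reproduce hand-computed geometry", {
  tmp <- tempfile(fileext = ".pdb")
  coords <- rbind(c(0, 0, 0), c(3, 4, 0))
  writeCaPdb(coords, "AG", tmp)
  d <- pdbToDistanceMap(tmp)
  expect_equal(unname(d[1, 2]), 5.0, tolerance = 1e-6)
  expect_equal(unname(diag(d)), c(0, 0))

  coords3 <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  writeCaPdb(coords3, "AGV", tmp)
  d3 <- pdbToDistanceMap(tmp)
  expect_equal(sort(unname(d3[upper.tri(d3)])), c(6, 6, 12))
  expect_equal(attr(d3, "resid"), c("A", "G", "V"))
})

test_that("residues without a Calpha are skipped with a warning", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   GLY A   2       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  VAL A   3       3.000   4.000   0.000  1.00  0.00",
    "END"
  ), tmp)
  expect_warning(d <- pdbToDistanceMap(tmp), "without a Calpha")
  expect_equal(nrow(d), 2)
  expect_equal(attr(d, "resno"), c(1, 3))  # index gap recorded
  expect_equal(unname(d[1, 2]), 5.0, tolerance = 1e-6)
})

test_that("distance maps are invariant to rigid-body motion", {
  set.seed(7)
  coords <- matrix(rnorm(30), 10, 3)
  # random rotation via QR of a random matrix
  qr <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr)
  moved <- coords %*% R + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  d1 <- as.matrix(dist(coords))
  d2 <- as.matrix(dist(moved))
  expect_lt(max(abs(d1 - d2)), 1e-6)
})

test_that("contact map thresholding is strict and symmetric", {
  d <- rbind(c(0, 5, 12), c(5, 0, 8), c(12, 8, 0))
  cm <- distanceMapToContactMap(d, 8)
  m <- contactMatrix(cm)
  expect_equal(m[1, 2], 1)  # 5 < 8
  expect_equal(m[1, 3], 0)  # 12 >= 8
  expect_equal(m[2, 3], 0)  # 8 is not < 8 (strict)
  expect_equal(m, t(m))

  # threshold 0: no contacts at positive distances
  cm0 <- distanceMapToContactMap(d, 0)
  expect_equal(sum(contactMatrix(cm0)), 0)

  # collinear 3-residue toy: exactly the two 6 A pairs
  d3 <- as.matrix(dist(cbind(c(0, 6, 12), 0, 0)))
  cm3 <- distanceMapToContactMap(d3, 8)
  expect_equal(sum(contactMatrix(cm3)[upper.tri(d3)]), 2)

  expect_error(distanceMapToContactMap(matrix(1, 2, 3)), "square")
})

test_that("contact maps are nested across increasing thresholds", {
  set.seed(11)
  for (rep in 1:5) {
    coords <- matrix(cumsum(rnorm(20 * 3, sd = 2)), 20, 3)
    d <- as.matrix(dist(coords))
    prev <- NULL
    for (t in c(6, 8, 10)) {
      m <- contactMatrix(distanceMapToContactMap(d, t))
      if (!is.null(prev)) expect_true(all(m >= prev))
      prev <- m
    }
  }
})

test_that("PPM matches the count-and-divide formula", {
  # single sequence, no pseudocount: M[A,1] = 1 / (4 * 1)
  p <- computePPM("A", pseudocount = 0)
  expect_equal(unname(ppmMatrix(p)["A", 1]), 0.25)
  expect_equal(sum(ppmMatrix(p)[-1, 1]), 0)

  # N identical sequences: N / (4N) = 0.25 at the observed residue
  p <- computePPM(rep("ACD", 8), pseudocount = 0)
  expect_equal(unname(ppmMatrix(p)["A", 1]), 0.25)
  expect_equal(unname(ppmMatrix(p)["C", 2]), 0.25)

  # huge pseudocount dominates: all entries -> 1
  p <- computePPM(c("AC", "AD"), pseudocount = 1e9)
  expect_true(all(ppmMatrix(p) > 0.99))

  # brute-force oracle on random alignments, 1e-12
  set.seed(3)
  aa <- RESIDUE_ALPHABET[1:20]
  for (rep in 1:10) {
    N <- sample(2:6, 1); K <- sample(3:8, 1)
    seqs <- vapply(
      seq_len(N),
      function(i) paste(sample(c(aa, "-"), K, replace = TRUE),
                        collapse = ""),
      character(1)
    )
    pc <- runif(1, 0, 2)
    M <- ppmMatrix(computePPM(seqs, pseudocount = pc))
    chars <- do.call(rbind, strsplit(seqs, ""))
    worst <- 0
    for (k in seq_len(K)) {
      for (r in seq_len(21)) {
        cnt <- sum(chars[, k] == RESIDUE_ALPHABET[r])
        worst <- max(worst, abs(M[r, k] - (cnt + pc) / (4 * N + pc)))
      }
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("PPM rejects bad input and supports alternate denominators", {
  expect_error(computePPM(character(0)), "empty")
  expect_error(computePPM(c("AC", "A")), "ragged")
  expect_error(computePPM("AC", pseudocount = -1), "pseudocount")
  # 20N + p denominator selectable
  p <- computePPM("A", pseudocount = 0, alphabetSize = 20)
  expect_equal(unname(ppmMatrix(p)["A", 1]), 1 / 20)
  # gaps are not counted in the frequency matrix
  p <- computePPM(c("A-", "AC"), pseudocount = 0)
  expect_equal(unname(colSums(ppmMatrix(p))), c(2 / 8, 1 / 8))
})

test_that("residue features have the documented 54-column layout", {
  f <- residueFeatures("A")
  expect_equal(dim(f), c(1, 54))
  expect_equal(f[1, 1], 1)                      # alanine one-hot
  expect_equal(f[1, 43], 1)                     # aliphatic flag
  expect_equal(f[1, 44], 0)                     # not aromatic
  expect_equal(f[1, 48], 89.09)                 # weight (Da)

  sq <- "ARNDCQEGHILKMFPSTWYV"
  f <- residueFeatures(sq)
  expect_equal(dim(f), c(20, 54))
  expect_true(all(rowSums(f[, 1:21]) == 1))
  expect_equal(which(f[2, 1:21] == 1), 2)       # R in slot 2
  # ppm block is that position's column
  ppm <- computePPM(sq)
  for (i in c(1, 5, 20)) {
    expect_equal(unname(f[i, 22:42]), unname(ppmMatrix(ppm)[, i]))
  }
  expect_true(all(f[, 22:42] >= 0 & f[, 22:42] <= 1))
})

test_that("unknown residues map to the 21st class with a warning", {
  expect_warning(f <- residueFeatures("ABZ"), "unknown residue")
  expect_equal(which(f[2, 1:21] == 1), 21)
  expect_equal(which(f[3, 1:21] == 1), 21)
})

test_that("contactMapToGraph applies the backbone-edge rule", {
  feats <- residueFeatures("ACDE")
  # identity-only map: chain graph (backbone only)
  empty <- distanceMapToContactMap(matrix(100, 4, 4) - diag(100, 4), 8)
  g <- contactMapToGraph(empty, feats)
  expect_equal(nrow(edgeList(g)), 3)
  expect_equal(edgeList(g), cbind(1:3, 2:4), ignore_attr = TRUE)

  # fully contacting 4-residue map: complete graph
  fullM <- matrix(1, 4, 4); diag(fullM) <- 0
  fullCm <- distanceMapToContactMap(matrix(0.1, 4, 4), 8)
  g <- contactMapToGraph(fullCm, feats)
  expect_equal(nrow(edgeList(g)), 6)

  # collinear 3-residue toy: path graph with 2 edges
  d3 <- as.matrix(dist(cbind(c(0, 6, 12), 0, 0)))
  g3 <- contactMapToGraph(
    distanceMapToContactMap(d3, 8), residueFeatures("ACD")
  )
  expect_equal(nrow(edgeList(g3)), 2)

  expect_error(contactMapToGraph(empty, feats[1:3, ]), "does not match")
})

test_that("proteinToGraph runs the full structure pipeline", {
  set.seed(21)
  ds <- generateSyntheticDtiset(nDrugs = 4, nTargets = 4, seed = 4,
                                pdbDir = tempfile("pdb"))
  tg <- ds$targets[[1]]
  g <- proteinToGraph(tg$pdb, sequence = tg$sequence)
  expect_s4_class(g, "MolecularGraph")
  expect_equal(graphKind(g), "protein")
  expect_equal(numNodes(g), nchar(tg$sequence))
  expect_equal(ncol(nodeFeatures(g)), 54)
})
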