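# Ratiometric scores: shared-partner and control-bait modes, Welch
# significance, differential profiles and clustering.

test_that("shared-partner ratios subtract the best shared random pair", {
  pairs <- psFromMatrix(matrix(5, 1, 3), bait = "A", prey = "B")
  rnd <- psFromMatrix(matrix(rep(c(3, 4, 4.8), each = 3), 3, 3,
                             byrow = TRUE,
                             dimnames = list(c("A.X", "Y.B", "C.D"), NULL)),
                      bait = c("A", "Y", "C"), prey = c("X", "B", "D"))
  r <- sharedPartnerRatio(pairs, rnd)
  # only A.X and Y.B share a partner with A-B; max control is 4
  expect_equal(r$log2_ratio, 1)
  expect_identical(r$n_controls, 2L)
  # a pair equal to its best control scores zero
  pairs0 <- psFromMatrix(matrix(4, 1, 3), bait = "A", prey = "B")
  expect_equal(sharedPartnerRatio(pairs0, rnd)$log2_ratio, 0)
})

test_that("excluded pairs never serve as controls but are still scored", {
  pairs <- psFromMatrix(matrix(rep(c(5, 6), each = 2), 2, 2, byrow = TRUE,
                               dimnames = list(c("A.B", "C.X"), NULL)),
                        bait = c("A", "C"), prey = c("B", "X"))
  rnd <- psFromMatrix(matrix(rep(c(4.5, 3), each = 2), 2, 2, byrow = TRUE,
                             dimnames = list(c("A.X", "B.Y"), NULL)),
                      bait = c("A", "B"), prey = c("X", "Y"))
  # excluding A|X removes the strongest control of A-B and every control of
  # C-X; C-X is dropped with a warning naming it
  expect_warning(r <- sharedPartnerRatio(pairs, rnd,
                                         exclusions = pairKey("A", "X")),
                 "C\\|X")
  expect_identical(r$pair_id, "A|B")
  expect_equal(r$log2_ratio, 5 - 3)
})

test_that("shared-partner scores are monotone in the pair and antitone in controls", {
  set.seed(7)
  rndM <- matrix(rnorm(9, 2), 3, 3,
                 dimnames = list(c("A.X", "B.Y", "A.Z"), NULL))
  rnd <- psFromMatrix(rndM, bait = c("A", "B", "A"), prey = c("X", "Y", "Z"))
  at <- function(v, rset = rnd)
    sharedPartnerRatio(psFromMatrix(matrix(v, 1, 3), "A", "B"),
                       rset)$log2_ratio
  expect_true(at(5) < at(6))
  rndHi <- psFromMatrix(rndM + 1, bait = c("A", "B", "A"),
                        prey = c("X", "Y", "Z"))
  expect_true(at(5, rndHi) < at(5))
})

test_that("control-bait ratios take the max over controls and flag censored pairs", {
  mat <- rbind("T.p1" = rep(6, 3), "C1.p1" = rep(4, 3), "C2.p1" = rep(5.5, 3))
  ps <- psFromMatrix(mat, bait = c("T", "C1", "C2"), prey = "p1")
  r <- controlBaitRatio(ps, "T", c("C1", "C2"))
  expect_equal(r$log2_ratio, 0.5)
  expect_identical(r$n_controls, 2L)
  expect_equal(controlBaitRatio(ps, "T", c("C1", "C2"),
                                aggregate = "mean")$log2_ratio, 6 - 4.75)
  expect_error(controlBaitRatio(ps, "T", character()), "empty")
  # target and all controls at the detection limit: uninformative, ratio 0
  cen <- matrix(TRUE, 3, 3, dimnames = list(rownames(mat), NULL))
  psC <- psFromMatrix(matrix(-4, 3, 3, dimnames = dimnames(cen)),
                      bait = c("T", "C1", "C2"), prey = "p1",
                      censored = cen, detLimit = -4)
  rC <- controlBaitRatio(psC, "T", c("C1", "C2"))
  expect_equal(rC$log2_ratio, 0)
  expect_true(rC$uninformative)
})

test_that("removing a control bait never decreases any ratio", {
  set.seed(8)
  preys <- sprintf("p%d", 1:10)
  mk <- function(b, mu) {
    m <- matrix(rnorm(30, mu), 10, 3,
                dimnames = list(paste(b, preys, sep = "."), NULL))
    psFromMatrix(m, bait = b, prey = preys)
  }
  ps <- do.call(rbind, list(mk("T", 3), mk("C1", 1), mk("C2", 1.5)))
  full <- controlBaitRatio(ps, "T", c("C1", "C2"))
  fewer <- controlBaitRatio(ps, "T", "C1")
  expect_true(all(fewer$log2_ratio >= full$log2_ratio - 1e-12))
})

test_that("background-only preys in a multi-bait screen score near zero", {
  s <- smallScreenSim(nPrey = 25, baits = c("B1", "B2"), seed = 44,
                      noiseSd = 0.1)
  ps <- normalizeScreen(s$sim@measurements, s$sim@strainMap)
  r <- controlBaitRatio(ps, "B1", "B2")
  # no true interactions anywhere: every ratio is noise around zero
  expect_true(all(abs(r$log2_ratio) < 6 * 0.1 + 0.5))
  expect_equal(median(r$log2_ratio), 0, tolerance = 0.2)
})

test_that("Welch significance handles degenerate and standard cases", {
  expect_equal(ratioSignificance(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_true(ratioSignificance(c(5, 5.001, 4.999), c(0, 0.001, -0.001)) <
                0.01)
  expect_true(is.na(ratioSignificance(5, c(1, 2, 3))))
  # oracle: stats::t.test Welch p-value
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(5, 1); y <- rnorm(7)
    expect_equal(ratioSignificance(x, y),
                 stats::t.test(x, y)$p.value, tolerance = 1e-12)
  }
})

test_that("Welch p-values agree with a permutation oracle within Monte-Carlo error", {
  set.seed(10)
  devs <- vapply(1:20, function(i) {
    x <- rnorm(10, sample(c(0, 0.5, 1), 1))
    y <- rnorm(10)
    abs(ratioSignificance(x, y) - oraclePermutationP(x, y))
  }, numeric(1))
  expect_true(mean(devs) < 0.05)
  expect_true(max(devs) < 0.15)
})

test_that("differential profiles recover planted perturbations", {
  preys <- sprintf("p%d", 1:6)
  base <- matrix(rep(c(8, 7, 6, 5, 4, 3), 4), 6, 4,
                 dimnames = list(paste0("WT.", preys), NULL))
  wt <- psFromMatrix(base, bait = "WT", prey = preys)
  # mutant identical to WT: all log2FC zero
  mutSame <- psFromMatrix(base, bait = "M0", prey = preys)
  prof0 <- differentialProfile(wt, list(M0 = mutSame))
  expect_equal(unname(prof0$log2fc[, "M0"]), rep(0, 6))
  # a 2-fold decrease for p2: log2FC exactly -1
  m1 <- base; m1[2, ] <- m1[2, ] - 1
  rownames(m1) <- paste0("M1.", preys)
  prof1 <- differentialProfile(wt, list(M1 = psFromMatrix(m1, "M1", preys)))
  expect_equal(unname(prof1$log2fc[, "M1"]),
               c(0, -1, 0, 0, 0, 0))
  # prey missing from WT is dropped with a warning
  m2 <- rbind(m1, "M1.extra" = rep(1, 4))
  expect_warning(
    prof2 <- differentialProfile(
      wt, list(M1 = psFromMatrix(m2, "M1", c(preys, "extra")))),
    "extra")
  expect_false("extra" %in% rownames(prof2$log2fc))
})

test_that("profile clustering merges identical rows at height zero and ignores row order", {
  m <- rbind(a = c(1, 0, 2), b = c(1, 0, 2), c = c(-3, 4, 0))
  cl <- clusterProfiles(m)
  expect_equal(min(cl$rows$height), 0)
  first <- cl$rows$merge[1, ]
  expect_setequal(cl$rows$labels[-first], c("a", "b"))
  # permuting rows leaves memberships unchanged
  cl2 <- clusterProfiles(m[c(3, 1, 2), ])
  k1 <- cutree(cl$rows, 2)
  k2 <- cutree(cl2$rows, 2)[names(k1)]
  expect_true(all((k1 == k1[1]) == (k2 == k2[1])))
  # degenerate single-row matrix: trivial dendrogram
  cl3 <- clusterProfiles(m[1, , drop = FALSE])
  expect_null(cl3$rows)
  expect_identical(cl3$row_order, "a")
  # Newick export is parseable and holds all leaves
  tr <- ape::read.tree(text = cl$newick_rows)
  expect_setequal(tr$tip.label, rownames(m))
})
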