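# Background subtraction, density correction, plate regression and
# replicate aggregation.

mkRec <- function(well, strain, value, channel = "luminescence",
                  plate = "p1", rep = "r1") {
  data.frame(plate_id = plate, replicate_id = rep, well = well,
             strain_id = strain, channel = channel, value = value,
             stringsAsFactors = FALSE)
}

test_that("background subtraction uses the blank median and censors at the floor", {
  rec <- rbind(mkRec("A01", "s1", 1000), mkRec("A02", "s2", 180),
               mkRec("P01", "BLANK", 98), mkRec("P02", "BLANK", 100),
               mkRec("P03", "BLANK", 102))
  out <- subtractBackground(rec)
  expect_equal(out$value[out$strain_id == "s1"], 900)
  floor <- 3 * mad(c(98, 100, 102))
  # 180 - 100 = 80 exceeds the floor; a weaker well is censored to the floor
  expect_false(out$below_detection[out$strain_id == "s2"])
  rec2 <- rbind(rec, mkRec("A03", "s3", 100 + floor / 2))
  out2 <- subtractBackground(rec2)
  expect_true(out2$below_detection[out2$strain_id == "s3"])
  expect_equal(out2$value[out2$strain_id == "s3"], floor)
  # no blanks anywhere and no constant: error
  expect_error(subtractBackground(rec[1:2, ]), "no blank")
  expect_silent(subtractBackground(rec[1:2, ], background = 100))
})

test_that("injected background is recovered within blank sampling error", {
  s <- smallScreenSim(nPrey = 12, baits = "B1", seed = 31,
                      backgroundLevel = 250, backgroundSd = 2)$sim
  out <- subtractBackground(s@measurements)
  bgs <- attr(out, "backgrounds")
  expect_true(all(abs(bgs$background - 250) < 3 * 2 / sqrt(16) + 1))
})

test_that("density correction divides matched wells and drops dead wells", {
  lum <- rbind(mkRec("A01", "s1", 900), mkRec("A02", "s2", 600))
  dens <- rbind(mkRec("A01", "s1", 450, channel = "fluorescence"),
                mkRec("A02", "s2", 0, channel = "fluorescence"))
  expect_warning(out <- densityCorrect(lum, dens), "invalid")
  expect_equal(out$value, 2)
  expect_identical(out$strain_id, "s1")
})

test_that("uniform densities rescale globally and leave downstream ratios unchanged", {
  s <- smallScreenSim(nPrey = 15, baits = c("B1", "B2"), seed = 32,
                      noiseSd = 0, backgroundSd = 0)
  ps1 <- normalizeScreen(s$sim@measurements, s$sim@strainMap)
  # double every density reading: all corrected values shift by -1 in log2
  m2 <- s$sim@measurements
  isD <- m2$channel == "fluorescence" & m2$strain_id != "BLANK"
  m2$value[isD] <- 100 + 2 * (m2$value[isD] - 100)
  ps2 <- normalizeScreen(m2, s$sim@strainMap)
  r1 <- controlBaitRatio(ps1, "B1", "B2")
  r2 <- controlBaitRatio(ps2, "B1", "B2")
  expect_equal(r2$log2_ratio, r1$log2_ratio, tolerance = 1e-9)
})

test_that("plate regression recovers identity and constant offsets exactly", {
  x <- seq(2, 12, length.out = 20)
  strains <- sprintf("s%02d", 1:20)
  recs <- do.call(rbind, lapply(1:3, function(r) {
    v <- if (r == 3) x + 0.5 else x
    data.frame(plate_id = "p1", replicate_id = paste0("r", r),
               well = sprintf("A%02d", 1:20), strain_id = strains,
               channel = "luminescence", value = v,
               stringsAsFactors = FALSE)
  }))
  adj <- plateNormalize(recs)
  fits <- attr(adj, "fits")
  expect_equal(fits$slope, rep(1, 3), tolerance = 1e-9)
  expect_equal(fits$intercept, c(0, 0, 0.5), tolerance = 1e-9)
  expect_equal(adj$value, rep(x, 3), tolerance = 1e-9)
})

test_that("single replicates pass through with a warning; flat plates stay unadjusted", {
  one <- data.frame(plate_id = "p1", replicate_id = "r1",
                    well = sprintf("A%02d", 1:12),
                    strain_id = sprintf("s%02d", 1:12),
                    channel = "luminescence", value = rnorm(12),
                    stringsAsFactors = FALSE)
  expect_warning(out <- plateNormalize(one), "single replicate")
  expect_equal(out$value, one$value)
  # a plate uncorrelated with the medians (|slope| < floor) is left alone
  x <- seq(1, 10, length.out = 20)
  recs <- do.call(rbind, lapply(1:3, function(r) {
    v <- if (r == 3) rep(5, 20) else x
    data.frame(plate_id = paste0("p", r), replicate_id = paste0("r", r),
               well = sprintf("A%02d", 1:20),
               strain_id = sprintf("s%02d", 1:20),
               channel = "luminescence", value = v,
               stringsAsFactors = FALSE)
  }))
  adj <- plateNormalize(recs)
  fits <- attr(adj, "fits")
  expect_false(fits$adjusted[fits$replicate_id == "r3"])
  expect_equal(adj$value[adj$replicate_id == "r3"], rep(5, 20))
})

test_that("scaling one plate's raw luminescence cancels after plate normalization", {
  s <- smallScreenSim(nPrey = 20, baits = "B1", seed = 33,
                      noiseSd = 0, backgroundSd = 0)
  ps1 <- normalizeScreen(s$sim@measurements, s$sim@strainMap)
  m2 <- s$sim@measurements
  isL <- m2$channel == "luminescence" & m2$replicate_id == "rep2"
  m2$value[isL] <- m2$value[isL] * 4   # scales blanks and strains alike
  ps2 <- normalizeScreen(m2, s$sim@strainMap)
  expect_equal(signalMatrix(ps2), signalMatrix(ps1), tolerance = 1e-9)
})

test_that("replicate aggregation averages, flags censored strains and is order-invariant", {
  rec <- data.frame(plate_id = "p1",
                    replicate_id = rep(c("r1", "r2"), each = 2),
                    well = "A01",
                    strain_id = rep(c("s1", "s2"), 2),
                    channel = "luminescence",
                    value = c(1, -4, 3, -4.2),
                    below_detection = c(FALSE, TRUE, FALSE, TRUE),
                    det_floor = c(-5, -4, -5, -4.2),
                    stringsAsFactors = FALSE)
  rec$well <- c("A01", "A02", "A01", "A02")
  map <- data.frame(strain_id = c("s1", "s2"), bait = "B",
                    prey = c("X", "Y"), tag_config = "NanoBiT",
                    ploidy = "haploid", stringsAsFactors = FALSE)
  ps <- aggregateReplicates(rec, map)
  expect_equal(unname(meanLog2(ps)["s1"]), 2)
  # fully censored strain: mean sits at its detection floor, flagged
  expect_equal(unname(meanLog2(ps)["s2"]), mean(c(-4, -4.2)))
  expect_equal(unname(pairInfo(ps)$below_detection_frac), c(0, 1))
  # permuting replicate order changes nothing
  ps2 <- aggregateReplicates(rec[c(3, 4, 1, 2), ], map)
  expect_equal(meanLog2(ps2), meanLog2(ps))
})

test_that("noise-free screens show perfect inter-replicate correlation", {
  s <- smallScreenSim(nPrey = 15, baits = "B1", seed = 34,
                      noiseSd = 0, backgroundSd = 0)
  ps <- normalizeScreen(s$sim@measurements, s$sim@strainMap)
  qc <- S4Vectors::metadata(ps)$replicate_correlation
  expect_equal(qc[upper.tri(qc)], rep(1, 3), tolerance = 1e-9)
})

test_that("a wider blank spread only adds censoring flags, never removes them", {
  strainVals <- seq(101, 140)
  mk <- function(spread) {
    rec <- rbind(
      mkRec(sprintf("A%02d", 1:20), sprintf("s%02d", 1:20), strainVals[1:20]),
      mkRec(sprintf("B%02d", 1:8), "BLANK", 100 + spread * c(-2, -1, 0, 0, 0, 0, 1, 2)))
    out <- subtractBackground(rec)
    out$below_detection[order(out$strain_id)]
  }
  narrow <- mk(1)
  wide <- mk(8)
  expect_true(all(wide[narrow]))   # flagged stays flagged
  expect_true(sum(wide) > sum(narrow))
})
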