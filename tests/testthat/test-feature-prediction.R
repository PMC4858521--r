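test_that("kdProfile equals brute-force window means", {
  expect_equal(kdProfile(strrep("I", 19)), 4.5)
  expect_equal(kdProfile(strrep("R", 19)), -4.5)
  set.seed(42)
  seq <- paste(sample(names(kdScale()), 50, replace = TRUE), collapse = "")
  vals <- unname(kdScale()[strsplit(seq, "")[[1]]])
  brute <- sapply(1:(50 - 19 + 1), function(i) mean(vals[i:(i + 18)]))
  expect_equal(kdProfile(seq), brute)
})

test_that("unknown residues score 0.0 with a warning", {
  expect_warning(p <- kdProfile(paste0(strrep("X", 19))), "unknown residue")
  expect_equal(p, 0)
})

test_that("TM caller recovers the constructed peptidase topologies", {
  set.seed(7)
  p5 <- emitTMProtein(pibdTopology()$starts, pibdTopology()$length)
  p9 <- emitTMProtein(eppaTopology()$starts, eppaTopology()$length)
  expect_equal(predictTMSegments(p5)$count, 5L)
  expect_equal(predictTMSegments(p9)$count, 9L)
  hydrophilic <- emitBackgroundProtein(200L)
  expect_equal(predictTMSegments(hydrophilic)$count, 0L)
  expect_equal(predictTMSegments(emitTMProtein(integer(0), 120L))$count, 0L)
})

test_that("TM segments are sorted, non-overlapping and >= 15 residues", {
  set.seed(8)
  for (k in c(2L, 5L, 9L)) {
    tm <- predictTMSegments(emitTMProtein(seq(10L, by = 40L, length.out = k),
                                          40L * k + 30L))
    s <- tm$segments
    expect_equal(tm$count, k)
    expect_true(all(diff(s[, "start"]) > 0))
    if (k > 1L) expect_true(all(s[-1L, "start"] > s[-k, "end"]))
    expect_true(all(s[, "end"] - s[, "start"] + 1L >= 15L))
  }
})

test_that("TM segment count is invariant under sequence reversal", {
  set.seed(9)
  for (k in c(0L, 3L, 5L, 9L)) {
    seq <- emitTMProtein(if (k) seq(12L, by = 41L, length.out = k)
                         else integer(0), 41L * max(k, 1L) + 40L)
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(predictTMSegments(rev_seq)$count,
                 predictTMSegments(seq)$count)
  }
})

test_that("class III detection follows the [K/R]G + charge + hydropathy rule", {
  sp <- detectClass3(paste0("MKG", strrep("L", 20), strrep("S", 30)))
  expect_equal(sp$klass, "class_III")
  expect_equal(sp$cleavage_pos, 3L)
  expect_equal(sp$leader_net_charge, 1L)
  expect_gte(sp$downstream_hydrophobicity, 1.0)
  # acidic leader fails the charge clause
  sp2 <- detectClass3(paste0("M", strrep("D", 5), "KG", strrep("L", 20),
                             strrep("S", 30)))
  expect_false(sp2$klass == "class_III")
  # hydrophilic downstream fails the hydropathy clause
  sp3 <- detectClass3(paste0("MKG", strrep("S", 60)))
  expect_equal(sp3$klass, "none")
})

test_that("emitted prepilins are class III positive at both size regimes", {
  set.seed(10)
  for (len in c(70L, 200L, 500L)) {
    for (i in 1:20) {
      sp <- detectClass3(emitPrepilin(len))
      expect_equal(sp$klass, "class_III")
      expect_lte(sp$cleavage_pos, 35L)
      expect_gte(sp$leader_net_charge, 1L)
    }
  }
})

test_that("shuffling a prepilin destroys the class III call", {
  set.seed(11)
  pre <- emitPrepilin(70L)
  ch <- strsplit(pre, "")[[1]]
  neg <- 0L
  for (i in 1:100) {
    shuf <- paste(sample(ch), collapse = "")
    if (detectClass3(shuf)$klass != "class_III") neg <- neg + 1L
  }
  expect_gte(neg, 95L)
})

test_that("class III call ignores residues appended after the scan region", {
  set.seed(12)
  pre <- emitPrepilin(70L)
  padded <- paste0(pre, strrep("W", 40))
  expect_equal(detectClass3(padded)$cleavage_pos, detectClass3(pre)$cleavage_pos)
  bg <- emitBackgroundProtein(80L)
  expect_equal(detectClass3(paste0(bg, strrep("Q", 30)))$klass,
               detectClass3(bg)$klass)
})

test_that("localization integrates TM and signal-peptide calls", {
  set.seed(13)
  tm5 <- predictTMSegments(emitTMProtein(pibdTopology()$starts, 230L))
  none <- list(klass = "none", cleavage_pos = NA_integer_)
  expect_equal(classifyLocalization(tm5, none), "membrane")
  pre <- emitPrepilin(70L)
  expect_equal(classifyLocalization(predictTMSegments(pre),
                                    detectClass3(pre)), "secreted")
  bg <- emitBackgroundProtein(150L)
  expect_equal(classifyLocalization(predictTMSegments(bg),
                                    detectClass3(bg)), "cytoplasmic")
  expect_equal(classifyLocalization(tm5, none, has_seq = FALSE), "unknown")
})

test_that("detectors separate planted roles exactly on generator output", {
  fx <- defaultFixture()
  feat <- fx$features
  roles <- collectionTruth(fx$coll)$role_of_family
  pilin_roles <- c("major_pilin", "minor_pilin", "archaellin", "flaF",
                   "flaG", "adhesin")
  pilin <- feat[!is.na(feat$family_id) &
                  feat$family_id %in% names(roles)[roles %in% pilin_roles], ]
  expect_true(nrow(pilin) > 100L)
  expect_true(all(pilin$sp_class == "class_III"))       # sensitivity 1.0
  bg <- feat[!is.na(feat$family_id) &
               grepl("^(bg|rare)", feat$family_id), ]
  expect_true(nrow(bg) > 500L)
  expect_true(all(bg$sp_class != "class_III"))          # FPR 0.0
  expect_true(all(bg$localization == "cytoplasmic"))
  # membrane roles carry the advertised TM counts
  tadc <- feat[!is.na(feat$family_id) &
                 feat$family_id %in% names(roles)[roles == "peptidase_5TM"], ]
  expect_true(all(tadc$tm_count == 5L))
  eppa <- feat[!is.na(feat$family_id) &
                 feat$family_id %in% names(roles)[roles == "peptidase_9TM"], ]
  expect_true(all(eppa$tm_count == 9L))
})
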