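test_that("expansion applies the distinct-genome threshold", {
  mk <- function(n) lapply(seq_len(n), function(i)
    toyGenome(paste0("g", i), c("seed", "X", NA, NA)))
  expect_true("X" %in% expandOnce(mk(5L), "seed", 3L, 5L))
  expect_false("X" %in% expandOnce(mk(4L), "seed", 3L, 5L))
  # multiplicity within one genome counts once
  g <- toyGenome("g1", c("seed", "X", "X", "X"))
  expect_false("X" %in% expandOnce(list(g), "seed", 3L, 2L))
})

test_that("expansion equals the brute-force pair enumeration on random toys", {
  set.seed(101)
  pool <- c("seed", paste0("f", 1:12), NA)
  for (rep in 1:12) {
    genomes <- lapply(seq_len(sample(3:8, 1)), function(i)
      toyGenome(paste0("g", i),
                sample(pool, sample(10:60, 1), replace = TRUE)))
    w <- sample(1:4, 1); mg <- sample(1:4, 1)
    cur <- "seed"
    for (it in 1:3) {
      expanded <- expandOnce(genomes, cur, w, mg)
      expect_identical(expanded, bruteExpandOnce(genomes, cur, w, mg))
      cur <- expanded
    }
  }
})

test_that("accepted sets are monotone in iterations and reach a fixed point", {
  fx <- defaultFixture()
  acc <- acceptedByIteration(fx$census)
  for (i in seq_len(length(acc) - 1L))
    expect_true(all(acc[[i]] %in% acc[[i + 1L]]))
  expect_true(all(CensusConfig(seedFamilies(fx$coll))@seedFamilies %in%
                    finalFamilies(fx$census)))
  # iterate a small instance to convergence; expansion is then the identity
  set.seed(7)
  genomes <- lapply(1:6, function(i)
    toyGenome(paste0("g", i), sample(c("seed", "a", "b", NA, NA), 30,
                                     replace = TRUE)))
  cur <- "seed"
  repeat {
    nxt <- expandOnce(genomes, cur, 2L, 3L)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  expect_identical(expandOnce(genomes, cur, 2L, 3L), cur)
})

test_that("lowering min_genomes never removes accepted families", {
  set.seed(55)
  genomes <- lapply(1:8, function(i)
    toyGenome(paste0("g", i), sample(c("seed", paste0("f", 1:6), NA), 40,
                                     replace = TRUE)))
  prev <- NULL
  for (mg in 8:1) {
    cur <- expandOnce(genomes, "seed", 3L, mg)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("chained neighborhoods need the full iteration count", {
  # seed-A-B-C, each link within the window but the next family beyond it
  fams <- rep(NA_character_, 10)
  fams[c(1, 4, 7, 10)] <- c("seed", "A", "B", "C")
  genomes <- list(toyGenome("g1", fams))
  cfg1 <- CensusConfig("seed", window = 3L, minGenomes = 1L, iterations = 1L)
  cfg3 <- CensusConfig("seed", window = 3L, minGenomes = 1L, iterations = 3L)
  r1 <- runCensus(genomes, cfg1, curate = FALSE)
  r3 <- runCensus(genomes, cfg3, curate = FALSE)
  expect_false("C" %in% finalFamilies(r1))
  expect_true(all(c("A", "B", "C") %in% finalFamilies(r3)))
})

test_that("census recovers exactly the planted families on the default collection", {
  fx <- defaultFixture()
  final <- finalFamilies(fx$census)
  catalogFams <- collectionCatalog(fx$coll)@families$family_id
  # zero background families accepted
  expect_length(setdiff(final, catalogFams), 0L)
  # full recall of planted families present in loci in >= 5 genomes
  eligible <- setdiff(eligiblePlantedFamilies(fx$coll, 5L),
                      familiesWithRole(collectionCatalog(fx$coll), "s_layer"))
  expect_gt(length(eligible), 40L)
  expect_true(all(eligible %in% final))
  # S-layer families are excluded but retained as potential components
  excl <- excludedFamilies(fx$census)
  expect_true("fam.slayer" %in% excl$family_id)
  expect_false("fam.slayer" %in% final)
  expect_match(excl$reason[excl$family_id == "fam.slayer"], "s_layer")
})

test_that("curation accepts secreted, exclusive, operonic families only", {
  # 3 genomes: candidate X operonic with seed, secreted, always in loci
  set.seed(77)
  pre <- emitPrepilin(120L)
  mkg <- function(i, extraX = FALSE) {
    fams <- c("seed", "other", "X", if (extraX) c(NA, NA, NA, NA, "X"))
    gt <- toyGenome(paste0("g", i), fams, strand = "+",
                    gaps = c(300L, rep(10L, length(fams) - 1L)))
    g <- genes(gt)
    g$protein_seq[g$family_id %in% "X"] <- pre
    g$protein_seq[g$family_id %in% "other"] <- pre
    GenomeTable(paste0("g", i), g)
  }
  genomes <- lapply(1:3, mkg)
  feat <- computeFeatures(genomes)
  cc <- curateCandidates(c("X", "other"), genomes, feat, accepted = "seed")
  expect_true(all(cc$accepted))
  expect_equal(unique(cc$reason), "a+b+c")
  # one member in a different gene context breaks exclusivity
  genomes2 <- c(lapply(1:2, mkg), list(mkg(3, extraX = TRUE)))
  feat2 <- computeFeatures(genomes2)
  cc2 <- curateCandidates("X", genomes2, feat2, accepted = "seed")
  expect_false(cc2$accepted)
  expect_lt(cc2$exclusivity, 1.0)
  # cytoplasmic-only family fails the localization clause
  genomes3 <- lapply(1:3, function(i) {
    gt <- toyGenome(paste0("g", i), c("seed", "cyt"), strand = "+",
                    gaps = c(300L, 10L))
    g <- genes(gt)
    g$protein_seq[2L] <- emitBackgroundProtein(150L)
    GenomeTable(paste0("g", i), g)
  })
  cc3 <- curateCandidates("cyt", genomes3, computeFeatures(genomes3),
                          accepted = "seed")
  expect_false(cc3$accepted)
})

test_that("an empty exclusion role set excludes nothing", {
  fx <- defaultFixture()
  cfg <- CensusConfig(seedFamilies(fx$coll), exclusionRoles = character(0))
  cen <- runCensus(fx$genomes, cfg, fx$features,
                   collectionCatalog(fx$coll))
  expect_equal(nrow(excludedFamilies(cen)), 0L)
  expect_true("fam.slayer" %in% finalFamilies(cen))
})

test_that("empty seed set is a configuration error", {
  fx <- defaultFixture()
  cfg <- CensusConfig(character(0))
  expect_error(runCensus(fx$genomes, cfg), "configuration error")
})

test_that("T4P counting uses gene, not family, multiplicity", {
  g1 <- toyGenome("g1", c("atp", NA, "atp"))
  g2 <- toyGenome("g2", c(NA, NA))
  counts <- countT4pPerGenome(list(g1, g2), "atp")
  expect_equal(unname(counts), c(2L, 0L))
  expect_equal(unname(countT4pPerGenome(list(g1, g2), "atp",
                                        distinct_families = TRUE)),
               c(1L, 0L))
})

test_that("phyletic matrix cells count genes and marginals recount", {
  g1 <- toyGenome("g1", c("famA", "famA", "famA"))
  m <- phyleticMatrix(list(g1), c("famA", "famB"))
  expect_equal(m["famA", "g1"], 3L)
  expect_equal(unname(m["famB", ]), 0L)
  fx <- defaultFixture()
  fams <- finalFamilies(fx$census)[1:10]
  m2 <- phyleticMatrix(fx$genomes, fams)
  recount <- vapply(fams, function(f)
    sum(vapply(fx$genomes, function(gt)
      sum(!is.na(genes(gt)$family_id) & genes(gt)$family_id == f), 1L)),
    1L)
  expect_equal(attr(m2, "family_totals"), recount)
  expect_equal(unname(rowSums(m2)), unname(recount))
})

test_that("census summary reports the hypothetical-annotation fraction", {
  fx <- defaultFixture()
  s <- censusSummary(fx$census)
  expect_equal(s$n_families, length(finalFamilies(fx$census)))
  expect_equal(s$n_proteins, nrow(assignments(fx$census)))
  expect_gt(s$fraction_hypothetical, 0.2)
  expect_lt(s$fraction_hypothetical, 0.9)
})
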