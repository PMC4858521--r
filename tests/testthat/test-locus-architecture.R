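test_that("operon prediction follows strand and intergenic distance", {
  gt <- toyGenome("g", paste0("f", 1:3), strand = "+",
                  gaps = c(300L, 20L, 20L))
  expect_length(predictOperons(gt), 1L)
  gt2 <- toyGenome("g", paste0("f", 1:4), strand = c("+", "+", "-", "-"),
                   gaps = c(300L, 20L, 20L, 20L))
  expect_length(predictOperons(gt2), 2L)
  gt3 <- toyGenome("g", paste0("f", 1:3), strand = "+",
                   gaps = c(300L, 20L, 500L))
  expect_length(predictOperons(gt3), 2L)
})

test_that("operon blocks reproduce the generator's operon plan", {
  fx <- defaultFixture()
  tr <- collectionTruth(fx$coll)
  for (gid in names(fx$genomes)[1:5]) {
    blocks <- predictOperons(fx$genomes[[gid]])
    truth <- split(tr$operons$gene_id[tr$operons$genome_id == gid],
                   tr$operons$block_id[tr$operons$genome_id == gid])
    expect_identical(unname(lapply(blocks, unname)), unname(truth))
  }
})

test_that("locus assembly bridges at most max_intervening non-census genes", {
  gt <- toyGenome("g", c("A", NA, NA, "B"))
  L <- buildLoci(gt, c("A", "B"), max_intervening = 2L)
  expect_equal(nrow(L), 1L)
  expect_equal(L$type, "locus")
  expect_equal(c(L$start_index, L$end_index), c(0L, 3L))
  gt2 <- toyGenome("g", c("A", NA, NA, NA, "B"))
  L2 <- buildLoci(gt2, c("A", "B"), max_intervening = 2L)
  expect_equal(nrow(L2), 2L)
  # single-family runs are flagged stand-alone
  gt3 <- toyGenome("g", c("A", "A", NA, NA, NA, NA, "B", "C"))
  L3 <- buildLoci(gt3, c("A", "B", "C"))
  expect_equal(L3$type, c("standalone", "locus"))
})

test_that("assembled locus ranges equal the planted truth ranges", {
  fx <- defaultFixture()
  pl <- collectionTruth(fx$coll)$planted_loci
  hit <- vapply(seq_len(nrow(pl)), function(i)
    any(fx$loci$genome_id == pl$genome_id[i] & fx$loci$type == "locus" &
          fx$loci$start_index == pl$start_index[i] &
          fx$loci$end_index == pl$end_index[i]), TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("every census gene lies in exactly one locus or stand-alone run", {
  fx <- defaultFixture()
  final <- finalFamilies(fx$census)
  memberIds <- unlist(strsplit(fx$loci$gene_ids, ";", fixed = TRUE))
  expect_false(anyDuplicated(memberIds) > 0L)
  censusIds <- unlist(lapply(fx$genomes, function(gt) {
    g <- genes(gt)
    g$gene_id[!is.na(g$family_id) & g$family_id %in% final]
  }))
  expect_setequal(memberIds, censusIds)
})

test_that("locus scores follow the required-fraction rule with forbidden penalty", {
  templates <- builtinTemplates()
  arch <- templates$archaellum
  full <- c(secretion_ATPase = 1, flaH = 1, tadC = 1, flaF = 1, flaG = 1,
            archaellin = 3, flaCDE = 1)
  expect_equal(scoreLocus(full, arch), 1.0)
  noH <- full[names(full) != "flaH"]
  expect_equal(scoreLocus(noH, arch), 6 / 7)
  cl <- classifyLocus(noH, templates)
  expect_equal(cl$template, "archaellum")
  expect_equal(cl$score, 6 / 7, tolerance = 1e-12)
  # forbidden role floors the score at 0
  d4 <- c(secretion_ATPase = 1, membrane_accessory = 1)
  expect_equal(scoreLocus(d4, templates$sub4D), 1.0)
  expect_equal(scoreLocus(c(d4, major_pilin = 1), templates$sub4D), 0)
  expect_equal(classifyLocus(d4, templates)$template, "sub4D")
})

test_that("in-trans majors satisfy the major-pilin requirement", {
  templates <- builtinTemplates()
  simple <- c(secretion_ATPase = 1, tadC = 1)
  expect_lt(scoreLocus(simple, templates$sulfolobales_simple), 1.0)
  expect_equal(scoreLocus(simple, templates$sulfolobales_simple,
                          in_trans_major = TRUE), 1.0)
  # in-trans applies to majors only, not minors
  noMinor <- c(secretion_ATPase = 1, tadC = 1, major_pilin = 1)
  expect_lt(scoreLocus(noMinor, templates$clade2_B, in_trans_major = TRUE),
            1.0)
})

test_that("raising the score threshold yields unclassified calls", {
  templates <- builtinTemplates()
  weak <- c(secretion_ATPase = 1)
  cl <- classifyLocus(weak, templates, min_score = 0.6)
  expect_equal(cl$template, "unclassified")
})

test_that("archaellum completeness accepts 1-9 archaellins and 1-3 FlaC/D/E", {
  catalog <- FamilyCatalog(
    c("fI", "fH", "fJ", "fF", "fG", "fB", "fCDE"),
    c("secretion_ATPase", "flaH", "tadC", "flaF", "flaG", "archaellin",
      "flaCDE"))
  mkLocus <- function(nB, nCDE, drop = NULL) {
    fams <- c(rep("fB", nB), rep("fCDE", nCDE), "fF", "fG", "fH", "fI", "fJ")
    fams <- setdiff_keep <- fams[!fams %in% drop]
    gt <- toyGenome("g1", fams)
    loci <- data.frame(locus_id = "L1", genome_id = "g1", contig_id = "c1",
                       start_index = 0L, end_index = length(fams) - 1L,
                       n_members = length(fams), type = "locus",
                       gene_ids = paste(genes(gt)$gene_id, collapse = ";"),
                       family_ids = paste(fams, collapse = ";"),
                       classification = "archaellum", score = 1.0,
                       stringsAsFactors = FALSE)
    checkArchaellumCompleteness(gt, loci, catalog)
  }
  expect_true(mkLocus(1L, 1L)$complete)
  expect_true(mkLocus(9L, 3L)$complete)     # nine paralogs still complete
  r <- mkLocus(0L, 1L)                      # zero archaellins
  expect_false(r$complete)
  expect_true("archaellin" %in% r$missing)
  for (role in c("fI", "fH", "fJ", "fF", "fG", "fCDE")) {
    r <- mkLocus(2L, 1L, drop = role)
    expect_false(r$complete)
  }
  r10 <- mkLocus(10L, 1L)                   # beyond the 1-9 range
  expect_false(r10$complete)
  expect_true("archaellin" %in% r10$violations)
})

test_that("stand-alone archaellins count toward completeness", {
  catalog <- FamilyCatalog(
    c("fI", "fH", "fJ", "fF", "fG", "fB", "fCDE"),
    c("secretion_ATPase", "flaH", "tadC", "flaF", "flaG", "archaellin",
      "flaCDE"))
  # locus without archaellins, one stand-alone fB elsewhere
  fams <- c("fCDE", "fF", "fG", "fH", "fI", "fJ", NA, NA, NA, NA, "fB")
  gt <- toyGenome("g1", fams)
  g <- genes(gt)
  loci <- data.frame(locus_id = "L1", genome_id = "g1", contig_id = "c1",
                     start_index = 0L, end_index = 5L, n_members = 6L,
                     type = "locus",
                     gene_ids = paste(g$gene_id[1:6], collapse = ";"),
                     family_ids = paste(fams[1:6], collapse = ";"),
                     classification = "archaellum", score = 6 / 7,
                     stringsAsFactors = FALSE)
  r <- checkArchaellumCompleteness(gt, loci, catalog)
  expect_true(r$complete)
  expect_equal(unname(r$multiplicities[["archaellin"]]), 1L)
})

test_that("template classification is exact on the default collection", {
  fx <- defaultFixture()
  pl <- plantedPredictions(fx$coll, fx$loci)
  expect_true(all(pl$pred == pl$template))
})

test_that("template YAML round-trips the built-in library", {
  f <- tempfile(fileext = ".yaml")
  writeTemplates(builtinTemplates(), f)
  back <- readTemplates(f)
  orig <- builtinTemplates()
  expect_setequal(names(back), names(orig))
  for (nm in names(orig)) {
    expect_identical(back[[nm]]@required, orig[[nm]]@required)
    expect_identical(back[[nm]]@forbidden, orig[[nm]]@forbidden)
  }
})
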