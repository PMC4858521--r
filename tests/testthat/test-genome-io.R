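test_that("a minimal gene table parses with normalized order indices", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("genome_id", "lineage", "contig_id", "order_index",
                       "gene_id", "strand", "start", "end", "family_id",
                       "product", "protein_seq"), collapse = "\t"),
               "g1\tEury\tc1\t5\ta\t+\t10\t100\tfamA\tp1\t",
               "g1\tEury\tc1\t9\tb\t-\t200\t300\t\tp2\t"), f)
  tabs <- readGeneTable(f)
  expect_length(tabs, 1L)
  g <- genes(tabs$g1)
  expect_equal(nrow(g), 2L)
  expect_equal(g$order_index, c(0L, 1L))
  expect_true(is.na(g$family_id[2L]))
  expect_equal(lineage(tabs$g1), "Eury")
})

test_that("malformed rows are rejected with their line numbers", {
  hdr <- paste(c("genome_id", "lineage", "contig_id", "order_index",
                 "gene_id", "strand", "start", "end", "family_id",
                 "product", "protein_seq"), collapse = "\t")
  row <- function(gid, oi, id, strand = "+")
    paste("g1", "", "c1", oi, id, strand, "", "", "", "", "", sep = "\t")
  f <- tempfile()
  writeLines(c(hdr, row("g1", 0, "a"), row("g1", 1, "b"), row("g1", 2, "c"),
               row("g1", 3, "d"), row("g1", 4, "e"),
               row("g1", 5, "f", strand = "x")), f)
  expect_error(readGeneTable(f), "line 7")
  f2 <- tempfile()
  writeLines(c(hdr, row("g1", 0, "a"), row("g1", 1, "a")), f2)
  expect_error(readGeneTable(f2), "duplicate gene_id 'a'")
  f3 <- tempfile()
  writeLines(c(sub("\tstrand", "", hdr)), f3)
  expect_error(readGeneTable(f3), "missing column")
})

test_that("gene-table TSV round-trips generator output field by field", {
  params <- defaultGeneratorParams(rng_seed = 5L)
  params$n_genomes <- 20L
  params$architecture_plan <- c(archaellum = 5L, clade1 = 5L)
  params$genes_per_genome <- c(25L, 40L)
  coll <- generateCollection(params)
  f <- tempfile(fileext = ".tsv")
  writeGeneTable(collectionGenomes(coll), f)
  back <- readGeneTable(f)
  expect_length(back, 20L)
  for (gt in collectionGenomes(coll)) {
    rt <- back[[genomeId(gt)]]
    expect_equal(genes(rt), genes(gt))
    expect_equal(lineage(rt), lineage(gt))
  }
})

test_that("GFF3 genes are ordered by start coordinate per contig", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tCDS\t100\t400\t.\t+\t0\tID=gA",
               "c1\tx\tCDS\t900\t1200\t.\t+\t0\tID=gB",
               "c1\tx\tCDS\t50\t80\t.\t-\t0\tID=gC"), gff)
  fa <- tempfile(fileext = ".faa")
  writeLines(character(0), fa)
  gt <- readGffFasta(gff, fa, genome_id = "g")
  g <- genes(gt)
  expect_equal(g$order_index[match(c("gA", "gB", "gC"), g$gene_id)],
               c(1L, 2L, 0L))
  expect_true(all(is.na(g$protein_seq)))
})

test_that("GFF3+FASTA round-trips a generator genome", {
  params <- defaultGeneratorParams(rng_seed = 11L)
  params$n_genomes <- 5L
  params$architecture_plan <- c(sulfolobales_simple = 5L)
  params$genes_per_genome <- c(20L, 25L)
  coll <- generateCollection(params)
  gt <- collectionGenomes(coll)[[1L]]
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".faa")
  writeGffFasta(gt, gff, fa)
  back <- readGffFasta(gff, fa, genome_id = genomeId(gt))
  expect_equal(genes(back)[, c("contig_id", "order_index", "gene_id",
                               "strand", "start", "end", "family_id",
                               "protein_seq")],
               genes(gt)[, c("contig_id", "order_index", "gene_id", "strand",
                             "start", "end", "family_id", "protein_seq")])
})

test_that("FASTA records without a matching feature are dropped with warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "c1\tx\tCDS\t1\t90\t.\t+\t0\tID=gA"), gff)
  fa <- tempfile(fileext = ".faa")
  writeLines(c(">gA", "MKLV", ">orphan", "MMMM"), fa)
  expect_warning(gt <- readGffFasta(gff, fa, genome_id = "g"), "orphan")
  expect_equal(genes(gt)$protein_seq, "MKLV")
})

test_that("neighborhood returns the window around the focal gene, truncated", {
  gt <- toyGenome("g", rep(NA_character_, 20L))
  nb <- neighborhood(gt, "g_g6", 3L)  # order_index 5
  expect_equal(nrow(nb), 7L)
  expect_equal(nb$order_index, 2:8)
  expect_equal(nrow(neighborhood(gt, "g_g1", 3L)), 4L)
  expect_equal(neighborhood(gt, "g_g1", 3L)$order_index, 0:3)
  expect_equal(nrow(neighborhood(gt, "g_g6", 0L)), 1L)
  expect_error(neighborhood(gt, "nope", 3L), "unknown gene_id")
})

test_that("neighborhood never crosses contigs and obeys the size bound", {
  g <- data.frame(contig_id = rep(c("c1", "c2"), each = 5L),
                  gene_id = paste0("x", 1:10), strand = "+",
                  stringsAsFactors = FALSE)
  gt <- GenomeTable("g", g)
  nb <- neighborhood(gt, "x5", 3L)  # last gene of c1
  expect_true(all(nb$contig_id == "c1"))
  expect_equal(nrow(nb), 4L)
  for (w in 0:4) for (id in paste0("x", c(1, 3, 5, 8)))
    expect_lte(nrow(neighborhood(gt, id, w)), 2L * w + 1L)
})

test_that("neighborhood membership is symmetric under gene-order reversal", {
  gt <- toyGenome("g", paste0("f", 1:11))
  g <- genes(gt)
  rev_g <- g
  rev_g$order_index <- max(g$order_index) - g$order_index
  gt_rev <- GenomeTable("g", rev_g)
  for (id in c("g_g1", "g_g5", "g_g11"))
    expect_setequal(neighborhood(gt, id, 3L)$gene_id,
                    neighborhood(gt_rev, id, 3L)$gene_id)
})

test_that("GenomeTable validity rejects inconsistent records", {
  expect_error(GenomeTable("g", data.frame(contig_id = "c", gene_id = "a",
                                           strand = "z")), "strand")
  expect_error(GenomeTable("g", data.frame(contig_id = "c",
                                           gene_id = c("a", "a"),
                                           strand = "+")), "duplicate")
  expect_error(GenomeTable("g", data.frame(contig_id = "c", gene_id = "a",
                                           strand = "+", start = 10L,
                                           end = 5L)), "start")
})
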