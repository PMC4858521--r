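# Shared fixtures, built in code and cached for the test session.

# default study-condition collection (30 genomes, all 11 templates x 5,
# seed 17) plus derived census products
defaultFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    coll <- generateCollection(defaultGeneratorParams())
    genomes <- collectionGenomes(coll)
    features <- computeFeatures(genomes)
    census <- runCensus(genomes, CensusConfig(seedFamilies(coll)), features,
                        collectionCatalog(coll))
    loci <- do.call(rbind, lapply(genomes, buildLoci,
                                  final_families = finalFamilies(census)))
    rownames(loci) <- NULL
    class3 <- unique(features$family_id[!is.na(features$family_id) &
                                          features$sp_class == "class_III"])
    pcalls <- pilinCalls(union(finalFamilies(census), class3), genomes,
                         features, loci)
    loci <- classifyLoci(loci, builtinTemplates(), collectionCatalog(coll),
                         pcalls, features)
    cache <<- list(coll = coll, genomes = genomes, features = features,
                   census = census, loci = loci, pcalls = pcalls)
    cache
  }
})

# larger collection for the template confusion matrix (>= 200 planted loci)
confusionFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    params <- defaultGeneratorParams(rng_seed = 29L)
    params$n_genomes <- 70L
    params$architecture_plan <- stats::setNames(rep(20L, 11L),
                                                names(builtinTemplates()))
    coll <- generateCollection(params)
    genomes <- collectionGenomes(coll)
    features <- computeFeatures(genomes)
    census <- runCensus(genomes, CensusConfig(seedFamilies(coll)), features,
                        collectionCatalog(coll))
    loci <- do.call(rbind, lapply(genomes, buildLoci,
                                  final_families = finalFamilies(census)))
    rownames(loci) <- NULL
    class3 <- unique(features$family_id[!is.na(features$family_id) &
                                          features$sp_class == "class_III"])
    pcalls <- pilinCalls(union(finalFamilies(census), class3), genomes,
                         features, loci)
    loci <- classifyLoci(loci, builtinTemplates(), collectionCatalog(coll),
                         pcalls, features)
    cache <<- list(coll = coll, genomes = genomes, census = census,
                   loci = loci)
    cache
  }
})

# match each planted locus to the predicted classification of the overlapping
# assembled locus
plantedPredictions <- function(coll, loci) {
  pl <- collectionTruth(coll)$planted_loci
  pl$pred <- vapply(seq_len(nrow(pl)), function(i) {
    hit <- loci$genome_id == pl$genome_id[i] & loci$type == "locus" &
      loci$start_index <= pl$end_index[i] &
      loci$end_index >= pl$start_index[i]
    if (sum(hit) == 1L) loci$classification[hit]
    else paste0("split:", sum(hit))
  }, "")
  pl
}

# planted families that occur inside planted loci in >= min_genomes genomes
# (stand-alone-only major pilins are not neighborhood-recoverable)
eligiblePlantedFamilies <- function(coll, min_genomes = 5L) {
  pl <- collectionTruth(coll)$planted_loci
  genomes <- collectionGenomes(coll)
  seen <- list()
  for (i in seq_len(nrow(pl))) {
    g <- genes(genomes[[pl$genome_id[i]]])
    fams <- unique(g$family_id[g$order_index >= pl$start_index[i] &
                                 g$order_index <= pl$end_index[i]])
    for (f in fams) seen[[f]] <- union(seen[[f]], pl$genome_id[i])
  }
  names(seen)[vapply(seen, length, 1L) >= min_genomes]
}

# a single-contig toy genome from a vector of family labels (NA = unlabeled)
toyGenome <- function(id, fams, strand = "+", gaps = NULL) {
  n <- length(fams)
  if (is.null(gaps)) gaps <- rep(20L, n)
  len <- 300L
  starts <- integer(n); cursor <- 0L
  for (i in seq_len(n)) {
    starts[i] <- cursor + gaps[i]
    cursor <- starts[i] + len - 1L
  }
  GenomeTable(id, data.frame(
    contig_id = "c1", order_index = seq_len(n) - 1L,
    gene_id = paste0(id, "_g", seq_len(n)),
    strand = rep_len(strand, n), start = starts, end = starts + len - 1L,
    family_id = fams, product = "protein",
    stringsAsFactors = FALSE))
}

# independent brute-force census expansion: set comprehension over all
# (gene, neighbor) pairs on the same contig within the window
bruteExpandOnce <- function(genomes, current, window, min_genomes) {
  hits <- list()
  for (gt in genomes) {
    g <- genes(gt)
    found <- character(0)
    for (i in seq_len(nrow(g))) {
      if (is.na(g$family_id[i]) || !(g$family_id[i] %in% current)) next
      for (j in seq_len(nrow(g))) {
        if (g$contig_id[j] != g$contig_id[i]) next
        if (abs(g$order_index[j] - g$order_index[i]) > window) next
        if (!is.na(g$family_id[j])) found <- c(found, g$family_id[j])
      }
    }
    for (f in unique(found)) hits[[f]] <- c(hits[[f]], genomeId(gt))
  }
  counts <- vapply(hits, function(x) length(unique(x)), 1L)
  sort(union(current, names(counts)[counts >= min_genomes]))
}

# brute-force column homogeneity: explicit unordered pair enumeration
bruteHomogeneity <- function(col) {
  res <- col[!col %in% c("-", ".")]
  n <- length(res)
  if (n == 0L) return(0)
  if (n == 1L) return(1)
  same <- 0L; tot <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + 1L
    if (res[i] == res[j]) same <- same + 1L
  }
  same / tot
}

randomAlignment <- function(nseq, width, gap_p = 0.3) {
  sapply(seq_len(nseq), function(i)
    paste(sample(c("A", "C", "D", "E", "-"), width, replace = TRUE,
                 prob = c((1 - gap_p) / 4, (1 - gap_p) / 4, (1 - gap_p) / 4,
                          (1 - gap_p) / 4, gap_p)), collapse = ""))
}
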