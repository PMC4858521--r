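## The iterative guilt-by-association census: starting from the secretion
## ATPase seed families, families found in the gene neighborhoods (window
## genes up- and downstream) of current-set genes in >= min_genomes distinct
## genomes are accepted, for a fixed number of iterations; sub-threshold
## candidates then pass an automated curation step standing in for manual
## inspection, and excluded roles (S-layer) are set aside as potential
## components.

# For every family occurring within `window` genes of a current-set gene,
# the number of distinct genomes where that happens.
.neighborFamilyGenomeCounts <- function(genomes, current, window) {
  counts <- new.env(parent = emptyenv())
  for (gt in genomes) {
    fams <- character(0)
    g <- genes(gt)
    for (ct in unique(g$contig_id)) {
      sub <- g[g$contig_id == ct, , drop = FALSE]
      sub <- sub[order(sub$order_index), , drop = FALSE]
      n <- nrow(sub)
      cur <- which(!is.na(sub$family_id) & sub$family_id %in% current)
      if (!length(cur)) next
      mask <- logical(n)
      for (i in cur)
        mask[max(1L, i - window):min(n, i + window)] <- TRUE
      fams <- c(fams, sub$family_id[mask & !is.na(sub$family_id)])
    }
    for (f in unique(fams))
      assign(f, (if (exists(f, envir = counts)) get(f, envir = counts)
                 else 0L) + 1L, envir = counts)
  }
  fams <- ls(counts)
  stats::setNames(vapply(fams, get, 1L, envir = counts), fams)
}

#' One iteration of neighborhood expansion
#'
#' Returns `current` plus every family that occurs within the
#' `window`-gene neighborhood of at least one current-set gene in at least
#' `min_genomes` distinct genomes. Multiple occurrences within one genome
#' count once; genes without a family label are ignored.
#'
#' @param genomes List of [GenomeTable-class].
#' @param current Non-empty character vector of currently accepted families.
#' @param window Genes up- and downstream (default 3).
#' @param min_genomes Distinct-genome threshold (default 5).
#' @return Character vector: the expanded family set (a superset of
#'   `current`).
#' @export
expandOnce <- function(genomes, current, window = 3L, min_genomes = 5L) {
  if (!length(current)) stop("current family set must be non-empty")
  counts <- .neighborFamilyGenomeCounts(genomes, current, window)
  sort(union(current, names(counts)[counts >= min_genomes]))
}

#' Automated curation of sub-threshold candidate families
#'
#' Surrogate for manual neighborhood inspection: a candidate family is
#' accepted iff (a) at least `localizationMin` of its members are predicted
#' secreted or membrane proteins, (b) the fraction of its members lying inside
#' candidate loci is at least `contextExclusivityMin` (the "never occurred in
#' a different gene context" criterion), and (c) at least one member shares a
#' predicted operon with a gene of an already-accepted family.
#'
#' @param candidates Families seen in neighborhoods but below the genome
#'   threshold (disjoint from `accepted`).
#' @param genomes List of [GenomeTable-class].
#' @param features Per-protein feature calls from [computeFeatures()].
#' @param accepted Currently accepted family set.
#' @param contextExclusivityMin,localizationMin Clause thresholds.
#' @param max_intervening Passed to [buildLoci()] when forming candidate loci.
#' @return data.frame with one row per candidate: `family_id`, the three
#'   clause measurements (`secreted_membrane_fraction`, `exclusivity`,
#'   `operonic`), `accepted` and a `reason` code listing the clauses that
#'   held (e.g. `"a+b+c"`).
#' @export
curateCandidates <- function(candidates, genomes, features, accepted,
                             contextExclusivityMin = 1.0,
                             localizationMin = 0.8, max_intervening = 2L) {
  if (!length(candidates))
    return(data.frame(family_id = character(0),
                      secreted_membrane_fraction = numeric(0),
                      exclusivity = numeric(0), operonic = logical(0),
                      accepted = logical(0), reason = character(0)))
  stopifnot(!any(candidates %in% accepted))
  pool <- union(accepted, candidates)
  locs <- lapply(genomes, function(gt) buildLoci(gt, pool, max_intervening))
  ops <- lapply(genomes, predictOperons)
  rows <- lapply(candidates, function(f) {
    inLoci <- 0L; total <- 0L; operonic <- FALSE
    locv <- character(0)
    for (gi in seq_along(genomes)) {
      g <- genes(genomes[[gi]])
      mem <- which(!is.na(g$family_id) & g$family_id == f)
      if (!length(mem)) next
      total <- total + length(mem)
      L <- locs[[gi]]
      L <- L[L$type == "locus", , drop = FALSE]  # single-family runs are a
                                                 # different gene context
      for (i in mem) {
        ct <- g$contig_id[i]; oi <- g$order_index[i]
        hit <- L$contig_id == ct & L$start_index <= oi & L$end_index >= oi
        if (any(hit)) inLoci <- inLoci + 1L
      }
      if (!operonic) {
        accGenes <- g$gene_id[!is.na(g$family_id) & g$family_id %in% accepted]
        if (length(accGenes)) {
          for (block in ops[[gi]]) {
            if (any(g$gene_id[mem] %in% block) && any(accGenes %in% block)) {
              operonic <- TRUE; break
            }
          }
        }
      }
      locv <- c(locv, g$gene_id[mem])
    }
    if (total == 0L)
      return(data.frame(family_id = f, secreted_membrane_fraction = NA_real_,
                        exclusivity = NA_real_, operonic = FALSE,
                        accepted = FALSE, reason = "no_members"))
    fl <- features[features$family_id %in% f & features$gene_id %in% locv, ,
                   drop = FALSE]
    smf <- if (nrow(fl)) mean(fl$localization %in% c("secreted", "membrane"))
           else 0
    excl <- inLoci / total
    a <- smf >= localizationMin
    b <- excl >= contextExclusivityMin
    ok <- a && b && operonic
    reason <- paste(c("a", "b", "c")[c(a, b, operonic)], collapse = "+")
    if (reason == "") reason <- "none"
    data.frame(family_id = f, secreted_membrane_fraction = smf,
               exclusivity = excl, operonic = operonic, accepted = ok,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full iterative census
#'
#' Applies [expandOnce()] `iterations` times from the seed families, curates
#' the remaining sub-threshold candidates with [curateCandidates()], removes
#' families whose catalog role is in `exclusionRoles` into the excluded set
#' (retained as "potential components"), and assigns every gene of a final
#' family.
#'
#' @param genomes List of [GenomeTable-class].
#' @param config A [CensusConfig-class]; its seed set must be non-empty.
#' @param features Per-protein feature calls from [computeFeatures()]; if
#'   `NULL` they are computed here (needed for curation only).
#' @param catalog Optional [FamilyCatalog-class] used for role-based
#'   exclusion; without it no family is excluded.
#' @param curate Set `FALSE` to skip the curation step (pure threshold
#'   census).
#' @return A [CensusResult-class].
#' @export
runCensus <- function(genomes, config, features = NULL, catalog = NULL,
                      curate = TRUE) {
  stopifnot(is(config, "CensusConfig"))
  if (!length(config@seedFamilies))
    stop("configuration error: empty seed family set")
  if (is.null(features) && curate) features <- computeFeatures(genomes)
  current <- sort(unique(config@seedFamilies))
  acc <- list()
  for (i in seq_len(config@iterations)) {
    current <- expandOnce(genomes, current, config@window, config@minGenomes)
    acc[[i]] <- current
  }
  counts <- .neighborFamilyGenomeCounts(genomes, current, config@window)
  candidates <- setdiff(names(counts)[counts < config@minGenomes], current)
  curated <- if (curate && length(candidates)) {
    cc <- curateCandidates(candidates, genomes, features, current,
                           config@contextExclusivityMin,
                           config@localizationMin)
    cc[cc$accepted, c("family_id", "reason"), drop = FALSE]
  } else data.frame(family_id = character(0), reason = character(0))
  final <- union(current, curated$family_id)
  excluded <- data.frame(family_id = character(0), reason = character(0))
  if (!is.null(catalog) && length(config@exclusionRoles)) {
    roles <- familyRole(catalog, final)
    drop <- roles %in% config@exclusionRoles
    if (any(drop))
      excluded <- data.frame(family_id = final[drop],
                             reason = paste0("role:", roles[drop]),
                             stringsAsFactors = FALSE)
    final <- final[!drop]
  }
  asn <- lapply(genomes, function(gt) {
    g <- genes(gt)
    sel <- !is.na(g$family_id) & g$family_id %in% final
    data.frame(genome_id = rep(genomeId(gt), sum(sel)),
               gene_id = g$gene_id[sel], family_id = g$family_id[sel],
               product = g$product[sel], stringsAsFactors = FALSE)
  })
  asn <- do.call(rbind, asn)
  rownames(asn) <- NULL
  hyp <- grepl("hypothetical|uncharacterized", asn$product,
               ignore.case = TRUE)
  summ <- list(n_families = length(final), n_proteins = nrow(asn),
               fraction_hypothetical = if (nrow(asn)) mean(hyp) else NA_real_)
  new("CensusResult", acceptedByIteration = acc,
      finalFamilies = sort(final),
      curatedAdditions = curated, excludedFamilies = excluded,
      assignments = asn[, c("genome_id", "gene_id", "family_id")],
      summary = summ)
}

#' Count T4P systems per genome
#'
#' The number of T4P encoded in a genome is proxied by its number of
#' secretion-ATPase genes (genes, not families: duplicated ATPase genes mark
#' duplicated systems). Set `distinct_families = TRUE` to count distinct
#' ATPase families instead.
#'
#' @param genomes List of [GenomeTable-class].
#' @param atpase_families Family ids counted as secretion ATPases.
#' @param distinct_families Count families rather than genes.
#' @return Named integer vector, one entry per genome.
#' @export
countT4pPerGenome <- function(genomes, atpase_families,
                              distinct_families = FALSE) {
  vapply(genomes, function(gt) {
    fam <- genes(gt)$family_id
    fam <- fam[!is.na(fam) & fam %in% atpase_families]
    if (distinct_families) length(unique(fam)) else length(fam)
  }, 1L)
}

#' Phyletic pattern matrix
#'
#' Occurrence counts of each family in each genome (cell = number of genes),
#' with marginal sums as attributes `family_totals` and `genome_totals`.
#'
#' @param genomes List of [GenomeTable-class].
#' @param families Families to tabulate (rows).
#' @return Integer matrix families x genomes.
#' @export
phyleticMatrix <- function(genomes, families) {
  ids <- vapply(genomes, genomeId, "")
  m <- matrix(0L, nrow = length(families), ncol = length(genomes),
              dimnames = list(families, ids))
  for (j in seq_along(genomes)) {
    fam <- genes(genomes[[j]])$family_id
    tab <- table(fam[!is.na(fam) & fam %in% families])
    if (length(tab)) m[names(tab), j] <- as.integer(tab)
  }
  attr(m, "family_totals") <- rowSums(m)
  attr(m, "genome_totals") <- colSums(m)
  m
}
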