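## Major/minor pilin calling from the cues the census provides: class III
## signal-peptide fraction, mature length, stand-alone occurrence and
## per-genome paralogy. Major pilins are small (~70 aa mature), class III
## positive, and typically encoded by stand-alone (often tandem-duplicated)
## genes; other class-III-positive families in T4P loci are most likely minor
## pilins.

#' Fraction of a family's members encoded outside census loci
#'
#' Tandem runs of the same family outside loci (`type = "standalone"` in the
#' locus table) count as stand-alone.
#'
#' @param family_id One family id.
#' @param genomes List of [GenomeTable-class].
#' @param loci Locus table from [buildLoci()] (row-bound over genomes).
#' @return Fraction in \[0, 1\].
#' @export
standaloneFraction <- function(family_id, genomes, loci) {
  total <- 0L; inLoci <- 0L
  L <- loci[loci$type == "locus", , drop = FALSE]
  for (gt in genomes) {
    g <- genes(gt)
    mem <- which(!is.na(g$family_id) & g$family_id == family_id)
    if (!length(mem)) next
    total <- total + length(mem)
    Lg <- L[L$genome_id == genomeId(gt), , drop = FALSE]
    if (!nrow(Lg)) next
    for (i in mem) {
      hit <- Lg$contig_id == g$contig_id[i] &
        Lg$start_index <= g$order_index[i] & Lg$end_index >= g$order_index[i]
      if (any(hit)) inLoci <- inLoci + 1L
    }
  }
  if (total == 0L) stop("unknown family: ", family_id)
  1 - inLoci / total
}

#' Evidence table for pilin classification
#'
#' @param families Character vector of family ids.
#' @param genomes List of [GenomeTable-class].
#' @param features Feature calls from [computeFeatures()].
#' @param loci Locus table from [buildLoci()].
#' @return data.frame: `family_id`, `class3_fraction`,
#'   `median_mature_length`, `standalone_fraction`,
#'   `max_paralogs_per_genome`.
#' @export
pilinEvidence <- function(families, genomes, features, loci) {
  rows <- lapply(families, function(f) {
    fl <- features[!is.na(features$family_id) & features$family_id == f, ,
                   drop = FALSE]
    byg <- vapply(genomes, function(gt) {
      fam <- genes(gt)$family_id
      sum(!is.na(fam) & fam == f)
    }, 1L)
    data.frame(
      family_id = f,
      class3_fraction = if (nrow(fl)) mean(fl$sp_class == "class_III") else 0,
      median_mature_length = if (nrow(fl))
        as.integer(stats::median(fl$mature_length, na.rm = TRUE))
        else NA_integer_,
      standalone_fraction = standaloneFraction(f, genomes, loci),
      max_paralogs_per_genome = max(byg),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one family as major pilin, minor pilin, or non-pilin
#'
#' `major_pilin` iff class III fraction >= `class3_min` AND median mature
#' length <= `major_max_length` AND (stand-alone fraction >= 0.5 OR at least 2
#' paralogs in some genome); `minor_pilin` iff class III fraction >=
#' `class3_min` but not major; otherwise `non_pilin`. The 160 aa default
#' length bound separates ~70 aa majors (and PilA-family majors) from the
#' 250-550 aa minor pilins prone to duplication.
#'
#' @param evidence One row of [pilinEvidence()] (or a list with the same
#'   fields).
#' @param class3_min Minimum class III fraction to be any pilin.
#' @param major_max_length Maximum median mature length (aa) of a major.
#' @return One of `"major_pilin"`, `"minor_pilin"`, `"non_pilin"`.
#' @export
classifyPilinFamily <- function(evidence, class3_min = 0.8,
                                major_max_length = 160L) {
  if (is.na(evidence$class3_fraction) || evidence$class3_fraction < class3_min)
    return("non_pilin")
  isMajor <- !is.na(evidence$median_mature_length) &&
    evidence$median_mature_length <= major_max_length &&
    (evidence$standalone_fraction >= 0.5 ||
       evidence$max_paralogs_per_genome >= 2L)
  if (isMajor) "major_pilin" else "minor_pilin"
}

#' Pilin calls for a family set
#'
#' Evaluates [pilinEvidence()] and [classifyPilinFamily()] for every family;
#' each family receives exactly one call.
#'
#' @inheritParams pilinEvidence
#' @inheritParams classifyPilinFamily
#' @return The evidence data.frame with a `call` column.
#' @export
pilinCalls <- function(families, genomes, features, loci, class3_min = 0.8,
                       major_max_length = 160L) {
  ev <- pilinEvidence(families, genomes, features, loci)
  ev$call <- vapply(seq_len(nrow(ev)), function(i)
    classifyPilinFamily(ev[i, ], class3_min, major_max_length), "")
  ev
}
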