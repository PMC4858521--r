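## Operon prediction, locus assembly from census genes, and classification of
## loci against the declarative architecture templates.

#' Predict operons
#'
#' Maximal runs of same-strand, same-contig genes whose intergenic distance is
#' at most `max_gap_bp`. When coordinates are absent the fallback is
#' same-strand adjacency in gene order. Every gene belongs to exactly one
#' block.
#'
#' @param genome A [GenomeTable-class].
#' @param max_gap_bp Maximum intergenic gap within an operon (default 100).
#' @return List of character vectors of gene ids, in genome order.
#' @export
predictOperons <- function(genome, max_gap_bp = 100L) {
  g <- genes(genome)
  g <- g[order(g$contig_id, g$order_index), , drop = FALSE]
  n <- nrow(g)
  if (!n) return(list())
  newblock <- c(TRUE, vapply(seq_len(n)[-1L], function(i) {
    if (g$contig_id[i] != g$contig_id[i - 1L]) return(TRUE)
    if (g$strand[i] != g$strand[i - 1L]) return(TRUE)
    if (is.na(g$start[i]) || is.na(g$end[i - 1L])) return(FALSE)
    (g$start[i] - g$end[i - 1L] - 1L) > max_gap_bp
  }, TRUE))
  split(g$gene_id, cumsum(newblock))
}

#' Assemble census genes into loci
#'
#' Greedy left-to-right merge per contig: genes of final census families are
#' joined into one run while separated by at most `max_intervening` non-census
#' genes; run endpoints are census genes. Runs carrying at least two distinct
#' census families are loci (`type = "locus"`); runs of a single family
#' (singletons or tandem copies, characteristic of stand-alone major pilins)
#' are flagged `type = "standalone"`.
#'
#' @param genome A [GenomeTable-class].
#' @param final_families Census family set.
#' @param max_intervening Maximum non-census genes bridged inside a locus.
#' @return data.frame: `locus_id`, `genome_id`, `contig_id`, `start_index`,
#'   `end_index` (0-based order-index range, inclusive), `n_members`,
#'   `type`, `gene_ids`, `family_ids` (semicolon-joined, members only).
#' @export
buildLoci <- function(genome, final_families, max_intervening = 2L) {
  g <- genes(genome)
  out <- list()
  for (ct in unique(g$contig_id)) {
    sub <- g[g$contig_id == ct, , drop = FALSE]
    sub <- sub[order(sub$order_index), , drop = FALSE]
    hits <- which(!is.na(sub$family_id) & sub$family_id %in% final_families)
    if (!length(hits)) next
    run_start <- hits[1L]
    prev <- hits[1L]
    members <- hits[1L]
    flush <- function(members) {
      fams <- sub$family_id[members]
      out[[length(out) + 1L]] <<- data.frame(
        genome_id = genomeId(genome), contig_id = ct,
        start_index = sub$order_index[members[1L]],
        end_index = sub$order_index[members[length(members)]],
        n_members = length(members),
        type = if (length(unique(fams)) >= 2L) "locus" else "standalone",
        gene_ids = paste(sub$gene_id[members], collapse = ";"),
        family_ids = paste(fams, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    for (i in hits[-1L]) {
      if (i - prev - 1L <= max_intervening) {
        members <- c(members, i)
      } else {
        flush(members)
        members <- i
      }
      prev <- i
    }
    flush(members)
  }
  if (!length(out))
    return(data.frame(locus_id = character(0), genome_id = character(0),
                      contig_id = character(0), start_index = integer(0),
                      end_index = integer(0), n_members = integer(0),
                      type = character(0), gene_ids = character(0),
                      family_ids = character(0)))
  tab <- do.call(rbind, out)
  tab <- cbind(locus_id = sprintf("%s_L%03d", genomeId(genome),
                                  seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}

# role of each family: catalog first, then pilin calls, then localization
.familyRoles <- function(families, catalog = NULL, pilin_calls = NULL,
                         features = NULL) {
  roles <- if (!is.null(catalog)) familyRole(catalog, families)
           else rep("unknown", length(families))
  if (!is.null(pilin_calls)) {
    idx <- match(families, pilin_calls$family_id)
    use <- roles == "unknown" & !is.na(idx) &
      pilin_calls$call[idx] %in% c("major_pilin", "minor_pilin")
    roles[use] <- pilin_calls$call[idx[use]]
  }
  if (!is.null(features)) {
    for (i in which(roles == "unknown")) {
      loc <- features$localization[!is.na(features$family_id) &
                                     features$family_id == families[i]]
      if (!length(loc)) next
      mode <- names(sort(table(loc), decreasing = TRUE))[1L]
      roles[i] <- switch(mode, membrane = "membrane_accessory",
                         cytoplasmic = "cytoplasmic_accessory",
                         secreted = "adhesin", "unknown")
    }
  }
  roles
}

# multiset of roles carried by one locus row
.locusRoleCounts <- function(locus_row, catalog = NULL, pilin_calls = NULL,
                             features = NULL) {
  fams <- strsplit(locus_row$family_ids, ";", fixed = TRUE)[[1L]]
  roles <- .familyRoles(fams, catalog, pilin_calls, features)
  table(roles)
}

#' Score a locus against one architecture template
#'
#' The score is the fraction of required role multiplicity ranges satisfied,
#' minus 1.0 when any forbidden role is present (floored at 0). A required
#' `major_pilin` with zero in-locus copies is satisfied when the genome
#' carries stand-alone major pilins (`in_trans_major = TRUE`): major pilins
#' are frequently encoded in trans.
#'
#' @param role_counts Named table/vector of role counts in the locus.
#' @param template An [ArchitectureTemplate-class].
#' @param in_trans_major Does the genome carry stand-alone major pilins?
#' @return Numeric score in \[0, 1\].
#' @export
scoreLocus <- function(role_counts, template, in_trans_major = FALSE) {
  cnt <- function(r) if (r %in% names(role_counts))
    as.integer(role_counts[[r]]) else 0L
  req <- template@required
  sat <- vapply(names(req), function(r) {
    k <- cnt(r)
    ok <- k >= req[[r]][1L] && k <= req[[r]][2L]
    if (!ok && r == "major_pilin" && k == 0L && in_trans_major) ok <- TRUE
    ok
  }, TRUE)
  frac <- sum(sat) / length(req)
  forb <- any(vapply(template@forbidden, function(r) cnt(r) > 0L, TRUE))
  max(0, frac - as.numeric(forb))
}

#' Classify a locus against the template library
#'
#' Scores the locus against every template; the best-scoring template wins,
#' with ties broken by specificity (more required roles) then template name;
#' loci whose best score is below `min_score` are `"unclassified"`.
#'
#' @param role_counts Named role-count table for the locus (see
#'   [classifyLoci()] for the full pipeline version).
#' @param templates List of [ArchitectureTemplate-class].
#' @param in_trans_major Does the genome carry stand-alone major pilins?
#' @param min_score Classification threshold (default 0.6).
#' @return List with `template` (name or `"unclassified"`) and `score`.
#' @export
classifyLocus <- function(role_counts, templates, in_trans_major = FALSE,
                          min_score = 0.6) {
  scores <- vapply(templates, scoreLocus, 1.0, role_counts = role_counts,
                   in_trans_major = in_trans_major)
  nreq <- vapply(templates, function(t) length(t@required), 1L)
  nms <- vapply(templates, function(t) t@name, "")
  ord <- order(-scores, -nreq, nms)
  best <- ord[1L]
  if (scores[best] < min_score)
    return(list(template = "unclassified", score = unname(scores[best])))
  list(template = unname(nms[best]), score = unname(scores[best]))
}

#' Classify all loci of a collection
#'
#' Adds `roles_present`, `classification` and `score` columns to a locus
#' table. Genome context (stand-alone major pilin availability, for the
#' in-trans rule) is derived from `standalone`-type runs whose family is a
#' major pilin by catalog role or pilin call.
#'
#' @param loci Locus data.frame rows from [buildLoci()] (possibly several
#'   genomes row-bound).
#' @param templates List of [ArchitectureTemplate-class].
#' @param catalog Optional [FamilyCatalog-class].
#' @param pilin_calls Optional data.frame from [pilinCalls()].
#' @param features Optional feature calls (role fallback for unknown
#'   families).
#' @param min_score Classification threshold.
#' @return The locus data.frame with classification columns; `standalone`
#'   runs are left `"unclassified"` with score `NA`.
#' @export
classifyLoci <- function(loci, templates, catalog = NULL, pilin_calls = NULL,
                         features = NULL, min_score = 0.6) {
  majorFams <- character(0)
  if (!is.null(catalog)) majorFams <- familiesWithRole(catalog, "major_pilin")
  if (!is.null(pilin_calls))
    majorFams <- union(majorFams,
                       pilin_calls$family_id[pilin_calls$call == "major_pilin"])
  sa <- loci[loci$type == "standalone", , drop = FALSE]
  ctx <- stats::setNames(vapply(unique(loci$genome_id), function(gid) {
    fams <- unlist(strsplit(sa$family_ids[sa$genome_id == gid], ";",
                            fixed = TRUE))
    any(fams %in% majorFams)
  }, TRUE), unique(loci$genome_id))
  loci$roles_present <- NA_character_
  loci$classification <- "unclassified"
  loci$score <- NA_real_
  for (i in seq_len(nrow(loci))) {
    if (loci$type[i] != "locus") next
    rc <- .locusRoleCounts(loci[i, ], catalog, pilin_calls, features)
    loci$roles_present[i] <- paste(paste0(names(rc), ":", as.integer(rc)),
                                   collapse = ";")
    cl <- classifyLocus(rc, templates, in_trans_major = ctx[[loci$genome_id[i]]],
                        min_score = min_score)
    loci$classification[i] <- cl$template
    loci$score[i] <- cl$score
  }
  loci
}

#' Check archaellum completeness in one genome
#'
#' The archaellum needs genes for its seven components: the ATPase FlaI, the
#' ATP-binding protein FlaH, the membrane platform FlaJ, minor archaellins
#' FlaF and FlaG (one copy each), 1-9 major archaellins (FlaA/FlaB) and 1-3
#' FlaC/D/E genes (fused DE or CDE genes count once per gene). Stand-alone
#' archaellins encoded outside the archaellum locus count toward the
#' archaellin multiplicity.
#'
#' @param genome A [GenomeTable-class].
#' @param loci Classified locus table from [classifyLoci()] (all genomes or
#'   just this one).
#' @param catalog A [FamilyCatalog-class] assigning archaellum roles.
#' @return List: `complete` (logical), `missing` (roles with zero copies),
#'   `violations` (roles present but outside their multiplicity range) and
#'   `multiplicities` (named integer vector).
#' @export
checkArchaellumCompleteness <- function(genome, loci, catalog) {
  gid <- genomeId(genome)
  g <- genes(genome)
  arch <- loci[loci$genome_id == gid & loci$type == "locus" &
                 loci$classification == "archaellum", , drop = FALSE]
  fams <- unlist(strsplit(arch$family_ids, ";", fixed = TRUE))
  roles <- .familyRoles(fams, catalog)
  counts <- table(roles)
  cnt <- function(r) if (r %in% names(counts)) as.integer(counts[[r]]) else 0L
  need <- list(secretion_ATPase = c(1L, 1L), flaH = c(1L, 1L),
               tadC = c(1L, 1L), flaF = c(1L, 1L), flaG = c(1L, 1L),
               archaellin = c(1L, 9L), flaCDE = c(1L, 3L))
  # stand-alone archaellins elsewhere in the genome count
  inLocus <- unlist(lapply(seq_len(nrow(arch)), function(i)
    strsplit(arch$gene_ids[i], ";", fixed = TRUE)[[1L]]))
  allArch <- g$gene_id[!is.na(g$family_id) &
                         familyRole(catalog, g$family_id) == "archaellin"]
  nArch <- cnt("archaellin") + sum(!allArch %in% inLocus)
  mult <- vapply(names(need), cnt, 1L)
  mult[["archaellin"]] <- nArch
  missing <- names(need)[mult == 0L]
  viol <- names(need)[vapply(names(need), function(r)
    mult[[r]] > 0L && (mult[[r]] < need[[r]][1L] || mult[[r]] > need[[r]][2L]),
    TRUE)]
  list(complete = length(missing) == 0L && length(viol) == 0L,
       missing = missing, violations = viol, multiplicities = mult)
}
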