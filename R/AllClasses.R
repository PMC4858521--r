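#' @import methods
NULL

#' Role vocabulary for T4P component families
#'
#' Controlled vocabulary of functional roles a gene family can play in an
#' archaeal type IV pilus (T4P) or archaellum system. `secretion_ATPase` is the
#' VirB11/FlaI-family energizing ATPase used as census seed and system-count
#' proxy; `tadC` the FlaJ/TadC membrane platform; `flaH`, `flaF`, `flaG`,
#' `flaCDE` the remaining dedicated archaellum components; `archaellin` the
#' FlaA/FlaB filament subunits; `peptidase_5TM`/`peptidase_9TM` the two
#' prepilin-peptidase subfamilies (PibD/FlaK vs EppA). Families without an
#' assigned role default to `unknown`.
#'
#' @return Character vector of valid role labels.
#' @export
t4pRoles <- function() {
  c("secretion_ATPase", "tadC", "flaH", "fleN_minD",
    "major_pilin", "minor_pilin", "archaellin",
    "flaF", "flaG", "flaCDE",
    "peptidase_5TM", "peptidase_9TM",
    "adhesin", "s_layer",
    "membrane_accessory", "cytoplasmic_accessory",
    "regulator", "unknown")
}

.geneColumns <- c("contig_id", "order_index", "gene_id", "strand",
                  "start", "end", "family_id", "product", "protein_seq")

#' GenomeTable: ordered gene models of one genome
#'
#' Container for the gene complement of a single genome: one row per gene with
#' contig, 0-based order index along the contig, strand, optional 1-based
#' inclusive nucleotide coordinates, optional family label (arCOG-like),
#' product annotation and optional protein sequence. All neighborhood logic
#' operates on gene order, not nucleotide distance.
#'
#' @slot genomeId Genome identifier.
#' @slot lineage Ordered taxon labels (e.g. phylum to order); may be empty.
#' @slot genes data.frame with columns `contig_id`, `order_index`, `gene_id`,
#'   `strand`, `start`, `end`, `family_id`, `product`, `protein_seq`.
#'
#' @export
setClass("GenomeTable",
  representation(genomeId = "character", lineage = "character",
                 genes = "data.frame"))

setValidity("GenomeTable", function(object) {
  g <- object@genes
  msgs <- character(0)
  if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msgs <- c(msgs, "genomeId must be a single non-empty string")
  miss <- setdiff(.geneColumns, names(g))
  if (length(miss))
    return(paste("missing gene columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    msgs <- c(msgs, paste0("duplicate gene_id: ",
                           g$gene_id[duplicated(g$gene_id)][1L]))
  bad <- !g$strand %in% c("+", "-")
  if (any(bad))
    msgs <- c(msgs, paste0("invalid strand '", g$strand[bad][1L], "'"))
  for (ct in unique(g$contig_id)) {
    oi <- sort(g$order_index[g$contig_id == ct])
    if (!identical(as.integer(oi), seq.int(0L, length(oi) - 1L)))
      msgs <- c(msgs, paste0("order_index not consecutive 0..n-1 on contig ",
                             ct))
  }
  one <- xor(is.na(g$start), is.na(g$end))
  if (any(one))
    msgs <- c(msgs, "start/end must be both present or both absent")
  both <- !is.na(g$start) & !is.na(g$end)
  if (any(g$start[both] > g$end[both]))
    msgs <- c(msgs, "start must be <= end")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeTable
#'
#' Builds a validated [GenomeTable-class] from a gene data.frame. Genes are
#' sorted by contig and by the supplied `order_index` (falling back to `start`
#' coordinate, then input order), and `order_index` is renumbered to the
#' consecutive 0..n-1 convention per contig.
#'
#' @param genomeId Genome identifier.
#' @param genes data.frame carrying at least `contig_id`, `gene_id`, `strand`;
#'   missing optional columns are added as NA.
#' @param lineage Character vector of taxon labels.
#' @return A `GenomeTable`.
#' @examples
#' gt <- GenomeTable("g1", data.frame(
#'   contig_id = "c1", gene_id = c("a", "b"), strand = "+",
#'   stringsAsFactors = FALSE))
#' nGenes(gt)
#' @export
GenomeTable <- function(genomeId, genes, lineage = character(0)) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"order_index" %in% names(genes)) genes$order_index <- NA_integer_
  for (col in c("start", "end")) if (!col %in% names(genes))
    genes[[col]] <- NA_integer_
  for (col in c("family_id", "product", "protein_seq"))
    if (!col %in% names(genes)) genes[[col]] <- NA_character_
  genes$order_index <- as.integer(genes$order_index)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  for (col in c("contig_id", "gene_id", "strand", "family_id", "product",
                "protein_seq"))
    genes[[col]] <- as.character(genes[[col]])
  key <- ifelse(is.na(genes$order_index),
                ifelse(is.na(genes$start), seq_len(nrow(genes)), genes$start),
                genes$order_index)
  genes <- genes[order(genes$contig_id, key), , drop = FALSE]
  genes$order_index <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                                  FUN = seq_along) - 1L
  genes <- genes[, .geneColumns, drop = FALSE]
  rownames(genes) <- NULL
  new("GenomeTable", genomeId = as.character(genomeId),
      lineage = as.character(lineage), genes = genes)
}

#' FamilyCatalog: role and clade annotation for gene families
#'
#' Maps family identifiers to a functional [t4pRoles()] role and an optional
#' secretion-ATPase tree clade label (e.g. "1", "2", "3", "4A".."4J").
#' Families absent from the catalog default to role `unknown`.
#'
#' @slot families data.frame with columns `family_id`, `role`, `clade_label`.
#' @export
setClass("FamilyCatalog", representation(families = "data.frame"))

setValidity("FamilyCatalog", function(object) {
  f <- object@families
  if (!all(c("family_id", "role", "clade_label") %in% names(f)))
    return("families needs columns family_id, role, clade_label")
  if (anyDuplicated(f$family_id))
    return("duplicate family_id in catalog")
  bad <- setdiff(unique(f$role), t4pRoles())
  if (length(bad)) return(paste("unknown role(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a FamilyCatalog
#'
#' @param family_id Character vector of family identifiers.
#' @param role Roles from [t4pRoles()] (recycled).
#' @param clade_label Optional clade tags (recycled; NA allowed).
#' @return A `FamilyCatalog`.
#' @export
FamilyCatalog <- function(family_id = character(0), role = character(0),
                          clade_label = NA_character_) {
  n <- length(family_id)
  new("FamilyCatalog", families = data.frame(
    family_id = as.character(family_id),
    role = rep_len(as.character(role), n),
    clade_label = rep_len(as.character(clade_label), n),
    stringsAsFactors = FALSE))
}

#' CensusConfig: parameters of the iterative neighborhood census
#'
#' Defaults follow the census protocol: neighborhoods of three genes up- and
#' downstream, candidate families accepted when seen in five or more genomes,
#' three expansion iterations, S-layer families excluded from the final set
#' (kept aside as potential components).
#'
#' @slot seedFamilies Seed family identifiers (the known T4P ATPase families).
#' @slot window Genes up- and downstream defining a neighborhood.
#' @slot minGenomes Distinct-genome threshold for accepting a family.
#' @slot iterations Number of expansion iterations.
#' @slot exclusionRoles Roles removed from the final set after curation.
#' @slot contextExclusivityMin Minimum fraction of a curated family's members
#'   that must lie inside candidate loci ("never occurred in a different gene
#'   context" surrogate).
#' @slot localizationMin Minimum fraction of members predicted secreted or
#'   membrane for automated curation.
#' @export
setClass("CensusConfig",
  representation(seedFamilies = "character", window = "integer",
                 minGenomes = "integer", iterations = "integer",
                 exclusionRoles = "character",
                 contextExclusivityMin = "numeric",
                 localizationMin = "numeric"))

setValidity("CensusConfig", function(object) {
  msgs <- character(0)
  if (object@window < 1L) msgs <- c(msgs, "window must be >= 1")
  if (object@minGenomes < 1L) msgs <- c(msgs, "minGenomes must be >= 1")
  if (object@iterations < 1L) msgs <- c(msgs, "iterations must be >= 1")
  if (object@contextExclusivityMin < 0 || object@contextExclusivityMin > 1)
    msgs <- c(msgs, "contextExclusivityMin must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CensusConfig-class
#' @param seedFamilies,window,minGenomes,iterations,exclusionRoles See slots.
#' @param contextExclusivityMin,localizationMin See slots.
#' @return A `CensusConfig`.
#' @export
CensusConfig <- function(seedFamilies, window = 3L, minGenomes = 5L,
                         iterations = 3L, exclusionRoles = "s_layer",
                         contextExclusivityMin = 1.0, localizationMin = 0.8) {
  new("CensusConfig", seedFamilies = as.character(seedFamilies),
      window = as.integer(window), minGenomes = as.integer(minGenomes),
      iterations = as.integer(iterations),
      exclusionRoles = as.character(exclusionRoles),
      contextExclusivityMin = contextExclusivityMin,
      localizationMin = localizationMin)
}

#' CensusResult: outcome of the iterative census
#'
#' @slot acceptedByIteration List of family-id vectors, one per iteration
#'   (non-decreasing chain, starting from the seeds).
#' @slot finalFamilies Families in the final T4P-linked set.
#' @slot curatedAdditions data.frame `family_id`, `reason` for sub-threshold
#'   families admitted by automated curation.
#' @slot excludedFamilies data.frame `family_id`, `reason` for families removed
#'   by role (retained here as "potential components").
#' @slot assignments data.frame `genome_id`, `gene_id`, `family_id`: every gene
#'   of a final family.
#' @slot summary list with `n_families`, `n_proteins`, `fraction_hypothetical`.
#' @export
setClass("CensusResult",
  representation(acceptedByIteration = "list", finalFamilies = "character",
                 curatedAdditions = "data.frame",
                 excludedFamilies = "data.frame",
                 assignments = "data.frame", summary = "list"))

setValidity("CensusResult", function(object) {
  sets <- object@acceptedByIteration
  if (length(sets) > 1L)
    for (i in seq_len(length(sets) - 1L))
      if (!all(sets[[i]] %in% sets[[i + 1L]]))
        return("accepted family sets must be non-decreasing across iterations")
  if (nrow(object@assignments) &&
      !all(object@assignments$family_id %in% object@finalFamilies))
    return("every assignment's family must be in finalFamilies")
  TRUE
})

#' ArchitectureTemplate: declarative model of one T4P system variant
#'
#' A template lists, per role, the multiplicity range a conforming locus must
#' carry (`required`), roles that must not occur (`forbidden`) and roles that
#' may occur without affecting the score (`optional`).
#'
#' @slot name Template name.
#' @slot required Named list; each element an integer c(min, max) multiplicity
#'   range for a role.
#' @slot forbidden Roles that disqualify a locus.
#' @slot optional Tolerated accessory roles.
#' @export
setClass("ArchitectureTemplate",
  representation(name = "character", required = "list",
                 forbidden = "character", optional = "character"))

setValidity("ArchitectureTemplate", function(object) {
  if (length(intersect(names(object@required), object@forbidden)))
    return("required and forbidden roles must be disjoint")
  for (r in object@required)
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 0L)
      return("each required entry must be c(min, max) with 0 <= min <= max")
  TRUE
})

#' @rdname ArchitectureTemplate-class
#' @param name,required,forbidden,optional See slots.
#' @return An `ArchitectureTemplate`.
#' @export
ArchitectureTemplate <- function(name, required, forbidden = character(0),
                                 optional = character(0)) {
  required <- lapply(required, function(x) as.integer(rep_len(x, 2L)))
  new("ArchitectureTemplate", name = name, required = required,
      forbidden = as.character(forbidden), optional = as.character(optional))
}

#' SyntheticCollection: generated genomes plus planted ground truth
#'
#' @slot genomes List of [GenomeTable-class].
#' @slot truth List with elements `planted_loci` (data.frame genome_id,
#'   contig_id, start_index, end_index, template), `role_of_family` (named
#'   character), `expected_t4p_count` (named integer per genome),
#'   `standalone_genes` (data.frame genome_id, gene_id, family_id),
#'   `operons` (data.frame genome_id, contig_id, block_id, gene_id) and
#'   `hgt_events` (data.frame).
#' @slot catalog [FamilyCatalog-class] for the planted families.
#' @slot params The generator parameter list used.
#' @export
setClass("SyntheticCollection",
  representation(genomes = "list", truth = "list", catalog = "FamilyCatalog",
                 params = "list"))

## ---- accessors ----

#' @describeIn GenomeTable-class Genome identifier.
#' @param object,x A `GenomeTable`.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname GenomeTable-class
#' @export
setMethod("genomeId", "GenomeTable", function(x) x@genomeId)

#' @rdname GenomeTable-class
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @rdname GenomeTable-class
#' @export
setMethod("lineage", "GenomeTable", function(x) x@lineage)

#' @rdname GenomeTable-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GenomeTable-class
#' @export
setMethod("genes", "GenomeTable", function(x) x@genes)

#' @rdname GenomeTable-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname GenomeTable-class
#' @export
setMethod("nGenes", "GenomeTable", function(x) nrow(x@genes))

setMethod("show", "GenomeTable", function(object) {
  cat("GenomeTable", object@genomeId, "|", nrow(object@genes), "genes on",
      length(unique(object@genes$contig_id)), "contig(s)\n")
  if (length(object@lineage))
    cat("  lineage:", paste(object@lineage, collapse = "; "), "\n")
})

#' Look up family roles
#'
#' Returns the catalog role for each family id, defaulting to `"unknown"`
#' for families absent from the catalog (or NA family ids).
#'
#' @param catalog A [FamilyCatalog-class].
#' @param family_id Character vector of family ids.
#' @return Character vector of roles, same length as `family_id`.
#' @export
familyRole <- function(catalog, family_id) {
  stopifnot(is(catalog, "FamilyCatalog"))
  idx <- match(family_id, catalog@families$family_id)
  role <- catalog@families$role[idx]
  role[is.na(role)] <- "unknown"
  role
}

#' Families carrying a given role
#'
#' @param catalog A [FamilyCatalog-class].
#' @param role One or more roles from [t4pRoles()].
#' @return Character vector of family ids.
#' @export
familiesWithRole <- function(catalog, role) {
  f <- catalog@families
  f$family_id[f$role %in% role]
}

setMethod("show", "FamilyCatalog", function(object) {
  tab <- table(object@families$role)
  cat("FamilyCatalog with", nrow(object@families), "families\n")
  cat(" ", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

#' @describeIn CensusResult-class Final accepted family set.
#' @param x A `CensusResult`.
#' @export
setGeneric("finalFamilies", function(x) standardGeneric("finalFamilies"))

#' @rdname CensusResult-class
#' @export
setMethod("finalFamilies", "CensusResult", function(x) x@finalFamilies)

#' @rdname CensusResult-class
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname CensusResult-class
#' @export
setMethod("assignments", "CensusResult", function(x) x@assignments)

#' @rdname CensusResult-class
#' @export
setGeneric("acceptedByIteration", function(x)
  standardGeneric("acceptedByIteration"))

#' @rdname CensusResult-class
#' @export
setMethod("acceptedByIteration", "CensusResult",
          function(x) x@acceptedByIteration)

#' @rdname CensusResult-class
#' @export
setGeneric("censusSummary", function(x) standardGeneric("censusSummary"))

#' @rdname CensusResult-class
#' @export
setMethod("censusSummary", "CensusResult", function(x) x@summary)

#' @rdname CensusResult-class
#' @export
setGeneric("excludedFamilies", function(x) standardGeneric("excludedFamilies"))

#' @rdname CensusResult-class
#' @export
setMethod("excludedFamilies", "CensusResult", function(x) x@excludedFamilies)

#' @rdname CensusResult-class
#' @export
setGeneric("curatedAdditions", function(x) standardGeneric("curatedAdditions"))

#' @rdname CensusResult-class
#' @export
setMethod("curatedAdditions", "CensusResult", function(x) x@curatedAdditions)

setMethod("show", "CensusResult", function(object) {
  cat("CensusResult:", length(object@finalFamilies), "families,",
      nrow(object@assignments), "protein assignments\n")
  cat("  iterations:",
      paste(vapply(object@acceptedByIteration, length, 1L), collapse = " -> "),
      "\n")
  cat("  curated additions:", nrow(object@curatedAdditions),
      "| excluded (potential components):", nrow(object@excludedFamilies), "\n")
})

setMethod("show", "ArchitectureTemplate", function(object) {
  req <- vapply(names(object@required), function(r) {
    rng <- object@required[[r]]
    if (rng[1L] == rng[2L]) paste0(r, ":", rng[1L])
    else paste0(r, ":", rng[1L], "-", rng[2L])
  }, "")
  cat("ArchitectureTemplate", object@name, "\n  required:",
      paste(req, collapse = " "), "\n")
  if (length(object@forbidden))
    cat("  forbidden:", paste(object@forbidden, collapse = " "), "\n")
})

setMethod("show", "SyntheticCollection", function(object) {
  cat("SyntheticCollection:", length(object@genomes), "genomes,",
      nrow(object@truth$planted_loci), "planted loci\n")
})

#' @describeIn SyntheticCollection-class List of genome tables.
#' @param x A `SyntheticCollection`.
#' @export
setGeneric("collectionGenomes", function(x) standardGeneric("collectionGenomes"))

#' @rdname SyntheticCollection-class
#' @export
setMethod("collectionGenomes", "SyntheticCollection", function(x) x@genomes)

#' @rdname SyntheticCollection-class
#' @export
setGeneric("collectionTruth", function(x) standardGeneric("collectionTruth"))

#' @rdname SyntheticCollection-class
#' @export
setMethod("collectionTruth", "SyntheticCollection", function(x) x@truth)

#' @rdname SyntheticCollection-class
#' @export
setGeneric("collectionCatalog", function(x) standardGeneric("collectionCatalog"))

#' @rdname SyntheticCollection-class
#' @export
setMethod("collectionCatalog", "SyntheticCollection", function(x) x@catalog)
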