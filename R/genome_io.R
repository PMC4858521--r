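## Gene-table TSV dialect and GFF3+FASTA ingestion, plus neighborhood access.
## Coordinates are 1-based inclusive (GFF3 convention); order_index is 0-based
## and counts genes, not base pairs. Contigs are linear: neighborhoods truncate
## at contig ends and never cross contigs.

.tableColumns <- c("genome_id", "lineage", "contig_id", "order_index",
                   "gene_id", "strand", "start", "end", "family_id",
                   "product", "protein_seq")

.blank2na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Read a genome gene table (TSV dialect)
#'
#' Parses the tab-separated gene-table dialect (one gene per row; columns
#' `genome_id`, `lineage`, `contig_id`, `order_index`, `gene_id`, `strand`,
#' `start`, `end`, `family_id`, `product`, `protein_seq`; empty string means
#' absent; `lineage` is a semicolon-joined taxon path) into one
#' [GenomeTable-class] per distinct genome. `order_index` is renumbered to the
#' consecutive 0..n-1 convention per contig.
#'
#' @param path Path to the TSV file (a header row is required).
#' @return Named list of `GenomeTable`, one per genome id.
#' @seealso [writeGeneTable()], [readGffFasta()]
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "")
  miss <- setdiff(.tableColumns, names(raw))
  if (length(miss))
    stop("gene table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  # line number in file = data row + 1 (header)
  bad <- which(!raw$strand %in% c("+", "-"))
  if (length(bad))
    stop("gene table validation error: invalid strand '",
         raw$strand[bad[1L]], "' on line ", bad[1L] + 1L)
  for (col in c("family_id", "product", "protein_seq", "lineage"))
    raw[[col]] <- .blank2na(raw[[col]])
  for (col in c("order_index", "start", "end")) {
    v <- suppressWarnings(as.integer(.blank2na(raw[[col]])))
    newly <- !is.na(.blank2na(raw[[col]])) & is.na(v)
    if (any(newly))
      stop("gene table validation error: non-integer ", col, " on line ",
           which(newly)[1L] + 1L)
    raw[[col]] <- v
  }
  out <- list()
  for (gid in unique(raw$genome_id)) {
    sub <- raw[raw$genome_id == gid, , drop = FALSE]
    if (anyDuplicated(sub$gene_id))
      stop("gene table validation error: duplicate gene_id '",
           sub$gene_id[duplicated(sub$gene_id)][1L], "' in genome ", gid)
    lin <- sub$lineage[!is.na(sub$lineage)]
    lin <- if (length(lin)) strsplit(lin[1L], ";", fixed = TRUE)[[1L]]
           else character(0)
    out[[gid]] <- GenomeTable(gid, sub[, .geneColumns], lineage = lin)
  }
  out
}

#' Write genome tables in the gene-table TSV dialect
#'
#' Inverse of [readGeneTable()]: writing then re-reading reproduces the tables
#' field by field.
#'
#' @param genomes A `GenomeTable` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genomes, path) {
  if (is(genomes, "GenomeTable")) genomes <- list(genomes)
  rows <- lapply(genomes, function(gt) {
    g <- genes(gt)
    data.frame(genome_id = genomeId(gt),
               lineage = paste(lineage(gt), collapse = ";"),
               g[, .geneColumns], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[] <- lapply(tab, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome from GFF3 + protein FASTA
#'
#' Imports CDS (fallback: gene) features from a GFF3 file, orders them by start
#' coordinate per contig, assigns 0-based `order_index` from that ordering, and
#' attaches protein sequences from an amino-acid FASTA whose ids match the GFF
#' feature `ID` attributes. Family labels are taken from a configurable GFF
#' attribute (default `family`). FASTA records with no matching feature are
#' dropped with a warning.
#'
#' @param gff_path GFF3 file path.
#' @param fasta_path Protein FASTA path (may contain zero records).
#' @param genome_id Genome identifier; default: GFF file name without extension.
#' @param family_attr GFF attribute key holding the family label.
#' @return A [GenomeTable-class].
#' @export
readGffFasta <- function(gff_path, fasta_path, genome_id = NULL,
                         family_attr = "family") {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(gff_path))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "gene")
  if (any(as.character(gr$type) == "CDS"))
    keep <- as.character(gr$type) == "CDS"
  gr <- gr[keep]
  md <- as.data.frame(gr)
  fam <- if (family_attr %in% names(md)) as.character(md[[family_attr]])
         else rep(NA_character_, nrow(md))
  genes <- data.frame(
    contig_id = as.character(md$seqnames),
    gene_id = as.character(md$ID),
    strand = ifelse(as.character(md$strand) == "-", "-", "+"),
    start = md$start, end = md$end,
    family_id = fam,
    product = if ("product" %in% names(md)) as.character(md$product)
              else NA_character_,
    protein_seq = NA_character_,
    stringsAsFactors = FALSE)
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa)) {
    ids <- sub("\\s.*$", "", names(aa))
    hit <- match(ids, genes$gene_id)
    if (anyNA(hit))
      warning("dropping ", sum(is.na(hit)),
              " FASTA record(s) absent from GFF: ",
              paste(utils::head(ids[is.na(hit)], 3L), collapse = ", "))
    ok <- !is.na(hit)
    genes$protein_seq[hit[ok]] <- as.character(aa[ok])
  }
  GenomeTable(genome_id, genes)
}

#' Write a genome as GFF3 + protein FASTA
#'
#' @param genome A [GenomeTable-class] with coordinates present.
#' @param gff_path,fasta_path Output paths.
#' @param family_attr GFF attribute key for the family label.
#' @return Invisibly, `c(gff_path, fasta_path)`.
#' @export
writeGffFasta <- function(genome, gff_path, fasta_path,
                          family_attr = "family") {
  g <- genes(genome)
  if (anyNA(g$start)) stop("coordinates required for GFF export")
  attrs <- paste0("ID=", g$gene_id)
  hasfam <- !is.na(g$family_id)
  attrs[hasfam] <- paste0(attrs[hasfam], ";", family_attr, "=",
                          g$family_id[hasfam])
  hasprod <- !is.na(g$product)
  attrs[hasprod] <- paste0(attrs[hasprod], ";product=", g$product[hasprod])
  lines <- c("##gff-version 3",
             paste(g$contig_id, "T4PCensus", "CDS", g$start, g$end, ".",
                   g$strand, "0", attrs, sep = "\t"))
  writeLines(lines, gff_path)
  withseq <- !is.na(g$protein_seq)
  aa <- Biostrings::AAStringSet(g$protein_seq[withseq])
  names(aa) <- g$gene_id[withseq]
  Biostrings::writeXStringSet(aa, fasta_path)
  invisible(c(gff_path, fasta_path))
}

#' Gene-order neighborhood of a focal gene
#'
#' Returns the focal gene plus up to `window` genes up- and downstream in gene
#' order on the same contig (so at most `2*window + 1` records), truncated at
#' contig ends. Neighborhoods are defined by gene order, not nucleotide
#' distance, and never cross contigs; the focal gene's strand does not reorient
#' the result.
#'
#' @param genome A [GenomeTable-class].
#' @param gene_id Focal gene identifier.
#' @param window Non-negative number of genes on each side (default 3, the
#'   census convention).
#' @return data.frame of gene records ordered by `order_index`.
#' @examples
#' gt <- GenomeTable("g", data.frame(contig_id = "c",
#'   gene_id = paste0("g", 1:10), strand = "+"))
#' nrow(neighborhood(gt, "g5", 3))  # 7
#' @export
neighborhood <- function(genome, gene_id, window = 3L) {
  stopifnot(window >= 0L)
  g <- genes(genome)
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  ct <- g$contig_id[i]
  oi <- g$order_index[i]
  sel <- g$contig_id == ct & g$order_index >= oi - window &
    g$order_index <= oi + window
  out <- g[sel, , drop = FALSE]
  out[order(out$order_index), , drop = FALSE]
}

#' Export loci as BED
#'
#' Converts locus nucleotide ranges (1-based inclusive, taken from member gene
#' coordinates) to BED's 0-based half-open convention.
#'
#' @param loci Locus data.frame as returned by [buildLoci()].
#' @param genomes Named list of [GenomeTable-class] supplying coordinates.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeLociBed <- function(loci, genomes, path) {
  rows <- character(0)
  for (i in seq_len(nrow(loci))) {
    gt <- genomes[[loci$genome_id[i]]]
    g <- genes(gt)
    sel <- g$contig_id == loci$contig_id[i] &
      g$order_index >= loci$start_index[i] &
      g$order_index <= loci$end_index[i]
    if (!any(sel) || anyNA(g$start[sel])) next
    rows <- c(rows, paste(loci$contig_id[i], min(g$start[sel]) - 1L,
                          max(g$end[sel]), loci$locus_id[i], sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
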