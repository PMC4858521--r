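## Synthetic genome-collection generator with planted ground truth.
##
## Protein sequences are emitted from two fixed composition profiles
## (hydrophobic- vs hydrophilic-enriched) so that the feature detectors
## succeed or fail by construction: pilins get class III leaders, membrane
## accessories get TM segments, background proteins are hydrophilic with no
## motif. Family labels are arranged so that the census min_genomes threshold
## is decisive: interior background families recur across genomes (Zipf-like,
## exponent 1.5) but never inside seed neighborhoods, while the gene margins
## flanking planted loci draw from a "rare" pool capped at 4 genomes per
## family.

.hydrophobicPool <- c("I", "L", "V", "F")
.hydrophilicPool <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H",
                      "P", "Y")

.sampleAA <- function(pool, n) paste(sample(pool, n, replace = TRUE),
                                     collapse = "")

#' Default generator parameters (the study conditions)
#'
#' The default collection has 30 genomes; each of the eleven built-in
#' architecture templates is planted in 5 genomes (55 systems in all),
#' distributed so that per-genome system counts take every value from 1 to 7.
#' Major pilins go in trans (stand-alone, outside the locus) for half the
#' systems; archaellin paralog counts are drawn from 1-9.
#'
#' @param rng_seed Integer seed; the collection is a deterministic function of
#'   the parameter list.
#' @return Parameter list for [generateCollection()].
#' @export
defaultGeneratorParams <- function(rng_seed = 17L) {
  list(n_genomes = 30L,
       genes_per_genome = c(60L, 120L),
       background_family_pool = 300L,
       architecture_plan = stats::setNames(rep(5L, 11L),
                                           names(builtinTemplates())),
       standalone_major_pilin_rate = 0.5,
       paralog_expansion_max = 9L,
       hgt_swap_rate = 0,
       rng_seed = as.integer(rng_seed))
}

#' Emit a prepilin (class III signal peptide) sequence
#'
#' Constructs Met + a positively charged N-terminal tract (2-8 residues, net
#' charge >= +1, no D/E/G), the \[K/R\]G cleavage motif, a 21-residue
#' hydrophobic tract, then a hydrophilic remainder; the mature part (after the
#' G) has exactly `mature_length` residues. The output is positive under
#' [detectClass3()] by construction.
#'
#' @param mature_length Mature protein length (>= 30). Typical major pilins
#'   are ~70 aa; large pilins/adhesins reach ~500 aa.
#' @return Amino-acid string.
#' @export
emitPrepilin <- function(mature_length) {
  stopifnot(mature_length >= 30L)
  tract_len <- sample(2:8, 1L)
  tract <- c(sample(c("K", "R"), 1L),
             if (tract_len > 1L)
               sample(c("K", "R", "S", "T", "N", "Q", "A"), tract_len - 1L,
                      replace = TRUE))
  tract <- paste(sample(tract), collapse = "")
  motif <- paste0(sample(c("K", "R"), 1L), "G")
  hydro <- .sampleAA(.hydrophobicPool, 21L)
  tail <- .sampleAA(.hydrophilicPool, mature_length - 21L)
  paste0("M", tract, motif, hydro, tail)
}

#' Emit a polytopic membrane protein sequence
#'
#' Places hydrophobic 21-mers (mean Kyte-Doolittle >= 2.8 by composition) at
#' the requested start positions on a hydrophilic backbone. Segment starts
#' must be >= 37 residues apart and fit inside `length` so that
#' [predictTMSegments()] recovers exactly `length(starts)` segments.
#'
#' @param starts Integer vector of 1-based segment start positions (may be
#'   empty for a fully hydrophilic protein).
#' @param length Total protein length.
#' @return Amino-acid string.
#' @export
emitTMProtein <- function(starts, length) {
  starts <- as.integer(sort(starts))
  if (base::length(starts)) {
    if (starts[1L] < 1L || starts[base::length(starts)] + 20L > length)
      stop("infeasible packing: segment outside sequence")
    if (base::length(starts) > 1L && any(diff(starts) < 37L))
      stop("infeasible packing: segments closer than 37 residues")
  }
  ch <- strsplit(.sampleAA(.hydrophilicPool, length), "")[[1L]]
  for (s in starts)
    ch[s:(s + 20L)] <- sample(.hydrophobicPool, 21L, replace = TRUE)
  paste(ch, collapse = "")
}

#' Topology templates of the two prepilin-peptidase subfamilies
#'
#' `pibdTopology()` is the 5-TM form (PibD/FlaK subfamily, the most abundant);
#' `eppaTopology()` the 9-TM form (EppA, clade-1-associated). Each returns
#' segment start positions and total length for [emitTMProtein()].
#'
#' @return List with `starts` and `length`.
#' @export
pibdTopology <- function() list(starts = seq(10L, by = 40L, length.out = 5L),
                                length = 230L)

#' @rdname pibdTopology
#' @export
eppaTopology <- function() list(starts = seq(10L, by = 40L, length.out = 9L),
                                length = 380L)

#' Emit a hydrophilic background protein
#'
#' Drawn from the hydrophilic-enriched composition profile only; it can carry
#' neither a class III nor a Sec-like signal nor a TM segment, so the feature
#' detectors reject it by construction.
#'
#' @param length Protein length.
#' @return Amino-acid string.
#' @export
emitBackgroundProtein <- function(length) {
  paste0("M", .sampleAA(.hydrophilicPool, length - 1L))
}

#' Emit a Sec-like secreted protein
#'
#' Met + short neutral linker + a 10-residue hydrophobic core (Sec-like
#' signal; too short to be called a TM segment) + hydrophilic remainder.
#'
#' @param length Protein length (>= 60).
#' @return Amino-acid string.
#' @export
emitSecProtein <- function(length) {
  stopifnot(length >= 60L)
  paste0("MSS", strrep("L", 10L),
         .sampleAA(setdiff(.hydrophilicPool, "K"), 23L),
         .sampleAA(.hydrophilicPool, length - 36L))
}

## ---- internal: plan layout ----

# Per-genome system capacities: everyone >= 1 (while systems remain), the
# surplus distributed as a descending ramp so counts take every value from
# max(cap) down to 1.
.systemsPerGenome <- function(total, n, max_cap = 7L) {
  if (total > n * max_cap) stop("architecture plan exceeds genome capacity")
  caps <- rep(min(1L, total), n)
  if (total <= n) { caps[seq_len(n) > total] <- 0L; return(caps) }
  deficit <- total - n
  ramp <- c(6L, 5L, 4L, 3L, 2L, 1L)
  i <- 1L
  while (deficit > 0L) {
    add <- min(deficit, ramp[((i - 1L) %% 6L) + 1L], max_cap - caps[i])
    caps[i] <- caps[i] + add
    deficit <- deficit - add
    i <- if (i == n) 1L else i + 1L
  }
  caps
}

# Assign each template's genome quota greedily to the genomes with the largest
# remaining capacity (ties: lowest index), never twice to the same genome.
.assignTemplates <- function(plan, caps) {
  n <- length(caps)
  assign <- vector("list", n)
  for (tpl in names(sort(plan, decreasing = TRUE))) {
    quota <- plan[[tpl]]
    avail <- which(caps > 0L)
    avail <- avail[order(-caps[avail], avail)]
    if (length(avail) < quota)
      stop("architecture plan exceeds n_genomes for template ", tpl)
    take <- avail[seq_len(quota)]
    for (g in take) assign[[g]] <- c(assign[[g]], tpl)
    caps[take] <- caps[take] - 1L
  }
  assign
}

## ---- internal: family registry ----

.cladeOf <- c(clade1 = "1", archaellum = "3", clade2_pilA = "2",
              clade2_B = "2", sub4C = "4C", sub4F = "4F",
              sulfolobales_simple = "4A", sub4B = "4B", sub4E = "4E",
              sub4G = "4G", sub4D = "4D")

.roleProduct <- c(
  secretion_ATPase = "type IV pili assembly ATPase, VirB11 family",
  tadC = "type IV pili membrane platform protein, TadC/FlaJ family",
  flaH = "archaellum ATP-binding protein FlaH",
  fleN_minD = "FleN/MinD family regulatory ATPase",
  major_pilin = "hypothetical protein",
  minor_pilin = "hypothetical protein",
  archaellin = "major archaellin, FlaA/FlaB family",
  flaF = "minor archaellin FlaF",
  flaG = "minor archaellin FlaG",
  flaCDE = "archaellum accessory protein, FlaC/D/E family",
  peptidase_5TM = "prepilin peptidase, PibD/FlaK subfamily (5 TM)",
  peptidase_9TM = "prepilin peptidase, EppA subfamily (9 TM)",
  adhesin = "putative adhesin",
  s_layer = "S-layer-like protein",
  membrane_accessory = "hypothetical protein",
  cytoplasmic_accessory = "hypothetical protein",
  regulator = "TFIIB family transcription regulator")

# family ids and roles planted for each template's locus
.familyRegistry <- function(templates) {
  fams <- list()
  rows <- list()
  addFam <- function(id, role, clade) {
    rows[[length(rows) + 1L]] <<- data.frame(family_id = id, role = role,
      clade_label = clade, stringsAsFactors = FALSE)
    id
  }
  minorCounts <- c(clade1 = 5L, clade2_pilA = 1L, clade2_B = 3L, sub4C = 1L,
                   sub4E = 2L, sub4G = 3L)
  slayer <- addFam("fam.slayer", "s_layer", NA_character_)
  for (nm in names(templates)) {
    cl <- unname(.cladeOf[nm])
    f <- list(atpase = addFam(paste0(nm, ".atpase"), "secretion_ATPase", cl))
    req <- templates[[nm]]@required
    if ("tadC" %in% names(req)) {
      ntad <- if (nm == "archaellum") 1L else req$tadC[1L]
      f$tadc <- vapply(seq_len(ntad), function(i)
        addFam(paste0(nm, ".tadC", i), "tadC", cl), "")
    }
    if (nm %in% names(minorCounts))
      f$minors <- vapply(seq_len(minorCounts[[nm]]), function(i)
        addFam(paste0(nm, ".minor", i), "minor_pilin", cl), "")
    if ("major_pilin" %in% names(req))
      f$major <- addFam(paste0(nm, ".major"), "major_pilin", cl)
    if ("adhesin" %in% names(req))
      f$adhesin <- addFam(paste0(nm, ".adhesin"), "adhesin", cl)
    if ("fleN_minD" %in% names(req))
      f$fleN <- addFam(paste0(nm, ".fleN"), "fleN_minD", cl)
    if ("membrane_accessory" %in% names(req))
      f$mem <- addFam(paste0(nm, ".mem"), "membrane_accessory", cl)
    if ("cytoplasmic_accessory" %in% names(req)) {
      ncyt <- req$cytoplasmic_accessory[1L]
      f$cyto <- vapply(seq_len(ncyt), function(i)
        addFam(paste0(nm, ".cyto", i), "cytoplasmic_accessory", cl), "")
    }
    if ("peptidase_9TM" %in% names(req))
      f$pept9 <- addFam(paste0(nm, ".eppA"), "peptidase_9TM", cl)
    if (nm == "archaellum") {
      f$flaH <- addFam("archaellum.flaH", "flaH", cl)
      f$flaF <- addFam("archaellum.flaF", "flaF", cl)
      f$flaG <- addFam("archaellum.flaG", "flaG", cl)
      f$flaB <- addFam("archaellum.flaB", "archaellin", cl)
      f$flaCDE <- addFam("archaellum.flaCDE", "flaCDE", cl)
      f$pept5 <- addFam("archaellum.flaK", "peptidase_5TM", cl)
    }
    if (nm == "sub4D")
      f$regulator <- addFam("sub4D.tfiib", "regulator", cl)
    if (nm %in% c("clade2_pilA", "sub4B")) f$slayer <- slayer
    fams[[nm]] <- f
  }
  list(fams = fams, catalog = do.call(rbind, rows))
}

.roleSeq <- function(role) {
  switch(role,
    secretion_ATPase = emitBackgroundProtein(500L),
    flaH = emitBackgroundProtein(230L),
    fleN_minD = emitBackgroundProtein(270L),
    cytoplasmic_accessory = emitBackgroundProtein(150L),
    regulator = emitBackgroundProtein(300L),
    tadC = emitTMProtein(seq(10L, by = 40L, length.out = 6L), 260L),
    membrane_accessory = emitTMProtein(seq(10L, by = 40L, length.out = 4L),
                                       180L),
    peptidase_5TM = emitTMProtein(pibdTopology()$starts,
                                  pibdTopology()$length),
    peptidase_9TM = emitTMProtein(eppaTopology()$starts,
                                  eppaTopology()$length),
    major_pilin = emitPrepilin(70L),
    minor_pilin = emitPrepilin(200L),
    archaellin = emitPrepilin(210L),
    flaF = emitPrepilin(150L),
    flaG = emitPrepilin(120L),
    flaCDE = emitTMProtein(220L, 250L),
    adhesin = emitPrepilin(500L),
    s_layer = emitSecProtein(450L),
    stop("no sequence emitter for role ", role))
}

.geneRow <- function(family_id, role) {
  data.frame(family_id = family_id, role = role,
             product = unname(.roleProduct[role]),
             protein_seq = .roleSeq(role), stringsAsFactors = FALSE)
}

# one locus instance: list(locus = data.frame, standalone = data.frame or NULL)
.plantLocus <- function(tpl, f, standalone_rate, paralog_max) {
  rows <- list()
  add <- function(fid, role) rows[[length(rows) + 1L]] <<- .geneRow(fid, role)
  majors_in_locus <- c(clade1 = 2L, clade2_pilA = 3L, clade2_B = 2L,
                       sub4C = 2L, sub4F = 2L, sulfolobales_simple = 2L,
                       sub4B = 2L, sub4E = 2L, sub4G = 2L)
  if (tpl == "archaellum") {
    k <- sample.int(min(9L, paralog_max), 1L)
    j <- sample.int(3L, 1L)
    n_standalone_arch <- if (k > 1L && stats::runif(1L) < 0.3) 1L else 0L
    for (i in seq_len(k - n_standalone_arch)) add(f$flaB, "archaellin")
    for (i in seq_len(j)) add(f$flaCDE, "flaCDE")
    add(f$flaF, "flaF"); add(f$flaG, "flaG"); add(f$flaH, "flaH")
    add(f$atpase, "secretion_ATPase"); add(f$tadc[1L], "tadC")
    add(f$pept5, "peptidase_5TM")
    sa <- if (n_standalone_arch)
      do.call(rbind, lapply(seq_len(n_standalone_arch),
                            function(i) .geneRow(f$flaB, "archaellin")))
    return(list(locus = do.call(rbind, rows), standalone = sa))
  }
  if (tpl == "sub4D") {
    add(f$atpase, "secretion_ATPase"); add(f$mem, "membrane_accessory")
    add(f$regulator, "regulator")
    return(list(locus = do.call(rbind, rows), standalone = NULL))
  }
  pre <- switch(tpl,
    clade1 = { for (m in f$minors) add(m, "minor_pilin")
               add(f$tadc[1L], "tadC"); add(f$atpase, "secretion_ATPase")
               add(f$tadc[2L], "tadC"); add(f$pept9, "peptidase_9TM") },
    clade2_pilA = { add(f$minors[1L], "minor_pilin"); add(f$tadc[1L], "tadC")
                    add(f$slayer, "s_layer")
                    add(f$atpase, "secretion_ATPase")
                    add(f$tadc[2L], "tadC") },
    clade2_B = { for (m in f$minors) add(m, "minor_pilin")
                 add(f$tadc[1L], "tadC"); add(f$atpase, "secretion_ATPase") },
    sub4C = { add(f$minors[1L], "minor_pilin"); add(f$adhesin, "adhesin")
              add(f$tadc[1L], "tadC"); add(f$atpase, "secretion_ATPase") },
    sub4F = { add(f$cyto[1L], "cytoplasmic_accessory")
              add(f$tadc[1L], "tadC"); add(f$atpase, "secretion_ATPase") },
    sulfolobales_simple = { add(f$tadc[1L], "tadC")
                            add(f$atpase, "secretion_ATPase") },
    sub4B = { add(f$adhesin, "adhesin"); add(f$tadc[1L], "tadC")
              add(f$slayer, "s_layer"); add(f$atpase, "secretion_ATPase")
              add(f$tadc[2L], "tadC") },
    sub4E = { for (m in f$minors) add(m, "minor_pilin")
              add(f$tadc[1L], "tadC"); add(f$atpase, "secretion_ATPase")
              add(f$mem, "membrane_accessory")
              add(f$cyto[1L], "cytoplasmic_accessory") },
    sub4G = { for (m in f$minors) add(m, "minor_pilin")
              add(f$adhesin, "adhesin"); add(f$fleN, "fleN_minD")
              add(f$atpase, "secretion_ATPase"); add(f$tadc[1L], "tadC")
              add(f$cyto[1L], "cytoplasmic_accessory")
              add(f$cyto[2L], "cytoplasmic_accessory") },
    stop("unknown template ", tpl))
  standalone <- NULL
  n_major <- unname(majors_in_locus[tpl])
  if (stats::runif(1L) < standalone_rate) {
    n_sa <- sample.int(3L, 1L)
    standalone <- do.call(rbind, lapply(seq_len(n_sa),
      function(i) .geneRow(f$major, "major_pilin")))
  } else {
    for (i in seq_len(n_major)) add(f$major, "major_pilin")
  }
  list(locus = do.call(rbind, rows), standalone = standalone)
}

## ---- internal: rare flank-family pool ----

.newRareState <- function() new.env(parent = emptyenv())

.drawRareFamily <- function(state, genome) {
  pool <- ls(state)
  reusable <- pool[vapply(pool, function(f) {
    g <- get(f, envir = state); length(g) < 4L && !(genome %in% g)
  }, TRUE)]
  if (length(reusable) && stats::runif(1L) < 0.6) {
    fam <- sample(reusable, 1L)
  } else {
    fam <- sprintf("rare%05d", length(pool) + 1L)
    assign(fam, character(0), envir = state)
  }
  assign(fam, union(get(fam, envir = state), genome), envir = state)
  fam
}

.bgGeneRow <- function(family_id) {
  data.frame(family_id = family_id, role = "background",
             product = "hypothetical protein",
             protein_seq = emitBackgroundProtein(sample(120:300, 1L)),
             stringsAsFactors = FALSE)
}

## ---- the generator ----

#' Generate a synthetic genome collection with planted T4P loci
#'
#' Builds `n_genomes` single-contig genomes carrying planted T4P/archaellum
#' loci per the architecture plan, stand-alone major pilins (in-trans systems),
#' paralog expansions, Zipf-distributed background families, and protein
#' sequences that the feature detectors resolve by construction. Deterministic
#' given `rng_seed`.
#'
#' @param params Parameter list as from [defaultGeneratorParams()]; fields:
#'   `n_genomes`, `genes_per_genome` (c(min, max) target), `background_family_pool`,
#'   `architecture_plan` (named template -> number of genomes), `standalone_major_pilin_rate`,
#'   `paralog_expansion_max`, `hgt_swap_rate`, `rng_seed`.
#' @return A [SyntheticCollection-class].
#' @export
generateCollection <- function(params = defaultGeneratorParams()) {
  p <- params
  stopifnot(p$n_genomes >= 1L, p$paralog_expansion_max >= 1L)
  for (fld in c("standalone_major_pilin_rate", "hgt_swap_rate"))
    if (p[[fld]] < 0 || p[[fld]] > 1) stop(fld, " must be in [0,1]")
  templates <- builtinTemplates()
  unknown <- setdiff(names(p$architecture_plan), names(templates))
  if (length(unknown))
    stop("unknown template(s) in architecture_plan: ",
         paste(unknown, collapse = ", "))
  if (any(p$architecture_plan > p$n_genomes))
    stop("architecture plan exceeds n_genomes")
  if (exists(".Random.seed", globalenv())) {
    oldseed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  }
  set.seed(p$rng_seed)

  plan <- p$architecture_plan[p$architecture_plan > 0L]
  total <- sum(plan)
  caps <- .systemsPerGenome(total, p$n_genomes)
  assign <- .assignTemplates(plan, caps)
  genomeIds <- sprintf("genome%02d", seq_len(p$n_genomes))
  lineages <- list(c("Euryarchaeota", "Methanococci"),
                   c("Euryarchaeota", "Halobacteria"),
                   c("Crenarchaeota", "Sulfolobales"),
                   c("Crenarchaeota", "Thermoproteales"),
                   c("Euryarchaeota", "Thermococci"),
                   c("Thaumarchaeota", "Nitrososphaerales"))

  reg <- .familyRegistry(templates[names(plan)])
  rare <- .newRareState()

  # horizontal transfer: copy a planted system into another genome
  hgt <- list()
  if (p$hgt_swap_rate > 0 && p$n_genomes > 1L) {
    for (g in seq_len(p$n_genomes)) for (tpl in assign[[g]]) {
      if (stats::runif(1L) < p$hgt_swap_rate) {
        to <- sample(setdiff(seq_len(p$n_genomes), g), 1L)
        assign[[to]] <- c(assign[[to]], tpl)
        hgt[[length(hgt) + 1L]] <- data.frame(
          template = tpl, from = genomeIds[g], to = genomeIds[to],
          stringsAsFactors = FALSE)
      }
    }
  }

  window <- 3L  # flank margin matches the census neighborhood window
  genomes <- list()
  loci_rows <- list()
  sa_rows <- list()
  op_rows <- list()

  for (g in seq_len(p$n_genomes)) {
    gid <- genomeIds[g]
    blocks <- list()
    for (tpl in assign[[g]]) {
      pl <- .plantLocus(tpl, reg$fams[[tpl]], p$standalone_major_pilin_rate,
                        p$paralog_expansion_max)
      blocks[[length(blocks) + 1L]] <- list(type = "locus", tpl = tpl,
                                            genes = pl$locus)
      if (!is.null(pl$standalone))
        blocks[[length(blocks) + 1L]] <- list(type = "standalone", tpl = tpl,
                                              genes = pl$standalone)
    }
    n_block_genes <- sum(vapply(blocks, function(b) nrow(b$genes), 1L)) +
      2L * window * length(blocks)
    target <- sample(p$genes_per_genome[1L]:p$genes_per_genome[2L], 1L)
    n_bg <- max(0L, target - n_block_genes)
    items <- c(blocks,
               lapply(seq_len(n_bg), function(i) list(type = "bg")))
    items <- items[sample.int(length(items))]

    rows <- list()
    ops <- list()
    cursor <- sample(200:800, 1L)
    block_id <- 0L
    emit <- function(generow, strand, gap, new_operon) {
      len <- 3L * (nchar(generow$protein_seq) + 1L)
      if (new_operon) block_id <<- block_id + 1L
      start <- cursor + gap
      cursor <<- start + len - 1L
      rows[[length(rows) + 1L]] <<- cbind(generow,
        data.frame(strand = strand, start = start, end = cursor,
                   operon = block_id, stringsAsFactors = FALSE))
    }
    flank <- function() {
      for (i in seq_len(window))
        emit(.bgGeneRow(.drawRareFamily(rare, gid)),
             sample(c("+", "-"), 1L), sample(200:800, 1L), TRUE)
    }
    locus_ranges <- list()
    for (it in items) {
      if (it$type == "bg") {
        fam <- sprintf("bg%04d",
                       sample.int(p$background_family_pool, 1L,
                                  prob = (seq_len(p$background_family_pool))^-1.5))
        emit(.bgGeneRow(fam), sample(c("+", "-"), 1L),
             sample(200:800, 1L), TRUE)
      } else {
        flank()
        strand <- sample(c("+", "-"), 1L)
        first <- length(rows) + 1L
        for (i in seq_len(nrow(it$genes))) {
          emit(it$genes[i, , drop = FALSE], strand,
               if (i == 1L) sample(200:800, 1L) else sample(1:50, 1L),
               i == 1L)
        }
        if (it$type == "locus")
          locus_ranges[[length(locus_ranges) + 1L]] <-
            list(tpl = it$tpl, first = first, last = length(rows))
        else
          sa_rows[[length(sa_rows) + 1L]] <- data.frame(
            genome_id = gid, template = it$tpl,
            idx = seq(first, length(rows)),
            family_id = it$genes$family_id, role = it$genes$role,
            stringsAsFactors = FALSE)
        flank()
      }
    }
    tab <- do.call(rbind, rows)
    n <- nrow(tab)
    tab$gene_id <- sprintf("%s_g%04d", gid, seq_len(n))
    tab$order_index <- seq_len(n) - 1L
    for (lr in locus_ranges)
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        genome_id = gid, contig_id = "c1",
        start_index = lr$first - 1L, end_index = lr$last - 1L,
        template = lr$tpl, stringsAsFactors = FALSE)
    op_rows[[length(op_rows) + 1L]] <- data.frame(
      genome_id = gid, contig_id = "c1", block_id = tab$operon,
      gene_id = tab$gene_id, stringsAsFactors = FALSE)
    genomes[[gid]] <- GenomeTable(gid, data.frame(
      contig_id = "c1", order_index = tab$order_index, gene_id = tab$gene_id,
      strand = tab$strand, start = tab$start, end = tab$end,
      family_id = tab$family_id, product = tab$product,
      protein_seq = tab$protein_seq, stringsAsFactors = FALSE),
      lineage = lineages[[((g - 1L) %% length(lineages)) + 1L]])
  }

  planted <- if (length(loci_rows)) do.call(rbind, loci_rows) else
    data.frame(genome_id = character(0), contig_id = character(0),
               start_index = integer(0), end_index = integer(0),
               template = character(0))
  standalone <- if (length(sa_rows)) {
    sa <- do.call(rbind, sa_rows)
    sa$gene_id <- vapply(seq_len(nrow(sa)), function(i)
      genes(genomes[[sa$genome_id[i]]])$gene_id[sa$idx[i]], "")
    sa$idx <- NULL
    sa
  } else data.frame(genome_id = character(0), template = character(0),
                    family_id = character(0), role = character(0),
                    gene_id = character(0))

  role_of_family <- stats::setNames(reg$catalog$role, reg$catalog$family_id)
  atpase_fams <- reg$catalog$family_id[reg$catalog$role == "secretion_ATPase"]
  counts <- vapply(genomes, function(gt)
    sum(genes(gt)$family_id %in% atpase_fams), 1L)

  catalog <- new("FamilyCatalog", families = reg$catalog)
  truth <- list(planted_loci = planted,
                role_of_family = role_of_family,
                expected_t4p_count = counts,
                standalone_genes = standalone,
                operons = do.call(rbind, op_rows),
                hgt_events = if (length(hgt)) do.call(rbind, hgt) else
                  data.frame(template = character(0), from = character(0),
                             to = character(0)))
  new("SyntheticCollection", genomes = genomes, truth = truth,
      catalog = catalog, params = p)
}

#' Seed families of a synthetic collection
#'
#' Convenience: the secretion-ATPase family ids of the planted catalog, the
#' natural census seed set.
#'
#' @param collection A [SyntheticCollection-class].
#' @return Character vector of family ids.
#' @export
seedFamilies <- function(collection) {
  familiesWithRole(collectionCatalog(collection), "secretion_ATPase")
}
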