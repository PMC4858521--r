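## Sequence-feature heuristics: Kyte-Doolittle hydropathy windows for
## transmembrane (TM) segment calling, a class III (prepilin) signal-peptide
## detector, and a secreted/membrane/cytoplasmic localization call. These are
## documented, threshold-exposed contracts, not re-implementations of HMM-based
## topology predictors.

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of per-residue hydropathy indices over the
#'   20-letter amino-acid alphabet.
#' @export
kdScale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

.kdValues <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  v <- unname(kdScale()[ch])
  if (anyNA(v)) {
    warning("unknown residue letter(s) scored 0.0: ",
            paste(unique(ch[is.na(v)]), collapse = ""))
    v[is.na(v)] <- 0
  }
  v
}

#' Sliding-window mean hydropathy profile
#'
#' Value `i` is the mean Kyte-Doolittle index over residues
#' `i..i+window-1`; the profile has `nchar(seq) - window + 1` values.
#' Unknown residue letters score 0.0 with a warning.
#'
#' @param seq Amino-acid string, at least `window` residues.
#' @param window Window length in residues (default 19, standard TM practice).
#' @return Numeric vector of window means.
#' @export
kdProfile <- function(seq, window = 19L) {
  v <- .kdValues(seq)
  n <- length(v)
  if (n < window) stop("sequence shorter than window")
  cs <- cumsum(c(0, v))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Predict transmembrane segments by hydropathy
#'
#' Candidate 19-residue windows with mean Kyte-Doolittle hydropathy at or above
#' `threshold` are merged when their residue spans overlap or are separated by
#' fewer than `merge_gap` residues; each merged run is one segment; merged
#' segments shorter than `min_length` residues are dropped.
#'
#' @param seq Amino-acid string (>= `window` residues).
#' @param window,threshold,merge_gap,min_length Tunables of the caller; the
#'   defaults (19, 1.6, 5, 15) are standard hydropathy-plot practice.
#' @return List with `segments` (integer matrix, columns `start`,`end`, 1-based
#'   inclusive residue ranges) and `count`.
#' @export
predictTMSegments <- function(seq, window = 19L, threshold = 1.6,
                              merge_gap = 5L, min_length = 15L) {
  prof <- kdProfile(seq, window)
  hit <- which(prof >= threshold)
  if (!length(hit)) {
    return(list(segments = matrix(integer(0), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))),
                count = 0L))
  }
  starts <- hit
  ends <- hit + window - 1L
  segs <- list()
  cur <- c(starts[1L], ends[1L])
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur[2L] + merge_gap - 1L) {
      cur[2L] <- max(cur[2L], ends[i])
    } else {
      segs[[length(segs) + 1L]] <- cur
      cur <- c(starts[i], ends[i])
    }
  }
  segs[[length(segs) + 1L]] <- cur
  m <- do.call(rbind, segs)
  m <- m[m[, 2L] - m[, 1L] + 1L >= min_length, , drop = FALSE]
  colnames(m) <- c("start", "end")
  list(segments = m, count = nrow(m))
}

#' Detect a class III (prepilin) signal peptide
#'
#' A class III signal peptide is the prepilin leader: a short, positively
#' charged N-terminus that a dedicated A24-family peptidase removes at a
#' \[K/R\]G motif, leaving a hydrophobic domain of about 20 residues at the
#' mature N-terminus. The detector scans leader positions `2..max_leader` for a
#' K or R immediately followed by G and accepts the first position where (a)
#' the net charge of the prefix through the K/R (K/R = +1, D/E = -1) is at
#' least +1 and (b) the mean Kyte-Doolittle hydropathy of the 20 residues after
#' the G is at least `min_hydro`. Failing that, a Sec-like signal is called
#' when the first 40 residues contain an 8-residue core of mean hydropathy
#' >= 1.5 (cleavage position set 5 residues after that core).
#'
#' @param seq Amino-acid string of at least 45 residues.
#' @param max_leader Last leader position scanned for the motif.
#' @param min_hydro Minimum mean hydropathy of the 20 mature-N-terminal
#'   residues.
#' @return List with `klass` (`"class_III"`, `"sec_like"` or `"none"`),
#'   `cleavage_pos` (residue index after which cleavage occurs; NA if none),
#'   `leader_net_charge`, and `downstream_hydrophobicity` (mean KD over the 20
#'   residues after cleavage; NA if none).
#' @examples
#' sp <- detectClass3(paste0("MKG", strrep("L", 20), strrep("S", 30)))
#' sp$klass; sp$cleavage_pos
#' @export
detectClass3 <- function(seq, max_leader = 35L, min_hydro = 1.0) {
  seq <- toupper(seq)
  if (nchar(seq) < 45L) stop("sequence too short (< 45 residues)")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  kd <- .kdValues(seq)
  n <- length(ch)
  charge <- cumsum((ch %in% c("K", "R")) - (ch %in% c("D", "E")))
  for (p in 2L:min(max_leader, n - 21L)) {
    if (ch[p] %in% c("K", "R") && ch[p + 1L] == "G") {
      if (charge[p] < 1L) next
      down <- kd[(p + 2L):(p + 21L)]
      hydro <- mean(down)
      if (hydro >= min_hydro) {
        return(list(klass = "class_III", cleavage_pos = p + 1L,
                    leader_net_charge = as.integer(charge[p]),
                    downstream_hydrophobicity = hydro))
      }
    }
  }
  # Sec-like fall-through: hydrophobic core of >= 8 residues within first 40
  lim <- min(40L, n)
  if (lim >= 8L) {
    cs <- cumsum(c(0, kd[1:lim]))
    core <- (cs[9L:(lim + 1L)] - cs[1L:(lim - 7L)]) / 8
    hitc <- which(core >= 1.5)
    if (length(hitc)) {
      cend <- hitc[1L] + 7L
      cpos <- min(cend + 5L, n - 1L)
      downEnd <- min(cpos + 20L, n)
      return(list(klass = "sec_like", cleavage_pos = as.integer(cpos),
                  leader_net_charge = as.integer(charge[cpos]),
                  downstream_hydrophobicity =
                    mean(kd[(cpos + 1L):downEnd])))
    }
  }
  list(klass = "none", cleavage_pos = NA_integer_,
       leader_net_charge = as.integer(charge[min(n, max_leader)]),
       downstream_hydrophobicity = NA_real_)
}

#' Classify protein localization
#'
#' Combines a TM profile and a signal-peptide call into one of `membrane`,
#' `secreted`, `cytoplasmic`, `unknown`. A single TM segment starting at or
#' before residue 45 is discounted when a signal peptide was detected (it is
#' the signal's own hydrophobic domain, not a true anchor).
#'
#' @param tm A TM profile from [predictTMSegments()].
#' @param sp A signal-peptide call from [detectClass3()].
#' @param has_seq Was a protein sequence available? If `FALSE`, returns
#'   `"unknown"`.
#' @return One of `"secreted"`, `"membrane"`, `"cytoplasmic"`, `"unknown"`.
#' @export
classifyLocalization <- function(tm, sp, has_seq = TRUE) {
  if (!has_seq) return("unknown")
  count <- tm$count
  if (sp$klass != "none" && count >= 1L && tm$segments[1L, "start"] <= 45L)
    count <- count - 1L
  if (count >= 1L) return("membrane")
  if (sp$klass != "none") return("secreted")
  "cytoplasmic"
}

#' Compute per-protein feature calls for a genome collection
#'
#' Runs [detectClass3()], [predictTMSegments()] and [classifyLocalization()]
#' over every gene with a protein sequence. Proteins shorter than 45 residues
#' get `sp_class = "none"`; shorter than the TM window, `tm_count = 0`.
#'
#' @param genomes A `GenomeTable` or (optionally named) list of them.
#' @return data.frame with one row per gene: `genome_id`, `gene_id`,
#'   `family_id`, `length`, `sp_class`, `cleavage_pos`, `tm_count`,
#'   `first_tm_start`, `localization`, `mature_length` (length after class III
#'   cleavage when detected, else full length).
#' @export
computeFeatures <- function(genomes) {
  if (is(genomes, "GenomeTable")) genomes <- list(genomes)
  out <- lapply(genomes, function(gt) {
    g <- genes(gt)
    n <- nrow(g)
    res <- data.frame(genome_id = rep(genomeId(gt), n),
                      gene_id = g$gene_id, family_id = g$family_id,
                      length = NA_integer_, sp_class = "unknown",
                      cleavage_pos = NA_integer_, tm_count = NA_integer_,
                      first_tm_start = NA_integer_,
                      localization = "unknown",
                      mature_length = NA_integer_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      aa <- g$protein_seq[i]
      if (is.na(aa) || !nzchar(aa)) next
      len <- nchar(aa)
      res$length[i] <- len
      sp <- if (len >= 45L) detectClass3(aa)
            else list(klass = "none", cleavage_pos = NA_integer_)
      tm <- if (len >= 19L) predictTMSegments(aa)
            else list(segments = matrix(integer(0), ncol = 2L,
                        dimnames = list(NULL, c("start", "end"))), count = 0L)
      res$sp_class[i] <- sp$klass
      res$cleavage_pos[i] <- sp$cleavage_pos
      res$tm_count[i] <- tm$count
      if (tm$count >= 1L) res$first_tm_start[i] <- tm$segments[1L, "start"]
      res$localization[i] <- classifyLocalization(tm, sp, TRUE)
      res$mature_length[i] <- if (sp$klass == "class_III")
        len - sp$cleavage_pos else len
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
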