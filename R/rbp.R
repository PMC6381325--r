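# IUPAC degeneracy map (DNA alphabet; U handled by normalization to T).
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Expand an IUPAC motif to plain A/C/G/T sequences
#'
#' Cartesian expansion of every degenerate symbol; the number of expanded
#' sequences equals the product of per-symbol degeneracies. RNA alphabet (U)
#' is accepted and normalized to T.
#'
#' @param motif IUPAC motif string.
#' @return character vector of A/C/G/T sequences.
#' @export
iupacExpand <- function(motif) {
  s <- toupper(motif)
  s <- gsub("U", "T", s, fixed = TRUE)
  syms <- strsplit(s, "")[[1L]]
  bad <- setdiff(syms, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in motif '", motif, "': ",
         paste(unique(bad), collapse = ", "))
  out <- ""
  for (sym in syms) out <- as.vector(outer(out, .IUPAC[[sym]], paste0))
  out
}

#' Parse an RBP motif table
#'
#' Reads a TSV with species, RBP id and IUPAC motif columns; rows are
#' filtered for Homo sapiens and grouped by RBP. Motifs are uppercased with
#' U normalized to T; each RBP's motifs are expanded to a deduplicated set
#' of plain A/C/G/T sequences.
#'
#' @param path TSV path. Columns are located by name (case-insensitive
#'   match on "species", "rbp" and "motif").
#' @return list of records, one per RBP, each with \code{rbp_id},
#'   \code{iupac_motifs} and \code{expanded}; attribute \code{n_unique}
#'   gives the number of distinct expanded sequences across all RBPs.
#' @export
parseMotifTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(structure(list(), n_unique = 0L))
  cn <- tolower(colnames(tab))
  sp <- which(grepl("species", cn))[1L]
  rb <- which(grepl("rbp", cn))[1L]
  mo <- which(grepl("motif", cn))[1L]
  if (any(is.na(c(sp, rb, mo))))
    stop("motif table needs species, RBP id and motif columns")
  human <- grepl("sapiens", tab[[sp]], ignore.case = TRUE)
  tab <- tab[human, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(tab)), tab[[rb]]), function(idx) {
    motifs <- toupper(gsub("U", "T", tab[[mo]][idx]))
    for (i in seq_along(motifs)) {
      row <- idx[i]
      syms <- strsplit(motifs[i], "")[[1L]]
      if (length(setdiff(syms, names(.IUPAC))))
        stop("invalid IUPAC motif in row ", row, ": ", tab[[mo]][row])
    }
    expanded <- unique(unlist(lapply(motifs, iupacExpand)))
    list(rbp_id = tab[[rb]][idx[1L]], iupac_motifs = motifs,
         expanded = expanded)
  })
  out <- out[order(names(out))]
  structure(out,
            n_unique = length(unique(unlist(lapply(out, `[[`, "expanded")))))
}

#' Count motif hits in a sequence
#'
#' Non-overlapping, left-to-right occurrence counting of each expanded
#' sequence, summed over the set. N in the target never matches.
#'
#' @param sequence A/C/G/T/N string.
#' @param expanded character vector of plain A/C/G/T motif sequences.
#' @param overlapping count overlapping occurrences instead.
#' @return integer total hit count.
#' @export
countMotifHits <- function(sequence, expanded, overlapping = FALSE) {
  if (nchar(sequence) == 0L || length(expanded) == 0L) return(0L)
  s <- toupper(sequence)
  total <- 0L
  for (m in expanded) {
    if (overlapping) {
      hits <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1L]]
    } else {
      hits <- gregexpr(m, s, fixed = TRUE)[[1L]]
    }
    total <- total + sum(hits > 0L)
  }
  total
}

#' Extract UTR sequences from a genome and annotation
#'
#' For every transcript of the requested genes, the genomic UTR intervals
#' are concatenated in transcript orientation (minus-strand sequences
#' reverse-complemented) into one 5' and one 3' record. GTFs with explicit
#' \code{five_prime_utr}/\code{three_prime_utr} features are used directly;
#' generic \code{UTR} features are classified by position relative to the
#' transcript's CDS (upstream of the CDS on the transcript strand is 5').
#' Transcripts without CDS (when classification would be needed) are skipped
#' with a warning.
#'
#' @param genome a \code{Biostrings::DNAStringSet} or FASTA path.
#' @param gtf a \code{GRanges} from \code{rtracklayer::import} or GTF path.
#' @param genes optional gene ids to restrict to.
#' @return data.frame with gene_id, transcript_id, side
#'   (\code{five_prime}/\code{three_prime}) and sequence.
#' @export
extractUTRs <- function(genome, gtf, genes = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(gtf)) gtf <- rtracklayer::import(gtf, format = "gtf")
  feat <- as.character(gtf$type)
  if (!is.null(genes)) gtf <- gtf[gtf$gene_id %in% genes]
  feat <- as.character(gtf$type)
  is5 <- feat %in% c("five_prime_utr", "5UTR")
  is3 <- feat %in% c("three_prime_utr", "3UTR")
  isU <- feat == "UTR"
  cds <- gtf[feat == "CDS"]
  recs <- list()
  utr <- gtf[is5 | is3 | isU]
  if (length(utr) == 0L)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      side = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  for (tx in unique(utr$transcript_id)) {
    u <- utr[utr$transcript_id == tx]
    side <- character(length(u))
    typ <- as.character(u$type)
    side[typ %in% c("five_prime_utr", "5UTR")] <- "five_prime"
    side[typ %in% c("three_prime_utr", "3UTR")] <- "three_prime"
    if (any(typ == "UTR")) {
      ctx <- cds[cds$transcript_id == tx]
      if (length(ctx) == 0L) {
        warning("transcript ", tx, " has UTR but no CDS; skipped")
        next
      }
      strand <- as.character(GenomicRanges::strand(u))[1L]
      cds_start <- min(GenomicRanges::start(ctx))
      cds_end <- max(GenomicRanges::end(ctx))
      gen_u <- typ == "UTR"
      before <- GenomicRanges::end(u) < cds_start
      if (strand == "-") {
        side[gen_u & GenomicRanges::start(u) > cds_end] <- "five_prime"
        side[gen_u & before] <- "three_prime"
      } else {
        side[gen_u & before] <- "five_prime"
        side[gen_u & GenomicRanges::start(u) > cds_end] <- "three_prime"
      }
    }
    for (sd in c("five_prime", "three_prime")) {
      part <- u[side == sd]
      if (length(part) == 0L) next
      part <- part[order(GenomicRanges::start(part))]
      seqs <- as.character(
        Biostrings::extractAt(
          genome[[as.character(GenomicRanges::seqnames(part))[1L]]],
          IRanges::IRanges(GenomicRanges::start(part),
                           GenomicRanges::end(part))))
      strand <- as.character(GenomicRanges::strand(part))[1L]
      seq <- paste(seqs, collapse = "")
      if (strand == "-")
        seq <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      recs[[length(recs) + 1L]] <-
        data.frame(gene_id = part$gene_id[1L], transcript_id = tx,
                   side = sd, sequence = seq, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      side = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Coverage gate for UTR records
#'
#' UTRs with no or minimal read coverage are not confidently present in
#' platelets: 5' UTRs need at least 3 reads and 3' UTRs at least 5 (the
#' higher 3' threshold accounts for the oligo-dT amplification bias).
#' Thresholds are inclusive (kept at exactly the threshold).
#'
#' @param records data.frame with at least \code{side} and
#'   \code{read_count}.
#' @param min_5p,min_3p thresholds (defaults 3 and 5).
#' @return the filtered data.frame.
#' @export
utrCoverageFilter <- function(records, min_5p = 3, min_3p = 5) {
  stopifnot("read_count" %in% colnames(records))
  keep <- (records$side == "five_prime" & records$read_count >= min_5p) |
    (records$side == "three_prime" & records$read_count >= min_3p)
  records[keep, , drop = FALSE]
}

#' Aggregate motif hits to the gene level
#'
#' Per gene, side and RBP, motif hits are summed over all surviving
#' transcripts' UTRs; invariant to transcript order.
#'
#' @param records UTR data.frame (post coverage filter) with gene_id,
#'   transcript_id, side and sequence.
#' @param motif_sets list of RBP records from \code{\link{parseMotifTable}}.
#' @param overlapping passed to \code{\link{countMotifHits}}.
#' @return data.frame gene_id x rbp_id x side with a \code{hits} column.
#' @export
aggregateGeneLevel <- function(records, motif_sets, overlapping = FALSE) {
  if (nrow(records) == 0L || length(motif_sets) == 0L)
    return(data.frame(gene_id = character(), rbp_id = character(),
                      side = character(), hits = integer(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (ms in motif_sets) {
    hits <- vapply(records$sequence, countMotifHits, integer(1),
                   expanded = ms$expanded, overlapping = overlapping,
                   USE.NAMES = FALSE)
    agg <- stats::aggregate(hits,
                            by = list(gene_id = records$gene_id,
                                      side = records$side), FUN = sum)
    agg$rbp_id <- ms$rbp_id
    out[[length(out) + 1L]] <- agg[, c("gene_id", "rbp_id", "side", "x")]
  }
  res <- do.call(rbind, out)
  colnames(res)[4L] <- "hits"
  res[order(res$rbp_id, res$gene_id, res$side), , drop = FALSE]
}

#' Keep RBPs expressed in the platelet gene universe
#'
#' An RBP is retained when its own transcript is part of the
#' abundance-filtered gene universe (a membership proxy for sufficient read
#' coverage of the RBP itself).
#'
#' @param rbp_ids character vector of RBP identifiers.
#' @param universe gene universe (e.g. gene ids of a filtered
#'   \linkS4class{SplicedCounts}).
#' @param id_map optional named vector mapping RBP id to gene id.
#' @return the retained RBP ids.
#' @export
rbpExpressionFilter <- function(rbp_ids, universe, id_map = NULL) {
  mapped <- if (is.null(id_map)) rbp_ids else unname(id_map[rbp_ids])
  unmappable <- is.na(mapped)
  if (any(unmappable))
    warning(sum(unmappable), " RBP id(s) not mappable; dropped")
  rbp_ids[!unmappable & mapped %in% universe]
}

#' Mean binding sites per RBP and UTR side
#'
#' @param hits gene x RBP x side hit table from
#'   \code{\link{aggregateGeneLevel}}.
#' @return data.frame rbp_id, mean_5p, mean_3p (mean hits over genes; an
#'   absent side counts as mean 0).
#' @export
tropismSummary <- function(hits) {
  rbps <- sort(unique(hits$rbp_id))
  m <- function(rbp, sd) {
    v <- hits$hits[hits$rbp_id == rbp & hits$side == sd]
    if (length(v) == 0L) 0 else mean(v)
  }
  data.frame(rbp_id = rbps,
             mean_5p = vapply(rbps, m, numeric(1), sd = "five_prime"),
             mean_3p = vapply(rbps, m, numeric(1), sd = "three_prime"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate RBP binding-site counts with differential logFC
#'
#' Per RBP and UTR side, Pearson correlation (Spearman optional) between the
#' per-gene binding-site counts and the genes' differential logFC, with
#' two-sided p values and Benjamini-Hochberg FDR within side.
#'
#' @param hits gene x RBP x side table from
#'   \code{\link{aggregateGeneLevel}}.
#' @param logfc named per-gene logFC vector (names are gene ids).
#' @param method "pearson" (default) or "spearman".
#' @return data.frame rbp_id, side, n, r, p, FDR (volcano-style table).
#' @export
correlateSitesLogFC <- function(hits, logfc, method = c("pearson",
                                                        "spearman")) {
  method <- match.arg(method)
  out <- list()
  for (sd in unique(hits$side)) {
    sub <- hits[hits$side == sd, , drop = FALSE]
    for (rbp in unique(sub$rbp_id)) {
      h <- sub[sub$rbp_id == rbp, , drop = FALSE]
      common <- intersect(h$gene_id, names(logfc))
      if (length(common) < 3) next
      x <- h$hits[match(common, h$gene_id)]
      y <- logfc[common]
      if (stats::sd(x) == 0) {
        warning("zero-variance site counts for ", rbp, " (", sd,
                "); excluded")
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = method))
      out[[length(out) + 1L]] <-
        data.frame(rbp_id = rbp, side = sd, n = length(common),
                   r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(rbp_id = character(), side = character(),
                      n = integer(), r = numeric(), p = numeric(),
                      FDR = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$FDR <- NA_real_
  for (sd in unique(res$side))
    res$FDR[res$side == sd] <- bhAdjust(res$p[res$side == sd])
  res
}
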