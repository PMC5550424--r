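#' Build a ranked transcript catalog
#'
#' A catalog holds transcript sequences from one source database plus its
#' priority rank (1 = best). Gene symbols and biotype classes default to the
#' transcript id and "unknown" when no mapping is supplied.
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`) of
#'   transcript sequences; names are transcript ids, unique within a source.
#' @param source Source label (e.g. the database name).
#' @param rank Integer priority rank; lower wins.
#' @param genes Optional named character: transcript id -> gene symbol.
#' @param biotypes Optional named character: transcript id -> biotype class.
#' @return List of class `transcript_catalog`.
#' @export
transcript_catalog <- function(sequences, source, rank,
                               genes = NULL, biotypes = NULL) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("transcript ids must be present and unique within a source", call. = FALSE)
  }
  if (is.null(genes)) genes <- stats::setNames(ids, ids)
  if (is.null(biotypes)) biotypes <- stats::setNames(rep("unknown", length(ids)), ids)
  structure(list(sequences = toupper(sequences), source = source,
                 rank = as.integer(rank), genes = genes, biotypes = biotypes),
            class = "transcript_catalog")
}

#' Read a transcript catalog from a FASTA file
#'
#' Headers of the form `id` or `id|gene|biotype` are supported.
#'
#' @param path FASTA file.
#' @param source Source label.
#' @param rank Integer priority rank.
#' @return A [transcript_catalog()].
#' @export
read_catalog_fasta <- function(path, source, rank) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(ss), "|", fixed = TRUE)
  ids <- vapply(hdr, `[`, character(1), 1)
  genes <- vapply(hdr, function(h) if (length(h) >= 2) h[2] else h[1], character(1))
  biotypes <- vapply(hdr, function(h) if (length(h) >= 3) h[3] else "unknown", character(1))
  names(ss) <- ids
  transcript_catalog(ss, source, rank,
                     genes = stats::setNames(genes, ids),
                     biotypes = stats::setNames(biotypes, ids))
}

#' Match probe sequences against a transcript catalog
#'
#' Reports every occurrence of each probe on the sense strand of each
#' transcript with at most `max_mismatch` substitutions (no indels). Offsets
#' are 0-based on the transcript. Probes containing non-ACGT symbols are
#' skipped with a warning. Matching delegates to
#' [Biostrings::vmatchPattern()]; mismatch counts are recomputed per hit by
#' direct Hamming comparison.
#'
#' @param probes Data frame with columns `probe` and `sequence` (>= 20 nt).
#' @param catalog A [transcript_catalog()].
#' @param max_mismatch Maximum substitutions per hit (default 1).
#' @param both_strands Also search the reverse complement (default FALSE;
#'   array probes are designed sense to transcripts).
#' @return Data frame: probe, transcript, offset (0-based), mismatches,
#'   strand, source, rank.
#' @export
match_probes <- function(probes, catalog, max_mismatch = 1, both_strands = FALSE) {
  stopifnot(all(c("probe", "sequence") %in% colnames(probes)),
            inherits(catalog, "transcript_catalog"))
  seqs <- toupper(probes$sequence)
  if (any(nchar(seqs) < 20)) stop("probe sequences must be >= 20 nt", call. = FALSE)
  ok <- grepl("^[ACGT]+$", seqs)
  if (!all(ok)) {
    warning(sum(!ok), " probe(s) with non-ACGT symbols skipped: ",
            paste(utils::head(probes$probe[!ok], 5), collapse = ", "))
  }
  subject <- Biostrings::DNAStringSet(catalog$sequences)
  hits <- vector("list", sum(ok))
  kept <- which(ok)
  for (j in seq_along(kept)) {
    i <- kept[j]
    pat <- seqs[i]
    res <- match_one_probe(pat, subject, catalog, max_mismatch, "+", probes$probe[i])
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
      res <- rbind(res, match_one_probe(rc, subject, catalog, max_mismatch, "-",
                                        probes$probe[i]))
    }
    hits[[j]] <- res
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(probe = character(0), transcript = character(0),
                      offset = integer(0), mismatches = integer(0),
                      strand = character(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

match_one_probe <- function(pat, subject, catalog, max_mismatch, strand, probe_id) {
  m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max_mismatch,
                                 with.indels = FALSE)
  starts <- Biostrings::startIndex(m)
  rows <- list()
  pl <- nchar(pat)
  pchars <- strsplit(pat, "")[[1]]
  for (t in seq_along(starts)) {
    st <- starts[[t]]
    if (is.null(st) || length(st) == 0) next
    tid <- names(catalog$sequences)[t]
    tseq <- catalog$sequences[[t]]
    # vmatchPattern can report out-of-bounds starts when max.mismatch > 0
    st <- st[st >= 1 & st + pl - 1 <= nchar(tseq)]
    if (length(st) == 0) next
    mm <- vapply(st, function(s) {
      sum(strsplit(substr(tseq, s, s + pl - 1), "")[[1]] != pchars)
    }, integer(1))
    keep <- mm <= max_mismatch
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      probe = probe_id, transcript = tid, offset = st[keep] - 1L,
      mismatches = mm[keep], strand = strand,
      source = catalog$source, rank = catalog$rank, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(probe = character(0), transcript = character(0),
                      offset = integer(0), mismatches = integer(0),
                      strand = character(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Resolve multi-catalog probe hits by source priority
#'
#' Per probe, only hits from the best (lowest) source rank are kept; within
#' that source 0-mismatch hits beat 1-mismatch hits; remaining ties go to the
#' lexicographically smallest transcript id. Probes with no hits are emitted
#' unannotated (NA fields). The output is invariant to input hit order.
#'
#' @param hits Data frame as produced by [match_probes()] (possibly
#'   concatenated over catalogs).
#' @param catalogs List of the [transcript_catalog()] objects the hits came
#'   from (for gene/biotype lookup).
#' @param all_probes Optional character vector of all probe ids, so probes
#'   without hits appear in the table.
#' @return Annotation table: probe, gene, biotype, source, rank, transcript,
#'   mismatches, n_hits (hits within the winning source).
#' @export
assign_priority <- function(hits, catalogs, all_probes = NULL) {
  stopifnot(is.data.frame(hits))
  lookup <- list()
  for (cat in catalogs) {
    lookup[[as.character(cat$rank)]] <- cat
  }
  if (is.null(all_probes)) all_probes <- unique(hits$probe)
  res <- lapply(all_probes, function(p) {
    h <- hits[hits$probe == p, , drop = FALSE]
    if (nrow(h) == 0) {
      return(data.frame(probe = p, gene = NA_character_, biotype = NA_character_,
                        source = NA_character_, rank = NA_integer_,
                        transcript = NA_character_, mismatches = NA_integer_,
                        n_hits = 0L, stringsAsFactors = FALSE))
    }
    h <- h[h$rank == min(h$rank), , drop = FALSE]
    n_src <- nrow(h)
    h <- h[order(h$mismatches, h$transcript, h$offset), , drop = FALSE]
    best <- h[1, ]
    cat <- lookup[[as.character(best$rank)]]
    data.frame(probe = p,
               gene = unname(cat$genes[best$transcript]),
               biotype = unname(cat$biotypes[best$transcript]),
               source = best$source, rank = best$rank,
               transcript = best$transcript, mismatches = best$mismatches,
               n_hits = n_src, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
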