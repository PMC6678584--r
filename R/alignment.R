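# Alignment of collapsed reads to precursors and genome, and cross-mapping
# correction of multi-mapped reads.  Precursor alignment is end-to-end with
# at most one internal substitution after splitting off a maximal
# non-templated 3' suffix (<= 3 nt) as a soft tail; genome alignment
# reports all loci on both strands within the mismatch budget.

#' Align collapsed reads to precursor sequences
#'
#' Each read is reported at every precursor position where it matches
#' end-to-end with at most `max_mismatch` internal substitutions after
#' splitting off a maximal non-templated 3' suffix of at most `max_tail`
#' nucleotides (including any overhang past the precursor 3' end) as a
#' soft tail.  Output ordering is deterministic (precursor id, offset,
#' read).
#'
#' @param reads collapsed reads: data.frame with `sequence`, `count`
#'   (optionally `min_q25`), or a character vector of sequences.
#' @param precursors precursor sequences: named character vector,
#'   `DNAStringSet`, data.frame with `id`/`sequence`, or a list of
#'   precursor records.
#' @param max_mismatch internal substitution budget (default 1).
#' @param max_tail maximal soft-tail length (default 3).
#' @return data.frame with `read` (sequence), `count`, `min_q25`,
#'   `precursor_id`, `offset` (1-based start on the precursor), `end`
#'   (last templated position), `nmm`, `mm` (comma-separated
#'   `pos:REF>ALT` in precursor coordinates), `tail` (possibly empty
#'   string).
#' @export
align_to_precursors <- function(reads, precursors, max_mismatch = 1L,
                                max_tail = 3L) {
    if (is.character(reads))
        reads <- data.frame(sequence = reads, count = 1L,
                            stringsAsFactors = FALSE)
    if (is.null(reads$count)) reads$count <- 1L
    if (is.null(reads$min_q25)) reads$min_q25 <- NA_integer_
    pseqs <- as_seq_vector(precursors, "precursors")
    if (!nrow(reads) || !length(pseqs))
        return(data.frame(read = character(0), count = numeric(0),
                          min_q25 = integer(0), precursor_id = character(0),
                          offset = integer(0), end = integer(0),
                          nmm = integer(0), mm = character(0),
                          tail = character(0), stringsAsFactors = FALSE))
    hits <- align_tail_cpp(toupper(reads$sequence), unname(pseqs),
                           as.integer(max_mismatch), as.integer(max_tail))
    out <- data.frame(read = reads$sequence[hits$query],
                      count = reads$count[hits$query],
                      min_q25 = reads$min_q25[hits$query],
                      precursor_id = names(pseqs)[hits$subject],
                      offset = hits$start,
                      end = hits$start + hits$tpl_len - 1L,
                      nmm = hits$nmm, mm = hits$mm, tail = hits$tail,
                      stringsAsFactors = FALSE)
    out <- out[order(out$precursor_id, out$offset, out$read), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Align collapsed reads to a genome
#'
#' Reports every genomic locus (both strands) where a read matches
#' end-to-end with at most `max_mismatch` substitutions.
#'
#' @param reads collapsed reads (as in [align_to_precursors()]).
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @param max_mismatch substitution budget (default 1).
#' @return data.frame with `read`, `count`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive on the plus strand), `nmm`.
#' @export
align_to_genome <- function(reads, genome, max_mismatch = 1L) {
    if (is.character(reads) && is.null(dim(reads)))
        reads <- data.frame(sequence = reads, count = 1L,
                            stringsAsFactors = FALSE)
    if (is.null(reads$count)) reads$count <- 1L
    gseqs <- as_seq_vector(genome, "genome")
    if (!nrow(reads) || !length(gseqs))
        return(data.frame(read = character(0), count = numeric(0),
                          chrom = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          nmm = integer(0), stringsAsFactors = FALSE))
    hits <- scan_matches_cpp(toupper(reads$sequence), unname(gseqs),
                             as.integer(max_mismatch), TRUE)
    out <- data.frame(read = reads$sequence[hits$query],
                      count = reads$count[hits$query],
                      chrom = names(gseqs)[hits$subject],
                      strand = hits$strand,
                      start = hits$start,
                      end = hits$start + nchar(reads$sequence[hits$query]) - 1L,
                      nmm = hits$nmm, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$strand, out$read), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Cross-mapping correction of multi-mapped reads
#'
#' Reassigns each multi-mapped read sequence across its candidate loci in
#' proportion to the loci's perfectly mapped (mismatch-free, untailed)
#' read support.  A read hitting loci with perfect counts `c_1..c_k`
#' receives weight `c_i / sum(c_j)` at locus `i`; if all perfect counts
#' are zero the weights fall back to the uniform `1/k`; single-locus reads
#' receive weight 1.  Weights sum to one per read sequence, so weighted
#' tallies conserve total read counts.
#'
#' @param alignments data.frame with at least `read` and a locus column
#'   (`precursor_id` or `locus`), e.g. from [align_to_precursors()].
#' @param perfect_counts optional named numeric vector of perfect-read
#'   counts per locus; computed from `alignments` (rows with `nmm == 0`
#'   and empty `tail`, summing `count`) when omitted.
#' @return data.frame with `read`, `locus`, `weight`; one row per distinct
#'   (read sequence, locus).
#' @export
cross_map_correct <- function(alignments, perfect_counts = NULL) {
    locus_col <- if ("locus" %in% names(alignments)) "locus" else "precursor_id"
    stopifnot(locus_col %in% names(alignments), "read" %in% names(alignments))
    key <- !duplicated(paste0(alignments$read, "\r", alignments[[locus_col]]))
    pairs <- data.frame(read = alignments$read[key],
                        locus = alignments[[locus_col]][key],
                        stringsAsFactors = FALSE)
    if (is.null(perfect_counts)) {
        perf <- alignments$nmm == 0 &
            (!("tail" %in% names(alignments)) | !nzchar(alignments$tail %||% ""))
        cnt <- alignments$count %||% rep(1, nrow(alignments))
        if (any(perf)) {
            agg <- rowsum(as.numeric(cnt[perf]), alignments[[locus_col]][perf])
            perfect_counts <- stats::setNames(agg[, 1], rownames(agg))
        } else perfect_counts <- numeric(0)
    }
    pc <- perfect_counts[pairs$locus]
    pc[is.na(pc)] <- 0
    tot <- rowsum(pc, pairs$read)[pairs$read, 1]
    nloci <- rowsum(rep(1, nrow(pairs)), pairs$read)[pairs$read, 1]
    weight <- ifelse(tot > 0, pc / tot, 1 / nloci)
    out <- data.frame(read = pairs$read, locus = pairs$locus,
                      weight = as.numeric(weight), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Attach cross-mapping weights to a precursor alignment table
#'
#' Convenience wrapper: computes [cross_map_correct()] weights over the
#' alignment's own loci and merges them back as a `weight` column.
#'
#' @param alignments data.frame from [align_to_precursors()].
#' @param perfect_counts optional override, see [cross_map_correct()].
#' @return `alignments` with an additional `weight` column.
#' @export
add_cross_map_weights <- function(alignments, perfect_counts = NULL) {
    if (!nrow(alignments)) {
        alignments$weight <- numeric(0)
        return(alignments)
    }
    w <- cross_map_correct(alignments, perfect_counts)
    locus_col <- if ("locus" %in% names(alignments)) "locus" else "precursor_id"
    idx <- match(paste0(alignments$read, "\r", alignments[[locus_col]]),
                 paste0(w$read, "\r", w$locus))
    alignments$weight <- w$weight[idx]
    alignments
}
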