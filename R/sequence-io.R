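# Read preprocessing and standard-format I/O: FASTQ in (Phred+33), quality
# gating over the first 25 nt, 3' adapter trimming, collapsing to unique
# reads, and strand-aware locus intersection.

#' The default 3' sequencing adapter
#'
#' The Illumina TruSeq small RNA 3' adapter ligated during library
#' preparation; reads are trimmed at its leftmost longest prefix match.
#' @return adapter string.
#' @export
default_adapter <- function() "TGGAATTCTCGAGTGCCAAGGAACTCC"

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to an uncompressed FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ: line count not a multiple of 4")
    idx <- seq(1L, length(lines), by = 4L)
    data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
               sequence = toupper(lines[idx + 1L]),
               quality = lines[idx + 3L],
               stringsAsFactors = FALSE)
}

#' Write FASTQ records (Phred+33)
#'
#' @param records data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
    stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
    out <- character(4L * nrow(records))
    out[seq(1L, length(out), 4L)] <- paste0("@", records$id)
    out[seq(2L, length(out), 4L)] <- records$sequence
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- records$quality
    writeLines(out, path)
    invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file path.
#' @return named character vector (uppercase).
#' @export
read_fasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(to_dna(seqs)), path)
    invisible(path)
}

# per-read minimum Phred score over the first `k` bases (NA if shorter)
#' @noRd
min_quality_first <- function(quality, k = 25L) {
    vapply(quality, function(q) {
        if (nchar(q) < k) return(NA_integer_)
        min(utf8ToInt(substr(q, 1L, k))) - 33L
    }, integer(1), USE.NAMES = FALSE)
}

#' Quality gate over the first 25 nucleotides
#'
#' A read passes iff it has at least 25 bases and every one of the first 25
#' base qualities is at least `q_min` (default 30); bases beyond position
#' 25 are not inspected.  Records shorter than 25 nt fail (they are not an
#' error).
#'
#' @param quality character vector of Phred+33 quality strings (or a
#'   data.frame with a `quality` column).
#' @param q_min minimum admissible Phred score (default 30).
#' @return logical vector, TRUE = pass.
#' @export
quality_gate <- function(quality, q_min = 30L) {
    if (is.data.frame(quality)) quality <- quality$quality
    q25 <- min_quality_first(quality, 25L)
    !is.na(q25) & q25 >= q_min
}

#' Trim the 3' adapter from read sequences
#'
#' Each sequence is truncated at the leftmost occurrence of the longest
#' matching adapter prefix; the minimum accepted match is `min_match`
#' nucleotides (6 by default).  Matching is exact.  Sequences without any
#' adapter prefix occurrence are returned unchanged; a sequence starting
#' with the adapter trims to the empty string (discarded downstream by
#' [collapse_unique()]).
#'
#' @param sequences character vector of read sequences.
#' @param adapter adapter string (non-empty).
#' @param min_match minimum adapter-prefix length to accept.
#' @return character vector of trimmed sequences.
#' @export
trim_adapter <- function(sequences, adapter = default_adapter(),
                         min_match = 6L) {
    stopifnot(nzchar(adapter))
    sequences <- toupper(sequences)
    adapter <- toupper(adapter)
    out <- sequences
    todo <- rep(TRUE, length(out))
    for (k in seq(nchar(adapter), min_match)) {
        if (!any(todo)) break
        pos <- regexpr(substr(adapter, 1L, k), out[todo], fixed = TRUE)
        hit <- pos > 0L
        if (any(hit)) {
            idx <- which(todo)[hit]
            out[idx] <- substr(out[idx], 1L, pos[hit] - 1L)
            todo[idx] <- FALSE
        }
    }
    out
}

#' Collapse reads to unique sequences
#'
#' One record per distinct sequence with summed counts; sequences of 18 nt
#' or shorter (i.e. below `min_length`) are dropped.  When quality strings
#' are supplied, the minimum Phred score over the first 25 bases is carried
#' along (the minimum across collapsed duplicates).
#'
#' @param sequences character vector of trimmed read sequences (or a
#'   data.frame with `sequence` and optionally `quality`/`count` columns).
#' @param counts per-read multiplicities (default 1).
#' @param qualities optional Phred+33 quality strings (pre-trimming length
#'   is fine; only the first 25 bases are inspected).
#' @param min_length minimum retained sequence length (default 19, i.e.
#'   "more than 18 nucleotides").
#' @return data.frame with `sequence`, `count`, `min_q25`, ordered by
#'   decreasing count then sequence.
#' @export
collapse_unique <- function(sequences, counts = NULL, qualities = NULL,
                            min_length = 19L) {
    if (is.data.frame(sequences)) {
        df <- sequences
        sequences <- df$sequence
        if (is.null(counts) && !is.null(df$count)) counts <- df$count
        if (is.null(qualities) && !is.null(df$quality)) qualities <- df$quality
    }
    if (is.null(counts)) counts <- rep(1L, length(sequences))
    if (!length(sequences))
        return(data.frame(sequence = character(0), count = numeric(0),
                          min_q25 = integer(0), stringsAsFactors = FALSE))
    q25 <- if (is.null(qualities)) rep(NA_integer_, length(sequences))
           else min_quality_first(qualities, 25L)
    keep <- nchar(sequences) >= min_length
    sequences <- sequences[keep]; counts <- counts[keep]; q25 <- q25[keep]
    if (!length(sequences))
        return(data.frame(sequence = character(0), count = numeric(0),
                          min_q25 = integer(0), stringsAsFactors = FALSE))
    cnt <- rowsum(as.numeric(counts), sequences)
    mq <- tapply(q25, sequences, function(v) {
        if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE)
    })
    out <- data.frame(sequence = rownames(cnt), count = as.numeric(cnt[, 1]),
                      min_q25 = as.integer(mq[rownames(cnt)]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Preprocess one small RNA profile
#'
#' Applies the full preprocessing chain to raw FASTQ records: quality gate
#' over the first 25 nt, 3' adapter trimming, and collapsing to unique
#' reads of more than 18 nt.
#'
#' @param records a FASTQ path or a data.frame from [read_fastq()].
#' @param adapter 3' adapter string.
#' @param q_min quality-gate threshold.
#' @param min_length minimum retained read length after trimming.
#' @return collapsed read data.frame (see [collapse_unique()]) with an
#'   `attrition` attribute recording read counts after each step.
#' @export
preprocess_profile <- function(records, adapter = default_adapter(),
                               q_min = 30L, min_length = 19L) {
    if (is.character(records) && length(records) == 1L)
        records <- read_fastq(records)
    n_raw <- nrow(records)
    gated <- records[quality_gate(records$quality, q_min), , drop = FALSE]
    trimmed <- trim_adapter(gated$sequence, adapter)
    out <- collapse_unique(trimmed, qualities = gated$quality,
                           min_length = min_length)
    attr(out, "attrition") <- data.frame(
        step = c("raw", "quality_gate", "collapse_min_length"),
        reads = c(n_raw, nrow(gated), sum(out$count)),
        stringsAsFactors = FALSE)
    out
}

#' @noRd
as_granges_loci <- function(x) {
    if (is(x, "GRanges")) {
        if (is.null(x$id)) x$id <- as.character(seq_along(x))
        return(x)
    }
    stopifnot(is.data.frame(x),
              all(c("chrom", "start", "end", "strand") %in% names(x)))
    if (any(x$start > x$end)) stop("locus with start > end")
    GenomicRanges::GRanges(
        seqnames = x$chrom,
        ranges = IRanges::IRanges(x$start, x$end),
        strand = x$strand,
        id = x$id %||% as.character(seq_len(nrow(x))))
}

#' Strand-aware intersection of two locus sets
#'
#' Reports every pair of loci from `a` and `b` that lie on the same strand
#' and overlap by at least one nucleotide, together with the overlap
#' length.  Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param a,b locus sets: data.frames with `chrom`, `start`, `end`,
#'   `strand`, `id`, or `GRanges` with an `id` metadata column.
#' @return data.frame with `id_a`, `id_b`, `overlap`.
#' @export
intersect_loci <- function(a, b) {
    ga <- as_granges_loci(a); gb <- as_granges_loci(b)
    hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = FALSE)
    ov <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                    gb[S4Vectors::subjectHits(hits)])
    data.frame(id_a = ga$id[S4Vectors::queryHits(hits)],
               id_b = gb$id[S4Vectors::subjectHits(hits)],
               overlap = BiocGenerics::width(ov),
               stringsAsFactors = FALSE)
}

#' Write loci to GFF3
#'
#' @param loci data.frame with `chrom`, `start`, `end`, `strand`, `id`
#'   (optionally `type`).
#' @param path output path.
#' @export
write_loci_gff3 <- function(loci, path) {
    gr <- as_granges_loci(loci)
    gr$type <- loci$type %||% rep("miRNA_primary_transcript", nrow(loci))
    gr$ID <- gr$id
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read loci from GFF3
#'
#' @param path GFF3 path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `id`, `type`.
#' @export
read_loci_gff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr),
               end = BiocGenerics::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               id = as.character(gr$ID %||% gr$id %||% seq_along(gr)),
               type = as.character(gr$type),
               stringsAsFactors = FALSE)
}
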