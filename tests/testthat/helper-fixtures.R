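# small constructed fixtures shared across test files

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# perfect-stem hairpin: stem + loop + reverse complement of the stem
stem_hairpin <- function(stem, loop) paste0(stem, loop, revcomp_dna(stem))

make_collapsed <- function(sequences, counts, min_q25 = 40L) {
    data.frame(sequence = sequences, count = counts,
               min_q25 = rep(min_q25, length(sequences)),
               stringsAsFactors = FALSE)
}

# embed named sequences into random background, in order, with spacing
plant_genome <- function(pieces, spacing = 60L, chrom = "chrT") {
    genome <- rand_seq(spacing)
    offsets <- NULL
    for (id in names(pieces)) {
        start <- nchar(genome) + 1L
        genome <- paste0(genome, pieces[[id]], rand_seq(spacing))
        offsets <- rbind(offsets, data.frame(
            id = id, chrom = chrom, start = start,
            end = start + nchar(pieces[[id]]) - 1L, strand = "+",
            stringsAsFactors = FALSE))
    }
    list(genome = stats::setNames(genome, chrom), offsets = offsets)
}

# canonical test precursor geometry (mirrors the simulator): stem `s`,
# A/C loop, 5p mature 4 nt into the stem, 3p mature with 2-nt overhangs
canonical_precursor <- function(s = 37L, loop_len = 8L, m = 22L) {
    stem <- rand_seq(s)
    loop <- paste(sample(c("A", "C"), loop_len, TRUE), collapse = "")
    seqs <- stem_hairpin(stem, loop)
    P <- 2L * s + loop_len
    list(sequence = seqs,
         mature5p = c(5L, 4L + m),
         mature3p = c(P - 1L - m, P - 2L))
}
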