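# Synthetic small RNA-seq data with planted ground truth.
#
# The generator builds a toy genome carrying hairpin-forming precursor
# loci on both strands (plus optional shuffled decoy loci that fail the
# hairpin criteria), then samples mature-arm reads with +/-2 nt end jitter,
# planted central editing events at specified levels, homozygous SNPs,
# non-templated 3' tails, Phred-quality-driven sequencing errors, and a
# ligated 3' adapter.  Every emitted read's provenance is recorded in a
# truth manifest so that recovery can be scored exactly.

#' Configuration for the synthetic small RNA-seq simulator
#'
#' Defaults describe the reference simulation used throughout the package's
#' validation: 50 precursors of 82 nt with 22-nt matures on both arms,
#' 500 reads per mature, constant base quality Q30 (per-base error
#' `10^(-30/10)`), and the standard Illumina 3' adapter.
#'
#' Planted positions for `editing_events` and `snp_events` are 1-based
#' within the 5p mature arm, which guarantees they are covered by reads;
#' the generator forces the reference nucleotide at each planted position.
#'
#' @param genome_length toy genome size in nt.
#' @param n_precursors number of planted hairpin precursors.
#' @param precursor_length precursor length in nt (60-110).
#' @param mature_length mature miRNA length in nt (20-24).
#' @param coverage_per_mature reads sampled per mature arm.
#' @param editing_events data.frame with columns `precursor` (index),
#'   `position` (1-based in the 5p mature), `ref`, `alt`, `level` in \[0,1\].
#' @param snp_events data.frame with `precursor`, `position` (1-based in
#'   the 5p mature), `ref`, `alt`; planted homozygous (all reads carry
#'   the alternative allele).
#' @param tail_events data.frame with `precursor`, `tail` (non-templated
#'   3' suffix), `fraction` in \[0,1\].
#' @param base_quality constant Phred score of every base (Phred+33).
#' @param arms which mature arms to sequence (`"5p"`, `"3p"`).
#' @param n_decoys shuffled decoy loci that fail the hairpin criteria.
#' @param duplicate_loci indices of precursors additionally planted at a
#'   second (untranscribed) genomic locus, for multi-mapping tests.
#' @param spacing background nt between consecutive planted loci.
#' @param adapter 3' adapter appended to every read.
#' @param seed RNG seed; fixes all outputs bit-for-bit.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(genome_length = 12000L,
                              n_precursors = 50L,
                              precursor_length = 82L,
                              mature_length = 22L,
                              coverage_per_mature = 500L,
                              editing_events = NULL,
                              snp_events = NULL,
                              tail_events = NULL,
                              base_quality = 30L,
                              arms = c("5p", "3p"),
                              n_decoys = 0L,
                              duplicate_loci = integer(0),
                              spacing = 30L,
                              adapter = default_adapter(),
                              seed = 1L) {
    stopifnot(precursor_length >= 60L, precursor_length <= 110L,
              mature_length >= 20L, mature_length <= 24L,
              base_quality >= 2L, base_quality <= 93L,
              all(arms %in% c("5p", "3p")), length(arms) >= 1L)
    norm_events <- function(ev, cols) {
        if (is.null(ev))
            return(stats::setNames(
                data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
        ev <- as.data.frame(ev, stringsAsFactors = FALSE)
        stopifnot(all(cols %in% names(ev)))
        ev[cols]
    }
    editing_events <- norm_events(editing_events,
                                  c("precursor", "position", "ref", "alt", "level"))
    snp_events <- norm_events(snp_events,
                              c("precursor", "position", "ref", "alt"))
    tail_events <- norm_events(tail_events, c("precursor", "tail", "fraction"))
    for (ev in list(editing_events, snp_events)) {
        if (!nrow(ev)) next
        if (any(ev$precursor < 1 | ev$precursor > n_precursors))
            stop("planted event names a precursor outside 1..n_precursors")
        if (any(ev$position < 1 | ev$position > mature_length))
            stop("planted position outside the mature arm")
        if (any(to_dna(ev$ref) == to_dna(ev$alt)))
            stop("planted event with ref == alt")
    }
    if (nrow(editing_events) &&
        any(editing_events$level < 0 | editing_events$level > 1))
        stop("editing levels must lie in [0, 1]")
    if (nrow(tail_events)) {
        if (any(tail_events$fraction < 0 | tail_events$fraction > 1))
            stop("tail fractions must lie in [0, 1]")
        check_alphabet(tail_events$tail)
    }
    n_loci <- n_precursors + n_decoys + length(duplicate_loci)
    if (n_loci * (precursor_length + spacing) + spacing > genome_length)
        stop("genome_length too small for the requested loci ",
             "(need > ", n_loci * (precursor_length + spacing) + spacing, " nt)")
    structure(list(genome_length = as.integer(genome_length),
                   n_precursors = as.integer(n_precursors),
                   precursor_length = as.integer(precursor_length),
                   mature_length = as.integer(mature_length),
                   coverage_per_mature = as.integer(coverage_per_mature),
                   editing_events = editing_events, snp_events = snp_events,
                   tail_events = tail_events,
                   base_quality = as.integer(base_quality),
                   arms = arms, n_decoys = as.integer(n_decoys),
                   duplicate_loci = as.integer(duplicate_loci),
                   spacing = as.integer(spacing), adapter = toupper(adapter),
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

# geometry of a planted precursor: full complementary stem of length `s`
# enclosing an unpairable A/C loop; the 5p mature sits 4 nt into the stem
# and the 3p mature is placed so both duplex 3' overhangs are exactly 2 nt.
#' @noRd
sim_geometry <- function(cfg) {
    a <- 4L
    m <- cfg$mature_length
    P <- cfg$precursor_length
    s <- (P - 8L) %/% 2L
    l <- P - 2L * s
    stopifnot(s >= a + m + 2L, l >= 4L)
    list(a = a, m = m, P = 2L * s + l, s = s, l = l,
         mature5p = c(a + 1L, a + m),
         mature3p = c(2L * s + l - 1L - m, 2L * s + l - 2L))
}

#' @noRd
contains_adapter_prefix <- function(seqs, adapter, min_match = 6L) {
    grepl(substr(adapter, 1L, min_match), seqs, fixed = TRUE)
}

# one planted precursor sequence honoring forced reference bases at
# planted 5p-mature positions
#' @noRd
sim_precursor_seq <- function(cfg, geo, forced) {
    for (try in 1:50) {
        stem <- sample(DNA_BASES, geo$s, replace = TRUE)
        if (nrow(forced))
            stem[geo$a + forced$position] <- to_dna(forced$ref)
        loop <- sample(c("A", "C"), geo$l, replace = TRUE)
        seqs <- paste0(paste(stem, collapse = ""), paste(loop, collapse = ""),
                       revcomp_dna(paste(stem, collapse = "")))
        if (contains_adapter_prefix(seqs, cfg$adapter)) next
        hp <- fold_hairpin(seqs)
        if (check_hairpin_criteria(hp)$pass) return(list(sequence = seqs,
                                                         structure = hp))
    }
    stop("failed to construct a criteria-passing precursor")  # nocov
}

#' Build the toy genome and truth manifest
#'
#' Plants `cfg$n_precursors` hairpin precursor loci (alternating strands),
#' optional shuffled decoy loci that fail [check_hairpin_criteria()], and
#' optional duplicate copies of selected precursors, embedded in random
#' background sequence.  Re-running with the same config yields
#' byte-identical output.
#'
#' @param cfg a [simulation_config()].
#' @return a `TruthManifest`: list with `genome` (named character vector,
#'   one chromosome), `loci` (data.frame `id`, `chrom`, `start`, `end`,
#'   `strand`, `type`, `source_of`), `precursors` (list of records with
#'   `id`, `sequence`, `matures`, `structure`), `sites` (planted-site truth
#'   with precursor coordinates), `cfg`, and `reads` (NULL until
#'   [simulate_profile()]).
#' @export
build_genome <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    geo <- sim_geometry(cfg)
    with_seed(cfg$seed, {
        precs <- vector("list", cfg$n_precursors)
        for (i in seq_len(cfg$n_precursors)) {
            forced <- rbind(
                cfg$editing_events[cfg$editing_events$precursor == i,
                                   c("position", "ref")],
                cfg$snp_events[cfg$snp_events$precursor == i,
                               c("position", "ref")])
            ps <- sim_precursor_seq(cfg, geo, forced)
            precs[[i]] <- list(
                id = sprintf("sim-mir-%d", i), sequence = ps$sequence,
                structure = ps$structure,
                matures = data.frame(
                    arm = c("5p", "3p"),
                    start = c(geo$mature5p[1], geo$mature3p[1]),
                    end = c(geo$mature5p[2], geo$mature3p[2]),
                    stringsAsFactors = FALSE))
        }
        decoys <- vector("list", cfg$n_decoys)
        for (i in seq_len(cfg$n_decoys)) {
            repeat {
                ds <- rand_dna(cfg$precursor_length)
                if (contains_adapter_prefix(ds, cfg$adapter)) next
                if (!check_hairpin_criteria(fold_hairpin(ds))$pass) break
            }
            decoys[[i]] <- list(id = sprintf("sim-decoy-%d", i), sequence = ds)
        }

        placed <- c(
            lapply(precs, function(p)
                list(id = p$id, sequence = p$sequence, type = "precursor",
                     source_of = NA_character_)),
            lapply(decoys, function(d)
                list(id = d$id, sequence = d$sequence, type = "decoy",
                     source_of = NA_character_)),
            lapply(cfg$duplicate_loci, function(i)
                list(id = sprintf("sim-mir-%d-dup", i),
                     sequence = precs[[i]]$sequence, type = "duplicate",
                     source_of = sprintf("sim-mir-%d", i))))

        genome <- sample(DNA_BASES, cfg$genome_length, replace = TRUE)
        loci <- data.frame(id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), type = character(0),
                           source_of = character(0), stringsAsFactors = FALSE)
        pos <- cfg$spacing + 1L
        for (k in seq_along(placed)) {
            p <- placed[[k]]
            strand <- if (k %% 2L == 1L) "+" else "-"
            insert <- if (strand == "+") p$sequence else revcomp_dna(p$sequence)
            genome[pos:(pos + nchar(insert) - 1L)] <-
                strsplit(insert, "", fixed = TRUE)[[1]]
            loci <- rbind(loci, data.frame(
                id = p$id, chrom = "chrSim", start = pos,
                end = pos + nchar(insert) - 1L, strand = strand,
                type = p$type, source_of = p$source_of,
                stringsAsFactors = FALSE))
            pos <- pos + nchar(insert) + cfg$spacing
        }
        genome <- paste(genome, collapse = "")

        sites <- data.frame(precursor = character(0), position = integer(0),
                            ref = character(0), alt = character(0),
                            level = numeric(0), kind = character(0),
                            stringsAsFactors = FALSE)
        if (nrow(cfg$editing_events))
            sites <- rbind(sites, data.frame(
                precursor = sprintf("sim-mir-%d", cfg$editing_events$precursor),
                position = geo$a + cfg$editing_events$position,
                ref = to_dna(cfg$editing_events$ref),
                alt = to_dna(cfg$editing_events$alt),
                level = cfg$editing_events$level, kind = "edit",
                stringsAsFactors = FALSE))
        if (nrow(cfg$snp_events))
            sites <- rbind(sites, data.frame(
                precursor = sprintf("sim-mir-%d", cfg$snp_events$precursor),
                position = geo$a + cfg$snp_events$position,
                ref = to_dna(cfg$snp_events$ref),
                alt = to_dna(cfg$snp_events$alt),
                level = 1.0, kind = "snp", stringsAsFactors = FALSE))

        structure(list(genome = c(chrSim = genome), loci = loci,
                       precursors = precs, sites = sites, cfg = cfg,
                       reads = NULL),
                  class = "TruthManifest")
    })
}

#' Simulate one small RNA-seq profile from a truth manifest
#'
#' Samples `cfg$coverage_per_mature` reads from each mature arm of each
#' planted precursor with uniform end jitter on -2..+2 nt (truncated to the
#' precursor).  Each read covering a planted editing site carries the
#' alternative nucleotide with probability equal to the planted level;
#' reads always carry planted SNP alleles; planted 3' tails are appended
#' with their configured fraction; sequencing errors are injected per base
#' of the biological insert with probability `10^(-Q/10)` (uniform over the
#' three other bases); finally the 3' adapter is appended and every base is
#' assigned the constant quality `cfg$base_quality`.
#'
#' @param cfg a [simulation_config()].
#' @param truth manifest from [build_genome()].
#' @param sample_id profile name used in read ids and provenance.
#' @param seed RNG seed for this profile (defaults to `cfg$seed`; pass
#'   distinct seeds to simulate replicate profiles).
#' @return list with `records` (data.frame `id`, `sequence`, `quality`,
#'   FASTQ-ready) and `truth` (the manifest with per-read provenance in
#'   `$reads`: precursor, arm, insert span, edits applied, tail applied,
#'   error positions).
#' @export
simulate_profile <- function(cfg, truth, sample_id = "sample1",
                             seed = cfg$seed) {
    stopifnot(inherits(cfg, "SimulationConfig"),
              inherits(truth, "TruthManifest"))
    perr <- 10^(-cfg$base_quality / 10)
    qchar <- intToUtf8(cfg$base_quality + 33L)
    recs <- list(); prov <- list()
    with_seed(seed, {
        for (p in truth$precursors) {
            L <- nchar(p$sequence)
            template <- p$sequence
            psites <- truth$sites[truth$sites$precursor == p$id, , drop = FALSE]
            for (k in which(psites$kind == "snp")) {
                stopifnot(substr(template, psites$position[k],
                                 psites$position[k]) == psites$ref[k])
                template <- subst_at(template, psites$position[k],
                                     psites$alt[k])
            }
            edits <- psites[psites$kind == "edit", , drop = FALSE]
            tails <- cfg$tail_events[
                sprintf("sim-mir-%d", cfg$tail_events$precursor) == p$id, ,
                drop = FALSE]
            for (arm in cfg$arms) {
                mt <- p$matures[p$matures$arm == arm, ]
                if (!nrow(mt)) next
                n <- cfg$coverage_per_mature
                starts <- pmax(1L, mt$start + sample(-2:2, n, replace = TRUE))
                ends <- pmin(L, mt$end + sample(-2:2, n, replace = TRUE))
                reads <- substring(template, starts, ends)
                edit_tags <- rep("", n)
                for (k in seq_len(nrow(edits))) {
                    pos <- edits$position[k]
                    covered <- starts <= pos & ends >= pos
                    take <- covered & stats::runif(n) < edits$level[k]
                    if (any(take)) {
                        reads[take] <- subst_at(reads[take],
                                                pos - starts[take] + 1L,
                                                edits$alt[k])
                        tag <- sprintf("%d:%s>%s", pos, edits$ref[k],
                                       edits$alt[k])
                        edit_tags[take] <- ifelse(nzchar(edit_tags[take]),
                                                  paste0(edit_tags[take], ";", tag),
                                                  tag)
                    }
                }
                tail_tags <- rep("", n)
                for (k in seq_len(nrow(tails))) {
                    take <- stats::runif(n) < tails$fraction[k]
                    if (any(take)) {
                        reads[take] <- paste0(reads[take],
                                              to_dna(tails$tail[k]))
                        tail_tags[take] <- paste0(tail_tags[take],
                                                  to_dna(tails$tail[k]))
                    }
                }
                len <- nchar(reads)
                nerr <- stats::rbinom(n, len, perr)
                err_tags <- rep("", n)
                for (i in which(nerr > 0L)) {
                    epos <- sample.int(len[i], nerr[i])
                    for (e in epos) {
                        oldb <- substr(reads[i], e, e)
                        newb <- sample(setdiff(DNA_BASES, oldb), 1L)
                        reads[i] <- subst_at(reads[i], e, newb)
                    }
                    err_tags[i] <- paste(sort(epos), collapse = ";")
                }
                ids <- sprintf("%s:%s:%s:%05d", sample_id, p$id, arm,
                               seq_len(n))
                recs[[length(recs) + 1L]] <- data.frame(
                    id = ids, sequence = paste0(reads, cfg$adapter),
                    quality = strrep(qchar, nchar(reads) + nchar(cfg$adapter)),
                    stringsAsFactors = FALSE)
                prov[[length(prov) + 1L]] <- data.frame(
                    read_id = ids, sample_id = sample_id, precursor = p$id,
                    arm = arm, start = starts, end = ends,
                    edits = edit_tags, tail = tail_tags, n_err = nerr,
                    err_pos = err_tags, stringsAsFactors = FALSE)
            }
        }
    })
    records <- do.call(rbind, recs) %||%
        data.frame(id = character(0), sequence = character(0),
                   quality = character(0), stringsAsFactors = FALSE)
    reads <- do.call(rbind, prov) %||%
        data.frame(read_id = character(0), stringsAsFactors = FALSE)
    truth$reads <- rbind(truth$reads, reads)
    list(records = records, truth = truth)
}

#' @noRd
subst_at <- function(x, pos, alt) {
    paste0(substr(x, 1L, pos - 1L), alt,
           substr(x, pos + 1L, nchar(x)))
}

#' Precursor table of a truth manifest
#' @param truth a `TruthManifest`.
#' @return data.frame with `id`, `sequence` for the planted precursors.
#' @export
truth_precursor_df <- function(truth) {
    data.frame(id = vapply(truth$precursors, `[[`, "", "id"),
               sequence = vapply(truth$precursors, `[[`, "", "sequence"),
               stringsAsFactors = FALSE)
}

#' Genomic SNP table implied by the planted SNP events
#'
#' Converts the planted (precursor-coordinate) SNP truth into a genomic
#' variant table of the kind [call_snps()] consumes, complementing alleles
#' for minus-strand loci.
#'
#' @param truth a `TruthManifest`.
#' @return data.frame with `chrom`, `position`, `ref`, `alt`, `rsid`.
#' @export
truth_snp_table <- function(truth) {
    snps <- truth$sites[truth$sites$kind == "snp", , drop = FALSE]
    if (!nrow(snps))
        return(data.frame(chrom = character(0), position = integer(0),
                          ref = character(0), alt = character(0),
                          rsid = character(0), stringsAsFactors = FALSE))
    loci <- truth$loci[match(snps$precursor, truth$loci$id), ]
    plus <- loci$strand == "+"
    gpos <- ifelse(plus, loci$start + snps$position - 1L,
                   loci$end - snps$position + 1L)
    cmp <- function(x) chartr("ACGT", "TGCA", x)
    data.frame(chrom = loci$chrom, position = as.integer(gpos),
               ref = ifelse(plus, snps$ref, cmp(snps$ref)),
               alt = ifelse(plus, snps$alt, cmp(snps$alt)),
               rsid = sprintf("sim_rs%d", seq_len(nrow(snps))),
               stringsAsFactors = FALSE)
}

#' Write a truth manifest to disk
#'
#' Emits the genome FASTA, precursor FASTA, locus GFF3, and TSV tables for
#' planted sites and (if simulated) per-read provenance.
#'
#' @param truth a `TruthManifest`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_manifest <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(truth$genome, file.path(dir, "genome.fa"))
    pdf_ <- truth_precursor_df(truth)
    if (nrow(pdf_))
        write_fasta(stats::setNames(pdf_$sequence, pdf_$id),
                    file.path(dir, "precursors.fa"))
    if (nrow(truth$loci))
        write_loci_gff3(truth$loci, file.path(dir, "loci.gff3"))
    utils::write.table(truth$sites, file.path(dir, "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth$reads))
        utils::write.table(truth$reads, file.path(dir, "reads.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
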