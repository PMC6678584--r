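# Discovery of miRNA precursors: the conserved (homology) pipeline and the
# twelve-step species-specific pipeline, plus merging of discovered and
# imported annotation sets.

#' Configuration for precursor discovery
#'
#' @param max_homology_mismatches mismatch budget for mapping known
#'   matures, genome mappability and blocklist matching (default 2).
#' @param flank_nt flanking nucleotides extracted on each side of a
#'   candidate locus before folding (default 80).
#' @param min_total_reads minimum summed read count across profiles for a
#'   candidate unique sequence (default 10).
#' @param accumulation_fraction minimum fraction of a precursor's reads
#'   that must fall in the mature regions (default 0.65).
#' @param shift_nt admissible end shift when attributing reads to a
#'   mature region (default 2).
#' @param merge_gap maximum gap when clustering genomic read hits into
#'   candidate loci (default 10).
#' @param hairpin a [hairpin_criteria()] object.
#' @param mature a [mature_criteria()] object.
#' @param overhang_tolerance tolerance passed to
#'   [check_duplex_overhang()].
#' @param q_min,min_length,adapter preprocessing parameters.
#' @param align_mismatch,align_tail read-to-precursor alignment budgets.
#' @return a `DiscoveryConfig` list.
#' @export
discovery_config <- function(max_homology_mismatches = 2L, flank_nt = 80L,
                             min_total_reads = 10L,
                             accumulation_fraction = 0.65, shift_nt = 2L,
                             merge_gap = 10L,
                             hairpin = hairpin_criteria(),
                             mature = mature_criteria(),
                             overhang_tolerance = 1L,
                             q_min = 30L, min_length = 19L,
                             adapter = default_adapter(),
                             align_mismatch = 1L, align_tail = 3L) {
    stopifnot(max_homology_mismatches >= 0, flank_nt >= 0,
              min_total_reads >= 0, accumulation_fraction >= 0,
              accumulation_fraction <= 1, shift_nt >= 0)
    structure(list(max_homology_mismatches = as.integer(max_homology_mismatches),
                   flank_nt = as.integer(flank_nt),
                   min_total_reads = as.numeric(min_total_reads),
                   accumulation_fraction = accumulation_fraction,
                   shift_nt = as.integer(shift_nt),
                   merge_gap = as.integer(merge_gap),
                   hairpin = hairpin, mature = mature,
                   overhang_tolerance = as.integer(overhang_tolerance),
                   q_min = as.integer(q_min),
                   min_length = as.integer(min_length), adapter = adapter,
                   align_mismatch = as.integer(align_mismatch),
                   align_tail = as.integer(align_tail)),
              class = "DiscoveryConfig")
}

#' Map known mature miRNAs to a genome
#'
#' Duplicate mature sequences are collapsed first; every genomic locus on
#' either strand where a mature aligns end-to-end with at most
#' `config$max_homology_mismatches` substitutions (no indels) is reported.
#'
#' @param matures known mature sequences (named character vector, FASTA
#'   path, or `DNAStringSet`); nominal length 18-26 nt.
#' @param genome named character vector of chromosome sequences.
#' @param config a [discovery_config()].
#' @return data.frame with `mature_id` (ids of identical sequences joined
#'   with `;`), `sequence`, `chrom`, `strand`, `start`, `end`, `nmm`.
#' @export
map_known_matures <- function(matures, genome, config = discovery_config()) {
    if (is.character(matures) && length(matures) == 1L && file.exists(matures))
        matures <- read_fasta(matures)
    mseq <- as_seq_vector(matures, "matures")
    mseq <- mseq[nchar(mseq) >= 18L & nchar(mseq) <= 26L]
    mseq <- to_dna(mseq)
    ids <- tapply(names(mseq), unname(mseq), paste, collapse = ";")
    useq <- stats::setNames(names(ids), unname(ids))  # sequence -> joined ids
    gseqs <- as_seq_vector(genome, "genome")
    if (!length(useq))
        return(data.frame(mature_id = character(0), sequence = character(0),
                          chrom = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          nmm = integer(0), stringsAsFactors = FALSE))
    hits <- scan_matches_cpp(unname(useq), unname(gseqs),
                             config$max_homology_mismatches, TRUE)
    out <- data.frame(mature_id = names(useq)[hits$query],
                      sequence = unname(useq)[hits$query],
                      chrom = names(gseqs)[hits$subject],
                      strand = hits$strand, start = hits$start,
                      end = hits$start + nchar(unname(useq)[hits$query]) - 1L,
                      nmm = hits$nmm, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$strand, out$mature_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

# terminal-loop regions of a structure as an IRanges-like list of spans
#' @noRd
terminal_loops <- function(structure) {
    p <- structure$pairs
    if (!nrow(p)) return(matrix(integer(0), 0, 2))
    term <- vapply(seq_len(nrow(p)), function(r)
        !any(p[, 1] > p[r, 1] & p[, 2] < p[r, 2]), logical(1))
    cbind(p[term, 1, drop = TRUE] + 1L, p[term, 2, drop = TRUE] - 1L)
}

#' @noRd
overlaps_terminal_loop <- function(structure, span) {
    tl <- terminal_loops(structure)
    any(tl[, 1] <= span[2] & tl[, 2] >= span[1])
}

# star span implied by a mature span and the duplex 2-nt 3' overhang
#' @noRd
infer_star_span <- function(structure, span) {
    partner <- structure$partner
    idx <- span[1]:span[2]
    p <- idx[!is.na(partner[idx])]
    if (!length(p)) return(NULL)
    anchor <- p[1]
    star_end <- partner[anchor] + (anchor - span[1]) + 2L
    star_start <- star_end - (span[2] - span[1])
    if (star_start < 1L || star_end > structure$n) return(NULL)
    sort(c(star_start, star_end))
}

#' Build homology precursor candidates around mapped matures
#'
#' For each genomic hit of a known mature, the window `flank_nt`
#' nucleotides up- and downstream of the mature is extracted
#' (minus-strand hits are reverse-complemented; windows truncated at
#' chromosome edges are flagged and still evaluated), folded, and kept iff
#' the mature lies on one arm of the hairpin (it does not overlap a
#' terminal loop) and [evaluate_mature_placement()] passes.
#'
#' @param hits data.frame from [map_known_matures()].
#' @param genome named character vector of chromosome sequences.
#' @param config a [discovery_config()].
#' @return list with `precursors` (records: `id`, `sequence`, `locus`,
#'   `structure`, `matures`, `source = "homology"`) and `report` (one row
#'   per hit with `pass`, `reasons`, `truncated`).
#' @export
build_homology_candidates <- function(hits, genome,
                                      config = discovery_config()) {
    gseqs <- as_seq_vector(genome, "genome")
    precursors <- list()
    report <- NULL
    for (r in seq_len(nrow(hits))) {
        h <- hits[r, ]
        glen <- nchar(gseqs[[h$chrom]])
        ws <- max(1L, h$start - config$flank_nt)
        we <- min(glen, h$end + config$flank_nt)
        truncated <- (ws > h$start - config$flank_nt) ||
            (we < h$end + config$flank_nt)
        win <- substr(gseqs[[h$chrom]], ws, we)
        if (h$strand == "-") win <- revcomp_dna(win)
        mspan <- if (h$strand == "+") c(h$start - ws + 1L, h$end - ws + 1L)
                 else c(we - h$end + 1L, we - h$start + 1L)
        hp <- fold_hairpin(win)
        reasons <- character(0)
        if (overlaps_terminal_loop(hp, mspan) || !nrow(hp$pairs))
            reasons <- c(reasons, "not_on_arm")
        mp <- evaluate_mature_placement(hp, mspan, config$mature)
        if (!mp$pass) reasons <- c(reasons, paste0("placement_", mp$reasons))
        pass <- length(reasons) == 0L
        cand_id <- sprintf("cand-%d-%s", r, strsplit(h$mature_id, ";")[[1]][1])
        if (pass) {
            partner <- hp$partner
            mid <- (mspan[1] + mspan[2]) %/% 2L
            anchors <- which(!is.na(partner))
            arm <- if (length(anchors)) {
                near <- anchors[which.min(abs(anchors - mid))]
                if (partner[near] > near) "5p" else "3p"
            } else NA_character_
            precursors[[length(precursors) + 1L]] <- list(
                id = cand_id, sequence = win,
                locus = data.frame(id = cand_id, chrom = h$chrom, start = ws,
                                   end = we, strand = h$strand,
                                   stringsAsFactors = FALSE),
                structure = hp,
                matures = data.frame(arm = arm, start = mspan[1],
                                     end = mspan[2], stringsAsFactors = FALSE),
                source = "homology", truncated = truncated)
        }
        report <- rbind(report, data.frame(
            candidate = cand_id, mature_id = h$mature_id, chrom = h$chrom,
            start = ws, end = we, strand = h$strand, truncated = truncated,
            pass = pass, reasons = paste(reasons, collapse = ";"),
            stringsAsFactors = FALSE))
    }
    list(precursors = precursors,
         report = report %||% data.frame(candidate = character(0),
                                         stringsAsFactors = FALSE))
}

#' Read accumulation on a precursor
#'
#' Fraction of the reads aligned to a precursor that lie within a mature
#' span extended by `shift_nt` on both sides; passes at
#' `accumulation_fraction` (the 65% rule).  With zero aligned reads the
#' fraction is reported as 0 and the check fails.
#'
#' @param precursor precursor record with a `matures` data.frame.
#' @param alignments alignment rows for this precursor
#'   ([align_to_precursors()] output, filtered or not — rows are matched
#'   on `precursor_id` when the column is present).
#' @param config a [discovery_config()].
#' @return list with `fraction`, `pass`, `n_reads`.
#' @export
read_accumulation_check <- function(precursor, alignments,
                                    config = discovery_config()) {
    if (!is.null(alignments$precursor_id))
        alignments <- alignments[alignments$precursor_id == precursor$id, ,
                                 drop = FALSE]
    cnt <- alignments$count %||% rep(1, nrow(alignments))
    total <- sum(cnt)
    if (total == 0)
        return(list(fraction = 0, pass = FALSE, n_reads = 0))
    mats <- precursor$matures
    sh <- config$shift_nt
    acc <- rep(FALSE, nrow(alignments))
    for (k in seq_len(nrow(mats)))
        acc <- acc | (alignments$offset >= mats$start[k] - sh &
                      alignments$end <= mats$end[k] + sh)
    fraction <- sum(cnt[acc]) / total
    list(fraction = fraction, pass = fraction >= config$accumulation_fraction,
         n_reads = total)
}

#' @noRd
collapse_profiles <- function(profiles, config) {
    per <- lapply(profiles, function(p) {
        if (is.character(p) && length(p) == 1L) p <- read_fastq(p)
        if (!is.null(p$count)) return(p)  # already collapsed
        preprocess_profile(p, adapter = config$adapter, q_min = config$q_min,
                           min_length = config$min_length)
    })
    pooled <- collapse_unique(
        do.call(rbind, lapply(per, function(x)
            x[c("sequence", "count", "min_q25")])),
        min_length = config$min_length)
    pooled
}

#' Species-specific precursor discovery (twelve-step filter chain)
#'
#' Executes the ordered filter chain on raw profiles: (1) quality gate;
#' (2) adapter trimming and collapsing to unique reads; (3) genome
#' mappability (either strand); (4-7) removal of reads matching any
#' supplied blocklist (mRNA, known pre-miRNA, ncRNA, repeats; a missing
#' blocklist is skipped with a warning); (8) total read count across
#' profiles of at least `min_total_reads`; (9) clustering of surviving
#' genomic hits into candidate loci and extraction of `flank_nt` flanks;
#' (10) folding; (11) the hairpin energy/pairs/loop criteria; (12) read
#' accumulation in the mature regions plus the duplex 2-nt 3' overhang.
#' Per-step attrition counts are returned.
#'
#' @param profiles named list of profiles: FASTQ paths, raw record
#'   data.frames (`sequence`, `quality`), or collapsed read data.frames
#'   (`sequence`, `count`).
#' @param genome named character vector of chromosome sequences.
#' @param blocklists named list of sequence sets (named character vectors
#'   or `DNAStringSet`); conventional names `mrna`, `pre_mirna`, `ncrna`,
#'   `repeats`.  `NULL` entries are skipped with a warning.
#' @param config a [discovery_config()].
#' @return list with `precursors` (passing records with read-supported
#'   mature spans), `candidates` (per-locus report with `pass` and
#'   `reasons`), `attrition` (per-step unique-sequence and read counts),
#'   and `reads` (sequences surviving steps 1-8).
#' @export
discover_species_specific <- function(profiles, genome, blocklists = list(),
                                      config = discovery_config()) {
    gseqs <- as_seq_vector(genome, "genome")
    reads <- collapse_profiles(profiles, config)
    attrition <- data.frame(step = "collapse", n_unique = nrow(reads),
                            n_reads = sum(reads$count),
                            stringsAsFactors = FALSE)
    log_step <- function(step) {
        attrition <<- rbind(attrition, data.frame(
            step = step, n_unique = nrow(reads), n_reads = sum(reads$count),
            stringsAsFactors = FALSE))
    }

    # (3) genome-mappable on either strand
    ghits <- align_to_genome(reads, gseqs, config$max_homology_mismatches)
    reads <- reads[reads$sequence %in% ghits$read, , drop = FALSE]
    log_step("genome_mappable")

    # (4-7) blocklists
    for (bn in names(blocklists)) {
        bl <- blocklists[[bn]]
        if (is.null(bl)) {
            warning("blocklist '", bn, "' missing; filter skipped")
            next
        }
        bseqs <- as_seq_vector(bl, bn)
        if (nrow(reads)) {
            bh <- scan_matches_cpp(reads$sequence, unname(bseqs),
                                   config$max_homology_mismatches, TRUE)
            matched <- unique(reads$sequence[bh$query])
            reads <- reads[!(reads$sequence %in% matched), , drop = FALSE]
        }
        log_step(paste0("blocklist_", bn))
    }

    # (8) abundance
    reads <- reads[reads$count >= config$min_total_reads, , drop = FALSE]
    log_step("min_total_reads")

    # (9) candidate loci from surviving genomic hits
    ghits <- ghits[ghits$read %in% reads$sequence, , drop = FALSE]
    precursors <- list(); cand_report <- NULL
    if (nrow(ghits)) {
        ghits <- ghits[order(ghits$chrom, ghits$strand, ghits$start), ,
                       drop = FALSE]
        grp_key <- paste(ghits$chrom, ghits$strand)
        new_locus <- c(TRUE, grp_key[-1] != grp_key[-nrow(ghits)] |
                       ghits$start[-1] > cummax_end(ghits)[-nrow(ghits)] +
                           config$merge_gap)
        locus_id <- cumsum(new_locus)
        li <- 0L
        for (lid in unique(locus_id)) {
            li <- li + 1L
            sel <- ghits[locus_id == lid, , drop = FALSE]
            chrom <- sel$chrom[1]; strandc <- sel$strand[1]
            glen <- nchar(gseqs[[chrom]])
            ls <- min(sel$start); le <- max(sel$end)
            ws <- max(1L, ls - config$flank_nt)
            we <- min(glen, le + config$flank_nt)
            if (we - ws + 1L > 300L) {  # keep fold input bounded
                mid <- (ls + le) %/% 2L
                ws <- max(1L, mid - 149L); we <- min(glen, ws + 299L)
            }
            win <- substr(gseqs[[chrom]], ws, we)
            if (strandc == "-") win <- revcomp_dna(win)
            cand_id <- sprintf("novel-%d", li)

            # read-cluster span in window coordinates
            cs <- if (strandc == "+") ls - ws + 1L else we - le + 1L
            ce <- if (strandc == "+") le - ws + 1L else we - ls + 1L

            # (10) fold the flanked window, then excise the candidate
            # hairpin: the innermost stem enclosing the expressed span
            # (flanking sequence routinely folds into spurious side
            # hairpins that would otherwise fail the single-loop clause)
            hp_win <- fold_hairpin(win)
            enc <- hp_win$pairs[hp_win$pairs[, 1] <= cs &
                                hp_win$pairs[, 2] >= ce, , drop = FALSE]
            if (!nrow(enc)) {
                cand_report <- rbind(cand_report, data.frame(
                    candidate = cand_id, chrom = chrom, start = ws, end = we,
                    strand = strandc, n_reads = NA_real_,
                    accumulation = NA_real_, energy = NA_real_,
                    paired = NA_integer_, loops = NA_integer_, pass = FALSE,
                    reasons = "no_hairpin", stringsAsFactors = FALSE))
                next
            }
            i0 <- max(enc[, 1])
            j0 <- enc[which.max(enc[, 1]), 2]
            pseq <- substr(win, i0, j0)
            # genomic locus of the excised precursor
            if (strandc == "+") {
                ps_g <- ws + i0 - 1L; pe_g <- ws + j0 - 1L
            } else {
                ps_g <- we - j0 + 1L; pe_g <- we - i0 + 1L
            }

            # (11) hairpin criteria on the excised precursor
            hp <- fold_hairpin(pseq)
            hc <- check_hairpin_criteria(hp, config$hairpin)
            reasons <- hc$reasons

            # (12) accumulation + duplex overhang from read-defined spans
            aln <- align_to_precursors(reads, stats::setNames(pseq, cand_id),
                                       config$align_mismatch,
                                       config$align_tail)
            mats <- NULL
            if (nrow(aln)) {
                m1 <- consensus_span(aln, config$shift_nt)
                rest <- aln[aln$offset > m1[2] + config$shift_nt |
                            aln$end < m1[1] - config$shift_nt, , drop = FALSE]
                m2 <- if (nrow(rest)) consensus_span(rest, config$shift_nt) else NULL
                star_inferred <- is.null(m2)
                if (star_inferred) m2 <- infer_star_span(hp, m1)
                mats <- data.frame(start = m1[1], end = m1[2],
                                   read_defined = TRUE,
                                   stringsAsFactors = FALSE)
                if (!is.null(m2))
                    mats <- rbind(mats, data.frame(
                        start = m2[1], end = m2[2],
                        read_defined = !star_inferred,
                        stringsAsFactors = FALSE))
                mats <- mats[order(mats$start), , drop = FALSE]
                mats$arm <- if (nrow(mats) == 2L) c("5p", "3p")
                            else NA_character_
            }
            prec <- list(id = cand_id, sequence = pseq,
                         locus = data.frame(id = cand_id, chrom = chrom,
                                            start = ps_g, end = pe_g,
                                            strand = strandc,
                                            stringsAsFactors = FALSE),
                         structure = hp,
                         matures = if (!is.null(mats))
                             mats[mats$read_defined, c("arm", "start", "end"),
                                  drop = FALSE]
                         else data.frame(arm = character(0), start = integer(0),
                                         end = integer(0)),
                         source = "novel")
            acc <- read_accumulation_check(prec, aln, config)
            if (!acc$pass) reasons <- c(reasons, "accumulation")
            oh_pass <- FALSE
            if (!is.null(mats) && nrow(mats) == 2L)
                oh_pass <- tryCatch(
                    check_duplex_overhang(hp, c(mats$start[1], mats$end[1]),
                                          c(mats$start[2], mats$end[2]),
                                          config$overhang_tolerance)$pass,
                    error = function(e) FALSE)
            if (!oh_pass) reasons <- c(reasons, "overhang")
            pass <- length(reasons) == 0L
            if (pass) {
                prec$matures <- mats[c("arm", "start", "end")]
                prec$n_reads <- acc$n_reads
                precursors[[length(precursors) + 1L]] <- prec
            }
            cand_report <- rbind(cand_report, data.frame(
                candidate = cand_id, chrom = chrom, start = ps_g, end = pe_g,
                strand = strandc, n_reads = acc$n_reads,
                accumulation = acc$fraction, energy = hp$energy,
                paired = hp$paired_count, loops = hp$n_loops, pass = pass,
                reasons = paste(reasons, collapse = ";"),
                stringsAsFactors = FALSE))
        }
    }
    # a hairpin's reverse complement is itself a hairpin, so every genuine
    # precursor is also recovered from the opposite strand; keep the
    # better-supported candidate per genomic region
    if (length(precursors) > 1L) {
        keep <- rep(TRUE, length(precursors))
        nreads <- vapply(precursors, function(p) p$n_reads %||% 0, 0)
        strands <- vapply(precursors, function(p) p$locus$strand, "")
        ord <- order(-nreads, strands != "+")
        loci_df <- do.call(rbind, lapply(precursors, `[[`, "locus"))
        for (a in ord) {
            if (!keep[a]) next
            for (b in ord) {
                if (a == b || !keep[b]) next
                if (loci_df$chrom[a] == loci_df$chrom[b] &&
                    loci_df$start[a] <= loci_df$end[b] &&
                    loci_df$end[a] >= loci_df$start[b] &&
                    nreads[b] <= nreads[a])
                    keep[b] <- FALSE
            }
        }
        precursors <- precursors[keep]
    }
    attrition <- rbind(attrition, data.frame(
        step = "hairpin_and_expression",
        n_unique = length(precursors),
        n_reads = NA_real_, stringsAsFactors = FALSE))
    list(precursors = precursors,
         candidates = cand_report %||%
             data.frame(candidate = character(0), stringsAsFactors = FALSE),
         attrition = attrition, reads = reads)
}

# consensus mature span of an alignment set: the isomiR cloud around the
# best-supported span (both ends within twice the admissible shift, so a
# full +/-shift jitter cloud is kept even when its modal span sits at the
# edge), summarized by count-weighted median ends (robust to symmetric
# end jitter, unlike the modal span)
#' @noRd
consensus_span <- function(aln, shift = 2L) {
    agg <- stats::aggregate(count ~ offset + end, data = aln, sum)
    top <- agg[order(-agg$count, agg$offset), ][1, ]
    grp <- aln[abs(aln$offset - top$offset) <= 2L * shift &
               abs(aln$end - top$end) <= 2L * shift, , drop = FALSE]
    wmed <- function(x, w) {
        o <- order(x)
        x[o][which(cumsum(w[o]) >= sum(w) / 2)[1]]
    }
    c(as.integer(wmed(grp$offset, grp$count)),
      as.integer(wmed(grp$end, grp$count)))
}

# running maximum of hit ends within the current chrom/strand group,
# used for gap-based locus clustering
#' @noRd
cummax_end <- function(ghits) {
    key <- paste(ghits$chrom, ghits$strand)
    out <- numeric(nrow(ghits))
    cur <- -Inf; prev <- ""
    for (i in seq_len(nrow(ghits))) {
        if (key[i] != prev) cur <- -Inf
        cur <- max(cur, ghits$end[i])
        out[i] <- cur
        prev <- key[i]
    }
    out
}

#' Merge discovered and imported precursor annotation sets
#'
#' Loci are intersected strand-aware; overlapping entries are unified
#' under one record (the lexicographically smallest member id) carrying
#' all provenance flags, so the result is independent of input order.
#' Records lacking mature annotation are matched against supplied known
#' matures aligned to the precursor sequence; precursors still lacking
#' matures are flagged `excluded_from_editing`.  Same-locus entries with
#' conflicting strands stay separate records flagged `strand_conflict`.
#'
#' @param ... named precursor sets (lists of precursor records with
#'   `locus`), e.g. `discovered =`, `mirbase =`, `ensembl =`.
#' @param known_matures optional named character vector of mature
#'   sequences used to annotate mature spans (aligned plus-strand with at
#'   most 2 substitutions).
#' @return list of unified precursor records with `provenance`,
#'   `has_mature`, `excluded_from_editing`, `strand_conflict` fields,
#'   sorted by locus.
#' @export
merge_annotations <- function(..., known_matures = NULL) {
    sets <- list(...)
    stopifnot(length(sets) >= 1L, !is.null(names(sets)))
    recs <- list()
    for (src in names(sets)) {
        for (p in sets[[src]]) {
            p$provenance <- src
            recs[[length(recs) + 1L]] <- p
        }
    }
    if (!length(recs)) return(list())
    loci <- do.call(rbind, lapply(recs, function(p) {
        l <- p$locus
        data.frame(id = p$id, chrom = l$chrom, start = l$start, end = l$end,
                   strand = l$strand, stringsAsFactors = FALSE)
    }))
    gr <- as_granges_loci(loci)
    ov <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE)
    # connected components under strand-aware overlap
    comp <- seq_along(recs)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (h in seq_along(ov)) {
        a <- find(S4Vectors::queryHits(ov)[h])
        b <- find(S4Vectors::subjectHits(ov)[h])
        if (a != b) comp[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_along(comp), find, integer(1))

    ov_any <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE)
    conflict <- rep(FALSE, length(recs))
    qh <- S4Vectors::queryHits(ov_any); sh <- S4Vectors::subjectHits(ov_any)
    diff_strand <- loci$strand[qh] != loci$strand[sh]
    conflict[unique(qh[diff_strand])] <- TRUE

    merged <- lapply(unique(comp), function(cl) {
        members <- recs[comp == cl]
        ord <- order(vapply(members, `[[`, "", "id"))
        members <- members[ord]
        rep_ <- members[[1]]
        rep_$provenance <- sort(unique(vapply(members, `[[`, "",
                                              "provenance")))
        if (is.null(rep_$matures) || !nrow(rep_$matures)) {
            for (m in members[-1]) {
                if (!is.null(m$matures) && nrow(m$matures)) {
                    rep_$matures <- m$matures
                    break
                }
            }
        }
        rep_$strand_conflict <- any(conflict[which(comp == cl)])
        rep_$members <- vapply(members, `[[`, "", "id")
        rep_
    })

    if (!is.null(known_matures)) {
        mseqs <- to_dna(as_seq_vector(known_matures, "known matures"))
        for (i in seq_along(merged)) {
            p <- merged[[i]]
            if (!is.null(p$matures) && nrow(p$matures)) next
            hits <- scan_matches_cpp(unname(mseqs), p$sequence, 2L, FALSE)
            if (nrow(hits)) {
                hits <- hits[order(hits$nmm, hits$start), , drop = FALSE]
                best <- hits[!duplicated(hits$start), , drop = FALSE][1, ]
                mlen <- nchar(mseqs[best$query])
                arm <- if (best$start + mlen / 2 < nchar(p$sequence) / 2)
                    "5p" else "3p"
                merged[[i]]$matures <- data.frame(
                    arm = arm, start = best$start,
                    end = best$start + mlen - 1L, stringsAsFactors = FALSE)
            }
        }
    }
    for (i in seq_along(merged)) {
        hm <- !is.null(merged[[i]]$matures) && nrow(merged[[i]]$matures) > 0L
        merged[[i]]$has_mature <- hm
        merged[[i]]$excluded_from_editing <- !hm
    }
    ord <- order(vapply(merged, function(p) p$locus$chrom, ""),
                 vapply(merged, function(p) p$locus$start, 0),
                 vapply(merged, `[[`, "", "id"))
    merged[ord]
}
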