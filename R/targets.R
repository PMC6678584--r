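# Expression quantification (RPTM), expressed-miRNA selection, seed-match
# target prediction for original versus edited miRNAs, target-set
# comparison, and generic hypergeometric set enrichment.

#' Reads-per-ten-million (RPTM) expression values
#'
#' `rptm = count * 1e7 / total`, where the default denominator is the
#' total read count mapped to the mature miRNA set in that sample (pass
#' `totals` to normalize per genome-mapped reads instead).
#'
#' @param counts data.frame with `mature_id`, `sample_id`, `count`
#'   (cross-map-weighted counts are fine).
#' @param totals optional named numeric vector of per-sample denominators;
#'   defaults to the per-sample sum of `count`.  A zero total is an error.
#' @return `counts` with an added `rptm` column.
#' @export
compute_rptm <- function(counts, totals = NULL) {
    stopifnot(all(c("mature_id", "sample_id", "count") %in% names(counts)))
    if (is.null(totals)) {
        agg <- rowsum(counts$count, counts$sample_id)
        totals <- stats::setNames(agg[, 1], rownames(agg))
    }
    if (any(totals <= 0)) stop("zero total read count in sample(s): ",
                               paste(names(totals)[totals <= 0], collapse = ", "))
    counts$rptm <- counts$count * 1e7 / totals[counts$sample_id]
    counts
}

#' Select expressed miRNAs across samples
#'
#' Keeps matures with mean RPTM of at least `min_mean` and sample standard
#' deviation (n-1 denominator) of at least `min_sd` across samples;
#' samples without a record contribute RPTM 0.
#'
#' @param records data.frame from [compute_rptm()] (needs at least two
#'   samples).
#' @param min_mean,min_sd selection thresholds (defaults 5 and 1).
#' @return character vector of selected `mature_id`s.
#' @export
select_expressed <- function(records, min_mean = 5, min_sd = 1) {
    samples <- unique(records$sample_id)
    if (length(samples) < 2L) stop("need at least two samples")
    mat <- matrix(0, length(unique(records$mature_id)), length(samples),
                  dimnames = list(unique(records$mature_id), samples))
    mat[cbind(records$mature_id, records$sample_id)] <- records$rptm
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, stats::sd)
    rownames(mat)[mu >= min_mean & sdv >= min_sd]
}

#' Apply one M/E event to a mature miRNA sequence
#'
#' Substitutes the alternative nucleotide at the site's position within
#' the mature; A-to-I edits substitute G (inosine is read as guanosine).
#' The reference must match the current sequence, so applying the same
#' edit twice is an error.
#'
#' @param mature mature miRNA sequence (RNA or DNA).
#' @param position 1-based position within the mature (e.g. a site's
#'   `mature_position`); NA/NULL is an error.
#' @param ref,alt reference and alternative nucleotides.
#' @return edited sequence, in the alphabet of the input.
#' @export
apply_edit <- function(mature, position, ref, alt) {
    if (is.null(position) || is.na(position)) stop("position is NULL/NA")
    if (position < 1 || position > nchar(mature))
        stop("position outside the mature sequence")
    was_rna <- grepl("U", toupper(mature), fixed = TRUE) &&
        !grepl("T", toupper(mature), fixed = TRUE)
    m <- to_rna(mature)
    if (substr(m, position, position) != to_rna(ref))
        stop("reference mismatch at position ", position, ": have ",
             substr(m, position, position), ", expected ", to_rna(ref))
    out <- subst_at(m, position, toupper(to_rna(alt)))
    if (was_rna) out else to_dna(out)
}

#' Seed-match target prediction
#'
#' A 3'UTR window is a predicted target iff, aligning it antiparallel to
#' miRNA positions 1-8, there is a run of at least `min_run` consecutive
#' Watson-Crick pairs (G:U not counted) intersecting the seed region
#' (positions 2-8).  Operationally the UTR must contain the reverse
#' complement of mature positions 2-8 or 1-7 (run 7), or 1-8 (run 8).
#' All matching windows are reported.
#'
#' @param mature mature miRNA sequence (>= 8 nt; RNA or DNA).
#' @param utrs named character vector of 3'UTR sequences (DNA), FASTA
#'   path, or `DNAStringSet`.
#' @param mirna_id id recorded in the output.
#' @param min_run minimum consecutive Watson-Crick matches (default 7).
#' @return data.frame with `mirna_id`, `transcript_id`, `position` (start
#'   of the matched window in the UTR), `run_length`, `run_positions`
#'   (the miRNA positions covered, e.g. `"2-8"`).
#' @export
predict_targets <- function(mature, utrs, mirna_id = "mirna",
                            min_run = 7L) {
    stopifnot(nchar(mature) >= 8L, min_run >= 1L)
    if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
        utrs <- read_fasta(utrs)
    utrs <- to_dna(as_seq_vector(utrs, "UTRs"))
    m <- to_dna(mature)
    probes <- list()   # probe sequence -> (run_length, run label)
    if (min_run <= 8L)
        probes[[revcomp_dna(substr(m, 1L, 8L))]] <- c(8L, "1-8")
    if (min_run <= 7L) {
        probes[[revcomp_dna(substr(m, 2L, 8L))]] <- c(7L, "2-8")
        probes[[revcomp_dna(substr(m, 1L, 7L))]] <- c(7L, "1-7")
    }
    out <- NULL
    for (tx in names(utrs)) {
        found <- NULL
        for (pr in names(probes)) {
            hits <- gregexpr(pr, utrs[[tx]], fixed = TRUE)[[1]]
            if (hits[1] == -1L) next
            found <- rbind(found, data.frame(
                position = as.integer(hits),
                end = as.integer(hits) + nchar(pr) - 1L,
                run_length = as.integer(probes[[pr]][1]),
                run_positions = probes[[pr]][2],
                stringsAsFactors = FALSE))
        }
        if (is.null(found)) next
        # keep the maximal run when a 7-mer lies inside an 8-mer window
        found <- found[order(-found$run_length, found$position), , drop = FALSE]
        keep <- rep(TRUE, nrow(found))
        for (i in seq_len(nrow(found))) {
            if (!keep[i]) next
            inside <- found$position >= found$position[i] &
                found$end <= found$end[i] &
                found$run_length < found$run_length[i]
            keep[inside] <- FALSE
        }
        found <- found[keep, , drop = FALSE]
        out <- rbind(out, data.frame(mirna_id = mirna_id, transcript_id = tx,
                                     found[c("position", "run_length",
                                             "run_positions")],
                                     stringsAsFactors = FALSE))
    }
    out <- out %||% data.frame(mirna_id = character(0),
                               transcript_id = character(0),
                               position = integer(0),
                               run_length = integer(0),
                               run_positions = character(0),
                               stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Compare the target sets of an original and an edited miRNA
#'
#' Transcript-level comparison (positions collapsed): sizes of both sets,
#' intersection, and percent shared `100 * |A and B| / |A or B|`.
#'
#' @param targets_a,targets_b target tables from [predict_targets()]
#'   computed against the same UTR set (or character vectors of
#'   transcript ids).
#' @return one-row data.frame with `n_a`, `n_b`, `n_shared`,
#'   `percent_shared` (100 when both sets are empty).
#' @export
compare_target_sets <- function(targets_a, targets_b) {
    ta <- unique(if (is.data.frame(targets_a)) targets_a$transcript_id
                 else targets_a)
    tb <- unique(if (is.data.frame(targets_b)) targets_b$transcript_id
                 else targets_b)
    un <- union(ta, tb)
    data.frame(n_a = length(ta), n_b = length(tb),
               n_shared = length(intersect(ta, tb)),
               percent_shared = if (length(un))
                   100 * length(intersect(ta, tb)) / length(un) else 100,
               stringsAsFactors = FALSE)
}

#' Hypergeometric set enrichment
#'
#' For each annotation term, tests over-representation of the target
#' genes with the hypergeometric upper tail and corrects across terms
#' with Benjamini-Hochberg; terms with corrected p below `alpha` are
#' significant.  Terms with empty gene sets are skipped.
#'
#' @param targets character vector of target gene ids (must be contained
#'   in `universe`).
#' @param annotation term-to-gene mapping: a named list of character
#'   vectors, or a data.frame with `term` and `gene` columns.
#' @param universe character vector of all considered genes.
#' @param alpha significance level on the corrected p-value.
#' @return data.frame with `term`, `n_targets_in_term`, `n_term`, `p`,
#'   `p_adj`, `significant`, ordered by p.
#' @export
enrich_sets <- function(targets, annotation, universe, alpha = 0.05) {
    targets <- unique(targets); universe <- unique(universe)
    if (!all(targets %in% universe))
        stop("targets must be a subset of the universe")
    if (is.data.frame(annotation))
        annotation <- split(annotation$gene, annotation$term)
    annotation <- lapply(annotation, function(g) intersect(unique(g), universe))
    annotation <- annotation[vapply(annotation, length, 0L) > 0L]
    if (!length(annotation) || !length(targets))
        return(data.frame(term = character(0), n_targets_in_term = integer(0),
                          n_term = integer(0), p = numeric(0),
                          p_adj = numeric(0), significant = logical(0),
                          stringsAsFactors = FALSE))
    N <- length(universe); n <- length(targets)
    K <- vapply(annotation, length, 0L)
    k <- vapply(annotation, function(g) length(intersect(g, targets)), 0L)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(term = names(annotation), n_targets_in_term = k,
                      n_term = K, p = p,
                      p_adj = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
    out$significant <- out$p_adj < alpha
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}
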