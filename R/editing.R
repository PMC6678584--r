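# Identification, significance testing and classification of
# mutation/editing (M/E) sites on pre-miRNAs.
#
# Candidate sites are per-(position, alternative-nucleotide) tallies of
# cross-map-weighted read support.  Significance is assessed with a
# one-sided exact binomial tail against the sequencing-error null
# (per-base specific-substitution probability 10^(-Q/10)/3 at the quality
# gate Q), corrected per sample with Benjamini-Hochberg, and filtered by
# the level / support / quality / significance criteria.  Significant
# sites are classified into the categories 3'-A, 3'-U, 3'-Other, 5' site,
# A-to-I, C-to-U, Other, SNP and Pseudo.

#' Configuration for M/E site calling
#'
#' The four significance criteria: (i) editing level at least `min_level`;
#' (ii) at least `min_support` supporting reads; (iii) reads pass the
#' quality gate at `q_threshold`; (iv) multiple-test corrected p-value
#' below `alpha`.  `per_base_error` is the null probability of one
#' specific erroneous substitution at one base, `10^(-q_threshold/10)/3`
#' by default.
#'
#' @param min_level minimum editing level (support/depth), default 0.05.
#' @param min_support minimum supporting reads, default 10.
#' @param q_threshold Phred quality gate, default 30.
#' @param alpha significance level on the corrected p-value, default 0.05.
#' @param per_base_error null per-base specific-substitution probability.
#' @param correction multiple-testing correction method (a
#'   [stats::p.adjust()] method; default `"BH"`).
#' @param pseudo_weight minimum cross-map weight elsewhere for a site to
#'   be classified `Pseudo`, default 0.5.
#' @param max_mismatch,max_tail alignment budgets passed to
#'   [align_to_precursors()].
#' @return an `EditingConfig` list.
#' @export
editing_config <- function(min_level = 0.05, min_support = 10L,
                           q_threshold = 30L, alpha = 0.05,
                           per_base_error = 10^(-q_threshold / 10) / 3,
                           correction = "BH", pseudo_weight = 0.5,
                           max_mismatch = 1L, max_tail = 3L) {
    stopifnot(min_level > 0, min_level < 1, min_support >= 1,
              per_base_error > 0, per_base_error < 1)
    structure(list(min_level = min_level,
                   min_support = as.numeric(min_support),
                   q_threshold = as.integer(q_threshold), alpha = alpha,
                   per_base_error = per_base_error, correction = correction,
                   pseudo_weight = pseudo_weight,
                   max_mismatch = as.integer(max_mismatch),
                   max_tail = as.integer(max_tail)),
              class = "EditingConfig")
}

#' Canonical M/E site identifier
#'
#' `"{precursor}_{position}_{REF}_{alt}"` with the reference nucleotide in
#' uppercase RNA and the alternative in lowercase RNA (e.g.
#' `mml-mir-376c_48_A_g`).
#'
#' @param precursor_id,position,ref,alt site fields.
#' @return character vector of site ids.
#' @export
make_site_id <- function(precursor_id, position, ref, alt) {
    sprintf("%s_%d_%s_%s", precursor_id, as.integer(position),
            to_rna(ref), tolower(to_rna(alt)))
}

#' @noRd
as_precursor_records <- function(precursors) {
    if (is.list(precursors) && !is.data.frame(precursors) &&
        length(precursors) && is.list(precursors[[1]]))
        return(precursors)
    seqs <- as_seq_vector(precursors, "precursors")
    mats <- NULL
    if (is.data.frame(precursors) && !is.null(precursors$matures))
        mats <- precursors$matures
    lapply(seq_along(seqs), function(i) {
        list(id = names(seqs)[i], sequence = seqs[[i]],
             matures = if (!is.null(mats)) mats[[i]] else
                 data.frame(arm = character(0), start = integer(0),
                            end = integer(0), stringsAsFactors = FALSE))
    })
}

#' Tally per-position variants on one precursor
#'
#' Computes the cross-map-weighted depth at every precursor position and
#' the weighted support of every observed substitution, from a weighted
#' alignment table.  Non-templated soft tails are tallied separately per
#' tail nucleotide at the positions immediately following each read's
#' templated 3' end (reference `"-"` beyond the precursor end); tail reads
#' contribute to the depth at the positions their tail spans.
#'
#' @param alignments weighted alignment data.frame (from
#'   [align_to_precursors()] + [add_cross_map_weights()]; a missing
#'   `weight` column defaults to 1).
#' @param precursor a precursor record (list with `id`, `sequence`) or a
#'   single named sequence.
#' @return data.frame with `precursor_id`, `position`, `ref`, `alt`,
#'   `is_tail`, `support` (weighted), `support_raw` (unweighted read
#'   count), `depth` (weighted reads covering the position).
#' @export
tally_variants <- function(alignments, precursor) {
    if (!is.list(precursor) || is.data.frame(precursor)) {
        seqs <- as_seq_vector(precursor, "precursor")
        precursor <- list(id = names(seqs)[1], sequence = seqs[[1]])
    }
    aln <- alignments[alignments$precursor_id == precursor$id, , drop = FALSE]
    L <- nchar(precursor$sequence)
    empty <- data.frame(precursor_id = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        is_tail = logical(0), support = numeric(0),
                        support_raw = numeric(0), depth = numeric(0),
                        stringsAsFactors = FALSE)
    if (!nrow(aln)) return(empty)
    if (is.null(aln$weight)) aln$weight <- 1
    w <- aln$count * aln$weight

    maxpos <- max(c(L, aln$end + nchar(aln$tail)))
    cov <- as.numeric(IRanges::coverage(
        IRanges::IRanges(aln$offset, aln$end), weight = w, width = maxpos))

    # templated substitutions (bulk-parse the "pos:REF>ALT,..." strings)
    has_mm <- which(aln$nmm > 0L)
    sub_rows <- NULL
    if (length(has_mm)) {
        entries <- strsplit(aln$mm[has_mm], ",", fixed = TRUE)
        rows <- rep(has_mm, lengths(entries))
        ent <- unlist(entries)
        sub_rows <- data.frame(
            position = as.integer(sub(":.*$", "", ent)),
            ref = sub("^[0-9]+:(.)>.*$", "\\1", ent),
            alt = sub("^.*>", "", ent),
            is_tail = FALSE, w = w[rows], raw = aln$count[rows],
            stringsAsFactors = FALSE)
    }
    # soft tails
    has_tail <- which(nzchar(aln$tail))
    tail_rows <- NULL
    if (length(has_tail)) {
        tl <- nchar(aln$tail[has_tail])
        rows <- rep(has_tail, tl)
        kk <- sequence(tl)
        pos <- aln$end[rows] + kk
        tail_rows <- data.frame(
            position = pos,
            ref = ifelse(pos <= L, substring(precursor$sequence, pos, pos), "-"),
            alt = substring(aln$tail[rows], kk, kk),
            is_tail = TRUE, w = w[rows], raw = aln$count[rows],
            stringsAsFactors = FALSE)
    }
    var <- rbind(sub_rows, tail_rows)
    if (is.null(var) || !nrow(var)) return(empty)

    key <- paste(var$position, var$ref, var$alt, var$is_tail, sep = "\r")
    sup <- rowsum(var$w, key)
    raw <- rowsum(var$raw, key)
    u <- !duplicated(key)
    out <- data.frame(precursor_id = precursor$id,
                      position = var$position[u], ref = var$ref[u],
                      alt = var$alt[u], is_tail = var$is_tail[u],
                      support = sup[key[u], 1], support_raw = raw[key[u], 1],
                      stringsAsFactors = FALSE)
    # tail reads extend coverage beyond their templated end
    tail_depth <- numeric(maxpos)
    if (length(has_tail)) {
        td <- rowsum(var$w[var$is_tail], var$position[var$is_tail])
        tail_depth[as.integer(rownames(td))] <- td[, 1]
    }
    out$depth <- cov[out$position] + tail_depth[out$position]
    out <- out[order(out$position, out$alt, out$is_tail), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Exact binomial test of one candidate site
#'
#' One-sided upper tail `P(X >= ceiling(k))` for
#' `X ~ Binomial(n, per_base_error)`: the probability of observing at
#' least the supporting read count under the sequencing-error null.
#' Fractional (cross-map-weighted) support is rounded up before the tail
#' sum (conservative); the depth is rounded to the nearest integer and
#' never below the support.
#'
#' @param support supporting read count(s) `k` (may be fractional).
#' @param depth total covering read count(s) `n`.
#' @param config an [editing_config()] (only `per_base_error` is used).
#' @return p-value vector.
#' @export
test_site <- function(support, depth, config = editing_config()) {
    if (any(support > depth + 1e-9))
        stop("support exceeds depth")
    k <- ceiling(support - 1e-9)
    n <- pmax(k, round(depth))
    stats::pbinom(k - 1, n, config$per_base_error, lower.tail = FALSE)
}

#' Apply the significance criteria to tallied sites
#'
#' Computes p-values where absent, applies the multiple-testing correction
#' across all (position, alternative) tests within each sample, and keeps
#' sites with level >= `min_level`, support >= `min_support`, and
#' corrected p < `alpha`.
#'
#' @param sites tallied sites (rows of [tally_variants()], optionally with
#'   a `sample_id` column defining the correction families).
#' @param config an [editing_config()].
#' @param keep_all if TRUE, return all tested sites with a `significant`
#'   flag instead of only the significant ones.
#' @return data.frame of sites with added `level`, `p`, `p_adj`,
#'   `site_id`, `significant`.
#' @export
adjust_and_filter <- function(sites, config = editing_config(),
                              keep_all = FALSE) {
    if (!nrow(sites)) {
        for (col in c("level", "p", "p_adj", "site_id"))
            sites[[col]] <- if (col == "site_id") character(0) else numeric(0)
        sites$significant <- logical(0)
        return(sites)
    }
    sites$level <- sites$support / sites$depth
    if (is.null(sites$p))
        sites$p <- test_site(sites$support, sites$depth, config)
    grp <- sites$sample_id %||% rep("*", nrow(sites))
    sites$p_adj <- stats::ave(sites$p, grp, FUN = function(p)
        stats::p.adjust(p, method = config$correction))
    sites$site_id <- make_site_id(sites$precursor_id, sites$position,
                                  sites$ref, sites$alt)
    sites$significant <- sites$level >= config$min_level &
        sites$support >= config$min_support &
        sites$p_adj < config$alpha
    out <- if (keep_all) sites else
        sites[sites$significant, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify M/E sites into the nine categories
#'
#' Decision order per site: (a) if the site's supporting reads carry at
#' least `pseudo_weight` of their cross-map weight at other loci, the site
#' is a cross-mapping artifact (`Pseudo`); (b) non-templated tail
#' nucleotides beyond the mature 3' end are `3'-A` / `3'-U` / `3'-Other`
#' by tail nucleotide; (c) substitutions at or upstream of the mature
#' 5'-terminal position are `5' site`; (d) internal A-to-G is `A-to-I`
#' (inosine reads as guanosine) and C-to-U is `C-to-U`; (e) any other
#' internal substitution is `Other`, with the substitution subtype
#' recorded.  `SNP` is assigned only by [call_snps()].
#'
#' @param sites site data.frame (from [adjust_and_filter()]).
#' @param precursor precursor record with a `matures` data.frame
#'   (`arm`, `start`, `end`); sites outside any mature are classified on
#'   precursor context with `mature_position` NA.
#' @param config an [editing_config()] (for `pseudo_weight`).
#' @param elsewhere_frac optional numeric vector (per site) of the
#'   cross-map weight fraction carried by other loci; computed as
#'   `1 - support/support_raw` when those columns are present.
#' @return `sites` with added `category`, `subtype`, `arm`,
#'   `mature_position`.
#' @export
classify_sites <- function(sites, precursor, config = editing_config(),
                           elsewhere_frac = NULL) {
    if (!nrow(sites)) {
        sites$category <- character(0); sites$subtype <- character(0)
        sites$arm <- character(0); sites$mature_position <- integer(0)
        return(sites)
    }
    mats <- precursor$matures
    if (is.null(mats) || !nrow(mats))
        mats <- data.frame(arm = NA_character_, start = NA_integer_,
                           end = NA_integer_, stringsAsFactors = FALSE)
    if (is.null(elsewhere_frac)) {
        elsewhere_frac <- if (!is.null(sites$support_raw))
            pmax(0, 1 - sites$support / sites$support_raw)
        else rep(0, nrow(sites))
    }
    n <- nrow(sites)
    category <- character(n); subtype <- rep(NA_character_, n)
    arm <- rep(NA_character_, n); mpos <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        pos <- sites$position[i]
        if (all(is.na(mats$start))) {
            mi <- 1L
        } else {
            d <- pmax(mats$start - pos, 0L) + pmax(pos - mats$end, 0L)
            mi <- which.min(d)
        }
        arm[i] <- mats$arm[mi]
        if (!is.na(mats$start[mi]) && pos >= mats$start[mi] &&
            pos <= mats$end[mi])
            mpos[i] <- pos - mats$start[mi] + 1L
        ref <- to_rna(sites$ref[i]); alt <- to_rna(sites$alt[i])
        if (elsewhere_frac[i] >= config$pseudo_weight) {
            category[i] <- "Pseudo"
        } else if (isTRUE(sites$is_tail[i])) {
            category[i] <- if (alt == "A") "3'-A"
                           else if (alt == "U") "3'-U" else "3'-Other"
        } else if (!is.na(mats$start[mi]) && pos <= mats$start[mi]) {
            category[i] <- "5' site"
        } else if (ref == "A" && alt == "G") {
            category[i] <- "A-to-I"
        } else if (ref == "C" && alt == "U") {
            category[i] <- "C-to-U"
        } else {
            category[i] <- "Other"
            subtype[i] <- sprintf("%s-to-%s", ref, alt)
        }
    }
    sites$category <- category; sites$subtype <- subtype
    sites$arm <- arm; sites$mature_position <- mpos
    sites
}

#' Relabel M/E sites as SNPs against a variant table
#'
#' A site is relabeled `SNP` iff (i) its genomic position equals an
#' annotated variant's, (ii) its reference and alternative nucleotides
#' equal the variant's alleles (complemented for minus-strand precursors),
#' and (iii) its editing level is 100% in at least one sample.
#'
#' @param sites site data.frame with `precursor_id`, `position`, `ref`,
#'   `alt`, `level` (and `site_id`; the level clause uses the maximum
#'   level per `site_id` across rows, or a `max_level` column if present).
#' @param snp_table data.frame with `chrom`, `position`, `ref`, `alt`
#'   (optionally `rsid`).
#' @param loci precursor locus table (`id`, `chrom`, `start`, `end`,
#'   `strand`) mapping precursor coordinates to the genome.
#' @return `sites` with `category` set to `"SNP"` (and `rsid` attached)
#'   where all three clauses hold; precursors without a locus are
#'   ineligible and collected in the `"unlocated"` attribute.
#' @export
call_snps <- function(sites, snp_table, loci) {
    if (!nrow(sites)) { sites$rsid <- character(0); return(sites) }
    if (is.null(sites$site_id))
        sites$site_id <- make_site_id(sites$precursor_id, sites$position,
                                      sites$ref, sites$alt)
    max_level <- sites$max_level %||%
        stats::ave(sites$level, sites$site_id, FUN = max)
    li <- match(sites$precursor_id, loci$id)
    unlocated <- unique(sites$precursor_id[is.na(li)])
    strand <- loci$strand[li]
    gpos <- ifelse(strand == "+", loci$start[li] + sites$position - 1L,
                   loci$end[li] - sites$position + 1L)
    cmp <- function(x) chartr("ACGTU", "TGCAA", to_dna(x))
    g_ref <- ifelse(strand == "+", to_dna(sites$ref), cmp(sites$ref))
    g_alt <- ifelse(strand == "+", to_dna(sites$alt), cmp(sites$alt))
    key <- paste(loci$chrom[li], gpos, g_ref, g_alt)
    snp_key <- paste(snp_table$chrom, snp_table$position,
                     to_dna(snp_table$ref), to_dna(snp_table$alt))
    hit <- match(key, snp_key)
    is_snp <- !is.na(li) & !is.na(hit) & max_level >= 1 - 1e-9
    if (is.null(sites$category)) sites$category <- NA_character_
    sites$category[is_snp] <- "SNP"
    sites$rsid <- NA_character_
    if (!is.null(snp_table$rsid))
        sites$rsid[is_snp] <- snp_table$rsid[hit[is_snp]]
    attr(sites, "unlocated") <- unlocated
    sites
}

#' Combine per-sample site sets into a site-by-sample level matrix
#'
#' Takes the union of sites across samples and assembles the matrix of
#' editing levels (NA where a site was not tallied in a sample), with
#' per-site flags: number of samples detected in, number significant in,
#' and tissue groups detected in (when a sample-to-tissue map is given).
#'
#' @param site_sets named list of per-sample site data.frames (each with
#'   `site_id` and `level`; a `significant` column defaults to TRUE).
#'   Duplicate sample names are an error.
#' @param tissue_map optional named character vector sample -> tissue.
#' @return list with `sites` (per-site metadata + `max_level`,
#'   `n_samples_detected`, `n_samples_significant`, `tissues`) and
#'   `levels` (site x sample numeric matrix).
#' @export
combine_samples <- function(site_sets, tissue_map = NULL) {
    if (is.null(names(site_sets)) || anyDuplicated(names(site_sets)))
        stop("site_sets must have unique sample names")
    samples <- names(site_sets)
    all_ids <- unique(unlist(lapply(site_sets, function(s) s$site_id)))
    levels <- matrix(NA_real_, length(all_ids), length(samples),
                     dimnames = list(all_ids, samples))
    signif <- matrix(FALSE, length(all_ids), length(samples),
                     dimnames = list(all_ids, samples))
    meta <- NULL
    meta_cols <- c("site_id", "precursor_id", "position", "ref", "alt",
                   "is_tail", "category", "subtype", "arm", "mature_position")
    for (s in samples) {
        df <- site_sets[[s]]
        if (!nrow(df)) next
        levels[df$site_id, s] <- df$level
        sg <- df$significant %||% rep(TRUE, nrow(df))
        signif[df$site_id, s] <- sg
        keep <- intersect(meta_cols, names(df))
        meta <- rbind(meta, df[keep])
    }
    if (is.null(meta))
        meta <- data.frame(site_id = character(0), stringsAsFactors = FALSE)
    meta <- meta[!duplicated(meta$site_id), , drop = FALSE]
    meta <- meta[match(all_ids, meta$site_id), , drop = FALSE]
    meta$max_level <- suppressWarnings(apply(levels, 1, max, na.rm = TRUE))
    meta$max_level[!is.finite(meta$max_level)] <- NA_real_
    meta$n_samples_detected <- rowSums(!is.na(levels))
    meta$n_samples_significant <- rowSums(signif)
    meta$tissues <- if (!is.null(tissue_map)) {
        vapply(seq_along(all_ids), function(r) {
            det <- samples[!is.na(levels[r, ])]
            paste(sort(unique(tissue_map[det])), collapse = ";")
        }, character(1))
    } else rep(NA_character_, nrow(meta))
    rownames(meta) <- NULL
    list(sites = meta, levels = levels)
}

#' @noRd
mirna_family_key <- function(id) {
    key <- tolower(id)
    key <- sub("^[a-z]{2,4}-", "", key)   # species prefix (mml-, hsa-, ...)
    key <- sub("-[0-9]+$", "", key)       # locus copy suffix (-1, -2)
    key
}

#' Match conserved editing sites between two species
#'
#' Sites from the two sets are paired iff they share the normalized miRNA
#' family key, the same 1-based position within the mature miRNA, and the
#' same reference-to-alternative substitution — precursors of different
#' lengths therefore still match through the mature-relative position.
#' Sites without a `mature_position` stay unmatched.
#'
#' @param sites_a,sites_b site data.frames with `precursor_id`,
#'   `mature_position`, `ref`, `alt` (e.g. combined site tables).
#' @param family_key function mapping a precursor id to its family key
#'   (default strips the species prefix and locus-copy suffix, so
#'   `mml-mir-376a-1` and `hsa-mir-376a-2` share `mir-376a`).
#' @return data.frame of matched pairs with `family`, `mature_position`,
#'   `substitution`, `site_a`, `site_b`.
#' @export
match_conserved_sites <- function(sites_a, sites_b,
                                  family_key = mirna_family_key) {
    prep <- function(s) {
        s <- s[!is.na(s$mature_position), , drop = FALSE]
        if (is.null(s$site_id))
            s$site_id <- make_site_id(s$precursor_id, s$position %||% 0L,
                                      s$ref, s$alt)
        s$key <- paste(family_key(s$precursor_id), s$mature_position,
                       to_rna(s$ref), to_rna(s$alt), sep = "|")
        s
    }
    a <- prep(sites_a); b <- prep(sites_b)
    m <- merge(a[c("key", "site_id")], b[c("key", "site_id")],
               by = "key", suffixes = c("_a", "_b"))
    if (!nrow(m))
        return(data.frame(family = character(0), mature_position = integer(0),
                          substitution = character(0), site_a = character(0),
                          site_b = character(0), stringsAsFactors = FALSE))
    parts <- strsplit(m$key, "|", fixed = TRUE)
    data.frame(family = vapply(parts, `[`, "", 1L),
               mature_position = as.integer(vapply(parts, `[`, "", 2L)),
               substitution = paste0(vapply(parts, `[`, "", 3L), "-to-",
                                     vapply(parts, `[`, "", 4L)),
               site_a = m$site_id_a, site_b = m$site_id_b,
               stringsAsFactors = FALSE)
}

#' Call M/E sites for one sample, end to end
#'
#' Driver chaining the per-sample steps: quality-threshold filter on
#' collapsed reads, tail-aware alignment to precursors, cross-mapping
#' correction, per-precursor variant tallying, exact binomial testing with
#' per-sample BH correction and the level/support filters, category
#' classification, and (when a variant table and locus map are supplied)
#' SNP relabeling.
#'
#' @param reads collapsed reads for one sample ([collapse_unique()]
#'   output; rows with `min_q25` below `config$q_threshold` are dropped).
#' @param precursors precursor records (list with `id`, `sequence`,
#'   `matures`), e.g. `truth$precursors` or discovery output.
#' @param config an [editing_config()].
#' @param sample_id sample name recorded on every site.
#' @param snp_table,loci optional inputs for [call_snps()].
#' @param keep_all return all tested sites (with `significant` flag)
#'   rather than significant ones only.
#' @return site data.frame (columns `site_id`, `precursor_id`, `position`,
#'   `ref`, `alt`, `category`, `level`, `support`, `depth`, `p`, `p_adj`,
#'   `sample_id`, `mature_position`, ...).
#' @export
call_editing_sites <- function(reads, precursors, config = editing_config(),
                               sample_id = "sample1", snp_table = NULL,
                               loci = NULL, keep_all = FALSE) {
    precs <- as_precursor_records(precursors)
    if (!is.null(reads$min_q25) && !all(is.na(reads$min_q25)))
        reads <- reads[is.na(reads$min_q25) |
                       reads$min_q25 >= config$q_threshold, , drop = FALSE]
    aln <- align_to_precursors(reads, precs, config$max_mismatch,
                               config$max_tail)
    aln <- add_cross_map_weights(aln)
    tallies <- lapply(precs, function(p) tally_variants(aln, p))
    sites <- do.call(rbind, tallies)
    sites$sample_id <- rep(sample_id, nrow(sites))
    sites <- adjust_and_filter(sites, config, keep_all = keep_all)
    out <- NULL
    for (p in precs) {
        ps <- sites[sites$precursor_id == p$id, , drop = FALSE]
        if (nrow(ps)) out <- rbind(out, classify_sites(ps, p, config))
    }
    sites <- out %||% classify_sites(sites[0, , drop = FALSE], precs[[1]])
    if (!is.null(snp_table) && !is.null(loci) && nrow(sites))
        sites <- call_snps(sites, snp_table, loci)
    rownames(sites) <- NULL
    sites
}

#' Write a site table with the canonical column order
#'
#' @param sites site data.frame.
#' @param path output TSV path.
#' @export
write_site_table <- function(sites, path) {
    cols <- c("site_id", "precursor_id", "position", "ref", "alt",
              "category", "level", "support", "depth", "p", "p_adj",
              "sample_id", "mature_position")
    for (col in setdiff(cols, names(sites))) sites[[col]] <- NA
    extra <- setdiff(names(sites), cols)
    utils::write.table(sites[c(cols, extra)], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
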