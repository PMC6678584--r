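# M/E site tallying, significance testing, classification, SNP calling,
# sample combination and cross-species matching.

mk_aln <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    if (is.null(df$weight)) df$weight <- 1
    if (is.null(df$tail)) df$tail <- ""
    df
}

test_that("variant tallies count weighted support and depth", {
    prec <- list(id = "p", sequence = paste0(strrep("A", 10), "C",
                                             strrep("A", 10)))
    aln <- mk_aln(read = c("ref", "alt"), count = c(90, 10),
                  precursor_id = "p", offset = 1L, end = 21L,
                  nmm = c(0L, 1L), mm = c("", "11:C>T"))
    tl <- tally_variants(aln, prec)
    expect_equal(nrow(tl), 1L)
    expect_equal(tl$support, 10)
    expect_equal(tl$depth, 100)
    expect_equal(tl$ref, "C"); expect_equal(tl$alt, "T")

    # cross-map weight 0.5 halves the weighted support but not the raw
    aln$weight <- 0.5
    tl <- tally_variants(aln, prec)
    expect_equal(tl$support, 5)
    expect_equal(tl$support_raw, 10)
    expect_equal(tl$depth, 50)

    # no coverage -> nothing tallied
    expect_equal(nrow(tally_variants(aln[0, ], prec)), 0L)
})

test_that("soft tails are tallied per nucleotide beyond the templated end", {
    prec <- list(id = "p", sequence = paste0(rand_seq(20), "CC",
                                             rand_seq(5)))
    aln <- mk_aln(read = "r", count = 8, precursor_id = "p", offset = 1L,
                  end = 20L, nmm = 0L, mm = "", tail = "AA")
    tl <- tally_variants(aln, prec)
    expect_equal(nrow(tl), 2L)
    expect_true(all(tl$is_tail))
    expect_equal(tl$position, c(21L, 22L))
    expect_equal(tl$ref, c("C", "C"))
    expect_equal(tl$alt, c("A", "A"))
    expect_equal(tl$support, c(8, 8))
    expect_equal(tl$depth, c(8, 8))  # tail reads are the only coverage
})

test_that("site depth conserves reference plus alternative reads", {
    set.seed(61)
    prec <- list(id = "p", sequence = rand_seq(60))
    pos <- 30L
    refnt <- substr(prec$sequence, pos, pos)
    altnt <- setdiff(c("A", "C", "G", "T"), refnt)[1]
    aln <- mk_aln(read = c("a", "b", "c"), count = c(40, 25, 35),
                  precursor_id = "p", offset = c(10L, 10L, 12L),
                  end = c(33L, 33L, 35L), nmm = c(0L, 1L, 1L),
                  mm = c("", sprintf("%d:%s>%s", pos, refnt, altnt),
                         sprintf("%d:%s>%s", pos, refnt, altnt)))
    tl <- tally_variants(aln, prec)
    expect_equal(tl$depth, 100)
    expect_equal(tl$support, 60)   # support + ref(40) = depth
})

test_that("the binomial test equals direct tail summation", {
    cfg <- editing_config(per_base_error = 1 / 3000)
    for (n in c(1L, 5L, 30L)) {
        for (k in 0:n) {
            expect_equal(test_site(k, n, cfg),
                         oracle_binom_tail(k, n, 1 / 3000),
                         tolerance = 1e-12)
        }
    }
    expect_equal(test_site(0, 100, cfg), 1)
    # fractional support is rounded up (conservative)
    expect_equal(test_site(2.4, 30, cfg), oracle_binom_tail(3, 30, 1 / 3000))
    # strong signal is significant long before correction
    expect_equal(test_site(10, 200, cfg), oracle_binom_tail(10, 200, 1 / 3000),
                 tolerance = 1e-12)
    expect_lt(test_site(10, 200, cfg), 1e-18)
    expect_error(test_site(5, 4, cfg), "exceeds depth")
})

test_that("the four significance criteria gate sites at their boundaries", {
    cfg <- editing_config()
    base <- data.frame(precursor_id = "p", position = 10L, ref = "A",
                       alt = "G", is_tail = FALSE, support_raw = 10,
                       stringsAsFactors = FALSE)
    ok <- cbind(base, support = 10, depth = 200)     # level 0.05 exactly
    low_sup <- cbind(base, support = 9, depth = 45)  # level 0.2
    low_lvl <- cbind(base, support = 50, depth = 1250)  # level 0.04
    out <- adjust_and_filter(rbind(ok, low_sup, low_lvl), cfg)
    expect_equal(nrow(out), 1L)
    expect_equal(out$support, 10)
    expect_equal(out$site_id, "p_10_A_g")

    # corrected p of 0.06 is not significant
    marginal <- cbind(base, support = 10, depth = 200, p = 0.06)
    expect_equal(nrow(adjust_and_filter(marginal, cfg)), 0L)
    # ... but p_adj just under alpha is
    marginal$p <- 0.049
    expect_equal(nrow(adjust_and_filter(marginal, cfg)), 1L)
})

test_that("BH correction is applied within each sample", {
    cfg <- editing_config()
    sites <- data.frame(precursor_id = "p", position = 1:4, ref = "A",
                        alt = "G", is_tail = FALSE, support = 20,
                        support_raw = 20, depth = 100,
                        p = c(0.01, 0.02, 0.03, 0.04),
                        sample_id = c("s1", "s1", "s2", "s2"),
                        stringsAsFactors = FALSE)
    out <- adjust_and_filter(sites, cfg, keep_all = TRUE)
    expect_equal(out$p_adj[out$sample_id == "s1"],
                 p.adjust(c(0.01, 0.02), "BH"))
    expect_equal(out$p_adj[out$sample_id == "s2"],
                 p.adjust(c(0.03, 0.04), "BH"))
})

test_that("sites are classified into the nine categories in order", {
    prec <- list(id = "p", sequence = rand_seq(80),
                 matures = data.frame(arm = c("5p", "3p"),
                                      start = c(5L, 55L), end = c(26L, 76L),
                                      stringsAsFactors = FALSE))
    mk_site <- function(position, ref, alt, is_tail = FALSE,
                        support = 10, support_raw = 10)
        data.frame(precursor_id = "p", position = position, ref = ref,
                   alt = alt, is_tail = is_tail, support = support,
                   support_raw = support_raw, stringsAsFactors = FALSE)
    cs <- function(...) classify_sites(mk_site(...), prec)$category

    expect_equal(cs(10L, "A", "G"), "A-to-I")
    expect_equal(cs(10L, "C", "T"), "C-to-U")
    got <- classify_sites(mk_site(10L, "G", "T"), prec)
    expect_equal(got$category, "Other")
    expect_equal(got$subtype, "G-to-U")
    expect_equal(got$mature_position, 6L)
    # 5'-terminal position and 5' extensions
    expect_equal(cs(5L, "A", "G"), "5' site")
    expect_equal(cs(3L, "A", "G"), "5' site")
    # non-templated tails beyond the mature 3' end
    expect_equal(cs(28L, "C", "A", is_tail = TRUE), "3'-A")
    expect_equal(cs(28L, "C", "T", is_tail = TRUE), "3'-U")
    expect_equal(cs(28L, "C", "G", is_tail = TRUE), "3'-Other")
    # majority cross-map weight elsewhere wins over everything
    expect_equal(cs(10L, "A", "G", support = 4, support_raw = 10), "Pseudo")
    # every significant site receives exactly one category
    many <- do.call(rbind, lapply(5:40, function(p)
        mk_site(p, substr(prec$sequence, p, p),
                setdiff(c("A", "C", "G", "T"),
                        substr(prec$sequence, p, p))[1])))
    out <- classify_sites(many, prec)
    expect_false(any(is.na(out$category)))
})

test_that("SNP calling enforces position, allele and 100%-level clauses", {
    loci <- data.frame(id = c("pp", "pm"), chrom = "c1",
                       start = c(1000L, 2000L), end = c(1081L, 2081L),
                       strand = c("+", "-"), stringsAsFactors = FALSE)
    mk <- function(prec, pos, ref, alt, level)
        data.frame(precursor_id = prec, position = pos, ref = ref,
                   alt = alt, level = level,
                   site_id = make_site_id(prec, pos, ref, alt),
                   category = "Other", stringsAsFactors = FALSE)
    snp <- data.frame(chrom = "c1", position = 1009L, ref = "G", alt = "A",
                      rsid = "rs1", stringsAsFactors = FALSE)

    hit <- call_snps(mk("pp", 10L, "G", "A", 1.0), snp, loci)
    expect_equal(hit$category, "SNP")
    expect_equal(hit$rsid, "rs1")
    # clause (iii): 97% maximum level is not an SNP
    expect_equal(call_snps(mk("pp", 10L, "G", "A", 0.97), snp, loci)$category,
                 "Other")
    # ... but 100% in one of several samples is
    two <- rbind(mk("pp", 10L, "G", "A", 0.4), mk("pp", 10L, "G", "A", 1.0))
    expect_true(all(call_snps(two, snp, loci)$category == "SNP"))
    # clause (ii): allele mismatch
    expect_equal(call_snps(mk("pp", 10L, "G", "C", 1.0), snp, loci)$category,
                 "Other")
    # clause (i): position mismatch
    expect_equal(call_snps(mk("pp", 11L, "G", "A", 1.0), snp, loci)$category,
                 "Other")
    # minus-strand precursor: genomic position and alleles are complemented
    snp_m <- data.frame(chrom = "c1", position = 2072L, ref = "C",
                        alt = "T", rsid = "rs2", stringsAsFactors = FALSE)
    hit_m <- call_snps(mk("pm", 10L, "G", "A", 1.0), snp_m, loci)
    expect_equal(hit_m$category, "SNP")
    # unlocated precursors are ineligible and reported
    out <- call_snps(mk("zz", 10L, "G", "A", 1.0), snp, loci)
    expect_equal(out$category, "Other")
    expect_equal(attr(out, "unlocated"), "zz")
})

test_that("sample combination unions sites and tracks flags", {
    s1 <- data.frame(site_id = c("p_10_A_g", "p_20_C_u"),
                     precursor_id = "p", position = c(10L, 20L),
                     ref = c("A", "C"), alt = c("G", "T"),
                     level = c(0.3, 0.1), significant = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
    s2 <- data.frame(site_id = "p_10_A_g", precursor_id = "p",
                     position = 10L, ref = "A", alt = "G", level = 0.5,
                     significant = TRUE, stringsAsFactors = FALSE)
    cmb <- combine_samples(list(brain = s1, liver = s2),
                           tissue_map = c(brain = "neural",
                                          liver = "hepatic"))
    expect_equal(dim(cmb$levels), c(2L, 2L))
    expect_equal(cmb$levels["p_10_A_g", ], c(brain = 0.3, liver = 0.5))
    expect_true(is.na(cmb$levels["p_20_C_u", "liver"]))
    f <- cmb$sites[cmb$sites$site_id == "p_10_A_g", ]
    expect_equal(f$n_samples_detected, 2)
    expect_equal(f$n_samples_significant, 2)
    expect_equal(f$max_level, 0.5)
    expect_equal(f$tissues, "hepatic;neural")
    f2 <- cmb$sites[cmb$sites$site_id == "p_20_C_u", ]
    expect_equal(f2$n_samples_detected, 1)
    expect_equal(f2$n_samples_significant, 0)

    expect_error(combine_samples(list(a = s1, a = s2)), "unique")
    empty <- combine_samples(list(a = s1[0, ], b = s1[0, ]))
    expect_equal(nrow(empty$sites), 0L)
})

test_that("conserved sites match on family, mature position and substitution", {
    a <- data.frame(precursor_id = c("mml-mir-376c", "mml-mir-125b-1",
                                     "mml-mir-99"),
                    mature_position = c(6L, 4L, 7L),
                    ref = "A", alt = "G", position = 1L,
                    site_id = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
    b <- data.frame(precursor_id = c("hsa-mir-376c", "hsa-mir-125b-2",
                                     "hsa-mir-99"),
                    mature_position = c(6L, 4L, 8L),
                    ref = c("A", "A", "A"), alt = c("G", "C", "G"),
                    position = 1L, site_id = c("b1", "b2", "b3"),
                    stringsAsFactors = FALSE)
    m <- match_conserved_sites(a, b)
    expect_equal(nrow(m), 1L)
    expect_equal(m$family, "mir-376c")
    expect_equal(m$mature_position, 6L)
    expect_equal(m$substitution, "A-to-G")
    # same family/position with a different substitution does not match;
    # nor does a 1-position shift
    expect_false("mir-125b" %in% m$family)
    expect_false("mir-99" %in% m$family)
    # sites without a mature position stay unmatched
    a$mature_position <- NA_integer_
    expect_equal(nrow(match_conserved_sites(a, b)), 0L)
})

test_that("cross-mapped variants between near-identical precursors are Pseudo", {
    set.seed(19)
    p1 <- canonical_precursor()
    seq2 <- p1$sequence
    pos <- 14L  # inside the 5p mature
    ref <- substr(seq2, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    substr(seq2, pos, pos) <- alt
    precs <- list(list(id = "pa", sequence = p1$sequence,
                       matures = data.frame(arm = "5p", start = 5L, end = 26L)),
                  list(id = "pb", sequence = seq2,
                       matures = data.frame(arm = "5p", start = 5L, end = 26L)))
    reads <- make_collapsed(c(substr(p1$sequence, 5, 26), substr(seq2, 5, 26)),
                            c(500, 500))
    sites <- call_editing_sites(reads, precs, sample_id = "s")
    expect_true(nrow(sites) >= 2L)
    expect_true(all(sites$category == "Pseudo"))
    expect_equal(sort(unique(sites$position)), pos)
})

test_that("the per-sample driver recovers a planted edit end to end", {
    cfg <- simulation_config(n_precursors = 2L, genome_length = 2500L,
                             coverage_per_mature = 300L, seed = 23L,
                             editing_events = data.frame(
                                 precursor = 1, position = 9, ref = "A",
                                 alt = "G", level = 0.25))
    tr <- build_genome(cfg)
    pp <- preprocess_profile(simulate_profile(cfg, tr)$records)
    sites <- call_editing_sites(pp, tr$precursors, sample_id = "s1")
    expect_equal(nrow(sites), 1L)
    expect_equal(sites$precursor_id, "sim-mir-1")
    expect_equal(sites$position, tr$sites$position)
    expect_equal(sites$category, "A-to-I")
    expect_equal(sites$mature_position, 9L)
    expect_lt(abs(sites$level - 0.25), 4 * sqrt(0.25 * 0.75 / 300))
    expect_equal(sites$site_id,
                 make_site_id("sim-mir-1", tr$sites$position, "A", "G"))
})
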