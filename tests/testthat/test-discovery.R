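# Conserved (homology) and species-specific (twelve-step) precursor
# discovery, and annotation merging.

test_that("known matures map with the two-mismatch budget on both strands", {
    set.seed(41)
    mat <- rand_seq(22)
    mat2 <- mat
    substr(mat2, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(mat, 4, 4))[1]
    substr(mat2, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(mat, 9, 9))[1]
    mat3 <- mat2
    substr(mat3, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                    substr(mat, 15, 15))[1]
    g <- plant_genome(c(fwd = mat, rev = revcomp_dna(mat)))
    hits0 <- map_known_matures(c(m = mat), g$genome)
    expect_equal(nrow(hits0), 2L)
    expect_setequal(hits0$strand, c("+", "-"))
    expect_equal(sort(hits0$start), g$offsets$start)
    expect_true(all(hits0$nmm[order(hits0$start)] == 0L))
    # two substitutions still hit, three do not
    expect_equal(nrow(map_known_matures(c(m = mat2), g$genome)), 2L)
    expect_equal(nrow(map_known_matures(c(m = mat3), g$genome)), 0L)
    # duplicate mature sequences are collapsed with joined ids
    dup <- map_known_matures(c(a = mat, b = mat), g$genome)
    expect_equal(unique(dup$mature_id), "a;b")
})

test_that("homology candidates require a hairpin arm and clean placement", {
    set.seed(43)
    p <- canonical_precursor()
    mature <- substr(p$sequence, p$mature5p[1], p$mature5p[2])
    g <- plant_genome(c(prec = p$sequence), spacing = 120L)
    hits <- map_known_matures(c(mat = mature), g$genome)
    # keep the sense hit at the planted precursor
    hits <- hits[hits$strand == "+", ]
    out <- build_homology_candidates(hits, g$genome)
    expect_equal(length(out$precursors), 1L)
    expect_equal(out$precursors[[1]]$matures$arm, "5p")
    expect_false(out$precursors[[1]]$truncated)

    # the same mature landing in unstructured background is rejected
    gbad <- plant_genome(c(bg = paste0(rand_seq(30), mature, rand_seq(30))),
                         spacing = 120L)
    hb <- map_known_matures(c(mat = mature), gbad$genome)
    outb <- build_homology_candidates(hb[hb$strand == "+", ], gbad$genome)
    expect_equal(length(outb$precursors), 0L)
    expect_false(any(outb$report$pass))

    # a hit near the chromosome start yields a truncated, still-evaluated window
    gshort <- stats::setNames(paste0(substr(p$sequence, 1, 120), rand_seq(150)),
                              "chrT")
    hs <- map_known_matures(c(mat = mature), gshort)
    hs <- hs[hs$strand == "+", ]
    outs <- build_homology_candidates(hs, gshort)
    expect_true(outs$report$truncated[1])
    expect_true(outs$report$pass[1])
})

test_that("read accumulation passes at 65% and fails below", {
    prec <- list(id = "p", matures = data.frame(arm = "5p", start = 10L,
                                                end = 31L))
    mk <- function(n_in, n_out) data.frame(
        precursor_id = rep("p", n_in + n_out),
        offset = c(rep(9L, n_in), rep(40L, n_out)),
        end = c(rep(32L, n_in), rep(60L, n_out)),
        count = rep(1, n_in + n_out), stringsAsFactors = FALSE)
    r <- read_accumulation_check(prec, mk(70, 30))
    expect_equal(r$fraction, 0.70)
    expect_true(r$pass)
    r <- read_accumulation_check(prec, mk(64, 36))
    expect_equal(r$fraction, 0.64)
    expect_false(r$pass)
    # all reads in the loop region
    r <- read_accumulation_check(prec, mk(0, 50))
    expect_equal(r$fraction, 0)
    expect_false(r$pass)
    # no reads at all
    r <- read_accumulation_check(prec, mk(0, 0))
    expect_equal(r$fraction, 0)
    expect_false(r$pass)
})

test_that("the filter chain is monotone and discovers a planted precursor", {
    cfg <- simulation_config(n_precursors = 2L, genome_length = 2500L,
                             coverage_per_mature = 400L, seed = 29L)
    tr <- build_genome(cfg)
    sim <- simulate_profile(cfg, tr)
    res <- discover_species_specific(list(s1 = sim$records), tr$genome)
    att <- res$attrition
    n <- att$n_unique[att$step != "hairpin_and_expression"]
    expect_true(all(diff(n) <= 0))
    expect_equal(length(res$precursors), 2L)
    # each discovered locus covers one planted locus (the reported strand
    # may be either, since a hairpin's reverse complement is a hairpin)
    got <- do.call(rbind, lapply(res$precursors, `[[`, "locus"))
    planted <- tr$loci[tr$loci$type == "precursor", ]
    covered <- vapply(seq_len(nrow(planted)), function(i)
        any(got$start <= planted$end[i] & got$end >= planted$start[i]),
        TRUE)
    expect_true(all(covered))
})

test_that("blocklisted reads are removed with attrition accounting", {
    cfg <- simulation_config(n_precursors = 2L, genome_length = 2500L,
                             coverage_per_mature = 400L, seed = 29L)
    tr <- build_genome(cfg)
    sim <- simulate_profile(cfg, tr)
    # blocklist the entire first precursor (an "rRNA" lookalike)
    bl <- list(ncrna = c(rna1 = tr$precursors[[1]]$sequence))
    res <- discover_species_specific(list(s1 = sim$records), tr$genome, bl)
    expect_equal(length(res$precursors), 1L)
    l2 <- tr$loci[tr$loci$id == "sim-mir-2", ]
    got <- res$precursors[[1]]$locus
    expect_true(got$start <= l2$end && got$end >= l2$start)
    att <- res$attrition
    drop <- att$n_unique[att$step == "genome_mappable"] -
        att$n_unique[att$step == "blocklist_ncrna"]
    expect_gt(drop, 0)
    # a missing blocklist is skipped with a warning
    expect_warning(
        discover_species_specific(list(s1 = sim$records), tr$genome,
                                  list(repeats = NULL)),
        "skipped")
})

test_that("merging unifies overlapping loci independent of input order", {
    mk <- function(id, start, end, strand = "+", matures = NULL)
        list(id = id, sequence = rand_seq(end - start + 1L),
             locus = data.frame(id = id, chrom = "c1", start = start,
                                end = end, strand = strand,
                                stringsAsFactors = FALSE),
             matures = matures)
    m <- data.frame(arm = "5p", start = 5L, end = 26L,
                    stringsAsFactors = FALSE)
    d <- list(mk("novel-1", 100L, 180L, matures = m))
    mb <- list(mk("mir-x", 120L, 200L), mk("mir-y", 500L, 580L))
    en <- list(mk("ENS1", 110L, 190L))

    u1 <- merge_annotations(discovered = d, mirbase = mb, ensembl = en)
    u2 <- merge_annotations(ensembl = en, mirbase = mb, discovered = d)
    expect_equal(length(u1), 2L)
    ids <- function(u) vapply(u, `[[`, "", "id")
    expect_identical(ids(u1), ids(u2))
    merged <- u1[[which(ids(u1) != "mir-y")]]
    expect_setequal(merged$provenance, c("discovered", "mirbase", "ensembl"))
    expect_setequal(merged$members, c("novel-1", "mir-x", "ENS1"))
    # the merged record inherited the mature annotation
    expect_true(merged$has_mature)
    lone <- u1[[which(ids(u1) == "mir-y")]]
    expect_equal(lone$provenance, "mirbase")
    expect_true(lone$excluded_from_editing)
})

test_that("imported precursors get matures attached from known mature sets", {
    set.seed(47)
    p <- canonical_precursor()
    mature <- substr(p$sequence, p$mature5p[1], p$mature5p[2])
    imp <- list(list(id = "imp-1", sequence = p$sequence,
                     locus = data.frame(id = "imp-1", chrom = "c1",
                                        start = 1000L,
                                        end = 1000L + nchar(p$sequence) - 1L,
                                        strand = "+",
                                        stringsAsFactors = FALSE),
                     matures = NULL))
    u <- merge_annotations(imported = imp,
                           known_matures = c(mat = mature))
    expect_true(u[[1]]$has_mature)
    expect_equal(u[[1]]$matures$start, p$mature5p[1])
    expect_equal(u[[1]]$matures$end, p$mature5p[2])
    expect_equal(u[[1]]$matures$arm, "5p")
    # opposite strands at one locus stay separate and are flagged
    imp2 <- list(list(id = "imp-2", sequence = revcomp_dna(p$sequence),
                      locus = data.frame(id = "imp-2", chrom = "c1",
                                         start = 1000L,
                                         end = 1000L + nchar(p$sequence) - 1L,
                                         strand = "-",
                                         stringsAsFactors = FALSE),
                      matures = NULL))
    u2 <- merge_annotations(a = imp, b = imp2)
    expect_equal(length(u2), 2L)
    expect_true(all(vapply(u2, `[[`, TRUE, "strand_conflict")))
})
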