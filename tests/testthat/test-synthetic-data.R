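# The synthetic-data generator: determinism, planted truth, and the
# statistical structure of the emitted reads.

small_cfg <- function(...) {
    simulation_config(n_precursors = 2L, genome_length = 2500L,
                      coverage_per_mature = 100L, seed = 7L, ...)
}

test_that("the generator is deterministic under a fixed seed", {
    cfg <- small_cfg(editing_events = data.frame(
        precursor = 1, position = 8, ref = "A", alt = "G", level = 0.3))
    t1 <- build_genome(cfg); t2 <- build_genome(cfg)
    expect_identical(t1$genome, t2$genome)
    expect_identical(t1$loci, t2$loci)
    s1 <- simulate_profile(cfg, t1); s2 <- simulate_profile(cfg, t2)
    expect_identical(s1$records, s2$records)
    expect_identical(s1$truth$reads, s2$truth$reads)
})

test_that("planted precursors pass and decoys fail the hairpin criteria", {
    cfg <- small_cfg(n_decoys = 2L)
    tr <- build_genome(cfg)
    for (p in tr$precursors)
        expect_true(check_hairpin_criteria(fold_hairpin(p$sequence))$pass)
    decoys <- tr$loci[tr$loci$type == "decoy", ]
    expect_equal(nrow(decoys), 2L)
    for (i in seq_len(nrow(decoys))) {
        ds <- substr(tr$genome[[decoys$chrom[i]]], decoys$start[i],
                     decoys$end[i])
        if (decoys$strand[i] == "-") ds <- revcomp_dna(ds)
        expect_false(check_hairpin_criteria(fold_hairpin(ds))$pass)
    }
})

test_that("planted loci appear in the genome on the annotated strand", {
    cfg <- small_cfg()
    tr <- build_genome(cfg)
    for (p in tr$precursors) {
        l <- tr$loci[tr$loci$id == p$id, ]
        gs <- substr(tr$genome[[l$chrom]], l$start, l$end)
        if (l$strand == "-") gs <- revcomp_dna(gs)
        expect_identical(gs, p$sequence)
    }
})

test_that("zero precursors yields background only, and capacity is enforced", {
    cfg <- simulation_config(n_precursors = 0L, genome_length = 500L,
                             seed = 3L)
    tr <- build_genome(cfg)
    expect_equal(nrow(tr$loci), 0L)
    expect_equal(nchar(tr$genome[[1]]), 500L)
    expect_equal(nrow(simulate_profile(cfg, tr)$records), 0L)
    expect_error(simulation_config(n_precursors = 50L, genome_length = 1000L),
                 "too small")
})

test_that("config validation rejects malformed planted events", {
    expect_error(small_cfg(editing_events = data.frame(
        precursor = 1, position = 40, ref = "A", alt = "G", level = 0.3)),
        "outside the mature")
    expect_error(small_cfg(editing_events = data.frame(
        precursor = 9, position = 5, ref = "A", alt = "G", level = 0.3)),
        "outside 1..n_precursors")
    expect_error(small_cfg(editing_events = data.frame(
        precursor = 1, position = 5, ref = "A", alt = "G", level = 1.3)),
        "\\[0, 1\\]")
    expect_error(small_cfg(tail_events = data.frame(
        precursor = 1, tail = "AA", fraction = -0.1)), "\\[0, 1\\]")
})

test_that("observed alt fraction matches the planted level within binomial error", {
    lv <- 0.30; cov <- 500L
    cfg <- simulation_config(n_precursors = 1L, genome_length = 1500L,
                             coverage_per_mature = cov, seed = 13L,
                             base_quality = 60L,
                             editing_events = data.frame(
                                 precursor = 1, position = 10, ref = "C",
                                 alt = "T", level = lv))
    tr <- build_genome(cfg)
    sim <- simulate_profile(cfg, tr)
    rd <- sim$truth$reads
    rd <- rd[rd$arm == "5p", ]
    obs <- mean(nzchar(rd$edits))
    expect_lt(abs(obs - lv), 3 * sqrt(lv * (1 - lv) / cov))
})

test_that("level zero with high base quality emits no alternative reads", {
    cfg <- simulation_config(n_precursors = 1L, genome_length = 1500L,
                             coverage_per_mature = 100L, seed = 5L,
                             base_quality = 60L,
                             editing_events = data.frame(
                                 precursor = 1, position = 10, ref = "C",
                                 alt = "T", level = 0))
    tr <- build_genome(cfg)
    sim <- simulate_profile(cfg, tr)
    p <- tr$precursors[[1]]
    site <- tr$sites$position[1]
    rd <- sim$truth$reads
    expect_true(all(rd$edits == ""))
    cover <- rd$start <= site & rd$end >= site
    base_at_site <- substr(sim$records$sequence[cover],
                           site - rd$start[cover] + 1L,
                           site - rd$start[cover] + 1L)
    expect_true(all(base_at_site == substr(p$sequence, site, site)))
})

test_that("a tail fraction of 1 puts the tail on every read, before the adapter", {
    cfg <- simulation_config(n_precursors = 1L, genome_length = 1500L,
                             coverage_per_mature = 50L, seed = 9L,
                             base_quality = 60L,
                             tail_events = data.frame(
                                 precursor = 1, tail = "AA", fraction = 1))
    tr <- build_genome(cfg)
    sim <- simulate_profile(cfg, tr)
    expect_true(all(grepl(paste0("AA", cfg$adapter, "$"),
                          sim$records$sequence)))
    expect_true(all(sim$truth$reads$tail == "AA"))
})

test_that("every emitted read appears exactly once in the provenance", {
    cfg <- small_cfg()
    tr <- build_genome(cfg)
    sim <- simulate_profile(cfg, tr)
    expect_equal(nrow(sim$records), nrow(sim$truth$reads))
    expect_identical(sim$records$id, sim$truth$reads$read_id)
    expect_false(anyDuplicated(sim$records$id) > 0)
    counts <- table(sim$truth$reads$precursor)
    expect_true(all(counts == 2L * cfg$coverage_per_mature))
})

test_that("planted levels are recoverable from moderate coverage", {
    # coverage 200, level 0.1: empirical level within 4 binomial SD
    ok <- vapply(1:6, function(s) {
        cfg <- simulation_config(n_precursors = 1L, genome_length = 1500L,
                                 coverage_per_mature = 200L, seed = 100L + s,
                                 base_quality = 60L,
                                 editing_events = data.frame(
                                     precursor = 1, position = 12, ref = "G",
                                     alt = "A", level = 0.1))
        tr <- build_genome(cfg)
        sim <- simulate_profile(cfg, tr)
        rd <- sim$truth$reads[sim$truth$reads$arm == "5p", ]
        abs(mean(nzchar(rd$edits)) - 0.1) <= 4 * sqrt(0.1 * 0.9 / 200)
    }, TRUE)
    expect_true(all(ok))
})

test_that("truth manifests serialize to plain-text files", {
    cfg <- small_cfg(snp_events = data.frame(precursor = 2, position = 6,
                                             ref = "T", alt = "C"))
    tr <- build_genome(cfg)
    tr <- simulate_profile(cfg, tr)$truth
    d <- tempfile("truth")
    write_truth_manifest(tr, d)
    expect_true(all(file.exists(file.path(
        d, c("genome.fa", "precursors.fa", "loci.gff3", "sites.tsv",
             "reads.tsv")))))
    snp <- truth_snp_table(tr)
    expect_equal(nrow(snp), 1L)
    l <- tr$loci[tr$loci$id == "sim-mir-2", ]
    g <- substr(tr$genome[[snp$chrom]], snp$position, snp$position)
    # table is on the plus strand of the genome
    expect_identical(g, snp$ref)
})
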