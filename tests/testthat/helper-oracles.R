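# Independent oracles used to validate the package's implementations:
# exhaustive enumeration for folding, direct summation for the binomial
# tail, quadratic scans for interval intersection and read alignment, and
# a per-window complementarity scan for seed matching.  These share only
# the model *definitions* with the package, never its algorithms.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_pair_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# all nested structures (lists of pair matrices) over a sequence,
# minimum hairpin loop 3 nt
oracle_enum_structures <- function(seq) {
    ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
    n <- length(ch)
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
        if (j - i < 4L) return(list(matrix(integer(0), 0, 2)))
        key <- paste(i, j)
        got <- memo[[key]]
        if (!is.null(got)) return(got)
        out <- rec(i + 1L, j)
        for (k in (i + 4L):j) {
            if (!oracle_pair_ok(ch[i], ch[k])) next
            for (a in rec(i + 1L, k - 1L))
                for (b in rec(k + 1L, j))
                    out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
        memo[[key]] <- out
        out
    }
    rec(1L, n)
}

# energy of one nested structure by loop decomposition, written against
# the published parameter tables independently of the package DP
oracle_structure_energy <- function(seq, pairs, par = rna_energy_params()) {
    ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
    if (!nrow(pairs)) return(0)
    pt <- function(i, j) match(paste0(ch[i], ch[j]),
                               c("AU", "UA", "CG", "GC", "GU", "UG"))
    total <- 0
    for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (is.na(pt(i, j)) || j - i < 4L) return(Inf)
        ins <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
        if (nrow(ins)) {
            top <- vapply(seq_len(nrow(ins)), function(a)
                !any(ins[, 1] < ins[a, 1] & ins[, 2] > ins[a, 2]), TRUE)
            ins <- ins[top, , drop = FALSE]
        }
        if (!nrow(ins)) {
            e <- par$hairpin[j - i - 1L + 1L]
        } else if (nrow(ins) == 1L) {
            k <- ins[1, 1]; l <- ins[1, 2]
            n1 <- k - i - 1L; n2 <- j - l - 1L
            if (n1 + n2 > par$max_interior) return(Inf)
            e <- if (n1 == 0L && n2 == 0L) par$stack[pt(i, j), pt(k, l)]
                 else if (n1 == 0L || n2 == 0L) par$bulge[n1 + n2 + 1L]
                 else par$interior[n1 + n2 + 1L] +
                     min(par$asym_max, par$asym_per * abs(n1 - n2))
        } else {
            e <- par$ml_a + par$ml_b * (nrow(ins) + 1L)
        }
        if (e >= 1e8) return(Inf)
        total <- total + e
    }
    total / 100
}

oracle_mfe <- function(seq, par = rna_energy_params()) {
    energies <- vapply(oracle_enum_structures(seq), function(p)
        oracle_structure_energy(seq, p, par), 0)
    min(0, energies[is.finite(energies)])
}

# exact binomial upper tail by direct summation
oracle_binom_tail <- function(k, n, p) {
    if (k <= 0) return(1)
    if (k > n) return(0)
    sum(dbinom(k:n, n, p))
}

# quadratic strand-aware interval intersection
oracle_intersect <- function(a, b) {
    out <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (a$chrom[i] != b$chrom[j] || a$strand[i] != b$strand[j]) next
        ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1L
        if (ov >= 1L)
            out <- rbind(out, data.frame(id_a = a$id[i], id_b = b$id[j],
                                         overlap = ov,
                                         stringsAsFactors = FALSE))
    }
    out
}

# sliding-window mirror of the tail-aware end-to-end alignment contract
oracle_align_one <- function(read, prec, max_mm = 1L, max_tail = 3L) {
    n <- nchar(read); L <- nchar(prec)
    if (n <= max_tail) return(NULL)
    rch <- strsplit(read, "")[[1]]; pch <- strsplit(prec, "")[[1]]
    out <- NULL
    for (s in seq_len(max(0L, L - (n - max_tail) + 1L))) {
        overhang <- max(0L, s + n - 1L - L)
        if (overhang > max_tail) next
        cov <- n - overhang
        mism <- which(rch[seq_len(cov)] != pch[s:(s + cov - 1L)])
        run <- 0L
        while (run < length(mism) && (cov - run) %in% mism) run <- run + 1L
        tlen <- overhang + min(run, max_tail - overhang)
        tpl <- n - tlen
        if (tpl < 1L) next
        internal <- sum(mism <= tpl)
        if (internal > max_mm) next
        out <- rbind(out, data.frame(offset = s, end = s + tpl - 1L,
                                     nmm = internal,
                                     tail = substr(read, tpl + 1L, n),
                                     stringsAsFactors = FALSE))
    }
    out
}

# per-offset seed-complementarity scan: returns anchor offsets s such that
# aligning miRNA position p to UTR position s + (8 - p) gives >= min_run
# consecutive Watson-Crick matches within miRNA positions 1..8
oracle_seed_anchors <- function(mature, utr, min_run = 7L) {
    m <- strsplit(chartr("Tt", "Uu", toupper(mature)), "")[[1]]
    u <- strsplit(chartr("Tt", "Uu", toupper(utr)), "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    n <- length(u)
    anchors <- integer(0)
    for (s in 0:(n - 1L)) {
        hit <- vapply(1:8, function(p) {
            idx <- s + (8L - p)
            idx >= 1L && idx <= n && u[idx] == comp[[m[p]]]
        }, TRUE)
        r <- rle(hit)
        if (any(r$values & r$lengths >= min_run)) anchors <- c(anchors, s)
    }
    anchors
}
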