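# Hairpin folding: a single-sequence minimum-free-energy fold over nested
# structures, plus the structural acceptance criteria applied to candidate
# pre-miRNAs (folding-energy / paired-nucleotide / loop-count gate,
# MIRcheck-style mature-placement rules, and the Dicer 2-nt 3' overhang).

ENERGY_INF <- 100000000L

#' Nearest-neighbor energy parameters for hairpin folding
#'
#' Returns the energy model used by [fold_hairpin()]: Turner-style stacking
#' energies for the 16 nearest-neighbor pair steps (Watson-Crick plus G.U
#' wobble), length-dependent hairpin, bulge and interior-loop penalties with
#' a Jacobson-Stockmayer logarithmic extrapolation for long loops, an
#' interior-loop asymmetry term, and an affine multibranch-loop penalty.
#' All energies are kcal/mol at 37 degrees C, stored internally as integer
#' centi-kcal so the dynamic program is exact.  The table is a module
#' constant and can be swapped by passing a modified copy to
#' [fold_hairpin()].
#'
#' @param max_size largest loop size for which penalties are tabulated.
#' @return a list with elements `stack` (6 x 6 integer matrix over pair
#'   types AU, UA, CG, GC, GU, UG), `hairpin`, `bulge`, `interior`
#'   (integer vectors, element `s + 1` holding the penalty for a loop of
#'   size `s`), `asym_per`, `asym_max`, `ml_a`, `ml_b`, `min_hp`,
#'   `max_interior`.
#' @export
rna_energy_params <- function(max_size = 300) {
    pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
    # outer pair (row) stacked on inner pair (column), kcal/mol
    stack <- matrix(c(
        #   AU     UA     CG     GC     GU     UG
        -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,  # AU
        -1.33, -0.93, -2.35, -2.11, -1.00, -0.99,  # UA
        -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,  # CG
        -2.35, -2.24, -3.42, -3.26, -1.53, -2.51,  # GC
        -1.27, -1.36, -2.51, -2.11, -0.50,  1.29,  # GU
        -1.00, -0.55, -1.53, -1.41,  0.30, -0.50), # UG
        nrow = 6, byrow = TRUE, dimnames = list(pt, pt))

    lxc <- 1.75 * 0.616  # RT ln-extrapolation coefficient
    sizes <- 0:max_size

    hp <- rep(NA_real_, max_size + 1)
    hp[(3:9) + 1] <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)
    big <- sizes > 9
    hp[big] <- 6.4 + lxc * log(sizes[big] / 9)

    bulge <- rep(NA_real_, max_size + 1)
    bulge[(1:6) + 1] <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
    big <- sizes > 6
    bulge[big] <- 4.4 + lxc * log(sizes[big] / 6)

    interior <- rep(NA_real_, max_size + 1)
    interior[(2:6) + 1] <- c(1.5, 1.6, 1.7, 2.0, 2.0)
    interior[big] <- 2.0 + lxc * log(sizes[big] / 6)

    cc <- function(x) {
        out <- as.integer(round(x * 100))
        out[is.na(out)] <- ENERGY_INF
        out
    }
    list(stack = matrix(as.integer(round(stack * 100)), 6, 6,
                        dimnames = dimnames(stack)),
         hairpin = cc(hp), bulge = cc(bulge), interior = cc(interior),
         asym_per = 50L, asym_max = 300L,
         ml_a = 340L, ml_b = 40L,
         min_hp = 3L, max_interior = 30L)
}

#' @noRd
encode_rna <- function(sequence) {
    s <- to_rna(sequence)
    check_alphabet(s)
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
    storage.mode(code) <- "integer"
    code
}

#' Fold a sequence into its minimum-free-energy nested structure
#'
#' Computes the minimum-free-energy secondary structure of a candidate
#' pre-miRNA under the nearest-neighbor model of [rna_energy_params()],
#' over all nested (pseudoknot-free) structures with hairpin loops of at
#' least 3 nt and bulge/interior loops of at most `params$max_interior`
#' unpaired nucleotides.  G.U wobble pairs are allowed.  Ties in energy are
#' broken toward the structure with more base pairs, then by a fixed
#' deterministic traceback order, so the result is reproducible.
#'
#' The nominal input is a 40-200 nt precursor candidate; shorter sequences
#' (down to a few nt) are accepted, which is convenient for exact
#' validation against exhaustive enumeration.
#'
#' @param sequence a single DNA or RNA string (A/C/G/T/U).
#' @param params energy model, see [rna_energy_params()].
#' @return an object of class `HairpinStructure`: a list with `n`,
#'   `sequence` (RNA, uppercase), `pairs` (two-column integer matrix of
#'   1-based base-pair indices, i < j), `partner` (integer vector, NA where
#'   unpaired), `energy` (kcal/mol, <= 0), `n_loops` (number of terminal
#'   hairpin loops) and `paired_count` (`2 * nrow(pairs)`).
#' @examples
#' hp <- fold_hairpin("GGGGAAAACCCC")
#' hp$energy
#' dot_bracket(hp)
#' @export
fold_hairpin <- function(sequence, params = rna_energy_params()) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) < 1L || nchar(sequence) > 300L)
        stop("sequence length must be between 1 and 300 nt")
    code <- encode_rna(sequence)
    res <- fold_mfe_cpp(code, params)
    pairs <- res$pairs
    if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    partner <- rep(NA_integer_, length(code))
    if (nrow(pairs)) {
        partner[pairs[, 1]] <- pairs[, 2]
        partner[pairs[, 2]] <- pairs[, 1]
    }
    structure(list(n = length(code), sequence = to_rna(sequence),
                   pairs = pairs, partner = partner,
                   energy = res$energy,
                   n_loops = count_terminal_loops(pairs),
                   paired_count = 2L * nrow(pairs)),
              class = "HairpinStructure")
}

# terminal (hairpin) loops = pairs with no pair nested inside
#' @noRd
count_terminal_loops <- function(pairs) {
    if (!nrow(pairs)) return(0L)
    n_inside <- vapply(seq_len(nrow(pairs)), function(r) {
        sum(pairs[, 1] > pairs[r, 1] & pairs[, 2] < pairs[r, 2])
    }, integer(1))
    sum(n_inside == 0L)
}

#' @export
print.HairpinStructure <- function(x, ...) {
    cat(sprintf("HairpinStructure: %d nt, %d pairs, %.2f kcal/mol, %d terminal loop(s)\n",
                x$n, nrow(x$pairs), x$energy, x$n_loops))
    cat(x$sequence, "\n", dot_bracket(x), "\n", sep = "")
    invisible(x)
}

#' Dot-bracket representation of a folded structure
#' @param x a `HairpinStructure`.
#' @return a dot-bracket string.
#' @export
dot_bracket <- function(x) {
    db <- rep(".", x$n)
    if (nrow(x$pairs)) {
        db[x$pairs[, 1]] <- "("
        db[x$pairs[, 2]] <- ")"
    }
    paste(db, collapse = "")
}

#' Build a HairpinStructure from a dot-bracket string
#'
#' The inverse of [dot_bracket()]; the energy of the imported structure is
#' evaluated under the same model as [fold_hairpin()].
#'
#' @param db dot-bracket string using `(`, `)` and `.`.
#' @param sequence the corresponding sequence.
#' @param params energy model.
#' @return a `HairpinStructure`.
#' @export
parse_dot_bracket <- function(db, sequence, params = rna_energy_params()) {
    ch <- strsplit(db, "", fixed = TRUE)[[1]]
    if (length(ch) != nchar(sequence))
        stop("dot-bracket and sequence lengths differ")
    open <- integer(0)
    pairs <- matrix(integer(0), 0, 2)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") open <- c(open, i)
        else if (ch[i] == ")") {
            if (!length(open)) stop("unbalanced dot-bracket")
            pairs <- rbind(pairs, c(open[length(open)], i))
            open <- open[-length(open)]
        }
    }
    if (length(open)) stop("unbalanced dot-bracket")
    partner <- rep(NA_integer_, length(ch))
    if (nrow(pairs)) {
        pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
        partner[pairs[, 1]] <- pairs[, 2]
        partner[pairs[, 2]] <- pairs[, 1]
    }
    structure(list(n = length(ch), sequence = to_rna(sequence), pairs = pairs,
                   partner = partner,
                   energy = structure_energy(sequence, pairs, params),
                   n_loops = count_terminal_loops(pairs),
                   paired_count = 2L * nrow(pairs)),
              class = "HairpinStructure")
}

#' Energy of a given nested structure
#'
#' Evaluates the free energy of an explicit set of base pairs under the
#' model of [rna_energy_params()], by decomposing the structure into its
#' loops (stacks, hairpin loops, bulges, interior loops, multibranch
#' loops).  [fold_hairpin()] minimizes exactly this quantity.
#'
#' @param sequence the sequence.
#' @param pairs two-column matrix of 1-based pair indices.
#' @param params energy model.
#' @return energy in kcal/mol (`Inf` if the structure is invalid under the
#'   model, e.g. a non-complementary pair or an oversized interior loop).
#' @export
structure_energy <- function(sequence, pairs, params = rna_energy_params()) {
    s <- strsplit(to_rna(sequence), "", fixed = TRUE)[[1]]
    n <- length(s)
    if (!nrow(pairs)) return(0)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    ptype <- function(i, j) {
        key <- paste0(s[i], s[j])
        m <- match(key, c("AU", "UA", "CG", "GC", "GU", "UG"))
        if (is.na(m)) 0L else m
    }
    cc <- function(v, size) {
        if (size + 1 > length(v)) return(ENERGY_INF)
        v[size + 1]
    }
    total <- 0L
    for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        pt <- ptype(i, j)
        if (pt == 0L || j - i < 4L) return(Inf)
        # children: pairs directly inside (i,j)
        inside <- which(pairs[, 1] > i & pairs[, 2] < j)
        if (length(inside)) {
            enclosed <- inside[vapply(inside, function(a) {
                !any(pairs[inside, 1] < pairs[a, 1] & pairs[inside, 2] > pairs[a, 2])
            }, logical(1))]
        } else enclosed <- integer(0)
        if (!length(enclosed)) {
            e <- cc(params$hairpin, j - i - 1L)
        } else if (length(enclosed) == 1L) {
            k <- pairs[enclosed, 1]; l <- pairs[enclosed, 2]
            n1 <- k - i - 1L; n2 <- j - l - 1L
            if (n1 + n2 > params$max_interior) return(Inf)
            if (n1 == 0L && n2 == 0L) {
                pti <- ptype(k, l)
                if (pti == 0L) return(Inf)
                e <- params$stack[pt, pti]
            } else if (n1 == 0L || n2 == 0L) {
                e <- cc(params$bulge, n1 + n2)
            } else {
                e <- cc(params$interior, n1 + n2) +
                    min(params$asym_max, params$asym_per * abs(n1 - n2))
            }
        } else {
            e <- params$ml_a + params$ml_b * (length(enclosed) + 1L)
        }
        if (e >= ENERGY_INF) return(Inf)
        total <- total + e
    }
    total / 100
}

#' Hairpin acceptance thresholds
#'
#' Thresholds applied by [check_hairpin_criteria()]: minimum folding energy
#' below `mfe_max` kcal/mol, at least `min_paired` paired nucleotides, and
#' at most `max_loops` terminal loop.
#'
#' @param mfe_max maximal admissible folding energy (kcal/mol, negative).
#' @param min_paired minimal number of paired nucleotides.
#' @param max_loops maximal number of terminal (hairpin) loops.
#' @return a `HairpinCriteria` list.
#' @export
hairpin_criteria <- function(mfe_max = -40, min_paired = 18L, max_loops = 1L) {
    stopifnot(mfe_max < 0, min_paired >= 0, max_loops >= 1)
    structure(list(mfe_max = mfe_max, min_paired = as.integer(min_paired),
                   max_loops = as.integer(max_loops)),
              class = "HairpinCriteria")
}

#' Check a folded candidate against the hairpin criteria
#'
#' A candidate pre-miRNA passes iff its folding energy is below
#' `criteria$mfe_max`, it has at least `criteria$min_paired` paired
#' nucleotides, and at most `criteria$max_loops` terminal loop (one central
#' loop for a canonical hairpin).  Every violated clause is reported.
#'
#' @param structure a `HairpinStructure` from [fold_hairpin()].
#' @param criteria a [hairpin_criteria()] object.
#' @return list with `pass` (logical) and `reasons` (character vector among
#'   `"energy"`, `"pairs"`, `"loops"`; empty when passing).
#' @export
check_hairpin_criteria <- function(structure, criteria = hairpin_criteria()) {
    stopifnot(inherits(structure, "HairpinStructure"))
    reasons <- character(0)
    if (!(structure$energy < criteria$mfe_max)) reasons <- c(reasons, "energy")
    if (structure$paired_count < criteria$min_paired) reasons <- c(reasons, "pairs")
    if (structure$n_loops > criteria$max_loops) reasons <- c(reasons, "loops")
    list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Mature-placement thresholds
#'
#' MIRcheck-style limits applied to the mature span on the folded
#' precursor: at most `max_bulged` bulged nucleotides, at most
#' `max_mismatch_or_asym` mismatched or asymmetrically unpaired
#' nucleotides, and at most `max_continuous_mismatch` consecutive
#' mismatched nucleotides.
#'
#' @param max_bulged,max_mismatch_or_asym,max_continuous_mismatch
#'   non-negative integer limits.
#' @return a `MatureCriteria` list.
#' @export
mature_criteria <- function(max_bulged = 2L, max_mismatch_or_asym = 5L,
                            max_continuous_mismatch = 3L) {
    stopifnot(max_bulged >= 0, max_mismatch_or_asym >= 0,
              max_continuous_mismatch >= 0)
    structure(list(max_bulged = as.integer(max_bulged),
                   max_mismatch_or_asym = as.integer(max_mismatch_or_asym),
                   max_continuous_mismatch = as.integer(max_continuous_mismatch)),
              class = "MatureCriteria")
}

#' Evaluate the placement of a mature miRNA on a folded precursor
#'
#' Classifies every unpaired nucleotide within the mature span as either
#' bulged (the opposite strand contributes no unpaired nucleotide between
#' the bracketing pairs) or mismatched/asymmetric, and applies the
#' [mature_criteria()] limits.  Runs without a paired flank on both sides
#' (e.g. reaching into the terminal loop) are counted as mismatches.
#'
#' @param structure a `HairpinStructure`.
#' @param mature integer vector `c(start, end)`, 1-based on the precursor.
#' @param criteria a [mature_criteria()] object.
#' @return list with `pass`, `reasons` (subset of `"bulge"`, `"mismatch"`,
#'   `"continuous"`), and counts `bulged`, `mismatch_or_asym`,
#'   `max_run`.
#' @export
evaluate_mature_placement <- function(structure, mature,
                                      criteria = mature_criteria()) {
    stopifnot(inherits(structure, "HairpinStructure"), length(mature) == 2L)
    s <- mature[1]; e <- mature[2]
    if (s < 1 || e > structure$n || s > e)
        stop("mature span outside precursor")
    partner <- structure$partner
    unpaired <- is.na(partner)

    bulged <- 0L; mm <- 0L; max_run <- 0L
    i <- s
    while (i <= e) {
        if (!unpaired[i]) { i <- i + 1L; next }
        # maximal unpaired run containing i (may extend beyond the span)
        a <- i; while (a > 1L && unpaired[a - 1L]) a <- a - 1L
        b <- i; while (b < structure$n && unpaired[b + 1L]) b <- b + 1L
        in_span <- min(b, e) - max(a, s) + 1L
        is_bulge <- FALSE
        if (a > 1L && b < structure$n && !unpaired[a - 1L] && !unpaired[b + 1L]) {
            opposite <- abs(partner[a - 1L] - partner[b + 1L]) - 1L
            is_bulge <- opposite == 0L
        }
        if (is_bulge) {
            bulged <- bulged + in_span
        } else {
            mm <- mm + in_span
            max_run <- max(max_run, in_span)
        }
        i <- b + 1L
    }
    reasons <- character(0)
    if (bulged > criteria$max_bulged) reasons <- c(reasons, "bulge")
    if (mm > criteria$max_mismatch_or_asym) reasons <- c(reasons, "mismatch")
    if (max_run > criteria$max_continuous_mismatch)
        reasons <- c(reasons, "continuous")
    list(pass = length(reasons) == 0L, reasons = reasons,
         bulged = bulged, mismatch_or_asym = mm, max_run = max_run)
}

#' Check the 2-nt 3' overhang of a miRNA duplex
#'
#' For a candidate 5p/3p mature pair on a folded precursor, computes the 3'
#' overhang of each strand of the implied duplex (the Dicer/Drosha
#' processing signature) and passes iff both are within `tolerance` of 2
#' nt.  If the terminal nucleotide used as anchor is unpaired, the nearest
#' paired position is used with the offset compensated.
#'
#' @param structure a `HairpinStructure`.
#' @param mature5p,mature3p integer `c(start, end)` spans of the 5p and 3p
#'   matures (5p must precede 3p; overlapping arms are an error).
#' @param tolerance admissible deviation from 2 nt (default 1).
#' @return list with `pass`, `overhang5p`, `overhang3p` (NA when no paired
#'   anchor exists on an arm, which fails the check).
#' @export
check_duplex_overhang <- function(structure, mature5p, mature3p,
                                  tolerance = 1L) {
    stopifnot(inherits(structure, "HairpinStructure"),
              length(mature5p) == 2L, length(mature3p) == 2L)
    if (any(c(mature5p, mature3p) < 1) || any(c(mature5p, mature3p) > structure$n))
        stop("mature span outside precursor")
    if (mature5p[2] >= mature3p[1])
        stop("mature arms overlap or are out of order")
    partner <- structure$partner

    anchor <- function(span) {
        # first paired position at/after the 5' end of the span
        idx <- span[1]:span[2]
        p <- idx[!is.na(partner[idx])]
        if (!length(p)) return(c(NA_integer_, NA_integer_))
        c(p[1], p[1] - span[1])   # position, offset from span start
    }
    a5 <- anchor(mature5p); a3 <- anchor(mature3p)
    oh3 <- if (is.na(a5[1])) NA_integer_
           else mature3p[2] - (partner[a5[1]] + a5[2])
    oh5 <- if (is.na(a3[1])) NA_integer_
           else mature5p[2] - (partner[a3[1]] + a3[2])
    pass <- !is.na(oh3) && !is.na(oh5) &&
        abs(oh3 - 2L) <= tolerance && abs(oh5 - 2L) <= tolerance
    list(pass = pass, overhang5p = oh5, overhang3p = oh3)
}
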