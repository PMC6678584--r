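# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
    vapply(x, function(s) {
        chartr("ACGTU", "TGCAA",
               paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
}

#' @noRd
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @noRd
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @noRd
rand_dna <- function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation helpers do not perturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    force(code)
}

#' @noRd
check_alphabet <- function(x, extra = "") {
    ok <- grepl(paste0("^[ACGTUacgtu", extra, "]*$"), x)
    if (!all(ok))
        stop("invalid characters in sequence(s): ",
             paste(utils::head(x[!ok], 3), collapse = ", "))
    invisible(TRUE)
}

# "12:A>G,40:C>T" -> data.frame(position, ref, alt); "" -> 0 rows
#' @noRd
parse_mm <- function(mm) {
    if (is.na(mm) || !nzchar(mm))
        return(data.frame(position = integer(0), ref = character(0),
                          alt = character(0), stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(mm, ",", fixed = TRUE)[[1]], "[:>]")
    data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
               ref = vapply(parts, `[`, "", 2L),
               alt = vapply(parts, `[`, "", 3L),
               stringsAsFactors = FALSE)
}

# normalize assorted sequence-set inputs to a named character vector
#' @noRd
as_seq_vector <- function(x, what = "sequences") {
    if (is(x, "DNAStringSet") || is(x, "RNAStringSet")) {
        out <- as.character(x)
        if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
        return(toupper(out))
    }
    if (is.character(x)) {
        if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
        return(toupper(x))
    }
    if (is.data.frame(x) && all(c("id", "sequence") %in% names(x)))
        return(stats::setNames(toupper(x$sequence), x$id))
    if (is.list(x) && length(x) && !is.null(x[[1]]$sequence))
        return(stats::setNames(toupper(vapply(x, `[[`, "", "sequence")),
                               vapply(x, `[[`, "", "id")))
    stop("cannot interpret ", what, " input of class ", class(x)[1])
}
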