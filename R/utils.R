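# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# 5' anchor of each read as a width-1 GRanges (alignment start on +,
# alignment end on -). No soft-clip adjustment: synthetic and filtered
# fixtures carry ungapped alignments.
fivePrimeEnds <- function(gr) {
    suppressWarnings(resize(gr, width = 1L, fix = "start"))
}

# 0-based peak center floor((start0 + end0)/2), returned as a width-1
# GRanges at the corresponding 1-based position.
centerPoints <- function(gr) {
    c0 <- (start(gr) - 1L + end(gr)) %/% 2L
    GRanges(seqnames(gr), IRanges(c0 + 1L, width = 1L),
            seqinfo = seqinfo(gr))
}

# Seqinfo -> full-genome GRanges (one range per chromosome).
genomeRanges <- function(si) {
    sl <- seqlengths(si)
    GRanges(names(sl), IRanges(1L, sl), seqinfo = si)
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Union length in bp of a (possibly overlapping) GRanges.
unionWidth <- function(gr) sum(width(reduce(gr, ignore.strand = TRUE)))
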