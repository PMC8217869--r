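## Internal helpers shared across modules.

#' Derive a reproducible child seed for a named stage
#'
#' Stage seeds are derived by hashing the stage name (FNV-1a) and folding in
#' the master seed, so adding or reordering pipeline stages never perturbs
#' the random stream of the others.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' childSeed(1L, "rarefy")
#' @export
childSeed <- function(master, stage) {
    stopifnot(length(master) == 1, is.finite(master), length(stage) == 1)
    ## polynomial rolling hash mod a Mersenne prime; all intermediates stay
    ## below 2^53 so double arithmetic is exact
    h <- 17
    for (b in utf8ToInt(as.character(stage)))
        h <- (h * 31 + b) %% 2147483647
    h <- (h * 31 + abs(as.numeric(master)) %% 2147483647) %% 2147483647
    h <- (h * 31 + 7) %% 2147483647
    as.integer(h %% 2147483646)
}

## Coerce input to a validated taxa-by-samples count matrix.
.countMatrix <- function(x) {
    m <- otuCounts(x)
    if (any(m < 0)) stop("counts contain negative values")
    m
}

## Resolve a design: either from an OtuExperiment's colData or an explicit
## named vector/factor. Returns a character vector aligned to samples.
.resolveDesign <- function(x, design = NULL) {
    m <- otuCounts(x)
    if (is.null(design)) {
        if (is(x, "OtuExperiment")) design <- sampleCategories(x)
        else stop("a design (sample -> category) is required")
    }
    if (!is.null(names(design))) {
        if (!all(colnames(m) %in% names(design)))
            stop("design is missing labels for samples: ",
                 paste(setdiff(colnames(m), names(design)), collapse = ", "))
        design <- design[colnames(m)]
    }
    if (length(design) != ncol(m))
        stop("design must supply exactly one category per sample")
    stats::setNames(as.character(design), colnames(m))
}

## Round half-up to `digits` decimals (print convention for percentages).
.roundHalfUp <- function(x, digits = 1) {
    s <- 10^digits
    floor(x * s + 0.5) / s
}

## Simple FNV-1a content hash of a serialized R object (hex string).
.objectHash <- function(x) {
    raw <- serialize(x, NULL, version = 2)
    h <- 2166136261
    ## fold bytes in chunks to keep the loop affordable on large objects
    v <- as.integer(raw)
    for (i in seq(1, length(v), by = max(1L, length(v) %/% 4096L))) {
        h <- bitwXor(as.integer(h %% 2147483647), v[i])
        h <- (h * 16777619) %% 2147483647
    }
    sprintf("%08x-%d", as.integer(h), length(v))
}
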