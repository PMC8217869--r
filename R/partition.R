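## Shared/exclusive/core OTU set algebra across categories and the
## headline percentages derived from it.

#' Per-category detected OTU sets
#'
#' An OTU belongs to a category's set when it is present (count >= 1) in at
#' least `min_reps` replicates of that category.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param design sample -> category labels (from `x` when omitted).
#' @param min_reps minimum replicates with presence (default 1).
#' @return named list of character vectors of OTU ids, one per category.
#' @export
detectSets <- function(x, design = NULL, min_reps = 1) {
    m <- .countMatrix(x)
    design <- .resolveDesign(x, design)
    lapply(split(names(design), design), function(cols) {
        pres <- rowSums(m[, cols, drop = FALSE] >= 1)
        rownames(m)[pres >= min_reps]
    })
}

#' Venn regions of category OTU sets
#'
#' Enumerates all `2^k - 1` membership regions, the core (intersection of
#' every category) and the exclusive set of each category. With more than
#' 6 sets the full enumeration is refused and only pairwise intersections
#' plus the core are returned.
#'
#' @param sets named list of character vectors, as from [detectSets()].
#' @return list with `regions` (named integer vector, names like
#'   `"A&B"`, counting OTUs in exactly those sets), `core` and `exclusive`
#'   (character vectors / named list), and `total` (size of the union).
#'   When `k > 6`: `pairwise` counts and `core` only.
#' @export
vennRegions <- function(sets) {
    k <- length(sets)
    if (k < 2) stop("need at least 2 sets")
    universe <- unique(unlist(sets))
    core <- Reduce(intersect, sets)
    exclusive <- lapply(seq_len(k), function(i)
        setdiff(sets[[i]], unique(unlist(sets[-i]))))
    names(exclusive) <- names(sets)
    if (k > 6) {
        pairs <- utils::combn(names(sets), 2)
        pw <- apply(pairs, 2, function(pp)
            length(intersect(sets[[pp[1]]], sets[[pp[2]]])))
        names(pw) <- apply(pairs, 2, paste, collapse = "&")
        return(list(pairwise = pw, core = core, exclusive = exclusive,
                    total = length(universe)))
    }
    memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    memb <- matrix(memb, ncol = k,
                   dimnames = list(universe, names(sets)))
    sig <- apply(memb, 1, function(row)
        paste(names(sets)[row], collapse = "&"))
    regions <- table(sig)
    ## report every region, including empty ones, in subset order
    all_sigs <- unlist(lapply(seq_len(k), function(r)
        apply(utils::combn(names(sets), r), 2, paste, collapse = "&")))
    out <- stats::setNames(integer(length(all_sigs)), all_sigs)
    out[names(regions)] <- as.integer(regions)
    list(regions = out, core = core, exclusive = exclusive,
         total = length(universe))
}

#' Headline partition percentages
#'
#' `percentSpecific`: share of a category's detected set that is exclusive
#' to it. `subsetShare`: share of all detected OTUs falling in the union
#' of a subset of categories. Percentages are rendered half-up to one
#' decimal, the usual print convention.
#'
#' @param sets named list from [detectSets()].
#' @param subset character vector of category names for [subsetShare()];
#'   defaults to all.
#' @param total denominator for [subsetShare()]; defaults to the size of
#'   the union of all sets.
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
percentSpecific <- function(sets) {
    vr <- vennRegions(sets)
    out <- vapply(names(sets), function(cc) {
        n <- length(sets[[cc]])
        if (n == 0) return(NA_real_)
        .roundHalfUp(100 * length(vr$exclusive[[cc]]) / n, 1)
    }, numeric(1))
    if (anyNA(out)) warning("empty category set: percentage undefined")
    out
}

#' @rdname percentSpecific
#' @export
subsetShare <- function(sets, subset = names(sets), total = NULL) {
    if (is.null(total)) total <- length(unique(unlist(sets)))
    if (total == 0) stop("empty universe")
    u <- length(unique(unlist(sets[subset])))
    .roundHalfUp(100 * u / total, 1)
}
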