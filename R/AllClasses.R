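#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' OtuExperiment: an OTU count table with sample and taxon annotation
#'
#' `OtuExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' stores a taxa-by-samples matrix of non-negative integer counts in the
#' `"counts"` assay. Sample categories (host species or environment type)
#' live in `colData(x)$category`; optional ranked taxonomy strings live in
#' `rowData(x)`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @section Validity:
#' Counts must be non-negative, finite and integer-valued; taxon and sample
#' identifiers must be present and unique.
#'
#' @seealso [otuExperiment()] for the user-facing constructor,
#'   [otuCounts()], [sampleCategories()].
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

.validOtuExperiment <- function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(m)))
            msg <- c(msg, "counts contain non-finite values")
        else {
            if (any(m < 0))
                msg <- c(msg, "counts contain negative values")
            if (any(abs(m - round(m)) > 1e-8))
                msg <- c(msg, "counts are not integer-valued")
        }
        if (is.null(rownames(object)))
            msg <- c(msg, "taxon identifiers (rownames) are required")
        else if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicated taxon identifiers")
        if (is.null(colnames(object)))
            msg <- c(msg, "sample identifiers (colnames) are required")
        else if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicated sample identifiers")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("OtuExperiment", .validOtuExperiment)

#' Construct an OtuExperiment
#'
#' @param counts taxa-by-samples matrix of non-negative integer counts with
#'   row and column names (trimmed of surrounding whitespace).
#' @param category optional character/factor of per-sample category labels,
#'   recycled against the columns of `counts` by name when named.
#' @param taxonomy optional data.frame of ranked lineage strings, one row
#'   per taxon (rownames matching `counts`).
#'
#' @return An [OtuExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 3,
#'             dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
#' otuExperiment(m, category = c("A", "B"))
#' @export
otuExperiment <- function(counts, category = NULL, taxonomy = NULL) {
    counts <- as.matrix(counts)
    if (!is.null(rownames(counts)))
        rownames(counts) <- trimws(rownames(counts))
    if (!is.null(colnames(counts)))
        colnames(counts) <- trimws(colnames(counts))
    storage.mode(counts) <- "integer"
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(category)) {
        if (!is.null(names(category)))
            category <- category[colnames(counts)]
        if (length(category) != ncol(counts))
            stop("'category' must supply one label per sample")
        cd$category <- as.character(category)
    }
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        taxonomy <- as.data.frame(taxonomy)
        rd <- S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE],
                                   row.names = rownames(counts))
    }
    new("OtuExperiment",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts), colData = cd, rowData = rd))
}

#' Result of a Sloan neutral community model fit
#'
#' Holds the fitted immigration rate `m`, the fit statistics of the beta
#' prediction and of the free-parameter-less binomial and Poisson
#' comparisons, the bootstrap confidence interval for `m`, and the
#' per-taxon partition relative to the 95% prediction band.
#'
#' @slot m fitted immigration rate in (0, 1].
#' @slot Nm product of `m` and mean library depth.
#' @slot N mean reads per sample.
#' @slot detectionLimit 1/N, the relative abundance of a single read.
#' @slot r2 coefficient of determination of the beta prediction.
#' @slot r2Binom,r2Pois fits of the binomial / Poisson alternatives.
#' @slot bootCI length-2 numeric, 2.5/97.5 bootstrap percentiles of `m`
#'   (`NA` before [bootstrapNCM()] is run).
#' @slot fitOk logical; `FALSE` when the optimiser failed or `m` is pinned
#'   at a bound.
#' @slot goodFit logical; `r2 > 0` and `r2 >= r2Pois`.
#' @slot taxa `DataFrame` with per-taxon metacommunity abundance `p`,
#'   observed frequency `freq`, prediction `pred`, band `lower`/`upper`,
#'   and `band` membership (above/within/below).
#' @export
setClass("NCMFit",
    representation(m = "numeric", Nm = "numeric", N = "numeric",
                   detectionLimit = "numeric", r2 = "numeric",
                   r2Binom = "numeric", r2Pois = "numeric",
                   bootCI = "numeric", fitOk = "logical",
                   goodFit = "logical", taxa = "DataFrame"))

setValidity("NCMFit", function(object) {
    msg <- NULL
    if (length(object@m) != 1 || object@m <= 0 || object@m > 1)
        msg <- c(msg, "m must be a single value in (0, 1]")
    if (object@r2 > 1 + 1e-12)
        msg <- c(msg, "r2 cannot exceed 1")
    tx <- object@taxa
    if (nrow(tx)) {
        if (any(tx$freq < 0 | tx$freq > 1) || any(tx$pred < 0 | tx$pred > 1))
            msg <- c(msg, "frequencies must lie in [0, 1]")
        if (!all(tx$band %in% c("above", "within", "below")))
            msg <- c(msg, "band labels must be above/within/below")
    }
    if (is.null(msg)) TRUE else msg
})

#' Modified stochasticity ratio result
#'
#' Pairwise observed Bray-Curtis dissimilarities, their null expectations
#' and MST values for all within-category sample pairs, with a per-category
#' summary and a deterministic/stochastic regime call at the 0.5 boundary.
#'
#' @slot pairs `DataFrame`: category, sample1, sample2, `d_obs`, `e_null`,
#'   `mst` per within-category pair.
#' @slot summary `DataFrame`: category, n_pairs, `mean_mst`, `regime`.
#' @slot nullModel short descriptor of the null community algorithm.
#' @slot nNull number of null randomizations.
#' @slot seed seed used for the null stream.
#' @export
setClass("MSTResult",
    representation(pairs = "DataFrame", summary = "DataFrame",
                   nullModel = "character", nNull = "integer",
                   seed = "integer"))

setValidity("MSTResult", function(object) {
    msg <- NULL
    p <- object@pairs
    if (nrow(p) && any(p$mst < -1e-12 | p$mst > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "MST values must lie in [0, 1]")
    s <- object@summary
    if (nrow(s) && !all(s$regime %in% c("deterministic", "stochastic")))
        msg <- c(msg, "regime must be deterministic/stochastic")
    if (is.null(msg)) TRUE else msg
})

#' Levins niche breadth classification
#'
#' Per-OTU observed Levins' B, the quasiswap null envelope, and the
#' generalist / specialist / neutral label.
#'
#' @slot table `DataFrame`: otu, `b_obs`, `null_mean`, `lower`, `upper`,
#'   `label`.
#' @slot nPerm number of quasiswap permutations behind the envelope.
#' @slot seed seed of the permutation stream.
#' @slot level `"sample"` or `"category"`: the resource states used.
#' @export
setClass("NicheClassification",
    representation(table = "DataFrame", nPerm = "integer",
                   seed = "integer", level = "character"))

setValidity("NicheClassification", function(object) {
    msg <- NULL
    tb <- object@table
    if (nrow(tb)) {
        if (!all(tb$label %in% c("generalist", "specialist", "neutral")))
            msg <- c(msg, "labels must be generalist/specialist/neutral")
        if (any(tb$lower > tb$upper + 1e-12))
            msg <- c(msg, "lower envelope exceeds upper envelope")
    }
    if (is.null(msg)) TRUE else msg
})

#' Permutation group-test result (PERMANOVA / ANOSIM)
#'
#' @slot method `"permanova"` or `"anosim"`.
#' @slot statistic pseudo-F (PERMANOVA) or R (ANOSIM).
#' @slot effect R-squared for PERMANOVA, `NA` for ANOSIM.
#' @slot p permutation p-value, never 0 by the +1 convention.
#' @slot nPerm,seed permutation bookkeeping.
#' @export
setClass("GroupTestResult",
    representation(method = "character", statistic = "numeric",
                   effect = "numeric", p = "numeric",
                   nPerm = "integer", seed = "integer"))

setValidity("GroupTestResult", function(object) {
    msg <- NULL
    if (object@p <= 0 || object@p > 1)
        msg <- c(msg, "p must lie in (0, 1]")
    if (object@method == "anosim" &&
        (object@statistic < -1 - 1e-12 || object@statistic > 1 + 1e-12))
        msg <- c(msg, "ANOSIM R must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Phylogenetic signal test result
#'
#' @slot K Blomberg's K.
#' @slot p permutation p-value.
#' @slot nPerm,seed permutation bookkeeping.
#' @slot trait name of the tested trait.
#' @export
setClass("PhyloSignalResult",
    representation(K = "numeric", p = "numeric", nPerm = "integer",
                   seed = "integer", trait = "character"))

setValidity("PhyloSignalResult", function(object) {
    msg <- NULL
    if (object@K < 0) msg <- c(msg, "K must be non-negative")
    if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})
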