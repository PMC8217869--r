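#' Extract the count matrix
#'
#' @param x an [OtuExperiment-class] or plain matrix.
#' @return taxa-by-samples integer matrix.
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname otuCounts
#' @export
setMethod("otuCounts", "OtuExperiment", function(x) {
    m <- SummarizedExperiment::assay(x, "counts")
    storage.mode(m) <- "integer"
    m
})

#' @rdname otuCounts
#' @export
setMethod("otuCounts", "matrix", function(x) {
    if (is.null(rownames(x)) && nrow(x) > 0)
        rownames(x) <- paste0("otu", seq_len(nrow(x)))
    if (is.null(colnames(x)) && ncol(x) > 0)
        colnames(x) <- paste0("s", seq_len(ncol(x)))
    storage.mode(x) <- "integer"
    x
})

#' Per-sample category labels
#'
#' @param x an [OtuExperiment-class].
#' @param value character/factor of category labels, one per sample.
#' @return named character vector of category labels.
#' @export
setGeneric("sampleCategories", function(x) standardGeneric("sampleCategories"))

#' @rdname sampleCategories
#' @export
setMethod("sampleCategories", "OtuExperiment", function(x) {
    if (!"category" %in% colnames(SummarizedExperiment::colData(x)))
        stop("no 'category' column in colData; supply a design")
    stats::setNames(as.character(SummarizedExperiment::colData(x)$category),
                    colnames(x))
})

#' @rdname sampleCategories
#' @export
setGeneric("sampleCategories<-",
           function(x, value) standardGeneric("sampleCategories<-"))

#' @rdname sampleCategories
#' @export
setMethod("sampleCategories<-", "OtuExperiment", function(x, value) {
    if (!is.null(names(value)))
        value <- value[colnames(x)]
    if (length(value) != ncol(x))
        stop("'value' must supply one label per sample")
    SummarizedExperiment::colData(x)$category <- as.character(value)
    x
})

#' @export
setMethod("show", "OtuExperiment", function(object) {
    cat(sprintf("OtuExperiment: %d taxa x %d samples (total reads %s)\n",
                nrow(object), ncol(object),
                format(sum(otuCounts(object)), big.mark = ",")))
    if ("category" %in% colnames(SummarizedExperiment::colData(object))) {
        tb <- table(SummarizedExperiment::colData(object)$category)
        cat("categories:",
            paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
    }
})

#' @export
setMethod("show", "NCMFit", function(object) {
    cat("Sloan neutral community model fit\n")
    cat(sprintf("  m = %.4g (Nm = %.4g, N = %.4g)\n",
                object@m, object@Nm, object@N))
    if (!anyNA(object@bootCI))
        cat(sprintf("  bootstrap 95%% CI for m: [%.4g, %.4g]\n",
                    object@bootCI[1], object@bootCI[2]))
    cat(sprintf("  R2 = %.4f (binomial %.4f, Poisson %.4f)\n",
                object@r2, object@r2Binom, object@r2Pois))
    cat(sprintf("  good fit: %s; taxa above/within/below band: %d/%d/%d\n",
                object@goodFit,
                sum(object@taxa$band == "above"),
                sum(object@taxa$band == "within"),
                sum(object@taxa$band == "below")))
})

#' @export
setMethod("show", "MSTResult", function(object) {
    cat(sprintf("Modified stochasticity ratio (%s null, %d randomizations)\n",
                object@nullModel, object@nNull))
    s <- as.data.frame(object@summary)
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %s: mean MST = %.3f over %d pairs -> %s\n",
                    s$category[i], s$mean_mst[i], s$n_pairs[i], s$regime[i]))
})

#' @export
setMethod("show", "NicheClassification", function(object) {
    tb <- table(factor(object@table$label,
                       c("generalist", "specialist", "neutral")))
    cat(sprintf(
        "Levins niche breadth classification (%d OTUs, %d permutations, %s-level)\n",
        nrow(object@table), object@nPerm, object@level))
    cat(sprintf("  generalists: %d, specialists: %d, neutral: %d\n",
                tb["generalist"], tb["specialist"], tb["neutral"]))
})

#' @export
setMethod("show", "GroupTestResult", function(object) {
    lab <- if (object@method == "permanova") "pseudo-F" else "R"
    cat(sprintf("%s: %s = %.4f", toupper(object@method), lab,
                object@statistic))
    if (!is.na(object@effect)) cat(sprintf(", R2 = %.4f", object@effect))
    cat(sprintf(", p = %.4g (%d permutations)\n", object@p, object@nPerm))
})

#' @export
setMethod("show", "PhyloSignalResult", function(object) {
    cat(sprintf("Blomberg's K for '%s': K = %.4g, p = %.4g (%d permutations)\n",
                object@trait, object@K, object@p, object@nPerm))
})

#' Classification table accessor
#' @param x a [NicheClassification-class].
#' @return `DataFrame` with one row per classified OTU.
#' @export
nicheTable <- function(x) x@table

#' Per-category MST summary accessor
#' @param x an [MSTResult-class].
#' @return `DataFrame` with category, n_pairs, mean_mst, regime.
#' @export
mstSummary <- function(x) x@summary

#' Pairwise MST values accessor
#' @param x an [MSTResult-class].
#' @return `DataFrame` of within-category pairs.
#' @export
mstPairs <- function(x) x@pairs

#' Per-taxon table of an NCM fit
#' @param x an [NCMFit-class].
#' @return `DataFrame` with p, freq, pred, lower, upper, band per taxon.
#' @export
ncmTaxa <- function(x) x@taxa

#' Point estimates of an NCM fit
#' @param x an [NCMFit-class].
#' @return named numeric vector: m, Nm, N, r2, r2_binom, r2_pois.
#' @export
ncmEstimates <- function(x) {
    c(m = x@m, Nm = x@Nm, N = x@N, r2 = x@r2,
      r2_binom = x@r2Binom, r2_pois = x@r2Pois)
}
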