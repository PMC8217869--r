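## Reading, writing and rarefying OTU count tables.

#' Read an OTU count table
#'
#' Two dialects are supported. `tsv_wide` is a plain tab-separated matrix:
#' first column taxon identifier, remaining columns samples, integer cells;
#' an optional trailing `taxonomy` column is diverted into `rowData`.
#' `shared` is the common amplicon-pipeline export where rows are samples
#' with leading `label`/`Group`/`numOtus` columns; it is transposed on load
#' so that taxa are rows internally.
#'
#' @param path path to an existing file.
#' @param dialect `"tsv_wide"` (default) or `"shared"`.
#' @param taxa_as_rows for `tsv_wide` only: set to `FALSE` when the file
#'   stores samples as rows; the matrix is transposed on load.
#' @return a validated [OtuExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("otu\ts1\ts2", "otu1\t5\t0", "otu2\t2\t3"), tf)
#' readCountTable(tf)
#' @export
readCountTable <- function(path, dialect = c("tsv_wide", "shared"),
                           taxa_as_rows = TRUE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed header: need an ID column plus data")
    taxonomy <- NULL
    if (dialect == "shared") {
        lead <- intersect(c("label", "Group", "numOtus"), colnames(df))
        if (!"Group" %in% lead)
            stop("malformed header: shared dialect requires a 'Group' column")
        sample_ids <- trimws(df$Group)
        df <- df[, setdiff(colnames(df), c("label", "Group", "numOtus")),
                 drop = FALSE]
        counts <- .parseCounts(df, row_ids = sample_ids)
        counts <- t(counts)
    } else {
        ids <- trimws(df[[1]])
        df <- df[, -1, drop = FALSE]
        if ("taxonomy" %in% colnames(df)) {
            taxonomy <- .parseTaxonomy(df$taxonomy, ids)
            df <- df[, setdiff(colnames(df), "taxonomy"), drop = FALSE]
        }
        counts <- .parseCounts(df, row_ids = ids)
        if (!taxa_as_rows) counts <- t(counts)
    }
    if (anyDuplicated(rownames(counts)))
        stop("duplicate taxon ID: ",
             rownames(counts)[duplicated(rownames(counts))][1])
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample ID: ",
             colnames(counts)[duplicated(colnames(counts))][1])
    otuExperiment(counts, taxonomy = taxonomy)
}

## Convert a character data.frame to an integer matrix, erroring with the
## offending row/column on negative or non-integer cells.
.parseCounts <- function(df, row_ids) {
    m <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(trimws(row_ids), trimws(colnames(df))))
    for (j in seq_len(ncol(df))) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) | v < 0 | v != floor(v))
        if (length(bad))
            stop(sprintf(
                "invalid count '%s' at row '%s', column '%s'",
                df[[j]][bad[1]], rownames(m)[bad[1]], colnames(m)[j]))
        m[, j] <- v
    }
    storage.mode(m) <- "integer"
    m
}

## Split "k__x; p__y; ..." style lineage strings into up to 7 ranks.
.parseTaxonomy <- function(lineages, ids) {
    parts <- strsplit(trimws(lineages), "\\s*;\\s*")
    depth <- min(max(lengths(parts)), 7L)
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")[seq_len(depth)]
    out <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
        p <- p[nzchar(p)]
        length(p) <- depth
        p[is.na(p)] <- "unclassified"
        p
    })), stringsAsFactors = FALSE)
    colnames(out) <- ranks
    rownames(out) <- trimws(ids)
    out
}

#' Write an OTU count table
#'
#' Inverse of [readCountTable()]: `readCountTable(writeCountTable(x, f))`
#' reproduces counts and identifiers exactly.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param path output path.
#' @param dialect `"tsv_wide"` or `"shared"`.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path, dialect = c("tsv_wide", "shared")) {
    dialect <- match.arg(dialect)
    m <- .countMatrix(x)
    if (nrow(m) == 0) stop("refusing to write a table with no taxa")
    if (dialect == "shared") {
        df <- data.frame(label = "0.03", Group = colnames(m),
                         numOtus = nrow(m), t(m), check.names = FALSE,
                         stringsAsFactors = FALSE)
    } else {
        df <- data.frame(otu = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a two-column sample metadata file
#'
#' @param path TSV with columns `sample_id` and `category` (header
#'   optional; the first two columns are used).
#' @return named character vector mapping sample to category.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("metadata needs two columns: sample_id, category")
    stats::setNames(trimws(as.character(df[[2]])), trimws(as.character(df[[1]])))
}

#' Rarefy every sample to a common depth
#'
#' Draws a single random subsample without replacement from each sample so
#' that every retained library has exactly `depth` reads; this mirrors the
#' normalize-once convention of amplicon workflows. The seed is mandatory
#' so the draw is reproducible and loggable.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed for the subsampling stream.
#' @param drop_below when `TRUE` (default) samples whose total is below
#'   `depth` are dropped with a warning; when `FALSE` such samples raise an
#'   error.
#' @return an [OtuExperiment-class] whose column sums all equal `depth`.
#'   Taxa that end up with zero reads everywhere are retained (so taxon
#'   identity is stable); drop them with `x[rowSums(otuCounts(x)) > 0, ]`
#'   where needed.
#' @examples
#' sim <- simulateNeutralCommunity(makeMetacommunity(50, 1, seed = 1),
#'                                 n_samples = 4, N = 1000, m = 0.5, seed = 2)
#' r <- rarefyCounts(sim, depth = 500, seed = 3)
#' colSums(otuCounts(r))
#' @export
rarefyCounts <- function(x, depth, seed, drop_below = TRUE) {
    m <- .countMatrix(x)
    if (depth < 1) stop("depth must be >= 1")
    if (missing(seed)) stop("a seed is required for rarefaction")
    totals <- colSums(m)
    low <- totals < depth
    if (all(low)) stop("depth exceeds every sample's total; empty table")
    if (any(low)) {
        if (!drop_below)
            stop("samples below depth: ",
                 paste(colnames(m)[low], collapse = ", "))
        warning("dropping ", sum(low), " sample(s) below depth: ",
                paste(colnames(m)[low], collapse = ", "))
        m <- m[, !low, drop = FALSE]
        totals <- totals[!low]
    }
    set.seed(as.integer(seed))
    out <- m
    need <- totals > depth
    if (any(need)) {
        ## vegan::rrarefy subsamples each row (= sample) without
        ## replacement; its are-these-really-counts heuristic warning is
        ## silenced because integer counts are already validated here
        sub <- suppressWarnings(
            vegan::rrarefy(t(m[, need, drop = FALSE]), depth))
        out[, need] <- t(sub)
    }
    des <- if (is(x, "OtuExperiment") &&
               "category" %in% colnames(SummarizedExperiment::colData(x)))
        sampleCategories(x)[colnames(out)] else NULL
    otuExperiment(out, category = des)
}

#' Read a host phylogeny
#'
#' @param path newick file with unique tip labels and non-negative branch
#'   lengths.
#' @return an [ape::phylo] tree.
#' @export
readHostTree <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tr <- ape::read.tree(path)
    if (anyDuplicated(tr$tip.label)) stop("duplicated tip labels")
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
        stop("negative branch lengths")
    tr
}
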