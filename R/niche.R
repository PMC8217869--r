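## Levins' niche breadth and habitat generalist/specialist classification
## against fixed-margin (quasiswap) permutation nulls.

#' Levins' niche breadth per OTU
#'
#' `B_j = 1 / sum_h p_jh^2` where `p_jh` is the fraction of OTU `j`'s reads
#' falling in resource state `h`. Resource states are individual samples by
#' default, or pooled categories with `by_category`.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param by_category pool samples into design categories before computing
#'   breadth.
#' @param design required when `by_category` and `x` carries no design.
#' @return named numeric vector of B values (zero-sum OTUs are `NA` and
#'   flagged with a warning).
#' @examples
#' m <- matrix(c(3L,3L,3L,3L, 6L,0L,0L,0L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("even", "narrow"), paste0("s", 1:4)))
#' levinsB(m)  # 4 and 1
#' @export
levinsB <- function(x, by_category = FALSE, design = NULL) {
    m <- .countMatrix(x)
    if (by_category) {
        design <- .resolveDesign(x, design)
        m <- t(rowsum(t(m), design))
    }
    tot <- rowSums(m)
    if (any(tot == 0)) warning(sum(tot == 0), " zero-sum OTU(s) return NA")
    b <- tot^2 / rowSums(m^2)
    b[tot == 0] <- NA_real_
    stats::setNames(b, rownames(m))
}

#' Patefield randomization of a count table
#'
#' Random contingency table with exactly the original row and column sums
#' (sequential multivariate-hypergeometric construction, `r2dtable`). Cell
#' fill is not preserved; see [quasiswapRandom()] for that.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param seed integer seed.
#' @return integer matrix with identical margins and dimnames.
#' @export
patefieldRandom <- function(x, seed) {
    m <- .countMatrix(x)
    if (nrow(m) == 1 || ncol(m) == 1) return(m)  # margins force the table
    set.seed(as.integer(seed))
    out <- stats::r2dtable(1, rowSums(m), colSums(m))[[1]]
    dimnames(out) <- dimnames(m)
    storage.mode(out) <- "integer"
    out
}

#' Quasiswap randomization of a count table
#'
#' Starts from a Patefield draw and applies 2x2 quasiswap updates until the
#' number of non-zero cells matches the original table, so row sums, column
#' sums and fill are all preserved exactly.
#'
#' @inheritParams patefieldRandom
#' @param nsim number of independent randomized tables.
#' @return an integer matrix (`nsim = 1`) or a list of matrices.
#' @export
quasiswapRandom <- function(x, seed, nsim = 1) {
    m <- .countMatrix(x)
    if (nrow(m) == 1 || ncol(m) == 1) {
        if (nsim == 1) return(m)
        return(rep(list(m), nsim))
    }
    out <- tryCatch({
        nm <- vegan::nullmodel(t(m), "quasiswap_count")
        sims <- stats::simulate(nm, nsim = nsim, seed = as.integer(seed))
        lapply(seq_len(nsim), function(k) {
            s <- t(sims[, , k])
            dimnames(s) <- dimnames(m)
            storage.mode(s) <- "integer"
            s
        })
    }, error = function(e) {
        if (!grepl("checkerboard", conditionMessage(e))) stop(e)
        ## no 2x2 swap is possible (dense or margin-forced table): sample
        ## Patefield tables conditioned on the observed fill by rejection
        set.seed(as.integer(seed))
        fill <- sum(m > 0)
        lapply(seq_len(nsim), function(k) {
            for (try in seq_len(1000L)) {
                cand <- stats::r2dtable(1, rowSums(m), colSums(m))[[1]]
                if (sum(cand > 0) == fill) {
                    dimnames(cand) <- dimnames(m)
                    storage.mode(cand) <- "integer"
                    return(cand)
                }
            }
            stop("fill-conditioned randomization unreachable; residual ",
                 "fill gap ", abs(sum(cand > 0) - fill))
        })
    })
    if (nsim == 1) out[[1]] else out
}

#' Classify OTUs as habitat generalists, specialists, or neutral
#'
#' For each OTU the null distribution of Levins' B is built from `n_perm`
#' quasiswap randomizations (fixed margins and fill); the envelope is the
#' 2.5th-97.5th percentile interval. Observed B above the envelope marks a
#' habitat generalist, below it a habitat specialist, inside it a neutral
#' taxon. Zero-sum OTUs are dropped before classification.
#'
#' @param x an [OtuExperiment-class] or count matrix with >= 3 samples.
#' @param n_perm number of quasiswap permutations (default 1000; below 100
#'   a warning is issued because the envelope is poorly resolved).
#' @param seed integer seed.
#' @param by_category classify against pooled categories instead of
#'   individual samples.
#' @param design design labels, needed only with `by_category`.
#' @return a [NicheClassification-class].
#' @export
classifyNiche <- function(x, n_perm = 1000, seed, by_category = FALSE,
                          design = NULL) {
    m <- .countMatrix(x)
    if (ncol(m) < 3) stop("need at least 3 samples")
    if (n_perm < 100) warning("n_perm < 100: null envelope poorly resolved")
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    if (by_category) design <- .resolveDesign(x, design)[colnames(m)]
    bfun <- function(mm) {
        if (by_category) levinsB(mm, by_category = TRUE, design = design)
        else levinsB(mm)
    }
    b_obs <- bfun(m)
    sims <- quasiswapRandom(m, seed = seed, nsim = n_perm)
    if (n_perm == 1) sims <- list(sims)
    nulls <- vapply(sims, bfun, numeric(nrow(m)))
    lower <- apply(nulls, 1, stats::quantile, probs = 0.025, names = FALSE)
    upper <- apply(nulls, 1, stats::quantile, probs = 0.975, names = FALSE)
    label <- rep("neutral", nrow(m))
    label[b_obs > upper] <- "generalist"
    label[b_obs < lower] <- "specialist"
    new("NicheClassification",
        table = S4Vectors::DataFrame(
            otu = rownames(m), b_obs = unname(b_obs),
            null_mean = unname(rowMeans(nulls)),
            lower = lower, upper = upper, label = label),
        nPerm = as.integer(n_perm), seed = as.integer(seed),
        level = if (by_category) "category" else "sample")
}
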