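## Beta diversity: Bray-Curtis dissimilarity and one-way permutation group
## tests. Bray-Curtis is delegated to vegan; the permutation machinery is
## implemented here so the p-value convention (+1 numerator/denominator)
## and seed handling are explicit and testable.

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum |x_i - x_j| / sum (x_i + x_j)` over taxa, computed on the
#' (rarefied) counts, not relative abundances.
#'
#' @param x an [OtuExperiment-class] or count matrix (taxa x samples).
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   sample ids as dimnames.
#' @export
brayCurtis <- function(x) {
    m <- .countMatrix(x)
    if (ncol(m) < 2) stop("need at least 2 samples")
    if (any(colSums(m) == 0)) stop("zero-sum sample(s)")
    as.matrix(vegan::vegdist(t(m), method = "bray"))
}

## Within-group sum of squared dissimilarities, divided by group size.
.ssWithin <- function(D2, groups) {
    s <- 0
    for (g in unique(groups)) {
        idx <- which(groups == g)
        s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Partitions squared dissimilarities into among- and within-category
#' components: `SS_T = sum_{i<j} d_ij^2 / N`,
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_A = SS_T - SS_W`;
#' `F = (SS_A / (a - 1)) / (SS_W / (N - a))`, `R^2 = SS_A / SS_T`. The
#' p-value counts label permutations with `F_perm >= F_obs`, including the
#' observed ordering, so it is never 0.
#'
#' @param D dissimilarity matrix (or `dist`).
#' @param design named character vector sample -> category (>= 2
#'   categories, each with >= 2 samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return a [GroupTestResult-class].
#' @export
permanovaTest <- function(D, design, n_perm = 999, seed) {
    D <- as.matrix(D)
    if (!is.null(names(design)) && !is.null(rownames(D)))
        design <- design[rownames(D)]
    groups <- as.character(design)
    if (length(groups) != nrow(D)) stop("design does not match samples")
    if (anyNA(groups)) stop("unlabeled samples in design")
    a <- length(unique(groups))
    if (a < 2) stop("need at least 2 categories")
    if (any(table(groups) < 2)) stop("every category needs >= 2 samples")
    N <- nrow(D)
    D2 <- D^2
    ss_t <- sum(D2) / (2 * N)
    ss_w <- .ssWithin(D2, groups)
    ss_a <- ss_t - ss_w
    f_obs <- (ss_a / (a - 1)) / (ss_w / (N - a))
    set.seed(as.integer(seed))
    exceed <- 0L
    for (b in seq_len(n_perm)) {
        gp <- sample(groups)
        ss_wp <- .ssWithin(D2, gp)
        fp <- ((ss_t - ss_wp) / (a - 1)) / (ss_wp / (N - a))
        if (fp >= f_obs) exceed <- exceed + 1L
    }
    new("GroupTestResult", method = "permanova", statistic = f_obs,
        effect = ss_a / ss_t, p = (1 + exceed) / (n_perm + 1),
        nPerm = as.integer(n_perm), seed = as.integer(seed))
}

#' ANOSIM on a dissimilarity matrix
#'
#' Midranks all off-diagonal dissimilarities and compares mean between- and
#' within-category ranks: `R = (r_between - r_within) / (M / 2)` with
#' `M = N (N - 1) / 2`. Permutation p-value as in [permanovaTest()].
#'
#' @inheritParams permanovaTest
#' @return a [GroupTestResult-class] (`effect` is `NA`).
#' @export
anosimTest <- function(D, design, n_perm = 999, seed) {
    D <- as.matrix(D)
    if (!is.null(names(design)) && !is.null(rownames(D)))
        design <- design[rownames(D)]
    groups <- as.character(design)
    if (length(groups) != nrow(D)) stop("design does not match samples")
    a <- length(unique(groups))
    if (a < 2) stop("need at least 2 categories")
    N <- nrow(D)
    iu <- which(upper.tri(D))
    r <- rank(D[iu])  # midranks for ties
    M <- N * (N - 1) / 2
    pair_rows <- row(D)[iu]
    pair_cols <- col(D)[iu]
    statfun <- function(g) {
        within <- g[pair_rows] == g[pair_cols]
        (mean(r[!within]) - mean(r[within])) / (M / 2)
    }
    r_obs <- statfun(groups)
    set.seed(as.integer(seed))
    exceed <- 0L
    for (b in seq_len(n_perm))
        if (statfun(sample(groups)) >= r_obs) exceed <- exceed + 1L
    new("GroupTestResult", method = "anosim", statistic = r_obs,
        effect = NA_real_, p = (1 + exceed) / (n_perm + 1),
        nPerm = as.integer(n_perm), seed = as.integer(seed))
}
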