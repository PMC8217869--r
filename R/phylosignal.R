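## Blomberg's K and its permutation test on a host phylogeny.

## Phylogenetic covariance with zero-length terminal branches perturbed
## slightly so V stays invertible (replicate polytomies sit at zero
## length by construction).
.phyloVcv <- function(tree) {
    if (!is.null(tree$edge.length)) {
        h <- max(ape::node.depth.edgelength(tree))
        eps <- 1e-8 * ifelse(h > 0, h, 1)
        term <- tree$edge[, 2] <= length(tree$tip.label)
        zl <- term & tree$edge.length <= 0
        if (any(zl)) tree$edge.length[zl] <- eps
    }
    ape::vcv.phylo(tree)
}

## Mean squared errors entering K for a trait vector (or matrix of
## column-wise trait vectors) given precomputed V^-1.
.kMSE <- function(X, Vi) {
    X <- as.matrix(X)
    n <- nrow(X)
    ones <- rep(1, n)
    c1 <- as.numeric(ones %*% Vi %*% ones)
    ahat <- as.numeric(ones %*% Vi %*% X) / c1
    R <- X - matrix(ahat, n, ncol(X), byrow = TRUE)
    mse0 <- colSums(R^2) / (n - 1)
    mse <- colSums(R * (Vi %*% R)) / (n - 1)
    list(mse0 = mse0, mse = mse, c1 = c1)
}

#' Blomberg's K for a continuous trait on a phylogeny
#'
#' `K = (MSE0 / MSE) / ((tr(V) - n / (1' V^-1 1)) / (n - 1))` where `MSE0`
#' is the mean squared deviation of tip values from the phylogenetic GLS
#' mean and `MSE` its V-weighted counterpart. `K` near 1 matches the
#' Brownian-motion expectation on the tree; larger values indicate
#' stronger-than-Brownian clustering of trait values among relatives.
#' `K` is invariant to affine transforms of the trait.
#'
#' @param tree an [ape::phylo] tree.
#' @param trait named numeric vector mapping 1:1 onto tip labels.
#' @return a single non-negative K value.
#' @export
blombergK <- function(tree, trait) {
    V <- .phyloVcv(tree)
    if (is.null(names(trait))) {
        if (length(trait) != nrow(V)) stop("trait does not match tips")
        names(trait) <- rownames(V)
    }
    miss <- setdiff(rownames(V), names(trait))
    if (length(miss))
        stop("trait missing for tips: ", paste(miss, collapse = ", "))
    x <- trait[rownames(V)]
    if (stats::var(x) == 0) stop("constant trait: K is undefined")
    Vi <- solve(V)
    k <- .kMSE(x, Vi)
    n <- nrow(V)
    expected <- (sum(diag(V)) - n / k$c1) / (n - 1)
    as.numeric((k$mse0 / k$mse) / expected)
}

#' Permutation test for phylogenetic signal
#'
#' Permutes trait values across tips and compares the V-weighted mean
#' squared error: lower observed MSE than permuted means the trait tracks
#' the phylogeny more closely than chance.
#' `p = (1 + #\{MSE_perm <= MSE_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams blombergK
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param trait_name label carried into the result.
#' @return a [PhyloSignalResult-class].
#' @export
phylosignalTest <- function(tree, trait, n_perm = 999, seed,
                            trait_name = deparse(substitute(trait))) {
    V <- .phyloVcv(tree)
    if (is.null(names(trait))) {
        if (length(trait) != nrow(V)) stop("trait does not match tips")
        names(trait) <- rownames(V)
    }
    x <- trait[rownames(V)]
    if (anyNA(x)) stop("trait missing for some tips")
    if (stats::var(x) == 0) stop("constant trait: signal is undefined")
    Vi <- solve(V)
    obs <- .kMSE(x, Vi)
    n <- nrow(V)
    expected <- (sum(diag(V)) - n / obs$c1) / (n - 1)
    K <- as.numeric((obs$mse0 / obs$mse) / expected)
    set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_perm), function(b) sample(x), numeric(n))
    mse_perm <- .kMSE(perm, Vi)$mse
    p <- (1 + sum(mse_perm <= obs$mse)) / (n_perm + 1)
    new("PhyloSignalResult", K = K, p = p, nPerm = as.integer(n_perm),
        seed = as.integer(seed), trait = as.character(trait_name))
}
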