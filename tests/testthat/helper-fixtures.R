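## Shared fixture builders; everything is generated in code under a seed.

## Random small count table with ids.
randomTable <- function(S, n, lambda = 5, seed) {
    set.seed(seed)
    m <- matrix(rpois(S * n, lambda), S, n,
                dimnames = list(paste0("otu", seq_len(S)),
                                paste0("s", seq_len(n))))
    storage.mode(m) <- "integer"
    m
}

## Balanced design over k categories, n_per each.
balancedDesign <- function(k, n_per, prefix = "c") {
    cats <- paste0(prefix, seq_len(k))
    stats::setNames(rep(cats, each = n_per),
                    paste0("s", seq_len(k * n_per)))
}

## A table whose columns are two clearly separated synthetic clusters.
clusteredTable <- function(seed = 1) {
    set.seed(seed)
    a <- matrix(rpois(60, 20), 20, 3)
    b <- matrix(rpois(60, 20), 20, 3)
    m <- cbind(rbind(a, matrix(0L, 20, 3)), rbind(matrix(0L, 20, 3), b))
    dimnames(m) <- list(paste0("otu", 1:40), paste0("s", 1:6))
    storage.mode(m) <- "integer"
    m
}

## Brute-force Bray-Curtis between two count vectors.
bcPair <- function(x, y) sum(abs(x - y)) / sum(x + y)
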