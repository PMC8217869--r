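test_that("Bray-Curtis matches hand evaluation, brute force, and its
           boundary cases", {
    m <- cbind(s1 = c(2L, 2L), s2 = c(1L, 3L))
    rownames(m) <- c("a", "b")
    expect_equal(brayCurtis(m)["s1", "s2"], 0.25)  # (1+1)/8

    ident <- cbind(s1 = c(3L, 1L), s2 = c(3L, 1L))
    rownames(ident) <- c("a", "b")
    expect_equal(brayCurtis(ident)["s1", "s2"], 0)

    disj <- cbind(s1 = c(5L, 0L), s2 = c(0L, 7L))
    rownames(disj) <- c("a", "b")
    expect_equal(brayCurtis(disj)["s1", "s2"], 1)

    mm <- randomTable(30, 5, seed = 31)
    D <- brayCurtis(mm)
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    for (i in 1:4) for (j in (i + 1):5)
        expect_equal(D[i, j], bcPair(mm[, i], mm[, j]))

    bad <- mm; bad[, 2] <- 0L
    expect_error(brayCurtis(bad), "zero-sum")
})

test_that("PERMANOVA agrees with an exhaustive all-permutations oracle and
           with the established reference implementation", {
    m <- clusteredTable(seed = 32)
    design <- stats::setNames(rep(c("g1", "g2"), each = 3), colnames(m))
    D <- brayCurtis(m)

    ## exhaustive oracle on 6 samples, brute-force SS partitioning
    D2 <- D^2
    ssw <- function(groups) {
        s <- 0
        for (g in unique(groups)) {
            idx <- which(groups == g)
            s <- s + sum(D2[idx, idx]) / (2 * length(idx))
        }
        s
    }
    ss_t <- sum(D2) / (2 * 6)
    f_of <- function(g) ((ss_t - ssw(g)) / 1) / (ssw(g) / 4)
    f_obs <- f_of(design)
    perms <- combn(6, 3)
    f_all <- apply(perms, 2, function(idx) {
        g <- rep("g2", 6); g[idx] <- "g1"
        f_of(g)
    })
    p_exact <- mean(f_all >= f_obs - 1e-12)

    res <- permanovaTest(D, design, n_perm = 999, seed = 33)
    expect_equal(res@statistic, f_obs)
    expect_equal(res@effect, (ss_t - ssw(design)) / ss_t)
    expect_lt(abs(res@p - p_exact), 0.05)
    ## R^2 + SS_W/SS_T = 1 exactly
    expect_equal(res@effect + ssw(design) / ss_t, 1)

    ## cross-check statistic and R^2 against vegan::adonis2
    ad <- vegan::adonis2(as.dist(D) ~ g,
                         data = data.frame(g = design), permutations = 99)
    expect_equal(res@statistic, ad$F[1])
    expect_equal(res@effect, ad$R2[1])

    ## clearly separated clusters: observed F is the maximum, so p equals
    ## the share of label permutations reproducing the partition
    expect_equal(max(f_all), f_obs)
    expect_lte(res@p, p_exact + 0.03)
})

test_that("ANOSIM reaches R = 1 on perfectly separated groups, matches the
           reference implementation, and stays within [-1, 1] under ties", {
    m <- clusteredTable(seed = 34)
    design <- stats::setNames(rep(c("g1", "g2"), each = 3), colnames(m))
    D <- brayCurtis(m)
    res <- anosimTest(D, design, n_perm = 199, seed = 35)
    expect_equal(res@statistic, 1)
    an <- vegan::anosim(as.dist(D), design, permutations = 9)
    expect_equal(res@statistic, unname(an$statistic))

    ## random labels on random data: R near 0, statistic matches vegan
    mm <- randomTable(25, 8, seed = 36)
    D2 <- brayCurtis(mm)
    g2 <- stats::setNames(rep(c("a", "b"), 4), colnames(mm))
    r2 <- anosimTest(D2, g2, n_perm = 99, seed = 37)
    an2 <- vegan::anosim(as.dist(D2), g2, permutations = 9)
    expect_equal(r2@statistic, unname(an2$statistic))
    expect_true(r2@statistic >= -1 && r2@statistic <= 1)

    ## heavy ties: duplicated distances keep R in range
    Dt <- matrix(0.5, 6, 6); diag(Dt) <- 0
    dimnames(Dt) <- list(paste0("s", 1:6), paste0("s", 1:6))
    gt <- stats::setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
    rt <- anosimTest(Dt, gt, n_perm = 49, seed = 38)
    expect_true(rt@statistic >= -1 && rt@statistic <= 1)
})

test_that("permutation p-values keep the +1 convention and the expected
           ANOSIM null mean is near zero", {
    mm <- randomTable(25, 8, seed = 39)
    D <- brayCurtis(mm)
    g <- stats::setNames(rep(c("a", "b"), each = 4), colnames(mm))
    rs <- vapply(1:60, function(s) {
        gg <- stats::setNames(sample(g), names(g))
        anosimTest(D, gg, n_perm = 19, seed = s)@statistic
    }, numeric(1))
    se <- sd(rs) / sqrt(length(rs))
    expect_lt(abs(mean(rs)), 3 * se + 0.02)
    p <- permanovaTest(D, g, n_perm = 19, seed = 40)@p
    expect_gt(p, 0)
    expect_lte(p, 1)
})
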