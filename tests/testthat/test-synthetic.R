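test_that("metacommunity profiles are normalized, positive, reproducible,
           and steepen with the lognormal shape", {
    expect_error(makeMetacommunity(1, seed = 1), "S must be")
    p0 <- makeMetacommunity(4, sdlog = 0, seed = 1)
    expect_equal(unname(p0), rep(0.25, 4))
    p <- makeMetacommunity(500, sdlog = 2, seed = 2)
    expect_equal(sum(p), 1)
    expect_true(min(p) > 0)
    expect_identical(p, makeMetacommunity(500, sdlog = 2, seed = 2))

    ## Gini coefficient increases with sdlog (Spearman > 0 over seeds)
    gini <- function(x) {
        x <- sort(x)
        n <- length(x)
        sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
    }
    sig <- rep(c(0.5, 1, 2, 3), each = 5)
    g <- mapply(function(s, seed) gini(makeMetacommunity(200, s, seed)),
                sig, seq_along(sig) + 10)
    expect_gt(cor(sig, g, method = "spearman"), 0)
})

test_that("neutral simulator approaches the metacommunity as the
           concentration grows and is seed-reproducible", {
    meta <- makeMetacommunity(50, 1, seed = 4)
    big <- simulateNeutralCommunity(meta, 10, 50000, m = 1, seed = 5)
    rel <- sweep(otuCounts(big), 2, colSums(otuCounts(big)), "/")
    expect_lt(max(apply(rel, 1, sd)), 0.01)
    again <- simulateNeutralCommunity(meta, 10, 50000, m = 1, seed = 5)
    expect_identical(otuCounts(big), otuCounts(again))
    expect_error(simulateNeutralCommunity(meta, 5, 100, m = 0, seed = 1),
                 "m must")
})

test_that("neutral simulator occupancy matches its beta-binomial marginal
           within Monte-Carlo error", {
    S <- 40
    meta <- makeMetacommunity(S, 1.5, seed = 6)
    N <- 2000
    m <- 0.2
    tab <- simulateNeutralCommunity(meta, 500, N, m, seed = 7)
    occ <- rowMeans(otuCounts(tab) > 0)
    a <- N * m * meta
    b <- N * m * (1 - meta)
    p_detect <- 1 - exp(lbeta(a, b + N) - lbeta(a, b))
    se <- sqrt(p_detect * (1 - p_detect) / 500)
    expect_true(all(abs(occ - p_detect) <= 3 * se + 1e-3))
    ## abundant taxa (concentration well above 1) are essentially always seen
    expect_true(all(occ[N * m * meta > 25] == 1))
})

test_that("niche simulator reduces to multinomial sampling at zero
           selection and separates categories at strong selection", {
    meta <- makeMetacommunity(100, 1.5, seed = 8)
    design <- balancedDesign(3, 4)
    flat <- simulateNicheCommunity(meta, design, 0, 5000, seed = 9)
    ## no category structure: between ~ within dissimilarity
    D <- brayCurtis(flat)
    w <- D[1:4, 1:4][upper.tri(diag(4))]
    b <- D[1:4, 5:12]
    expect_lt(abs(mean(b) - mean(w)), 0.05)

    sel <- simulateNicheCommunity(meta, design, 3, 5000, seed = 10)
    D2 <- brayCurtis(sel)
    same <- outer(design, design, "==")
    ut <- upper.tri(D2)
    expect_lt(mean(D2[ut & same]), mean(D2[ut & !same]) - 0.2)

    ## strong selection is picked up by PERMANOVA at high significance
    gt <- permanovaTest(D2, design, n_perm = 999, seed = 11)
    expect_lte(gt@p, 0.01)
})

test_that("planted generalists and specialists carry the promised niche
           breadth structure and truth labels", {
    meta <- makeMetacommunity(100, 1.5, seed = 12)
    design <- balancedDesign(4, 5)
    tab <- simulateNicheCommunity(meta, design, 0, 4000, seed = 13)
    pl <- plantNicheOtus(tab, design, n_generalist = 5, n_specialist = 8,
                         seed = 14)
    expect_setequal(unique(pl$truth), c("generalist", "specialist"))
    b <- levinsB(pl$table)
    gens <- names(pl$truth)[pl$truth == "generalist"]
    specs <- names(pl$truth)[pl$truth == "specialist"]
    expect_equal(unname(b[gens]), rep(20, 5))  # perfectly even occupancy
    expect_true(all(b[specs] <= 5 + 1e-9))     # confined to one category
    spec_m <- otuCounts(pl$table)[specs, , drop = FALSE]
    for (s in specs) {
        occupied <- unique(design[spec_m[s, ] > 0])
        expect_length(occupied, 1)
    }
    expect_error(plantNicheOtus(tab, design, 90, 20, seed = 1), "more taxa")
})

test_that("Brownian host traits carry K near 1, shuffling destroys the
           signal, and replicate expansion maps tips to species", {
    skip_if_not_installed("picante")
    set.seed(15)
    tr <- ape::rcoal(8)
    ks <- vapply(1:200, function(s)
        blombergK(tr, simulateHostTraits(tr, "brownian", 1,
                                         seed = 1000 + s)$trait),
        numeric(1))
    se <- sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - 1), 3 * se + 0.05)

    ## shuffled traits: permutation p roughly uniform -> rejections near 5%
    rej <- mean(vapply(1:150, function(s) {
        tv <- simulateHostTraits(tr, "shuffled", 1, seed = 2000 + s)$trait
        phylosignalTest(tr, tv, n_perm = 99, seed = 3000 + s)@p <= 0.05
    }, logical(1)))
    expect_gt(rej, 0.005)
    expect_lt(rej, 0.12)

    exp <- expandTreeReplicates(tr, reps = 5)
    expect_length(exp$tree$tip.label, 40)
    expect_setequal(unique(exp$species), tr$tip.label)
    tv <- simulateHostTraits(tr, "brownian", 1, reps_per_tip = 5,
                             seed = 16)
    expect_length(tv$trait, 40)
    ## replicates of a species stay within a tight noise band
    sp <- sub("_r[0-9]+$", "", names(tv$trait))
    spread <- tapply(tv$trait, sp, function(v) diff(range(v)))
    expect_lt(max(spread), 0.2 * sd(tv$trait))
    expect_error(simulateHostTraits(tr, "brownian", -1, seed = 1),
                 "non-negative")
})
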