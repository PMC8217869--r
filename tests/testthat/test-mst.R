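test_that("pairwise MST reproduces its defining two-branch form", {
    expect_equal(mstPairwise(0.5, 0.5), 1)
    expect_equal(mstPairwise(0, 0.5), 0)
    expect_equal(mstPairwise(0.9, 0.8), 0.5)  # (1-0.9)/(1-0.8)
    expect_equal(mstPairwise(0.25, 0.5), 0.5)
    ## degenerate null expectations are flagged NA
    expect_warning(out <- mstPairwise(c(0.2, 0.2), c(0, 1)), "degenerate")
    expect_true(all(is.na(out)))
    v <- mstPairwise(runif(50), runif(50, 0.05, 0.95))
    expect_true(all(v >= 0 & v <= 1))
})

test_that("null communities preserve per-sample richness and depth and
           draw taxa in proportion to regional occurrence", {
    m <- randomTable(30, 6, lambda = 2, seed = 61)
    design <- balancedDesign(2, 3)
    nulls <- nullCommunities(m, design, n_null = 30, seed = 62)
    for (nm in nulls[1:5]) {
        expect_identical(colSums(nm > 0), colSums(m > 0))
        expect_identical(colSums(nm), colSums(m))
    }
    ## selection frequency tracks occurrence frequency within the pool;
    ## the probed sample's richness (2) is below the pool size (5), so
    ## the weighted draw is non-trivial
    m2 <- rbind(common = c(5L, 6L, 4L, 4L), mid = c(0L, 3L, 2L, 0L),
                rare = c(0L, 0L, 0L, 2L), never = c(0L, 0L, 0L, 0L),
                filler = c(40L, 40L, 40L, 40L),
                filler2 = c(0L, 40L, 40L, 40L))
    colnames(m2) <- paste0("s", 1:4)
    des2 <- stats::setNames(rep("x", 4), colnames(m2))
    nn <- nullCommunities(m2, des2, n_null = 3000, seed = 63)
    sel <- rowMeans(vapply(nn, function(z) z[, 1] > 0, logical(6)))
    expect_equal(unname(sel["never"]), 0)
    expect_gt(sel["common"], sel["mid"])
    expect_gt(sel["mid"], sel["rare"])

    expect_warning(
        nullCommunities(m, stats::setNames(c("a", rep("b", 5)),
                                           colnames(m)),
                        n_null = 2, seed = 1),
        "single-sample")
})

test_that("category MST separates drift-dominated from selection-dominated
           assembly and a null draw scores near 1 against its ensemble", {
    meta <- makeMetacommunity(150, 2, seed = 64)
    design <- balancedDesign(3, 4)
    neu <- simulateNeutralCommunity(meta, 12, 4000, m = 0.3, seed = 65)
    sampleCategories(neu) <- design
    nic <- simulateNicheCommunity(meta, design, 3, 4000, seed = 66)
    mst_neu <- mstByCategory(neu, design, n_null = 120, seed = 67)
    mst_nic <- mstByCategory(nic, design, n_null = 120, seed = 68)
    expect_gt(mean(mstSummary(mst_neu)$mean_mst), 0.5)
    expect_lt(mean(mstSummary(mst_nic)$mean_mst), 0.5)
    expect_true(all(mstSummary(mst_neu)$regime == "stochastic"))
    expect_true(all(mstSummary(mst_nic)$regime == "deterministic"))
    p <- mstPairs(mst_neu)
    expect_true(all(p$mst >= 0 & p$mst <= 1, na.rm = TRUE))

    ## self-consistency: a table drawn from the null ensemble scores high
    ## (the expected score of an ensemble member is below 1 because MST is
    ## a concave transform of the dissimilarity around its expectation)
    base <- simulateNicheCommunity(meta, design, 0, 4000, seed = 69)
    nd <- nullCommunities(base, design, n_null = 1, seed = 70)[[1]]
    mst_self <- mstByCategory(nd, design, n_null = 120, seed = 71)
    self_mean <- mean(mstPairs(mst_self)$mst, na.rm = TRUE)
    expect_gt(self_mean, 0.6)
    expect_gt(self_mean, mean(mstPairs(mst_nic)$mst, na.rm = TRUE))
})

test_that("mean MST rises monotonically along the mixed-regime sweep", {
    meta <- makeMetacommunity(120, 2, seed = 72)
    design <- balancedDesign(3, 4)
    weights <- c(0, 0.25, 0.5, 0.75, 1)
    msts <- vapply(seq_along(weights), function(i) {
        tab <- simulateMixedCommunity(meta, design, m = 0.3, sigma_sel = 3,
                                      mix_weight = weights[i], N = 4000,
                                      seed = 73)
        mean(mstSummary(mstByCategory(tab, design, n_null = 80,
                                      seed = 74 + i))$mean_mst)
    }, numeric(1))
    expect_gt(cor(weights, msts, method = "spearman"), 0)
})
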