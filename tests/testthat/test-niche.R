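test_that("Levins' B matches brute force and its analytic extremes", {
    m <- rbind(even = rep(3L, 4), narrow = c(8L, 0L, 0L, 0L))
    colnames(m) <- paste0("s", 1:4)
    b <- levinsB(m)
    expect_equal(unname(b["even"]), 4)
    expect_equal(unname(b["narrow"]), 1)

    mm <- randomTable(40, 7, seed = 41)
    b2 <- levinsB(mm)
    for (i in seq_len(nrow(mm))) {
        p <- mm[i, ] / sum(mm[i, ])
        expect_equal(unname(b2[i]), 1 / sum(p^2))
    }
    ## zero-sum rows flagged as NA
    mz <- mm; mz[3, ] <- 0L
    expect_warning(bz <- levinsB(mz), "zero-sum")
    expect_true(is.na(bz[3]))

    ## pooling to categories bounds B by the number of categories
    design <- balancedDesign(3, 2, prefix = "h")
    names(design) <- colnames(mm)[1:6]
    bc <- levinsB(mm[, 1:6], by_category = TRUE, design = design)
    expect_true(all(bc <= 3 + 1e-9))
})

test_that("Patefield and quasiswap draws preserve their constraints
           exactly on random tables", {
    for (s in 1:100) {
        m <- randomTable(20, 10, lambda = sample(c(1, 3, 8), 1),
                         seed = 500 + s)
        pa <- patefieldRandom(m, seed = s)
        expect_identical(rowSums(pa), rowSums(m))
        expect_identical(colSums(pa), colSums(m))
        qs <- quasiswapRandom(m, seed = s)
        expect_identical(rowSums(qs), rowSums(m))
        expect_identical(colSums(qs), colSums(m))
        expect_identical(sum(qs > 0), sum(m > 0))
    }
    ## single-row/column tables are forced by their margins
    one <- matrix(c(3L, 1L, 4L), 1, 3,
                  dimnames = list("otu1", paste0("s", 1:3)))
    expect_identical(patefieldRandom(one, seed = 1), one)
    expect_identical(quasiswapRandom(one, seed = 1), one)
})

test_that("Patefield cell means follow the independence expectation", {
    m <- randomTable(6, 4, lambda = 6, seed = 42)
    draws <- vapply(1:2000, function(s) patefieldRandom(m, seed = s),
                    matrix(0L, 6, 4))
    mu <- apply(draws, c(1, 2), mean)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    se <- apply(draws, c(1, 2), sd) / sqrt(2000)
    expect_true(all(abs(mu - expected) <= 3 * se + 0.05))
})

test_that("niche classification labels planted structure correctly and
           keeps an exhaustive, exclusive partition", {
    meta <- makeMetacommunity(150, 2, seed = 43)
    design <- balancedDesign(5, 5)
    tab <- simulateNicheCommunity(meta, design, 0, 4000, seed = 44)
    pl <- plantNicheOtus(tab, design, 8, 8, seed = 45)
    nc <- classifyNiche(pl$table, n_perm = 300, seed = 46)
    tb <- nicheTable(nc)
    expect_equal(nrow(tb), sum(rowSums(otuCounts(pl$table)) > 0))
    expect_true(all(tb$label %in% c("generalist", "specialist", "neutral")))
    lab <- stats::setNames(tb$label, tb$otu)
    truth <- pl$truth
    expect_gte(mean(lab[names(truth)] == truth), 0.8)
    ## envelope ordering always holds
    expect_true(all(tb$lower <= tb$upper))
})

test_that("an OTU whose observed breadth equals every null draw is neutral
           and null envelopes are invariant to sample order", {
    ## a 2-taxon table where margins force every table: degenerate envelope
    m <- rbind(a = c(2L, 2L), b = c(2L, 2L))
    colnames(m) <- c("s1", "s2")
    ## with 3+ samples required, embed in a forced table
    m3 <- rbind(a = c(1L, 1L, 1L), b = c(1L, 1L, 1L))
    colnames(m3) <- paste0("s", 1:3)
    nc <- classifyNiche(m3, n_perm = 100, seed = 47)
    expect_true(all(nicheTable(nc)$label == "neutral"))

    mm <- randomTable(25, 6, seed = 48)
    nc1 <- classifyNiche(mm, n_perm = 150, seed = 49)
    perm <- sample(ncol(mm))
    nc2 <- classifyNiche(mm[, perm], n_perm = 150, seed = 49)
    t1 <- nicheTable(nc1)
    t2 <- nicheTable(nc2)
    expect_equal(t1$b_obs, t2$b_obs[match(t1$otu, t2$otu)])
    ## null means agree up to Monte-Carlo noise
    expect_lt(max(abs(t1$null_mean - t2$null_mean[match(t1$otu, t2$otu)])),
              1.5)
    expect_warning(classifyNiche(mm, n_perm = 50, seed = 1), "n_perm")
})

test_that("classification of a table drawn from the null ensemble calls
           close to the nominal 5% rate", {
    meta <- makeMetacommunity(300, 2, seed = 50)
    design <- balancedDesign(5, 5)
    base <- simulateNicheCommunity(meta, design, 0, 6000, seed = 51)
    obs <- quasiswapRandom(base, seed = 52)
    nc <- classifyNiche(obs, n_perm = 300, seed = 53)
    rate <- mean(nicheTable(nc)$label != "neutral")
    expect_lte(rate, 0.05 + 0.03)
})
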