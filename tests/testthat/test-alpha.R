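test_that("alpha indices reproduce hand-evaluated values", {
    v <- c(5, 1, 1, 2)
    expect_equal(observedRichness(v), 4L)
    expect_equal(chao1(v), 4.5)  # 4 + 2*1/(2*2)
    u <- rep(3, 4)
    expect_equal(shannonIndex(u), log(4))
    expect_equal(invSimpson(u), 4)
    expect_equal(as.numeric(pielouEvenness(u)), 1)
    single <- c(0, 7, 0)
    expect_equal(shannonIndex(single), 0)
    expect_equal(invSimpson(single), 1)
    expect_equal(as.numeric(pielouEvenness(single)), 0)
    expect_true(isTRUE(attr(pielouEvenness(single), "degenerate")))
    expect_warning(expect_equal(observedRichness(c(0, 0)), 0L), "all-zero")
    expect_error(shannonIndex(c(0, 0)), "empty")
})

test_that("chao1 and ACE agree with brute-force formula evaluation on
           random vectors and respect their bounds", {
    for (s in 1:100) {
        set.seed(s)
        v <- rpois(60, sample(c(0.5, 1, 3, 10), 1))
        if (sum(v) == 0) next
        s_obs <- sum(v > 0)
        f1 <- sum(v == 1); f2 <- sum(v == 2)
        expect_equal(chao1(v), s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
        expect_gte(chao1(v), s_obs)

        ## independent ACE evaluation
        rare <- v[v > 0 & v <= 10]
        ace_ref <- if (length(rare) == 0) sum(v > 10) else {
            n_rare <- sum(rare)
            c_ace <- 1 - sum(rare == 1) / n_rare
            if (c_ace == 0) NA else {
                g2 <- max(0, (length(rare) / c_ace) *
                    sum(vapply(1:10, function(i)
                        i * (i - 1) * sum(rare == i), numeric(1))) /
                    (n_rare * (n_rare - 1)) - 1)
                sum(v > 10) + length(rare) / c_ace +
                    sum(rare == 1) / c_ace * g2
            }
        }
        if (!is.na(ace_ref)) {
            expect_equal(aceRichness(v), ace_ref)
            if (sum(v == 1) > 0 && length(rare) < length(v[v > 0]))
                expect_gte(aceRichness(v), s_obs - 1e-9)
        }
    }
    ## no rare class: ACE equals observed richness
    expect_equal(aceRichness(c(50, 20, 11)), 3)
    ## all-singleton rare class falls back to chao1
    expect_warning(a <- aceRichness(c(1, 1, 1)), "Chao1")
    expect_equal(a, chao1(c(1, 1, 1)))
})

test_that("shannon and inverse Simpson match brute-force sums and are
           invariant to taxon order and count scaling", {
    for (s in 1:50) {
        set.seed(200 + s)
        v <- rpois(30, 4)
        if (sum(v) == 0) next
        p <- v[v > 0] / sum(v)
        expect_equal(shannonIndex(v), -sum(p * log(p)))
        expect_equal(invSimpson(v), 1 / sum(p^2))
        perm <- sample(v)
        expect_equal(shannonIndex(perm), shannonIndex(v))
        expect_equal(invSimpson(perm), invSimpson(v))
        expect_equal(shannonIndex(v * 7), shannonIndex(v))
        expect_equal(invSimpson(v * 7), invSimpson(v))
        expect_equal(chao1(perm), chao1(v))
    }
})

test_that("alphaDiversity summarizes per sample and per category with the
           requested dispersion", {
    m <- randomTable(40, 6, seed = 21)
    design <- balancedDesign(2, 3)
    out <- alphaDiversity(m, design)
    expect_equal(nrow(out$samples), 6)
    expect_equal(sort(unique(out$categories$category)), c("c1", "c2"))
    sh <- out$samples$shannon[out$samples$category == "c1"]
    row <- out$categories[out$categories$category == "c1" &
                          out$categories$metric == "shannon", ]
    expect_equal(row$mean, mean(sh))
    expect_equal(row$spread, sd(sh) / sqrt(3))
    out_sd <- alphaDiversity(m, design, dispersion = "sd")
    row_sd <- out_sd$categories[out_sd$categories$category == "c1" &
                                out_sd$categories$metric == "shannon", ]
    expect_equal(row_sd$spread, sd(sh))
})

test_that("rarefaction curves match the analytic hypergeometric
           expectation and saturate at the observed richness", {
    v <- c(a = 30L, b = 12L, c = 5L, d = 2L, e = 1L)
    m <- matrix(v, ncol = 1, dimnames = list(names(v), "s1"))
    ## closed form at depth = total equals observed richness
    expect_equal(expectedRarefiedRichness(v, sum(v)), 5)
    expect_equal(expectedRarefiedRichness(v, 1), 1)
    curve <- rarefactionCurve(m, depths = c(5, 20, 50), n_reps = 400,
                              seed = 22)
    for (i in seq_len(nrow(curve))) {
        ex <- expectedRarefiedRichness(v, curve$depth[i])
        ## 3 SE of a mean of n_reps bounded richness draws
        expect_lt(abs(curve$richness[i] - ex), 3 * sqrt(1.5 / 400) + 0.05)
    }
    full <- rarefactionCurve(m, depths = sum(v), n_reps = 2, seed = 1)
    expect_equal(full$richness, 5)
    ## depths above the sample total are omitted
    expect_equal(nrow(rarefactionCurve(m, depths = c(10, 1000),
                                       n_reps = 2, seed = 1)), 1)
})
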