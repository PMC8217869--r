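## Synthetic community generator: metacommunities, neutral and niche
## assembly, planted generalists/specialists, host trees with Brownian
## traits. Every downstream stage is exercised against these known truths.

#' Generate a metacommunity abundance profile
#'
#' Relative abundances follow a ranked lognormal: `S` lognormal deviates
#' sorted in decreasing order and normalized to sum to one. `sdlog = 0`
#' degenerates to the uniform profile.
#'
#' @param S number of taxa (>= 2).
#' @param sdlog lognormal shape parameter; larger values give a steeper,
#'   longer-tailed rank-abundance curve.
#' @param seed integer seed.
#' @return numeric vector `p` of length `S`, strictly positive, summing to
#'   1, named `otu1..otuS` in decreasing abundance.
#' @examples
#' p <- makeMetacommunity(100, sdlog = 2, seed = 1)
#' sum(p)
#' @export
makeMetacommunity <- function(S, sdlog = 2, seed) {
    if (S < 2) stop("S must be >= 2")
    if (sdlog < 0) stop("sdlog must be non-negative")
    set.seed(as.integer(seed))
    p <- sort(stats::rlnorm(S, meanlog = 0, sdlog = sdlog),
              decreasing = TRUE)
    p <- p / sum(p)
    names(p) <- paste0("otu", seq_len(S))
    p
}

## Dirichlet draw with concentration vector alpha (gamma representation).
.rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
}

#' Simulate neutrally assembled local communities
#'
#' Each sample's composition is drawn from a Dirichlet with concentration
#' `N * m * p`, whose marginals are exactly the `Beta(Nmp_i, Nm(1 - p_i))`
#' stationary distribution of the Sloan neutral model, then reads are drawn
#' multinomially. Small `m` means strong drift away from the
#' metacommunity; `m` near 1 reproduces `p` closely.
#'
#' @param meta metacommunity abundance vector from [makeMetacommunity()].
#' @param n_samples number of local communities.
#' @param N reads per sample.
#' @param m immigration rate in (0, 1].
#' @param seed integer seed.
#' @param category optional single category label (or vector, one per
#'   sample) stored in the design.
#' @param sample_prefix prefix for generated sample identifiers.
#' @return an [OtuExperiment-class].
#' @export
simulateNeutralCommunity <- function(meta, n_samples, N, m, seed,
                                     category = "neutral",
                                     sample_prefix = "s") {
    if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
    if (N < 1) stop("N must be >= 1")
    set.seed(as.integer(seed))
    alpha <- N * m * meta
    counts <- vapply(seq_len(n_samples), function(i) {
        q <- .rdirichlet(alpha)
        as.integer(stats::rmultinom(1, size = N, prob = q))
    }, integer(length(meta)))
    dimnames(counts) <- list(names(meta),
                             paste0(sample_prefix, seq_len(n_samples)))
    otuExperiment(counts, category = rep_len(category, n_samples))
}

#' Simulate deterministically (niche) assembled communities
#'
#' Each category draws a fixed vector of selection factors
#' `w ~ LogNormal(0, sigma_sel^2)`; all replicates of the category share it,
#' so determinism means a reproducible category signature. Sample
#' compositions are proportional to `p * w` and reads multinomial.
#' `sigma_sel = 0` reduces exactly to multinomial sampling of `p`.
#'
#' @param meta metacommunity abundance vector.
#' @param design named character vector: sample id -> category.
#' @param sigma_sel selection strength (>= 0), the SD of log selection
#'   factors.
#' @param N reads per sample.
#' @param seed integer seed.
#' @return an [OtuExperiment-class] with the design attached.
#' @export
simulateNicheCommunity <- function(meta, design, sigma_sel, N, seed) {
    if (sigma_sel < 0) stop("sigma_sel must be non-negative")
    set.seed(as.integer(seed))
    cats <- unique(design)
    w <- vapply(cats, function(cc)
        stats::rlnorm(length(meta), 0, sigma_sel), numeric(length(meta)))
    colnames(w) <- cats
    counts <- vapply(seq_along(design), function(i) {
        q <- meta * w[, design[i]]
        as.integer(stats::rmultinom(1, size = N, prob = q / sum(q)))
    }, integer(length(meta)))
    ids <- if (is.null(names(design)))
        paste0("s", seq_along(design)) else names(design)
    dimnames(counts) <- list(names(meta), ids)
    otuExperiment(counts, category = stats::setNames(design, ids))
}

#' Simulate a mixed assembly regime
#'
#' Per-sample composition is a convex blend
#' `q = mix_weight * q_neutral + (1 - mix_weight) * q_niche`, where the
#' neutral part is a fresh Dirichlet draw and the niche part is the fixed
#' category signature. `mix_weight = 1` is pure neutral assembly,
#' `mix_weight = 0` pure selection; sweeping it upward increases downstream
#' stochasticity ratios monotonically in expectation.
#'
#' @inheritParams simulateNicheCommunity
#' @param m immigration rate of the neutral component.
#' @param mix_weight neutral weight in `[0, 1]`.
#' @return an [OtuExperiment-class].
#' @export
simulateMixedCommunity <- function(meta, design, m, sigma_sel, mix_weight,
                                   N, seed) {
    if (mix_weight < 0 || mix_weight > 1)
        stop("mix_weight must lie in [0, 1]")
    set.seed(as.integer(seed))
    cats <- unique(design)
    w <- vapply(cats, function(cc)
        stats::rlnorm(length(meta), 0, sigma_sel), numeric(length(meta)))
    colnames(w) <- cats
    alpha <- N * m * meta
    counts <- vapply(seq_along(design), function(i) {
        qn <- meta * w[, design[i]]
        qn <- qn / sum(qn)
        q <- mix_weight * .rdirichlet(alpha) + (1 - mix_weight) * qn
        as.integer(stats::rmultinom(1, size = N, prob = q))
    }, integer(length(meta)))
    ids <- if (is.null(names(design)))
        paste0("s", seq_along(design)) else names(design)
    dimnames(counts) <- list(names(meta), ids)
    otuExperiment(counts, category = stats::setNames(design, ids))
}

#' Plant habitat generalists and specialists into a table
#'
#' Selected taxa are overwritten with known niche structure: generalists
#' receive the same count in every sample (maximally even occupancy,
#' Levins' B equal to the number of samples), specialists are confined to
#' the samples of one category and zero elsewhere. Truth labels are
#' returned for recovery scoring.
#'
#' Planted taxa are occupancy-matched rather than drawn at random:
#' specialists overwrite rows whose occupancy is already closest to a
#' single category's sample count, generalists overwrite the most
#' prevalent rows. Habitat specialists in real tables are sparse taxa, so
#' matched planting keeps the table's margin and zero-cell structure
#' realistic; replacing random rows would couple planting to a global
#' fill shift that perturbs fixed-fill null ensembles for every taxon,
#' not just the planted ones. For the same reason specialists are planted
#' at low abundance (about a quarter of the mean cell count per occupied
#' cell), matching the rare-and-restricted profile of real habitat
#' specialists.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param design named character vector sample -> category (taken from `x`
#'   when omitted).
#' @param n_generalist,n_specialist numbers of planted taxa.
#' @param seed integer seed.
#' @param boost per-sample expected count of a planted taxon, as a multiple
#'   of the table's mean per-taxon per-sample count; the default 1 plants
#'   taxa at the typical per-OTU abundance share, so planting perturbs the
#'   table margins as little as possible.
#' @return list with elements `table` (modified [OtuExperiment-class]) and
#'   `truth` (named character vector: planted taxon -> label).
#' @export
plantNicheOtus <- function(x, design = NULL, n_generalist, n_specialist,
                           seed, boost = 1) {
    m <- .countMatrix(x)
    design <- .resolveDesign(x, design)
    if (n_generalist + n_specialist > nrow(m))
        stop("cannot plant more taxa than the table holds")
    set.seed(as.integer(seed))
    cats <- unique(design)
    fill <- rowSums(m > 0)
    cat_size <- round(mean(table(design)))
    ## occupancy-matched choice: generalists from the most prevalent rows,
    ## specialists from rows already about one category wide (ties broken
    ## randomly via a jitter on the seeded stream)
    ord_gen <- order(-fill, stats::runif(nrow(m)))
    gens <- rownames(m)[ord_gen[seq_len(n_generalist)]]
    rest <- setdiff(rownames(m), gens)
    ord_spec <- order(abs(fill[rest] - cat_size), stats::runif(length(rest)))
    specs <- rest[ord_spec[seq_len(n_specialist)]]
    lev <- max(1L, as.integer(round(boost * mean(m))))
    ## specialists are planted rare (about a quarter of the mean cell
    ## count per occupied cell): real habitat specialists sit at the
    ## low-abundance end, and an abundant row confined to few cells
    ## carries a zero pattern atypical of fixed-margin fixed-fill null
    ## ensembles, which would shift every taxon's null envelope
    spec_cell <- max(2L, as.integer(round(boost * mean(m) / 4)))
    m[gens, ] <- lev
    truth <- c(stats::setNames(rep("generalist", length(gens)), gens))
    for (i in seq_along(specs)) {
        cc <- cats[1 + (i - 1) %% length(cats)]
        row <- integer(ncol(m))
        row[design == cc] <- spec_cell
        m[specs[i], ] <- row
        truth[specs[i]] <- "specialist"
    }
    list(table = otuExperiment(m, category = design), truth = truth)
}

#' Simulate host traits on a phylogeny
#'
#' `brownian` mode draws tip values from the multivariate normal implied by
#' Brownian motion with rate `sigma2` (covariance `sigma2 *` shared branch
#' length); `shuffled` mode permutes those values across tips, destroying
#' phylogenetic structure while keeping the trait distribution.
#' `reps_per_tip > 1` expands every tip into a zero-branch-length polytomy
#' of replicate tips sharing the species value plus small i.i.d. noise
#' (SD = 1% of the trait SD), mirroring conspecific replicate sampling.
#'
#' @param tree an [ape::phylo] tree.
#' @param mode `"brownian"` or `"shuffled"`.
#' @param sigma2 Brownian rate (>= 0).
#' @param reps_per_tip replicate tips per species (>= 1).
#' @param seed integer seed.
#' @return list with `trait` (named vector over tips of `tree`, expanded
#'   when `reps_per_tip > 1`) and `tree` (the possibly expanded tree).
#' @export
simulateHostTraits <- function(tree, mode = c("brownian", "shuffled"),
                               sigma2 = 1, reps_per_tip = 1, seed) {
    mode <- match.arg(mode)
    if (sigma2 < 0) stop("sigma2 must be non-negative")
    set.seed(as.integer(seed))
    V <- ape::vcv.phylo(tree)
    L <- chol(V + diag(1e-12 * max(diag(V)), nrow(V)))
    z <- as.numeric(t(L) %*% stats::rnorm(nrow(V))) * sqrt(sigma2)
    names(z) <- rownames(V)
    if (mode == "shuffled") {
        names_keep <- names(z)
        z <- sample(z)
        names(z) <- names_keep
    }
    if (reps_per_tip > 1) {
        exp <- expandTreeReplicates(tree, reps_per_tip)
        sdz <- stats::sd(z)
        noise_sd <- if (is.finite(sdz) && sdz > 0) 0.01 * sdz else 1e-8
        trait <- stats::setNames(
            z[exp$species] + stats::rnorm(length(exp$species), 0, noise_sd),
            exp$tree$tip.label)
        return(list(trait = trait, tree = exp$tree))
    }
    list(trait = z, tree = tree)
}

#' Expand each tip of a species tree into replicate tips
#'
#' Each tip becomes a polytomy of `reps` tips attached at zero branch
#' length, named `<species>_r1..` and mapping back to the species.
#'
#' @param tree an [ape::phylo] species tree.
#' @param reps replicates per species (>= 2).
#' @return list with `tree` (expanded [ape::phylo]) and `species` (character
#'   vector: replicate tip -> parent species, aligned to the new tips).
#' @export
expandTreeReplicates <- function(tree, reps) {
    if (reps < 2) stop("reps must be >= 2")
    out <- tree
    for (sp in tree$tip.label) {
        clade <- ape::stree(reps, type = "star")
        clade$tip.label <- paste0(sp, "_r", seq_len(reps))
        clade$edge.length <- rep(0, nrow(clade$edge))
        out <- ape::bind.tree(out, clade,
                              where = which(out$tip.label == sp))
    }
    species <- sub("_r[0-9]+$", "", out$tip.label)
    list(tree = out, species = species)
}
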