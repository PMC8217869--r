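## Alpha diversity: richness estimators, Shannon, inverse Simpson, Pielou,
## and rarefaction curves. Natural logs throughout (ecology convention for
## this index set).

#' Observed richness of a sample
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @return number of taxa with count > 0 (0 with a warning for an all-zero
#'   sample).
#' @export
observedRichness <- function(counts) {
    if (any(counts < 0)) stop("negative counts")
    if (all(counts == 0)) {
        warning("all-zero sample")
        return(0L)
    }
    sum(counts > 0)
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1` singletons and `F2`
#' doubletons; the bias-corrected form stays defined when no doubletons
#' exist and equals `S_obs` when there are no singletons.
#'
#' @inheritParams observedRichness
#' @return Chao1 estimate (>= observed richness).
#' @examples
#' chao1(c(5, 1, 1, 2))  # 4 + 2*1/(2*2) = 4.5
#' @export
chao1 <- function(counts) {
    s <- sum(counts > 0)
    f1 <- sum(counts == 1)
    f2 <- sum(counts == 2)
    s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Abundance-based coverage estimator (ACE)
#'
#' Standard ACE with a configurable rare/abundant boundary:
#' `S_abund + S_rare / C + (F1 / C) * g2` where `C = 1 - F1 / N_rare` is
#' the rare-class sample coverage and `g2` the squared coefficient of
#' variation (floored at 0). When every rare taxon is a singleton the
#' coverage is 0 and the estimator falls back to [chao1()] with a warning.
#'
#' @inheritParams observedRichness
#' @param rare_threshold counts `<= rare_threshold` define the rare class
#'   (default 10).
#' @return ACE estimate.
#' @export
aceRichness <- function(counts, rare_threshold = 10) {
    counts <- counts[counts > 0]
    rare <- counts[counts <= rare_threshold]
    s_abund <- sum(counts > rare_threshold)
    s_rare <- length(rare)
    if (s_rare == 0) return(s_abund)
    n_rare <- sum(rare)
    f1 <- sum(rare == 1)
    c_ace <- 1 - f1 / n_rare
    if (c_ace == 0) {
        warning("all rare taxa are singletons; falling back to Chao1")
        return(chao1(counts))
    }
    fi <- tabulate(rare, nbins = rare_threshold)
    i <- seq_len(rare_threshold)
    g2 <- max(0, (s_rare / c_ace) * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1)
    s_abund + s_rare / c_ace + (f1 / c_ace) * g2
}

#' Shannon diversity (natural log)
#'
#' @inheritParams observedRichness
#' @return `H' = -sum(p log p)` in nats.
#' @export
shannonIndex <- function(counts) {
    if (sum(counts) == 0) stop("empty sample")
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
}

#' Inverse Simpson diversity
#'
#' @inheritParams observedRichness
#' @return `D2 = 1 / sum(p^2)`, between 1 and the observed richness.
#' @export
invSimpson <- function(counts) {
    if (sum(counts) == 0) stop("empty sample")
    p <- counts[counts > 0] / sum(counts)
    1 / sum(p^2)
}

#' Pielou's evenness
#'
#' `J = H' / log(S_obs)`. A single-taxon sample has an undefined ratio and
#' is reported as 0 (with the `degenerate` attribute set).
#'
#' @inheritParams observedRichness
#' @return evenness in `[0, 1]`.
#' @export
pielouEvenness <- function(counts) {
    s <- sum(counts > 0)
    if (s == 0) stop("empty sample")
    if (s == 1) {
        out <- 0
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    shannonIndex(counts) / log(s)
}

#' Per-sample and per-category alpha diversity summary
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param design optional sample -> category labels; category means and
#'   dispersions are added when available.
#' @param dispersion `"se"` (default, standard error) or `"sd"` for the
#'   per-category spread column.
#' @return list with `samples` (data.frame, one row per sample:
#'   observed_otus, chao1, ace, shannon, inv_simpson, pielou) and
#'   `categories` (data.frame of per-category mean and spread per metric,
#'   `NULL` without a design).
#' @export
alphaDiversity <- function(x, design = NULL, dispersion = c("se", "sd")) {
    dispersion <- match.arg(dispersion)
    m <- .countMatrix(x)
    per <- data.frame(
        sample_id = colnames(m),
        observed_otus = apply(m, 2, observedRichness),
        chao1 = apply(m, 2, chao1),
        ace = apply(m, 2, aceRichness),
        shannon = apply(m, 2, shannonIndex),
        inv_simpson = apply(m, 2, invSimpson),
        pielou = apply(m, 2, function(v) as.numeric(pielouEvenness(v))),
        row.names = NULL, stringsAsFactors = FALSE)
    cats <- NULL
    design <- tryCatch(.resolveDesign(x, design), error = function(e) NULL)
    if (!is.null(design)) {
        per$category <- design[per$sample_id]
        metrics <- setdiff(colnames(per), c("sample_id", "category"))
        sp <- split(per[metrics], per$category)
        cats <- do.call(rbind, lapply(names(sp), function(cc) {
            mu <- colMeans(sp[[cc]])
            dv <- apply(sp[[cc]], 2, stats::sd)
            if (dispersion == "se") dv <- dv / sqrt(nrow(sp[[cc]]))
            data.frame(category = cc, metric = metrics, mean = unname(mu),
                       spread = unname(dv), dispersion = dispersion,
                       stringsAsFactors = FALSE)
        }))
    }
    list(samples = per, categories = cats)
}

#' Rarefaction curves
#'
#' Mean observed richness over `n_reps` random subsamples (without
#' replacement) of each sample at each depth. Depths exceeding a sample's
#' total are omitted for that sample.
#'
#' @param x an [OtuExperiment-class] or count matrix.
#' @param depths ascending vector of subsampling depths.
#' @param n_reps subsamples averaged per depth (default 10).
#' @param seed integer seed.
#' @return data.frame: sample_id, depth, richness (mean over replicates).
#' @export
rarefactionCurve <- function(x, depths, n_reps = 10, seed) {
    m <- .countMatrix(x)
    if (is.unsorted(depths)) stop("depths must be ascending")
    set.seed(as.integer(seed))
    out <- do.call(rbind, lapply(colnames(m), function(sid) {
        v <- m[, sid]
        tot <- sum(v)
        d <- depths[depths <= tot]
        if (!length(d)) return(NULL)
        rich <- vapply(d, function(dd) {
            mean(vapply(seq_len(n_reps), function(r) {
                sub <- as.integer(t(vegan::rrarefy(t(v), dd)))
                sum(sub > 0)
            }, numeric(1)))
        }, numeric(1))
        data.frame(sample_id = sid, depth = d, richness = rich,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Expected rarefied richness (analytic)
#'
#' Closed-form hypergeometric expectation of the number of taxa retained
#' when subsampling `depth` reads without replacement:
#' `sum_i 1 - C(T - n_i, depth) / C(T, depth)`.
#'
#' @inheritParams observedRichness
#' @param depth subsample size.
#' @return expected richness at `depth`.
#' @export
expectedRarefiedRichness <- function(counts, depth) {
    tot <- sum(counts)
    if (depth > tot) stop("depth exceeds sample total")
    n <- counts[counts > 0]
    sum(1 - exp(lchoose(tot - n, depth) - lchoose(tot, depth)))
}
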