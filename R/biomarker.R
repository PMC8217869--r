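## Discriminative-feature screen: lineage aggregation, Kruskal-Wallis
## filter, then a linear-discriminant effect size, one class vs all.

#' Aggregate counts into rank-qualified lineage features
#'
#' Counts are first scaled so every sample totals one million, then summed
#' within each lineage prefix at every taxonomic rank. Feature identifiers
#' are `rank|lineage` strings (e.g. `"class|Proteobacteria|Gamma..."`), so
#' child features sum to their parent within every sample.
#'
#' @param x an [OtuExperiment-class] (taxonomy taken from `rowData`) or a
#'   count matrix with `taxonomy` supplied.
#' @param taxonomy data.frame of ranked lineage strings, rownames matching
#'   taxa; "unclassified" tokens are allowed and aggregated like any other
#'   label.
#' @return numeric matrix, features x samples, on the per-million scale.
#' @export
aggregateLineages <- function(x, taxonomy = NULL) {
    m <- .countMatrix(x)
    if (is.null(taxonomy)) {
        if (is(x, "OtuExperiment") &&
            ncol(SummarizedExperiment::rowData(x)) > 0)
            taxonomy <- as.data.frame(SummarizedExperiment::rowData(x))
        else stop("a taxonomy table is required")
    }
    taxonomy <- as.data.frame(taxonomy)[rownames(m), , drop = FALSE]
    rel <- sweep(m, 2, colSums(m), "/") * 1e6
    out <- NULL
    lineage <- NULL
    for (r in seq_len(ncol(taxonomy))) {
        lineage <- if (is.null(lineage)) as.character(taxonomy[[r]])
                   else paste(lineage, taxonomy[[r]], sep = "|")
        agg <- rowsum(rel, group = lineage)
        rownames(agg) <- paste(colnames(taxonomy)[r], rownames(agg),
                               sep = "|")
        out <- rbind(out, agg)
    }
    out
}

## Align a named design vector with a feature matrix's samples.
.alignDesign <- function(features, design) {
    if (!is.null(names(design))) {
        if (!all(colnames(features) %in% names(design)))
            stop("design is missing labels for some samples")
        design <- design[colnames(features)]
    }
    if (length(design) != ncol(features))
        stop("design must supply one category per sample")
    as.character(design)
}

#' Kruskal-Wallis screen over features
#'
#' Per-feature Kruskal-Wallis H test (midranks, tie-corrected, as in
#' [stats::kruskal.test]) across the design categories; features with
#' `p <= alpha` pass. Constant features are assigned `p = 1`.
#'
#' @param features numeric matrix, features x samples.
#' @param design sample -> category labels (>= 2 categories).
#' @param alpha significance cut-off (default 0.05).
#' @return data.frame: feature, statistic, p, passed.
#' @export
kwScreen <- function(features, design, alpha = 0.05) {
    g <- factor(.alignDesign(features, design))
    if (nlevels(g) < 2) stop("need at least 2 categories")
    res <- t(apply(features, 1, function(v) {
        if (length(unique(v)) == 1) return(c(NA_real_, 1))
        kt <- stats::kruskal.test(v, g)
        c(unname(kt$statistic), kt$p.value)
    }))
    data.frame(feature = rownames(features), statistic = res[, 1],
               p = res[, 2], passed = res[, 2] <= alpha,
               row.names = NULL, stringsAsFactors = FALSE)
}

## Ridge-regularized one-vs-all discriminant weights for standardized
## features; returns |w| normalized to max 1.
.ldaWeights <- function(X, is_class, eps = 1e-6) {
    mu1 <- colMeans(X[is_class, , drop = FALSE])
    mu0 <- colMeans(X[!is_class, , drop = FALSE])
    S <- (stats::cov(X[is_class, , drop = FALSE]) * (sum(is_class) - 1) +
          stats::cov(X[!is_class, , drop = FALSE]) * (sum(!is_class) - 1)) /
         (nrow(X) - 2)
    S <- S + diag(eps * max(1, mean(diag(S))), ncol(X))
    w <- solve(S, mu1 - mu0)
    aw <- abs(w)
    if (max(aw) > 0) aw <- aw / max(aw)
    aw
}

#' Linear-discriminant effect sizes for screened features
#'
#' For each category (one vs all) and each bootstrap round, a fraction of
#' samples is drawn, features are z-standardized, and ridge-regularized
#' discriminant weights are fitted. The per-feature effect on the
#' per-million scale is `0.5 * (1 + w_f) * |Delta class means_f|`, i.e. the
#' average of the raw mean shift and its discriminant-weighted version;
#' the score is `log10` of the mean effect over bootstraps. A feature is
#' reported for its higher-mean (enriched) class only.
#'
#' @param features per-million feature matrix (features x samples),
#'   typically the [kwScreen()] survivors of [aggregateLineages()] output.
#' @param design sample -> category labels.
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample fraction of samples drawn per round (default 2/3,
#'   stratified by class; every class must retain >= 3 samples).
#' @param seed integer seed.
#' @param threshold minimum score to report (default 2.0 on the log10
#'   scale); `display_threshold` (4.5) additionally flags headline
#'   biomarkers.
#' @param display_threshold see above.
#' @return data.frame: feature, enriched class, score, displayed flag,
#'   sorted by decreasing score; only features with score >= threshold.
#' @export
ldaEffectSize <- function(features, design, n_boot = 30, subsample = 2 / 3,
                          seed, threshold = 2.0, display_threshold = 4.5) {
    g <- factor(.alignDesign(features, design))
    per_class <- table(g)
    ## the subsample keeps at least 3 samples per class, so 3 is the floor
    if (any(per_class < 3))
        stop("every class needs >= 3 samples for subsampled refits")
    X_all <- t(features)  # samples x features
    set.seed(as.integer(seed))
    classes <- levels(g)
    eff <- matrix(0, nrow(features), length(classes),
                  dimnames = list(rownames(features), classes))
    for (b in seq_len(n_boot)) {
        idx <- unlist(lapply(split(seq_along(g), g), function(ii)
            sample(ii, max(3, floor(length(ii) * subsample)))))
        X <- X_all[idx, , drop = FALSE]
        gb <- g[idx]
        sds <- apply(X, 2, stats::sd)
        sds[sds == 0] <- 1
        Z <- scale(X, scale = sds)
        for (cc in classes) {
            is_c <- gb == cc
            w <- .ldaWeights(Z, is_c)
            dmu <- abs(colMeans(X[is_c, , drop = FALSE]) -
                       colMeans(X[!is_c, , drop = FALSE]))
            eff[, cc] <- eff[, cc] + 0.5 * (1 + w) * dmu
        }
    }
    eff <- eff / n_boot
    class_means <- vapply(classes, function(cc)
        rowMeans(features[, g == cc, drop = FALSE]),
        numeric(nrow(features)))
    enriched <- classes[max.col(class_means, ties.method = "first")]
    score <- log10(pmax(eff[cbind(seq_len(nrow(eff)),
                                  match(enriched, classes))], 1e-12))
    out <- data.frame(feature = rownames(features), class = enriched,
                      score = score, displayed = score >= display_threshold,
                      row.names = NULL, stringsAsFactors = FALSE)
    out <- out[out$score >= threshold, , drop = FALSE]
    out[order(-out$score), , drop = FALSE]
}

#' Full biomarker screen
#'
#' [aggregateLineages()] then [kwScreen()] then [ldaEffectSize()], the
#' two-stage screen run with its conventional defaults (alpha 0.05, 30
#' bootstraps, 2/3 subsampling, score threshold 2.0).
#'
#' @inheritParams aggregateLineages
#' @inheritParams ldaEffectSize
#' @param design sample -> category labels.
#' @param alpha Kruskal-Wallis cut-off.
#' @return data.frame: feature, enriched class, kw_p, score, displayed.
#' @export
findBiomarkers <- function(x, design = NULL, taxonomy = NULL, alpha = 0.05,
                           n_boot = 30, subsample = 2 / 3, seed,
                           threshold = 2.0) {
    design <- .resolveDesign(x, design)
    feats <- aggregateLineages(x, taxonomy)
    kw <- kwScreen(feats, design, alpha = alpha)
    keep <- kw$feature[kw$passed]
    if (!length(keep)) return(data.frame(feature = character(0),
                                         class = character(0),
                                         kw_p = numeric(0),
                                         score = numeric(0),
                                         displayed = logical(0)))
    lda <- ldaEffectSize(feats[keep, , drop = FALSE], design,
                         n_boot = n_boot, subsample = subsample,
                         seed = seed, threshold = threshold)
    lda$kw_p <- kw$p[match(lda$feature, kw$feature)]
    lda[, c("feature", "class", "kw_p", "score", "displayed")]
}
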