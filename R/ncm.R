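## Sloan neutral community model: occurrence frequency vs metacommunity
## relative abundance, fitted by least squares over the immigration rate m.

## Predicted occurrence frequency under the Sloan model.
## "threshold": probability that a taxon's relative abundance exceeds the
## detection limit d under its Beta(Nmp, Nm(1-p)) stationary distribution
## (the published convention). "reads": exact probability of at least one
## read when N reads are drawn binomially from that Beta composition,
## 1 - B(a, b + N) / B(a, b).
.ncmPredict <- function(m, p, N, d, detection = "threshold") {
    a <- N * m * p
    b <- N * m * (1 - p)
    if (detection == "reads")
        return(1 - exp(lbeta(a, b + round(N)) - lbeta(a, b)))
    1 - stats::pbeta(d, a, b)
}

## Wilson 95% score interval for a frequency estimated from n samples.
.wilson <- function(p, n, z = 1.959964) {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}

#' Fit the Sloan neutral community model
#'
#' Occurrence frequency `f_i` (fraction of samples where taxon `i` is
#' detected) is regressed on metacommunity relative abundance `p_i` (mean
#' of per-sample relative abundances) through
#' `f_hat_i(m) = 1 - BetaCDF(1/N; N m p_i, N m (1 - p_i))`, with `N` the
#' mean library depth. `m` is fitted by bounded least squares on
#' `(1e-6, 1]` with a coarse log-spaced multistart ahead of local
#' refinement, since the one-parameter objective can be multimodal near the
#' bounds. Two free-parameter-less alternatives are scored alongside: a
#' binomial draw from the metacommunity (`1 - BinomCDF(0; N, p_i)`) and a
#' Poisson draw (`1 - PoisCDF(0; N p_i)`). The fit is declared good when
#' `R^2 > 0` and `R^2 >= R^2_pois` -- communities fitting random sampling
#' of the source pool better than the within-sample beta prediction (or
#' with negative `R^2`) are treated as rejecting neutrality.
#'
#' The per-taxon 95% prediction band is the Wilson score interval of
#' `f_hat_i` at the number of samples -- the binomial sampling noise of an
#' occurrence frequency estimated from finitely many local communities --
#' widened by a delta-method term for the sampling noise of the estimated
#' metacommunity abundance the prediction is evaluated at. Taxa are
#' partitioned as above/within/below the band.
#'
#' Because presence in a count table means at least one read, while the
#' threshold prediction treats detection as the latent composition
#' exceeding `1/N`, the threshold fit carries a systematic upward bias in
#' `m` on data whose reads are drawn from an underlying composition
#' (roughly +25-30% at typical depths). `detection = "reads"` replaces the
#' threshold with the exact beta-binomial probability of at least one
#' read, which removes that bias; the threshold form remains the default
#' because it is the established convention for this model.
#'
#' @param x an [OtuExperiment-class] or count matrix with >= 5 samples and
#'   >= 10 taxa.
#' @param pooled_p use pooled counts instead of the mean of per-sample
#'   relative abundances for `p_i`.
#' @param detection `"threshold"` (default) or `"reads"`, see Details.
#' @return an [NCMFit-class].
#' @export
fitNCM <- function(x, pooled_p = FALSE,
                   detection = c("threshold", "reads")) {
    detection <- match.arg(detection)
    mtx <- .countMatrix(x)
    if (ncol(mtx) < 5) stop("need at least 5 samples")
    keep <- rowSums(mtx) > 0
    mtx <- mtx[keep, , drop = FALSE]
    if (nrow(mtx) < 10) stop("need at least 10 non-empty taxa")
    N <- mean(colSums(mtx))
    d <- 1 / N
    rel <- sweep(mtx, 2, colSums(mtx), "/")
    p <- if (pooled_p) rowSums(mtx) / sum(mtx) else rowMeans(rel)
    f <- rowMeans(mtx > 0)
    sse <- function(m) sum((f - .ncmPredict(m, p, N, d, detection))^2)
    grid <- exp(seq(log(1e-6), log(1), length.out = 120))
    g_sse <- vapply(grid, sse, numeric(1))
    i0 <- which.min(g_sse)
    lo <- grid[max(1, i0 - 1)]
    hi <- grid[min(length(grid), i0 + 1)]
    opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-10)
    m_hat <- opt$minimum
    fit_ok <- TRUE
    if (m_hat <= 1e-6 * 1.01 || m_hat >= 1 - 1e-10) {
        fit_ok <- FALSE  # pinned at a bound
        m_hat <- min(max(m_hat, 1e-6), 1)
    }
    pred <- .ncmPredict(m_hat, p, N, d, detection)
    ss_tot <- sum((f - mean(f))^2)
    r2 <- 1 - sum((f - pred)^2) / ss_tot
    pred_bin <- 1 - stats::pbinom(0, size = round(N), prob = p)
    pred_pois <- 1 - stats::ppois(0, lambda = N * p)
    r2_bin <- 1 - sum((f - pred_bin)^2) / ss_tot
    r2_pois <- 1 - sum((f - pred_pois)^2) / ss_tot
    band <- .wilson(pred, n = ncol(mtx))
    ## the prediction is evaluated at the *estimated* metacommunity
    ## abundance; propagate that regressor noise (delta method) into the
    ## band, where the occurrence curve is steep it dominates
    eps <- pmax(p * 1e-3, 1e-12)
    dpred <- (.ncmPredict(m_hat, p + eps, N, d, detection) -
              .ncmPredict(m_hat, pmax(p - eps, 0), N, d, detection)) /
             (2 * eps)
    sd_p <- sqrt(apply(rel, 1, stats::var) / ncol(mtx))
    extra <- 1.959964 * abs(dpred) * sd_p
    band[, "lower"] <- pmax(0, band[, "lower"] - extra)
    band[, "upper"] <- pmin(1, band[, "upper"] + extra)
    memb <- rep("within", length(f))
    memb[f > band[, "upper"]] <- "above"
    memb[f < band[, "lower"]] <- "below"
    new("NCMFit", m = m_hat, Nm = N * m_hat, N = N, detectionLimit = d,
        r2 = r2, r2Binom = r2_bin, r2Pois = r2_pois,
        bootCI = c(NA_real_, NA_real_), fitOk = fit_ok,
        goodFit = (r2 > 0) && (r2 >= r2_pois),
        taxa = S4Vectors::DataFrame(
            otu = rownames(mtx), p = unname(p), freq = unname(f),
            pred = unname(pred), lower = unname(band[, "lower"]),
            upper = unname(band[, "upper"]), band = memb))
}

#' Bootstrap confidence intervals for the NCM immigration rate
#'
#' Resamples taxa (the regression units) with replacement, refits `m`, and
#' reports the 2.5/97.5 percentile interval plus a pointwise band of the
#' fitted prediction over a grid of metacommunity abundances. A flag
#' switches to resampling samples instead.
#'
#' @param x the table the fit came from.
#' @param fit an [NCMFit-class] from [fitNCM()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param resample `"taxa"` (default) or `"samples"`.
#' @param p_grid abundance grid for the prediction band (defaults to the
#'   fitted taxa's abundance range).
#' @param detection occurrence model, matching the one used in [fitNCM()].
#' @return the fit with `bootCI` filled in, plus attributes `boot_m`
#'   (replicate estimates) and `band` (data.frame p, lower, upper).
#' @export
bootstrapNCM <- function(x, fit, n_boot = 1000, seed,
                         resample = c("taxa", "samples"), p_grid = NULL,
                         detection = c("threshold", "reads")) {
    resample <- match.arg(resample)
    detection <- match.arg(detection)
    mtx <- .countMatrix(x)
    mtx <- mtx[rowSums(mtx) > 0, , drop = FALSE]
    N <- fit@N
    d <- fit@detectionLimit
    tx <- fit@taxa
    set.seed(as.integer(seed))
    fit_m <- function(p, f) {
        sse <- function(m) sum((f - .ncmPredict(m, p, N, d, detection))^2)
        grid <- exp(seq(log(1e-6), log(1), length.out = 60))
        i0 <- which.min(vapply(grid, sse, numeric(1)))
        stats::optimize(sse, interval = c(grid[max(1, i0 - 1)],
                                          grid[min(length(grid), i0 + 1)]),
                        tol = 1e-9)$minimum
    }
    boot_m <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
        if (resample == "taxa") {
            idx <- sample.int(nrow(tx), replace = TRUE)
            boot_m[b] <- tryCatch(fit_m(tx$p[idx], tx$freq[idx]),
                                  error = function(e) NA_real_)
        } else {
            jdx <- sample.int(ncol(mtx), replace = TRUE)
            sub <- mtx[, jdx, drop = FALSE]
            relb <- sweep(sub, 2, colSums(sub), "/")
            boot_m[b] <- tryCatch(
                fit_m(rowMeans(relb), rowMeans(sub > 0)),
                error = function(e) NA_real_)
        }
    }
    fail <- mean(is.na(boot_m))
    if (fail > 0.1)
        warning(sprintf("%.0f%% of bootstrap refits failed", 100 * fail))
    ok <- boot_m[!is.na(boot_m)]
    fit@bootCI <- unname(stats::quantile(ok, c(0.025, 0.975)))
    if (is.null(p_grid))
        p_grid <- exp(seq(log(min(tx$p)), log(max(tx$p)), length.out = 50))
    band_mat <- vapply(ok,
                       function(mm) .ncmPredict(mm, p_grid, N, d, detection),
                       numeric(length(p_grid)))
    band <- data.frame(
        p = p_grid,
        lower = apply(band_mat, 1, stats::quantile, 0.025),
        upper = apply(band_mat, 1, stats::quantile, 0.975))
    attr(fit, "boot_m") <- boot_m
    attr(fit, "band") <- band
    fit
}

#' Partition taxa relative to the NCM prediction band
#'
#' @param fit an [NCMFit-class].
#' @return named character vector: taxon -> above/within/below.
#' @export
partitionTaxa <- function(fit) {
    stats::setNames(fit@taxa$band, fit@taxa$otu)
}
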