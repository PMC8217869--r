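## End-to-end orchestration: simulate (or load) -> rarefy -> alpha/beta ->
## niche -> MST -> NCM -> phylosignal -> biomarkers -> partition, with one
## master seed from which every stage derives its own child seed.

#' Assemble a pipeline configuration
#'
#' @param sim list of synthetic-community settings (used when no input
#'   table is given): `S`, `n_per_category`, `categories`, `N`, `regime`
#'   (`"neutral"`, `"niche"` or `"mixed"`), `m`, `sigma_sel`, `mix_weight`,
#'   `sdlog`.
#' @param table_path,metadata_path,tree_path optional input files read via
#'   [readCountTable()], [readSampleMetadata()], [readHostTree()].
#' @param rarefy_depth depth for [rarefyCounts()]; `NULL` skips
#'   rarefaction.
#' @param n_perm,n_null,n_boot stage permutation/randomization counts.
#' @param seed master seed; each stochastic stage uses
#'   `childSeed(seed, stage)`.
#' @param stages character vector of stages to run.
#' @return a validated `list` of class `"maRunConfig"`.
#' @export
pipelineConfig <- function(sim = list(), table_path = NULL,
                           metadata_path = NULL, tree_path = NULL,
                           rarefy_depth = NULL, n_perm = 999,
                           n_null = 1000, n_boot = 1000, seed,
                           stages = c("alpha", "beta", "niche", "mst",
                                      "ncm", "phylosignal", "biomarkers",
                                      "partition")) {
    if (missing(seed)) stop("a master seed is required")
    sim_defaults <- list(S = 500, n_per_category = 5,
                         categories = c("hostA", "hostB", "hostC",
                                        "seawater", "sediment"),
                         N = 10000, regime = "neutral", m = 0.1,
                         sigma_sel = 3, mix_weight = 0.5, sdlog = 2)
    sim <- utils::modifyList(sim_defaults, sim)
    cfg <- list(sim = sim, table_path = table_path,
                metadata_path = metadata_path, tree_path = tree_path,
                rarefy_depth = rarefy_depth, n_perm = n_perm,
                n_null = n_null, n_boot = n_boot,
                seed = as.integer(seed), stages = stages)
    ## pre-flight validation before any computation
    for (p in c(table_path, metadata_path, tree_path))
        if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
    if (!sim$regime %in% c("neutral", "niche", "mixed"))
        stop("unknown regime: ", sim$regime)
    class(cfg) <- "maRunConfig"
    cfg
}

#' Run the full community-assembly pipeline
#'
#' Executes the configured stages in dependency order on either a loaded
#' or a simulated table. Every stochastic stage derives its seed from the
#' master seed by [childSeed()], so two runs of the same configuration are
#' identical and adding stages never perturbs earlier ones. The returned
#' bundle carries a provenance manifest (package version, seeds, parameter
#' echo, input hash).
#'
#' @param config a `"maRunConfig"` from [pipelineConfig()].
#' @return named list with one element per executed stage plus `table`
#'   (the analysis table), `design`, and `manifest`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "maRunConfig"))
    seeds <- stats::setNames(
        vapply(c("simulate", "rarefy", "niche", "mst", "ncm",
                 "phylosignal", "biomarkers", "beta", "traits"),
               function(s) childSeed(config$seed, s), integer(1)),
        c("simulate", "rarefy", "niche", "mst", "ncm", "phylosignal",
          "biomarkers", "beta", "traits"))
    tree <- NULL
    truth <- NULL
    if (!is.null(config$table_path)) {
        tab <- readCountTable(config$table_path)
        if (is.null(config$metadata_path))
            stop("a metadata file is required with an input table")
        sampleCategories(tab) <- readSampleMetadata(config$metadata_path)
        if (!is.null(config$tree_path)) tree <- readHostTree(config$tree_path)
    } else {
        s <- config$sim
        meta <- makeMetacommunity(s$S, sdlog = s$sdlog,
                                  seed = seeds["simulate"])
        design <- stats::setNames(
            rep(s$categories, each = s$n_per_category),
            paste0(rep(s$categories, each = s$n_per_category), "_",
                   seq_len(s$n_per_category)))
        tab <- switch(s$regime,
            neutral = simulateNeutralCommunity(
                meta, length(design), s$N, s$m, seed = seeds["simulate"]),
            niche = simulateNicheCommunity(
                meta, design, s$sigma_sel, s$N, seed = seeds["simulate"]),
            mixed = simulateMixedCommunity(
                meta, design, s$m, s$sigma_sel, s$mix_weight, s$N,
                seed = seeds["simulate"]))
        ## align design names with whatever sample ids the simulator used
        design <- stats::setNames(as.character(design), colnames(tab))
        sampleCategories(tab) <- design
        host_cats <- s$categories[seq_len(max(2, length(s$categories) - 2))]
        set.seed(seeds["traits"])
        tree <- ape::rcoal(length(host_cats), tip.label = host_cats)
    }
    design <- sampleCategories(tab)
    if (!is.null(config$rarefy_depth))
        tab <- rarefyCounts(tab, config$rarefy_depth,
                            seed = seeds["rarefy"])
    design <- sampleCategories(tab)
    res <- list(table = tab, design = design)
    st <- config$stages
    if ("alpha" %in% st)
        res$alpha <- alphaDiversity(tab)
    if ("beta" %in% st) {
        D <- brayCurtis(tab)
        res$beta <- list(
            distance = D,
            permanova = permanovaTest(D, design, n_perm = config$n_perm,
                                      seed = seeds["beta"]),
            anosim = anosimTest(D, design, n_perm = config$n_perm,
                                seed = seeds["beta"]))
    }
    if ("niche" %in% st)
        res$niche <- classifyNiche(tab, n_perm = config$n_perm,
                                   seed = seeds["niche"])
    if ("mst" %in% st)
        res$mst <- mstByCategory(tab, design, n_null = config$n_null,
                                 seed = seeds["mst"])
    if ("ncm" %in% st) {
        fit <- fitNCM(tab)
        res$ncm <- bootstrapNCM(tab, fit, n_boot = config$n_boot,
                                seed = seeds["ncm"])
    }
    if ("phylosignal" %in% st && !is.null(tree)) {
        al <- if (!is.null(res$alpha)) res$alpha else alphaDiversity(tab)
        sam <- al$samples
        sam$category <- design[sam$sample_id]
        host <- intersect(tree$tip.label, unique(design))
        sam <- sam[sam$category %in% host, ]
        if (length(host) >= 3 && nrow(sam) >= length(host)) {
            exp <- expandTreeReplicates(
                ape::keep.tip(tree, host),
                reps = max(table(sam$category)))
            trait <- stats::setNames(rep(NA_real_,
                                         length(exp$tree$tip.label)),
                                     exp$tree$tip.label)
            for (cc in host) {
                tips <- exp$tree$tip.label[exp$species == cc]
                vals <- sam$shannon[sam$category == cc]
                trait[tips] <- rep_len(vals, length(tips))
            }
            keep_tips <- names(trait)[!is.na(trait)]
            res$phylosignal <- phylosignalTest(
                ape::keep.tip(exp$tree, keep_tips), trait[keep_tips],
                n_perm = config$n_perm, seed = seeds["phylosignal"],
                trait_name = "shannon")
        }
    }
    if ("biomarkers" %in% st) {
        tax <- if (ncol(SummarizedExperiment::rowData(tab)) > 0)
            as.data.frame(SummarizedExperiment::rowData(tab))
        else  # fall back to a flat single-rank taxonomy over OTU ids
            data.frame(otu = rownames(tab), row.names = rownames(tab))
        res$biomarkers <- findBiomarkers(tab, design, taxonomy = tax,
                                         seed = seeds["biomarkers"])
    }
    if ("partition" %in% st) {
        sets <- detectSets(tab, design)
        res$partition <- list(sets = sets, venn = vennRegions(sets),
                              percent_specific = percentSpecific(sets))
    }
    res$manifest <- list(
        package = as.character(utils::packageVersion("microAssembly")),
        master_seed = config$seed, stage_seeds = as.list(seeds),
        config = unclass(config),
        table_hash = .objectHash(otuCounts(tab)),
        stages_run = intersect(st, names(res)))
    res
}
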