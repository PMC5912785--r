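## Stage orchestration: one entry point dispatching the pipeline stages from
## a single configuration (R list or YAML file), writing versioned CSV/TIFF
## artifacts plus a provenance log (config echo, seed, package version).

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (embryo, standard or En-channel rendering, writes
#' TIFFs and ground truth), `quantify-arm` (projection, membrane mask,
#' stripe/interstripe and pool separation, writes CSV), `count-molecules`
#' (detection, integration, saturation filtering, dual-standard counting,
#' writes the puncta table), `en-rows` (threshold + row counting),
#' `levels` (FPKM ratios and blot-fold chaining from CSV inputs), `stats`
#' (grouped comparisons from CSV) and `report` (summarises artifacts present
#' in `outDir`).
#'
#' @param subcommand one of `"simulate"`, `"quantify-arm"`,
#'   `"count-molecules"`, `"en-rows"`, `"levels"`, `"stats"`, `"report"`.
#' @param config configuration list, or path to a YAML file with one block
#'   per stage (see the package vignette for the schema).
#' @param outDir output directory.
#' @param seed integer seed overriding `config$seed`.
#' @return invisibly, a list of the stage's main results.
#' @examples
#' cfg <- list(simulate = list(what = "embryo",
#'             spec = list(nSegments = 3L), noise = FALSE))
#' out <- runPipeline("simulate", cfg, outDir = tempfile(), seed = 1)
#' @export
runPipeline <- function(subcommand, config = list(), outDir = ".",
                        seed = NULL) {
    sub <- match.arg(subcommand,
                     c("simulate", "quantify-arm", "count-molecules",
                       "en-rows", "levels", "stats", "report"))
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML file path")
    if (!is.null(seed)) config$seed <- seed
    if (is.null(config$seed)) config$seed <- 1L
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    res <- switch(sub,
        "simulate" = stageSimulate(config, outDir),
        "quantify-arm" = stageQuantifyArm(config, outDir),
        "count-molecules" = stageCountMolecules(config, outDir),
        "en-rows" = stageEnRows(config, outDir),
        "levels" = stageLevels(config, outDir),
        "stats" = stageStats(config, outDir),
        "report" = stageReport(config, outDir))
    prov <- list(subcommand = sub, seed = config$seed,
                 package = "wgquant",
                 version = as.character(packageVersion("wgquant")),
                 config = config)
    yaml::write_yaml(prov, file.path(outDir,
                                     paste0("provenance_", sub, ".yaml")))
    invisible(res)
}

buildSpec <- function(cfg, seed) {
    args <- cfg$spec
    if (is.null(args)) args <- list()
    args$seed <- as.integer(seed)
    do.call(embryoSpec, args)
}

stageSimulate <- function(config, outDir) {
    cfg <- config$simulate
    if (is.null(cfg$what)) stop("simulate block needs 'what': embryo|standard|en")
    noise <- !identical(cfg$noise, FALSE)
    if (cfg$what == "embryo") {
        spec <- buildSpec(cfg, config$seed)
        out <- renderEmbryo(spec, noise = noise)
        writeEmbryoTiff(out$image, outDir, prefix = "embryo",
                        truth = out$truth)
        return(out)
    }
    if (cfg$what == "standard") {
        args <- cfg$standard
        if (is.null(args)) args <- list(name = "Ndc80")
        args$seed <- as.integer(config$seed)
        spec <- do.call(standardSpec, args)
        out <- renderStandard(spec, noise = noise)
        pages <- lapply(seq_len(dim(out$stack)[1]), function(z)
            out$stack[z, , ] / max(out$stack, 1))
        tiff::writeTIFF(pages, file.path(outDir,
            paste0("standard_", spec@name, ".tif")), bits.per.sample = 32L)
        write.csv(out$positions, file.path(outDir,
            paste0("standard_", spec@name, "_truth.csv")), row.names = FALSE)
        return(out)
    }
    if (cfg$what == "en") {
        spec <- buildSpec(cfg, config$seed)
        out <- renderEnChannel(spec, noise = noise)
        tiff::writeTIFF(out$image / max(out$image, 1),
                        file.path(outDir, "en_channel.tif"),
                        bits.per.sample = 32L)
        return(out)
    }
    stop("unknown simulate target '", cfg$what, "'")
}

loadEmbryo <- function(cfg, outDir) {
    dir <- if (!is.null(cfg$inputDir)) cfg$inputDir else outDir
    prefix <- if (!is.null(cfg$prefix)) cfg$prefix else "embryo"
    img <- readEmbryoTiff(dir, prefix)
    required <- c("junction", "arm", "wg")
    missing <- setdiff(required, names(img@channelRoles))
    if (length(missing))
        stop("channel role(s) missing from input: ",
             paste(missing, collapse = ", "))
    img
}

stageQuantifyArm <- function(config, outDir) {
    cfg <- if (is.null(config$quantifyArm)) list() else config$quantifyArm
    img <- loadEmbryo(cfg, outDir)
    depth <- if (is.null(cfg$depthUm)) 8 else cfg$depthUm
    armP <- sumProjection(img, depthUm = depth, role = "arm")
    jP <- sumProjection(img, depthUm = depth, role = "junction")
    wgP <- sumProjection(img, depthUm = depth, role = "wg")
    fg <- foregroundMask(img)
    bg <- estimateBackground(armP, foreground = fg)
    mask <- segmentMembrane(jP)
    armMasked <- subtractMask(armP, mask)
    boxes <- placeStripeBoxes(wgP)
    si <- stripeInterstripe(armP, boxes, background = bg)
    siMasked <- stripeInterstripe(armMasked, boxes, background = bg)
    out <- data.frame(
        measure = c("stripe_mean", "interstripe_mean", "difference",
                    "stripe_mean_masked", "interstripe_mean_masked",
                    "difference_masked", "background"),
        value = c(si@stripeMean, si@interstripeMean, si@difference,
                  siMasked@stripeMean, siMasked@interstripeMean,
                  siMasked@difference, bg))
    write.csv(out, file.path(outDir, "arm_quantification.csv"),
              row.names = FALSE)
    writeMaskTiff(mask, file.path(outDir, "membrane_mask.tif"))
    invisible(list(table = out, mask = mask,
                   stripeInterstripe = si))
}

stageCountMolecules <- function(config, outDir) {
    cfg <- if (is.null(config$countMolecules)) list()
           else config$countMolecules
    img <- loadEmbryo(cfg, outDir)
    if (!"gfp" %in% names(img@channelRoles))
        stop("channel role(s) missing from input: gfp")
    stack <- channelData(img, "gfp")
    seeds <- config$seed + c(11L, 12L)
    tol <- if (is.null(cfg$toleranceMolecules)) 15
           else cfg$toleranceMolecules
    sat <- if (is.null(cfg$saturationLevel)) Inf else cfg$saturationLevel
    specA <- standardSpec("Ndc80", seed = seeds[1])
    specB <- standardSpec("Mif2", seed = seeds[2])
    stdA <- renderStandard(specA)
    stdB <- renderStandard(specB)
    sA <- measureStandard(stdA$stack, specA@moleculesPerStructure, "Ndc80",
                          stdA$opticsId)
    sB <- measureStandard(stdB$stack, specB@moleculesPerStructure, "Mif2",
                          stdB$opticsId)
    det <- detectPuncta(stack)
    det <- integratePuncta(det[!det$edge, , drop = FALSE], stack)
    det <- saturationFilter(det, stack, sat)$kept
    counts <- countMolecules(det, sA, sB, toleranceMolecules = tol,
                             punctaOpticsId = img@meta$opticsId)
    write.csv(counts, file.path(outDir, "puncta_molecules.csv"),
              row.names = FALSE)
    invisible(list(counts = counts, standards = list(sA, sB)))
}

stageEnRows <- function(config, outDir) {
    cfg <- if (is.null(config$enRows)) list() else config$enRows
    path <- if (!is.null(cfg$image)) cfg$image
            else file.path(outDir, "en_channel.tif")
    img <- tiff::readTIFF(path)
    if (is.list(img)) img <- img[[1]]
    res <- countEnRows(thresholdEn(img, threshold = cfg$threshold))
    tab <- as.data.frame(as.table(res@perLineCounts))
    names(tab) <- c("line", "band", "count")
    tab$mean <- res@meanRowsPerSegment
    write.csv(tab, file.path(outDir, "en_rows.csv"), row.names = FALSE)
    invisible(res)
}

stageLevels <- function(config, outDir) {
    cfg <- if (is.null(config$levels)) list() else config$levels
    out <- list()
    if (!is.null(cfg$fpkmCsv)) {
        tab <- read.csv(cfg$fpkmCsv)
        ratios <- do.call(rbind, lapply(unique(tab$stage), function(st) {
            genes <- tab$gene[tab$stage == st]
            data.frame(stage = st, numerator = genes[1],
                       denominator = genes[2],
                       ratio = fpkmRatio(tab, genes[1], genes[2],
                                         st)$ratio)
        }))
        ratios$fold <- round(ratios$ratio)
        write.csv(ratios, file.path(outDir, "fpkm_ratios.csv"),
                  row.names = FALSE)
        out$fpkm <- ratios
    }
    if (!is.null(cfg$foldsCsv)) {
        ftab <- read.csv(cfg$foldsCsv)
        measures <- lapply(seq_len(nrow(ftab)), function(i)
            foldMeasure(ftab$numerator[i], ftab$denominator[i],
                        ftab$fold[i], ftab$sd[i], ftab$n_blots[i],
                        dilutionVerified = TRUE))
        ch <- chainFolds(measures)
        chained <- data.frame(numerator = ch@numerator,
                              denominator = ch@denominator, fold = ch@fold,
                              sd = ch@sd, printed = formatFold(ch@fold))
        write.csv(chained, file.path(outDir, "chained_folds.csv"),
                  row.names = FALSE)
        out$chained <- chained
    }
    invisible(out)
}

stageStats <- function(config, outDir) {
    cfg <- if (is.null(config$stats)) list() else config$stats
    if (is.null(cfg$valuesCsv))
        stop("stats block needs 'valuesCsv' (columns group, value)")
    tab <- read.csv(cfg$valuesCsv)
    groups <- split(tab$value, tab$group)
    control <- if (!is.null(cfg$control)) cfg$control else names(groups)[1]
    ad <- anovaDunnett(groups, control)
    comp <- ad$comparisons
    comp$stars <- as.character(pStars(comp$pAdjusted))
    write.csv(comp, file.path(outDir, "stats_comparisons.csv"),
              row.names = FALSE)
    invisible(ad)
}

stageReport <- function(config, outDir) {
    files <- list.files(outDir, pattern = "\\.(csv|yaml|tif)$")
    report <- data.frame(artifact = files)
    write.csv(report, file.path(outDir, "report.csv"), row.names = FALSE)
    invisible(report)
}
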