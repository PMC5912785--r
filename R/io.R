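## TIFF and sidecar I/O.  Each channel is written as its own multi-page
## 32-bit float TIFF (one page per z slice), intensities scaled into [0, 1]
## by a per-file factor recorded in the YAML sidecar, alongside the spec
## echo and the ground-truth puncta table (CSV).

#' Write an EmbryoImage as per-channel multi-page TIFFs
#'
#' @param image an [EmbryoImage-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param truth optional [GroundTruth-class]; when given, the puncta table
#'   and spec echo are written alongside.
#' @return invisibly, the paths written.
#' @export
writeEmbryoTiff <- function(image, dir, prefix = "embryo", truth = NULL) {
    stopifnot(is(image, "EmbryoImage"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    d <- dim(image@data)
    paths <- character()
    scales <- list()
    for (role in names(image@channelRoles)) {
        st <- channelData(image, role)
        sc <- max(st, 1)
        pages <- lapply(seq_len(d[2]), function(z) st[z, , ] / sc)
        p <- file.path(dir, paste0(prefix, "_", role, ".tif"))
        tiff::writeTIFF(pages, p, bits.per.sample = 32L)
        paths <- c(paths, p)
        scales[[role]] <- sc
    }
    meta <- list(prefix = prefix,
                 channels = as.list(image@channelRoles),
                 scales = scales, pixelSizeUm = image@pixelSizeUm,
                 zStepUm = image@zStepUm, orientation = image@orientation,
                 meta = image@meta)
    if (!is.null(truth)) {
        meta$spec <- specAsList(truth@spec)
        pcsv <- file.path(dir, paste0(prefix, "_puncta_truth.csv"))
        write.csv(truth@puncta, pcsv, row.names = FALSE)
        paths <- c(paths, pcsv)
    }
    ymeta <- file.path(dir, paste0(prefix, "_meta.yaml"))
    yaml::write_yaml(meta, ymeta)
    invisible(c(paths, ymeta))
}

#' Read an EmbryoImage written by [writeEmbryoTiff()]
#'
#' @param dir directory holding the TIFFs and sidecar.
#' @param prefix file-name prefix used at write time.
#' @return an [EmbryoImage-class].
#' @export
readEmbryoTiff <- function(dir, prefix = "embryo") {
    meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
    roles <- unlist(meta$channels)
    stacks <- list()
    for (role in names(roles)) {
        pages <- tiff::readTIFF(
            file.path(dir, paste0(prefix, "_", role, ".tif")), all = TRUE)
        st <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                               ncol(pages[[1]])))
        for (z in seq_along(pages))
            st[z, , ] <- pages[[z]] * meta$scales[[role]]
        stacks[[role]] <- st
    }
    nz <- dim(stacks[[1]])[1]
    ## channel indices are remapped to a dense 1..n so a subset of roles
    ## still reads back cleanly
    roles <- sort(roles)
    roles[] <- seq_along(roles)
    data <- array(0, dim = c(length(roles), nz, dim(stacks[[1]])[2],
                             dim(stacks[[1]])[3]))
    for (role in names(roles)) data[roles[[role]], , , ] <- stacks[[role]]
    new("EmbryoImage", data = data, channelRoles = roles,
        pixelSizeUm = meta$pixelSizeUm, zStepUm = meta$zStepUm,
        orientation = meta$orientation,
        meta = lapply(meta$meta, function(v)
            if (is.list(v)) unlist(v) else v))
}

specAsList <- function(spec) {
    sl <- slotNames(class(spec))
    setNames(lapply(sl, function(s) {
        v <- slot(spec, s)
        if (length(v) > 1) as.list(v) else v
    }), sl)
}

specFromList <- function(lst) {
    args <- lapply(lst, function(v) if (is.list(v)) unlist(v) else v)
    do.call(new, c(list("EmbryoSpec"), args))
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask a [MembraneMask-class] or logical matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeMaskTiff <- function(mask, path) {
    m <- if (is(mask, "MembraneMask")) mask@mask else mask
    tiff::writeTIFF((m + 0), path, bits.per.sample = 8L)
    invisible(path)
}
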