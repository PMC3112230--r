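## Reading class-resolved lipid concentration tables and assembling
## per-sample datasets (normalize each replicate to a probability
## distribution, then average replicates with equal weight).

#' Read a class-resolved lipid concentration table
#'
#' Reads a delimited text table of per-replicate lipid concentrations
#' (nmol/mg mitochondrial protein, or any consistent unit). Two layouts
#' are supported:
#' \describe{
#'   \item{tidy}{columns \code{sample}, \code{replicate},
#'     \code{lipid_class}, \code{species}, \code{concentration}; one row
#'     per species measurement.}
#'   \item{wide}{columns \code{sample}, \code{lipid_class}, \code{species},
#'     then one column per replicate; pivoted to tidy on read.}
#' }
#' \code{lipid_class} must be one of \code{CL}, \code{PC_sn2},
#' \code{PE_sn2}, \code{PG}, \code{AC}. PC/PE species labels must be the
#' sn-2 chain only (single-chain \code{"C:D"} labels), since only sn-2
#' chains of diacyl donors enter the CL acyl pool. CL species labels are
#' total-carbons:total-double-bonds peak keys (e.g. \code{"72:8"}).
#' Species labels are validated by parsing; the Unicode ratio separator is
#' accepted. Negative concentrations are rejected.
#'
#' @param path path to a comma- (\code{.csv}) or tab-delimited text file
#'   with a header row.
#' @param format \code{"tidy"} (default) or \code{"wide"}.
#' @param sep field separator; inferred from the file extension when
#'   \code{NULL}.
#' @return A data.frame of records with columns \code{sample},
#'   \code{replicate}, \code{lipid_class}, \code{species} (ASCII
#'   normalized) and \code{concentration}.
#' @examples
#' tab <- data.frame(sample = "s1", replicate = 1, lipid_class = "CL",
#'                   species = c("72:8", "72:7"), concentration = c(2, 2))
#' tf <- tempfile(fileext = ".csv")
#' write.csv(tab, tf, row.names = FALSE)
#' readConcentrationTable(tf)
#' @seealso [buildSample()]
#' @export
readConcentrationTable <- function(path, format = c("tidy", "wide"),
                                   sep = NULL) {
    format <- match.arg(format)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "")
    if (format == "wide") {
        fixed <- c("sample", "lipid_class", "species")
        if (!all(fixed %in% names(raw)))
            stop("wide tables need columns: ", paste(fixed, collapse = ", "))
        repcols <- setdiff(names(raw), fixed)
        if (length(repcols) == 0L)
            stop("wide table has no replicate columns")
        raw <- do.call(rbind, lapply(seq_along(repcols), function(i) {
            data.frame(sample = raw$sample, replicate = i,
                       lipid_class = raw$lipid_class, species = raw$species,
                       concentration = raw[[repcols[i]]],
                       stringsAsFactors = FALSE)
        }))
    }
    need <- c("sample", "replicate", "lipid_class", "species",
              "concentration")
    if (!all(need %in% names(raw)))
        stop("tidy tables need columns: ", paste(need, collapse = ", "))
    rec <- raw[need]
    rec$concentration <- as.numeric(rec$concentration)
    if (anyNA(rec$concentration))
        stop("non-numeric concentration value(s) in ", path)
    if (any(rec$concentration < 0))
        stop("negative concentration(s) found; concentrations must be >= 0")
    badClass <- setdiff(unique(rec$lipid_class), c("CL", .DONOR_CLASSES))
    if (length(badClass))
        stop(sprintf("unknown lipid class(es) %s; allowed: %s",
                     paste(sQuote(badClass), collapse = ", "),
                     paste(c("CL", .DONOR_CLASSES), collapse = ", ")))
    ## validate + ASCII-normalize species labels per class
    isCL <- rec$lipid_class == "CL"
    if (any(isCL)) {
        pk <- .parsePeakLabel(rec$species[isCL])
        rec$species[isCL] <- .cdLabel(pk$carbons, pk$doubleBonds)
    }
    if (any(!isCL)) {
        ch <- parseChainLabel(rec$species[!isCL])
        rec$species[!isCL] <- .cdLabel(ch$carbons, ch$doubleBonds)
    }
    rec
}

#' Assemble a sample's normalized dataset from concentration records
#'
#' For one sample, each lipid class is processed per replicate: species
#' concentrations are normalized to a probability distribution (species
#' absent from a replicate but present in others count as concentration
#' 0), then the replicate probability vectors are averaged with equal
#' weight. Normalize-then-average follows the convention that replicates
#' are equally informative even when their absolute totals differ.
#'
#' @param records data.frame from [readConcentrationTable()] (or of the
#'   same shape).
#' @param sampleId the sample to assemble; defaults to the only sample
#'   present.
#' @return A [SampleDataset-class] with the observed CL profile and donor
#'   pools.
#' @examples
#' tab <- data.frame(sample = "s1", replicate = rep(1:2, each = 2),
#'                   lipid_class = "CL",
#'                   species = rep(c("72:8", "72:7"), 2),
#'                   concentration = c(1, 0, 0, 1))
#' tab <- rbind(tab, data.frame(sample = "s1", replicate = 1,
#'                              lipid_class = "PG", species = "18:1",
#'                              concentration = 3))
#' buildSample(tab)
#' @export
buildSample <- function(records, sampleId = NULL) {
    stopifnot(is.data.frame(records))
    if (is.null(sampleId)) {
        ids <- unique(records$sample)
        if (length(ids) != 1L)
            stop("multiple samples present; give 'sampleId'")
        sampleId <- ids
    }
    rec <- records[records$sample == sampleId, , drop = FALSE]
    if (nrow(rec) == 0L)
        stop(sprintf("no records for sample '%s'", sampleId))
    if (!"CL" %in% rec$lipid_class)
        stop(sprintf("sample '%s' has no CL records", sampleId))

    classMean <- function(sub) {
        species <- sort(unique(sub$species))
        reps <- unique(sub$replicate)
        mat <- matrix(0, nrow = length(reps), ncol = length(species),
                      dimnames = list(NULL, species))
        for (i in seq_along(reps)) {
            r <- sub[sub$replicate == reps[i], , drop = FALSE]
            if (anyDuplicated(r$species))
                stop(sprintf(
                    "duplicated species %s within replicate %s (%s)",
                    paste(sQuote(unique(r$species[duplicated(r$species)])),
                          collapse = ", "),
                    reps[i], r$lipid_class[1L]))
            tot <- sum(r$concentration)
            if (tot <= 0)
                stop(sprintf(
                    "replicate %s of class %s has zero total concentration",
                    reps[i], r$lipid_class[1L]))
            mat[i, r$species] <- r$concentration / tot
        }
        colMeans(mat)
    }

    cl <- classMean(rec[rec$lipid_class == "CL", , drop = FALSE])
    donorClasses <- intersect(.DONOR_CLASSES, unique(rec$lipid_class))
    pools <- lapply(donorClasses, function(cls)
        FADistribution(classMean(rec[rec$lipid_class == cls, ,
                                     drop = FALSE])))
    names(pools) <- donorClasses
    new("SampleDataset",
        sampleId = as.character(sampleId),
        clProfile = CLProfile(cl),
        donorPools = pools,
        nReplicates = length(unique(rec$replicate[rec$lipid_class == "CL"])))
}

#' Write per-sample fit results as delimited text
#'
#' Writes the fitted CL chain distribution(s), the observed/predicted peak
#' table, donor weights and per-chain residuals of a sample's analysis to
#' tab-separated files under \code{dir}, plus a JSON run summary with the
#' headline diagnostics.
#'
#' @param sampleId sample identifier used as the file prefix.
#' @param iidFit [CLFitResult-class] from [fitIID()].
#' @param propFit optional [PropFitResult-class] from [fitProportional()].
#' @param dir output directory (created if needed).
#' @param extra optional named list merged into the JSON summary (e.g.
#'   p-values, CV statistics).
#' @return Invisibly, the paths written.
#' @export
writeSampleResults <- function(sampleId, iidFit, propFit = NULL, dir = ".",
                               extra = list()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pre <- file.path(dir, sampleId)
    paths <- character(0)

    fa <- faDistributions(iidFit)[[1]]
    p <- file.path(dir, paste0(sampleId, "_fa_distribution.tsv"))
    utils::write.table(
        data.frame(chain = chainLabels(fa), prob = fa@probs),
        p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)

    p <- file.path(dir, paste0(sampleId, "_peak_fit.tsv"))
    utils::write.table(
        data.frame(peak = peakLabels(iidFit@observed),
                   observed = iidFit@observed@values,
                   predicted = iidFit@predicted@values),
        p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)

    summary <- c(list(sample = sampleId, model = iidFit@model,
                      error = fitError(iidFit),
                      pearson_r = pearsonR(iidFit),
                      unassigned_mass = iidFit@unassignedMass),
                 extra)
    if (!is.null(propFit)) {
        p <- file.path(dir, paste0(sampleId, "_weights.tsv"))
        utils::write.table(
            data.frame(donor = names(weights(propFit)),
                       weight = unname(weights(propFit))),
            p, sep = "\t", row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
        p <- file.path(dir, paste0(sampleId, "_residuals.tsv"))
        utils::write.table(
            data.frame(chain = names(residuals(propFit)),
                       residual = unname(residuals(propFit))),
            p, sep = "\t", row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
        summary$prop_error <- fitError(propFit)
        summary$prop_pearson_r <- pearsonR(propFit)
        summary$prop_weights <- as.list(weights(propFit))
    }
    p <- paste0(pre, "_summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
    invisible(paths)
}
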