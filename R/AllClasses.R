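#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' GenotypePanel: individuals x markers diploid genotype container
#'
#' A \code{GenotypePanel} holds the content of one chromosome's linkage-format
#' MAP/PED pair: marker metadata as \code{rowData}, individual metadata
#' (pedigree identity, sex, phenotype) as \code{colData}, and two character
#' assays \code{allele1}/\code{allele2} giving the unordered allele pair per
#' individual per marker. The token \code{"0"} marks a missing allele; a
#' genotype is treated as missing when either allele is \code{"0"}.
#'
#' Rows are markers, columns are individuals, following the
#' \code{SummarizedExperiment} features-by-samples convention.
#'
#' @slot .. inherits all slots from \linkS4class{SummarizedExperiment}.
#'
#' @section Phenotype encoding:
#' \code{colData(x)$phenotype} is numeric. In \code{"binary"} trait mode it is
#' 1 (unaffected/control), 2 (affected/case) or \code{NA} (missing); in
#' \code{"quantitative"} mode it is the trait value with \code{NA} for the
#' missing sentinel. The mode is stored in \code{metadata(x)$traitMode}.
#'
#' @seealso [readPed()], [genotypePanel()], [simulatePanel()]
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
    msg <- character()
    an <- names(SummarizedExperiment::assays(object))
    if (!all(c("allele1", "allele2") %in% an))
        msg <- c(msg, "assays must include 'allele1' and 'allele2'")
    else {
        a1 <- SummarizedExperiment::assay(object, "allele1")
        a2 <- SummarizedExperiment::assay(object, "allele2")
        if (!is.character(a1) || !is.character(a2))
            msg <- c(msg, "allele assays must be character matrices")
        if (length(a1) && any(xor(is.na(a1), is.na(a2))))
            msg <- c(msg, "allele1/allele2 NA patterns disagree")
    }
    rd <- SummarizedExperiment::rowData(object)
    for (f in c("name", "chrom", "bp"))
        if (!f %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", f))
    if ("bp" %in% colnames(rd) && length(rd$bp) && any(rd$bp < 0, na.rm = TRUE))
        msg <- c(msg, "marker bp positions must be non-negative")
    if ("chrom" %in% colnames(rd) && length(unique(rd$chrom)) > 1)
        msg <- c(msg, "all markers in a panel must share one chromosome")
    cd <- SummarizedExperiment::colData(object)
    for (f in c("pedID", "indivID", "fatherID", "motherID", "sex", "phenotype"))
        if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
    if (all(c("pedID", "indivID") %in% colnames(cd)) &&
        anyDuplicated(paste(cd$pedID, cd$indivID, sep = "\r")))
        msg <- c(msg, "(pedID, indivID) pairs must be unique")
    tm <- S4Vectors::metadata(object)$traitMode
    if (is.null(tm) || !tm %in% c("binary", "quantitative"))
        msg <- c(msg, "metadata(x)$traitMode must be 'binary' or 'quantitative'")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param markers data.frame with columns \code{name}, \code{chrom}, \code{bp}
#'   and optionally \code{geneticPos}, one row per marker (as from
#'   [readMap()]).
#' @param individuals data.frame with columns \code{pedID}, \code{indivID},
#'   \code{fatherID}, \code{motherID}, \code{sex}, \code{phenotype}, one row
#'   per individual.
#' @param allele1,allele2 character matrices (markers x individuals) of allele
#'   tokens; \code{"0"} = missing allele.
#' @param traitMode \code{"binary"} or \code{"quantitative"}.
#' @return A \linkS4class{GenotypePanel}.
#' @examples
#' mk <- data.frame(name = "SNP1", chrom = "1", bp = 1111L)
#' ind <- data.frame(pedID = "1", indivID = "1", fatherID = "0",
#'                   motherID = "0", sex = 1L, phenotype = 1)
#' genotypePanel(mk, ind, matrix("A", 1, 1), matrix("G", 1, 1), "binary")
#' @export
genotypePanel <- function(markers, individuals, allele1, allele2,
                          traitMode = c("binary", "quantitative")) {
    traitMode <- match.arg(traitMode)
    allele1 <- as.matrix(allele1); storage.mode(allele1) <- "character"
    allele2 <- as.matrix(allele2); storage.mode(allele2) <- "character"
    stopifnot(identical(dim(allele1), dim(allele2)),
              nrow(allele1) == nrow(markers),
              ncol(allele1) == nrow(individuals))
    dimnames(allele1) <- dimnames(allele2) <-
        list(markers$name, individuals$indivID)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays  = list(allele1 = allele1, allele2 = allele2),
        rowData = S4Vectors::DataFrame(markers),
        colData = S4Vectors::DataFrame(individuals),
        metadata = list(traitMode = traitMode))
    methods::new("GenotypePanel", se)
}

#' @describeIn genotypePanel marker metadata as a data.frame
#' @param x a \code{GenotypePanel}
#' @export
panelMarkers <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn genotypePanel individual metadata as a data.frame
#' @export
panelIndividuals <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn genotypePanel numeric phenotype vector (NA = missing)
#' @export
phenotypes <- function(x) SummarizedExperiment::colData(x)$phenotype

#' @describeIn genotypePanel trait mode, \code{"binary"} or
#'   \code{"quantitative"}
#' @export
traitMode <- function(x) S4Vectors::metadata(x)$traitMode

#' @describeIn genotypePanel number of markers
#' @export
nMarkers <- function(x) nrow(x)

#' @describeIn genotypePanel number of individuals
#' @export
nIndividuals <- function(x) ncol(x)

#' @describeIn genotypePanel logical markers x individuals matrix, TRUE where
#'   the genotype is missing (either allele \code{"0"})
#' @export
missingGenotypes <- function(x) {
    SummarizedExperiment::assay(x, "allele1") == "0" |
        SummarizedExperiment::assay(x, "allele2") == "0"
}

setMethod("show", "GenotypePanel", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("GenotypePanel: %d markers x %d individuals (chrom %s, %s trait)\n",
                nrow(object), ncol(object),
                if (nrow(object)) SummarizedExperiment::rowData(object)$chrom[1] else "?",
                S4Vectors::metadata(object)$traitMode))
    ph <- cd$phenotype
    if (S4Vectors::metadata(object)$traitMode == "binary")
        cat(sprintf("  cases: %d  controls: %d  missing phenotype: %d\n",
                    sum(ph == 2, na.rm = TRUE), sum(ph == 1, na.rm = TRUE),
                    sum(is.na(ph))))
    else
        cat(sprintf("  trait: mean %.3f sd %.3f, missing %d\n",
                    mean(ph, na.rm = TRUE), stats::sd(ph, na.rm = TRUE),
                    sum(is.na(ph))))
    invisible(NULL)
})
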