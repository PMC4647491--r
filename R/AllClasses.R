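#' @include RcppExports.R
NULL

#' Closed vocabulary of transcript class codes
#'
#' Cuffcompare-style single-letter codes describing a transcript's relation
#' to reference annotation. `x` (antisense exon) and `s` (antisense intron)
#' mark antisense transcripts; all other codes are treated as sense.
#'
#' @format Character vector of the eight recognized codes.
#' @export
CLASS_CODES <- c("=", "j", "o", "c", "x", "s", "u", "-")

ANTISENSE_CODES <- c("x", "s")

#' TranscriptSet: stranded transcript sequences with class metadata
#'
#' A [Biostrings::DNAStringSet] whose element metadata (`mcols`) carries, per
#' transcript, a `gene_id` (possibly `""` for intergenic transcripts), a
#' Cuffcompare-style `class_code`, and a derived `strand_note`
#' (`"sense"`/`"antisense"`; codes `x` and `s` are antisense). Uracil is
#' normalized to thymine on construction so sequences live in the DNA
#' alphabet.
#'
#' @slot .Data inherited from `DNAStringSet`.
#' @seealso [TranscriptSet()], [readTranscriptFasta()]
#' @export
setClass("TranscriptSet", contains = "DNAStringSet")

setValidity("TranscriptSet", function(object) {
    msg <- character()
    md <- S4Vectors::mcols(object)
    needed <- c("gene_id", "class_code", "strand_note")
    if (is.null(md) || !all(needed %in% colnames(md)))
        return(paste("mcols must contain", paste(needed, collapse = ", ")))
    if (length(object)) {
        if (is.null(names(object)) || anyNA(names(object)) ||
            any(names(object) == ""))
            msg <- c(msg, "every transcript needs a non-empty id")
        if (any(S4Vectors::width(object) < 1))
            msg <- c(msg, "sequence length must be >= 1")
        want <- ifelse(md$class_code %in% ANTISENSE_CODES,
                       "antisense", "sense")
        if (!identical(as.character(md$strand_note), want))
            msg <- c(msg, "strand_note inconsistent with class_code")
    }
    if (length(msg)) msg else TRUE
})

#' FoldingBackend: pluggable RNA secondary-structure energy engine
#'
#' Wraps a function `fold(sequence)` returning a single minimum free energy
#' (or pseudo-energy) value `<= 0`, deterministic for a given sequence and
#' strand-specific. Two backends ship with the package: see
#' [builtinFoldingBackend()] and [rnafoldBackend()].
#'
#' @slot name backend label used in error messages and manifests.
#' @slot fold function of one sequence returning a scalar energy.
#' @export
setClass("FoldingBackend",
         representation(name = "character", fold = "function"))

setValidity("FoldingBackend", function(object) {
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        return("backend needs a non-empty scalar name")
    TRUE
})

#' CodewiseModel: fitted coding-potential classifier
#'
#' Bundles the min-max feature scaler fitted on training data, the weighted
#' support vector machine (with sigmoid probability calibration on its
#' decision values), the ordered feature schema the model was trained with
#' (including which optional features were present), and the training seed.
#' Prediction refuses feature tables whose schema does not match.
#'
#' @slot kernel one of `"linear"`, `"rbf"`, `"polynomial"`.
#' @slot classWeightNoncoding weight applied to the noncoding class.
#' @slot scaler per-feature training min/max (data.frame: feature, min, max).
#' @slot fit the underlying fitted SVM object.
#' @slot featureSchema ordered feature names used at training time.
#' @slot trainingSeed integer seed the fit was made reproducible with.
#' @seealso [codewiseTrain()], [codewisePredict()]
#' @export
setClass("CodewiseModel",
         representation(kernel = "character",
                        classWeightNoncoding = "numeric",
                        scaler = "data.frame",
                        fit = "ANY",
                        featureSchema = "character",
                        trainingSeed = "integer"))

setValidity("CodewiseModel", function(object) {
    msg <- character()
    if (!object@kernel %in% c("linear", "rbf", "polynomial"))
        msg <- c(msg, "kernel must be linear, rbf or polynomial")
    if (length(object@classWeightNoncoding) != 1L ||
        object@classWeightNoncoding <= 0)
        msg <- c(msg, "classWeightNoncoding must be a positive scalar")
    if (!all(c("feature", "min", "max") %in% colnames(object@scaler)))
        msg <- c(msg, "scaler needs columns feature, min, max")
    if (length(msg)) msg else TRUE
})

#' EvaluationReport: test-set performance of a classifier
#'
#' Accuracy, area under the ROC curve of the coding-class probabilities
#' (trapezoidal; `NA` when the test set has a single class), confusion
#' counts with the coding class as positive (TP = coding predicted coding,
#' TN = noncoding predicted noncoding), and per-class rates.
#'
#' @slot accuracy fraction of correct predictions.
#' @slot auc AUC of coding-class probability, or `NA_real_`.
#' @slot confusion named numeric vector `TP`, `TN`, `FP`, `FN`.
#' @slot perClassRates named numeric vector `tpr` (coding) and `tnr`
#'   (noncoding).
#' @export
setClass("EvaluationReport",
         representation(accuracy = "numeric", auc = "numeric",
                        confusion = "numeric", perClassRates = "numeric"))

setValidity("EvaluationReport", function(object) {
    msg <- character()
    if (!all(c("TP", "TN", "FP", "FN") %in% names(object@confusion)))
        msg <- c(msg, "confusion needs TP, TN, FP, FN")
    else {
        n <- sum(object@confusion)
        acc <- (object@confusion[["TP"]] + object@confusion[["TN"]]) / n
        if (n > 0 && abs(acc - object@accuracy) > 1e-8)
            msg <- c(msg, "accuracy inconsistent with confusion counts")
    }
    if (length(msg)) msg else TRUE
})

#' CoexpressionNetwork: correlation-threshold co-expression graph
#'
#' An undirected graph over transcripts in which an edge joins two
#' transcripts whose Pearson correlation across the time course passes the
#' adjacency threshold (default 0.9), either signed-positive
#' (`r_ij >= threshold`) or absolute (`|r_ij| >= threshold`). Nodes carry
#' optional
#' super-cluster labels and gene ids used by the connectivity and hub
#' operations.
#'
#' @slot graph an `igraph` object; edge attribute `weight` stores `r`.
#' @slot threshold the edge-adjacency threshold.
#' @slot edgeRule `"signed_positive"` or `"absolute"`.
#' @seealso [buildNetwork()], [degreeOfConnectivity()], [findHubs()]
#' @export
setClass("CoexpressionNetwork",
         representation(graph = "ANY", threshold = "numeric",
                        edgeRule = "character"))

setValidity("CoexpressionNetwork", function(object) {
    msg <- character()
    if (!igraph::is_igraph(object@graph))
        msg <- c(msg, "graph must be an igraph object")
    if (length(object@threshold) != 1L || object@threshold <= 0)
        msg <- c(msg, "threshold must be a positive scalar")
    if (!object@edgeRule %in% c("signed_positive", "absolute"))
        msg <- c(msg, "edgeRule must be signed_positive or absolute")
    if (igraph::is_igraph(object@graph)) {
        g <- object@graph
        if (igraph::ecount(g)) {
            if (any(igraph::which_loop(g)))
                msg <- c(msg, "self-edges are not allowed")
            w <- igraph::E(g)$weight
            ok <- if (object@edgeRule == "signed_positive")
                all(w >= object@threshold - 1e-12)
            else all(abs(w) >= object@threshold - 1e-12)
            if (!ok) msg <- c(msg, "edge weights violate the threshold rule")
        }
    }
    if (length(msg)) msg else TRUE
})
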