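#' @include AllClasses.R
NULL

#' @describeIn TranscriptSet-accessors transcript identifiers
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @describeIn TranscriptSet-accessors gene of origin (may be `""`)
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn TranscriptSet-accessors Cuffcompare-style class codes
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' @describeIn TranscriptSet-accessors `"sense"`/`"antisense"` orientation
#'   derived from the class code
#' @export
setGeneric("strandNotes", function(x) standardGeneric("strandNotes"))

#' Accessors for TranscriptSet metadata
#'
#' @param x a [TranscriptSet].
#' @return a character vector, one element per transcript.
#' @name TranscriptSet-accessors
#' @examples
#' ts <- TranscriptSet(c(t1 = "ATGAAATAA"), class_code = "x")
#' strandNotes(ts)
NULL

setMethod("transcriptIds", "TranscriptSet", function(x) names(x))
setMethod("geneIds", "TranscriptSet",
          function(x) as.character(S4Vectors::mcols(x)$gene_id))
setMethod("classCodes", "TranscriptSet",
          function(x) as.character(S4Vectors::mcols(x)$class_code))
setMethod("strandNotes", "TranscriptSet",
          function(x) as.character(S4Vectors::mcols(x)$strand_note))

#' Compute the folding energy of one sequence with a backend
#'
#' @param backend a [FoldingBackend].
#' @param sequence nucleotide string.
#' @return scalar energy `<= 0` in the backend's units.
#' @export
setGeneric("foldSequence",
           function(backend, sequence) standardGeneric("foldSequence"))

#' @describeIn CoexpressionNetwork-accessors the underlying `igraph` graph
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @describeIn CoexpressionNetwork-accessors the edge-adjacency threshold
#' @export
setGeneric("edgeThreshold", function(x) standardGeneric("edgeThreshold"))

#' @describeIn CoexpressionNetwork-accessors edge list with correlation
#'   weights (data.frame: id_a, id_b, weight)
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @describeIn CoexpressionNetwork-accessors node ids
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Accessors for CoexpressionNetwork
#'
#' @param x a [CoexpressionNetwork].
#' @name CoexpressionNetwork-accessors
NULL

setMethod("networkGraph", "CoexpressionNetwork", function(x) x@graph)
setMethod("edgeThreshold", "CoexpressionNetwork", function(x) x@threshold)
setMethod("networkNodes", "CoexpressionNetwork",
          function(x) igraph::V(x@graph)$name)
setMethod("networkEdges", "CoexpressionNetwork", function(x) {
    if (!igraph::ecount(x@graph))
        return(data.frame(id_a = character(), id_b = character(),
                          weight = numeric(), stringsAsFactors = FALSE))
    e <- igraph::as_data_frame(x@graph, what = "edges")
    data.frame(id_a = e$from, id_b = e$to, weight = e$weight,
               stringsAsFactors = FALSE)
})

#' @describeIn CodewiseModel-accessors ordered feature names the model was
#'   trained with
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))

#' Accessors for CodewiseModel
#'
#' @param x a [CodewiseModel].
#' @name CodewiseModel-accessors
NULL

setMethod("featureSchema", "CodewiseModel", function(x) x@featureSchema)

setMethod("show", "CodewiseModel", function(object) {
    cat("CodewiseModel:", object@kernel, "kernel,",
        "noncoding class weight", object@classWeightNoncoding, "\n")
    cat("  features (", length(object@featureSchema), "): ",
        paste(object@featureSchema, collapse = ", "), "\n", sep = "")
    cat("  training seed:", object@trainingSeed, "\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
    g <- object@graph
    cat("CoexpressionNetwork:", igraph::vcount(g), "nodes,",
        igraph::ecount(g), "edges\n")
    cat("  rule:", object@edgeRule, ">=", object@threshold, "\n")
    sc <- igraph::V(g)$supercluster
    if (!is.null(sc) && any(!is.na(sc))) {
        tab <- table(sc, useNA = "no")
        cat("  super-clusters:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: accuracy %.4f, AUC %s\n",
                object@accuracy,
                ifelse(is.na(object@auc), "NA",
                       sprintf("%.4f", object@auc))))
    cat("  confusion:",
        paste(names(object@confusion), object@confusion,
              sep = "=", collapse = " "), "\n")
})
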