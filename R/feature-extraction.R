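#' @include folding.R orf-translation.R
NULL

#' Ordered feature schema of the coding-potential classifier
#'
#' The twelve per-transcript features, in canonical column order. The last
#' two (`in_mapman_bin`, `cpc_score`) are optional: models record whether
#' they were trained with them and refuse prediction on mismatched tables.
#'
#' @format Character vector of feature names.
#' @export
CODEWISE_FEATURES <- c("transcript_len", "orf_ratio", "utr5_ratio",
                       "protein_len", "gc_content", "ta_ratio", "gc_ratio",
                       "n_domains", "truncation_ratio", "mfe",
                       "in_mapman_bin", "cpc_score")

OPTIONAL_FEATURES <- c("in_mapman_bin", "cpc_score")

#' Sequence-content features
#'
#' GC content over non-N bases, the T/A count ratio and the G/C count
#' ratio. A zero denominator is clamped to 1 (the ratio then equals the
#' numerator count) and flagged, so downstream scaling never sees
#' non-finite values.
#'
#' @param sequence non-empty nucleotide string (`U` normalized to `T`).
#' @return list with `gc_content`, `ta_ratio`, `gc_ratio` and `clamped`
#'   (named logical vector marking which ratios had their denominator
#'   clamped).
#' @examples
#' sequenceContent("ATGC")
#' @export
sequenceContent <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (!nzchar(sequence)) stop("empty sequence")
    seq <- normalizeSeq(sequence)
    cnt <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                       letters = c("A", "C", "G", "T", "N"))
    a <- cnt[["A"]]; cc <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
    non_n <- a + cc + g + t
    clamped <- c(gc_content = non_n == 0, ta_ratio = a == 0,
                 gc_ratio = cc == 0)
    list(gc_content = (g + cc) / max(non_n, 1L),
         ta_ratio = t / max(a, 1L),
         gc_ratio = g / max(cc, 1L),
         clamped = clamped)
}

#' Conserved-domain features for one transcript
#'
#' @param hits data.frame of domain hits (as from [readDomainHits()]) all
#'   referring to one transcript; may have zero rows.
#' @param dedupe when `TRUE`, count each domain accession once (first hit
#'   kept); default counts hits.
#' @return list with `n_domains` and `truncation_ratio` (truncated hits /
#'   total hits; 0 when there are no hits).
#' @export
domainFeatures <- function(hits, dedupe = FALSE) {
    if (is.null(hits) || !nrow(hits))
        return(list(n_domains = 0L, truncation_ratio = 0))
    if (length(unique(hits$transcript_id)) > 1L)
        stop("hits must all belong to one transcript")
    if (dedupe) hits <- hits[!duplicated(hits$domain_accession), ,
                             drop = FALSE]
    n <- nrow(hits)
    list(n_domains = n, truncation_ratio = sum(hits$is_truncated) / n)
}

#' Assemble the full feature table for a set of transcripts
#'
#' Joins translation statistics, sequence content, domain features,
#' structure energy and functional annotation into one row per transcript,
#' in input order. Transcripts absent from the hit table get
#' `(n_domains, truncation_ratio) = (0, 0)`; transcripts absent from the
#' annotation table get `in_mapman_bin = 0` and an absent (`NA`)
#' `cpc_score`.
#'
#' @param x a [TranscriptSet].
#' @param stats translation-statistics table from [batchTranslate()];
#'   computed on the fly when `NULL`. Every transcript must be covered.
#' @param hits domain-hit data.frame ([readDomainHits()]) or `NULL`.
#' @param annotations annotation data.frame ([readAnnotationTable()]) or
#'   `NULL`.
#' @param backend folding backend passed to [computeMfe()].
#' @param dedupeDomains passed to [domainFeatures()].
#' @return data.frame with `transcript_id` plus the [CODEWISE_FEATURES]
#'   columns.
#' @export
buildFeatureTable <- function(x, stats = NULL, hits = NULL,
                              annotations = NULL,
                              backend = builtinFoldingBackend(),
                              dedupeDomains = FALSE) {
    stopifnot(methods::is(x, "TranscriptSet"), length(x) >= 1L)
    ids <- transcriptIds(x)
    if (is.null(stats)) stats <- batchTranslate(x)$stats
    miss <- setdiff(ids, stats$transcript_id)
    if (length(miss))
        stop("translation stats missing for: ", paste(miss, collapse = ", "))
    stats <- stats[match(ids, stats$transcript_id), , drop = FALSE]
    backend <- getFoldingBackend(backend)
    seqs <- as.character(x)
    rows <- lapply(seq_along(ids), function(i) {
        sc <- sequenceContent(seqs[i])
        df <- domainFeatures(
            if (is.null(hits)) NULL
            else hits[hits$transcript_id == ids[i], , drop = FALSE],
            dedupe = dedupeDomains)
        ann <- if (is.null(annotations)) NULL
               else annotations[annotations$transcript_id == ids[i], ,
                                drop = FALSE]
        data.frame(
            transcript_id = ids[i],
            transcript_len = stats$transcript_len[i],
            orf_ratio = stats$orf_ratio[i],
            utr5_ratio = stats$utr5_ratio[i],
            protein_len = stats$protein_len[i],
            gc_content = sc$gc_content,
            ta_ratio = sc$ta_ratio,
            gc_ratio = sc$gc_ratio,
            n_domains = df$n_domains,
            truncation_ratio = df$truncation_ratio,
            mfe = computeMfe(seqs[i], backend, id = ids[i]),
            in_mapman_bin = if (!is.null(ann) && nrow(ann))
                ann$in_mapman_bin[1] else 0L,
            cpc_score = if (!is.null(ann) && nrow(ann))
                ann$cpc_score[1] else NA_real_,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a feature table with the canonical column order
#'
#' @param features data.frame from [buildFeatureTable()] or
#'   [generateFeatureTable()].
#' @param path output file (tab-separated).
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
    cols <- c("transcript_id", intersect(CODEWISE_FEATURES,
                                         colnames(features)))
    utils::write.table(features[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#' @param path tab-separated feature table.
#' @return data.frame.
#' @export
readFeatureTable <- function(path) {
    stopifnot(file.exists(path))
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}
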