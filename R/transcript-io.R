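#' @include AllGenerics.R
NULL

VALID_SEQ_REGEX <- "^[ACGTN]+$"

normalizeSeq <- function(x) {
    # RNA input is accepted and stored as DNA: U -> T on ingest
    chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Construct a TranscriptSet
#'
#' @param sequences named character vector or `DNAStringSet` of transcript
#'   sequences; `U` is normalized to `T`.
#' @param gene_id gene of origin per transcript (recycled); `""` marks an
#'   intergenic transcript with no gene assignment.
#' @param class_code Cuffcompare-style class code per transcript (recycled).
#'   Codes outside [CLASS_CODES] are kept but trigger a warning.
#' @return a [TranscriptSet].
#' @examples
#' TranscriptSet(c(t1 = "AUGGCC"), gene_id = "g1", class_code = "j")
#' @export
TranscriptSet <- function(sequences, gene_id = "", class_code = "=") {
    if (methods::is(sequences, "XStringSet"))
        sequences <- stats::setNames(as.character(sequences), names(sequences))
    ids <- names(sequences)
    if (length(sequences) && (is.null(ids) || any(!nzchar(ids))))
        stop("every sequence must be named with a transcript id")
    seqs <- normalizeSeq(as.character(sequences))
    bad <- which(!grepl(VALID_SEQ_REGEX, seqs))
    if (length(bad))
        stop("invalid characters in sequence of record(s): ",
             paste(ids[bad], collapse = ", "))
    n <- length(seqs)
    gene_id <- rep_len(as.character(gene_id), n)
    class_code <- rep_len(as.character(class_code), n)
    unknown <- setdiff(unique(class_code), CLASS_CODES)
    if (length(unknown))
        warning("unknown class code(s) kept as-is: ",
                paste(unknown, collapse = ", "))
    dss <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    S4Vectors::mcols(dss) <- S4Vectors::DataFrame(
        gene_id = gene_id,
        class_code = class_code,
        strand_note = ifelse(class_code %in% ANTISENSE_CODES,
                             "antisense", "sense"))
    methods::new("TranscriptSet", dss)
}

#' Read transcripts from a FASTA file
#'
#' Headers may carry `gene=<id>` and `class_code=<code>` key=value tokens
#' after the transcript id; absent tokens default to `gene_id = ""` and
#' `class_code = "="`. `U` is normalized to `T`; characters outside
#' `A,C,G,T,N` after normalization are an error naming the record.
#'
#' @param path FASTA file, wrapped or unwrapped.
#' @return a [TranscriptSet] in file order; an empty file yields an empty
#'   set with a warning.
#' @export
readTranscriptFasta <- function(path) {
    stopifnot(file.exists(path))
    set <- Biostrings::readBStringSet(path)
    if (!length(set)) {
        warning("no FASTA records in ", path)
        return(TranscriptSet(stats::setNames(character(), character())))
    }
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    token <- function(key, default) {
        m <- regmatches(headers,
                        regexpr(paste0("\\b", key, "=\\S+"), headers))
        out <- rep(default, length(headers))
        hit <- grepl(paste0("\\b", key, "="), headers)
        out[hit] <- sub(paste0("^", key, "="), "", m)
        out
    }
    TranscriptSet(stats::setNames(as.character(set), ids),
                  gene_id = token("gene", ""),
                  class_code = token("class_code", "="))
}

#' Write a TranscriptSet to FASTA
#'
#' Inverse of [readTranscriptFasta()]: gene and class-code metadata are
#' stored as `gene=` / `class_code=` header tokens (the `gene=` token is
#' omitted for intergenic transcripts with empty `gene_id`).
#'
#' @param x a [TranscriptSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTranscriptFasta <- function(x, path) {
    stopifnot(methods::is(x, "TranscriptSet"))
    gid <- geneIds(x)
    headers <- paste0(transcriptIds(x),
                      ifelse(nzchar(gid), paste0(" gene=", gid), ""),
                      " class_code=", classCodes(x))
    out <- Biostrings::DNAStringSet(as.character(x))
    names(out) <- headers
    Biostrings::writeXStringSet(out, path)
    invisible(path)
}

#' Read a conserved-domain hit table
#'
#' Parses a tab-separated Batch CD-Search-style "hits" table. Required
#' columns (matched case-insensitively): a query id (`Query`), a domain
#' accession (`Accession`), a domain short name (`Short name`), and a
#' truncation field (`Incomplete`). Truncation values `N`, `C`, `NC`,
#' `incomplete` or `partial` (any case) mark the hit truncated; `-` or
#' empty mark it complete. A `Q#<k> - ><id>` query prefix is stripped.
#'
#' @param path tab-separated file with a header row.
#' @return data.frame with columns `transcript_id`, `domain_accession`,
#'   `domain_name`, `is_truncated` (logical, never `NA`); one row per
#'   input data row.
#' @export
readDomainHits <- function(path) {
    stopifnot(file.exists(path))
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "")
    pick <- function(candidates) {
        hit <- which(tolower(names(tab)) %in% tolower(candidates))
        if (!length(hit))
            stop("missing mandatory column (one of: ",
                 paste(candidates, collapse = ", "), "); found columns: ",
                 paste(names(tab), collapse = ", "))
        hit[1L]
    }
    qcol <- pick(c("Query", "query id", "query"))
    acol <- pick(c("Accession", "accession"))
    scol <- pick(c("Short name", "short_name", "shortname"))
    icol <- pick(c("Incomplete", "incomplete", "truncated", "truncation"))
    ids <- sub("^Q#\\d+\\s*-\\s*>?", "", as.character(tab[[qcol]]))
    trunc_raw <- tolower(trimws(as.character(tab[[icol]])))
    data.frame(
        transcript_id = ids,
        domain_accession = as.character(tab[[acol]]),
        domain_name = as.character(tab[[scol]]),
        is_truncated = trunc_raw %in% c("n", "c", "nc", "cn",
                                        "incomplete", "partial"),
        stringsAsFactors = FALSE)
}

#' Read an expression matrix (transcripts x time points, FPKM)
#'
#' @param path tab-separated file; first column transcript ids, remaining
#'   columns time points.
#' @return numeric matrix with transcript rownames and time-point colnames;
#'   negative entries are an error.
#' @export
readExpressionMatrix <- function(path) {
    stopifnot(file.exists(path))
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1]])
    if (anyNA(m)) stop("expression matrix contains missing values")
    if (any(m < 0)) stop("expression matrix contains negative FPKM values")
    m
}

#' Write an expression matrix
#'
#' @param m numeric matrix with transcript rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
    df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an annotation table (MapMan-bin presence and optional CPC score)
#'
#' @param path tab-separated file with columns `transcript_id`,
#'   `in_mapman_bin` (0/1) and `cpc_score` (number or `NA`). An absent
#'   `cpc_score` stays `NA`, which is distinct from a score of 0.
#' @return data.frame with those three columns.
#' @export
readAnnotationTable <- function(path) {
    stopifnot(file.exists(path))
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    needed <- c("transcript_id", "in_mapman_bin", "cpc_score")
    if (!all(needed %in% names(tab)))
        stop("annotation table needs columns ",
             paste(needed, collapse = ", "), "; found: ",
             paste(names(tab), collapse = ", "))
    if (anyDuplicated(tab$transcript_id))
        stop("annotation table has duplicated transcript ids")
    tab$in_mapman_bin <- as.integer(tab$in_mapman_bin)
    tab$cpc_score <- as.numeric(tab$cpc_score)
    tab[, needed]
}

#' Filter transcripts by total expression
#'
#' A transcript counts as expressed when the sum of its FPKM values across
#' the time course is strictly greater than `threshold` (default 1).
#'
#' @param m expression matrix (transcripts x time points).
#' @param threshold total-FPKM cutoff; rows with sums exactly equal to it
#'   are dropped.
#' @return the retained rows, original order preserved.
#' @export
filterExpressed <- function(m, threshold = 1) {
    stopifnot(is.matrix(m), is.numeric(m))
    m[rowSums(m) > threshold, , drop = FALSE]
}
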