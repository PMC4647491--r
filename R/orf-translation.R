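#' @include transcript-io.R
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

orfScan <- function(seq) {
    # All candidate ORFs: each ATG paired with the first in-frame stop
    # downstream. A codon containing N before any stop invalidates the
    # candidate (it cannot be said to reach a stop). Returns the maximal
    # span; ties broken by 5'-most start.
    n <- nchar(seq)
    best_len <- 0L
    best_start <- 0L
    starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
    if (starts[1] != -1L) {
        for (f in 0:2) {
            cod_pos <- seq.int(f + 1L, by = 3L,
                               length.out = (n - f) %/% 3L)
            if (!length(cod_pos)) next
            codons <- substring(seq, cod_pos, cod_pos + 2L)
            is_stop <- codons %in% STOP_CODONS
            is_bar <- grepl("N", codons, fixed = TRUE)
            term <- which(is_stop | is_bar)
            atg <- starts[(starts - 1L) %% 3L == f]
            if (!length(atg) || !length(term)) next
            i <- (atg - f - 1L) %/% 3L + 1L
            j <- term[findInterval(i, term) + 1L]
            ok <- !is.na(j) & is_stop[ifelse(is.na(j), 1L, j)]
            if (!any(ok)) next
            len <- (j[ok] - i[ok] + 1L) * 3L
            st <- atg[ok]
            pick <- which(len == max(len))
            pick <- pick[which.min(st[pick])]
            if (len[pick] > best_len ||
                (len[pick] == best_len && st[pick] < best_start)) {
                best_len <- len[pick]
                best_start <- st[pick]
            }
        }
    }
    c(start = best_start, orf_len = best_len)
}

#' Find the longest open reading frame of a transcript
#'
#' Scans the given strand for spans that begin with an `ATG` start codon and
#' end at the first in-frame stop codon (`TAA`/`TAG`/`TGA`) downstream of
#' that start, and returns the longest such span (ties go to the 5'-most
#' start). The span length includes the stop codon; the reported protein
#' excludes it. A codon containing `N` encountered before any stop
#' invalidates that candidate. Sequences with no qualifying span yield the
#' zero-ORF record with an empty protein.
#'
#' @param x a single nucleotide sequence (character scalar over
#'   `A,C,G,T,N`; `U` is normalized to `T`) or a length-1 [TranscriptSet].
#' @param id transcript id to report; taken from names when available.
#' @return named list: `transcript_id`, `transcript_len`, `utr5_len`
#'   (bases 5' of the chosen start), `orf_len`, `orf_ratio`, `utr5_ratio`,
#'   `protein_len` (amino acids, stop excluded) and `protein_seq`.
#' @examples
#' findLongestOrf("ATGAAATAA")$protein_seq  # "MK"
#' @export
findLongestOrf <- function(x, id = NULL) {
    if (methods::is(x, "TranscriptSet")) {
        stopifnot(length(x) == 1L)
        if (is.null(id)) id <- transcriptIds(x)
        x <- as.character(x)
    }
    stopifnot(is.character(x), length(x) == 1L)
    if (is.null(id)) id <- if (!is.null(names(x))) names(x) else ""
    seq <- normalizeSeq(x)
    if (!grepl(VALID_SEQ_REGEX, seq))
        stop("invalid characters in sequence", if (nzchar(id))
             paste0(" of record ", id))
    n <- nchar(seq)
    hit <- orfScan(seq)
    if (hit[["orf_len"]] == 0L) {
        return(list(transcript_id = id, transcript_len = n,
                    utr5_len = 0L, orf_len = 0L, orf_ratio = 0,
                    utr5_ratio = 0, protein_len = 0L, protein_seq = ""))
    }
    start <- hit[["start"]]
    orf_len <- hit[["orf_len"]]
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(
        substr(seq, start, start + orf_len - 4L))))
    list(transcript_id = id, transcript_len = n,
         utr5_len = start - 1L, orf_len = orf_len,
         orf_ratio = orf_len / n, utr5_ratio = (start - 1L) / n,
         protein_len = orf_len %/% 3L - 1L, protein_seq = prot)
}

#' Batch-translate transcripts at their longest ORF
#'
#' Applies [findLongestOrf()] to every transcript and produces the two
#' outputs of the batch translator: a protein FASTA restricted to
#' transcripts with a nonzero-length protein, and a translation-statistics
#' table with one row per input transcript (zero-ORF rows included), in
#' input order.
#'
#' @param x a [TranscriptSet] (non-empty).
#' @param proteinPath,statsPath optional output paths; when given, the
#'   protein FASTA and the tab-separated stats table are written there.
#' @return list with `proteins` (an `AAStringSet` named by transcript id)
#'   and `stats` (data.frame with columns `transcript_id`,
#'   `transcript_len`, `utr5_len`, `orf_len`, `orf_ratio`, `utr5_ratio`,
#'   `protein_len`).
#' @export
batchTranslate <- function(x, proteinPath = NULL, statsPath = NULL) {
    stopifnot(methods::is(x, "TranscriptSet"), length(x) >= 1L)
    rows <- lapply(seq_along(x),
                   function(i) findLongestOrf(as.character(x[i]),
                                              id = transcriptIds(x)[i]))
    stats <- do.call(rbind, lapply(rows, function(r)
        data.frame(r[c("transcript_id", "transcript_len", "utr5_len",
                       "orf_len", "orf_ratio", "utr5_ratio",
                       "protein_len")], stringsAsFactors = FALSE)))
    prot <- vapply(rows, `[[`, "", "protein_seq")
    keep <- nzchar(prot)
    proteins <- Biostrings::AAStringSet(
        stats::setNames(prot[keep], stats$transcript_id[keep]))
    if (!is.null(proteinPath))
        Biostrings::writeXStringSet(proteins, proteinPath)
    if (!is.null(statsPath))
        utils::write.table(stats, statsPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    list(proteins = proteins, stats = stats)
}
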