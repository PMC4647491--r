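#' @include codewise-classifier.R coexpression.R
NULL

#' Configuration of the synthetic benchmark generator
#'
#' Defaults encode the study conditions the analyses assume: a 3:1
#' coding:noncoding imbalance; structure pseudo-energies centered at -371
#' (coding) and -134 (noncoding) model units; coding transcripts longer
#' (lognormal, median ~1,500 nt) with ORF ratio concentrated near 0.7,
#' low 5'-UTR ratio (~0.1) and 1-4 conserved domains (each truncated with
#' probability 0.1); noncoding transcripts shorter (median ~600 nt) with
#' ORF ratio near 0.2, 5'-UTR ratio near 0.45 and no domains with
#' probability 0.95. GC content is drawn from the same distribution for
#' both classes (nucleotide content is deliberately non-discriminative).
#' The CPC-like score is a noisy monotone function of ORF ratio and
#' protein length. Expression profiles over 10 time points follow three
#' temporal archetypes: early-maturation decline, mid-to-late plateau,
#' and a final-timepoint desiccation spike.
#'
#' @param n_coding,n_noncoding class sizes (default 3,000 and 1,000).
#' @param seed integer seed reproducing every generated artifact.
#' @param coding_mfe_mean,coding_mfe_sd,noncoding_mfe_mean,noncoding_mfe_sd
#'   class-conditional Normal parameters of the structure energy (model
#'   units; samples are clamped at 0 from above).
#' @param coding_len_meanlog,coding_len_sdlog,noncoding_len_meanlog,noncoding_len_sdlog
#'   lognormal transcript-length parameters.
#' @param coding_orf_shape,noncoding_orf_shape Beta shapes of the ORF
#'   ratio (means 0.7 and 0.2).
#' @param coding_utr_frac_shape,noncoding_utr_frac_shape Beta shapes of
#'   the fraction of non-ORF sequence 5' of the start (overall 5'-UTR
#'   ratio means ~0.1 and ~0.45).
#' @param coding_domain_range integer domain counts sampled uniformly for
#'   coding transcripts.
#' @param coding_truncation_prob per-domain truncation probability.
#' @param noncoding_domain_zero_prob probability a noncoding transcript
#'   has no domain hit (else exactly one).
#' @param gc_mean,gc_sd GC-content Normal parameters shared by both
#'   classes.
#' @param cpc_like_noise_sd noise of the CPC-like score.
#' @param coding_mapman_prob,noncoding_mapman_prob probability of a
#'   MapMan-bin assignment per class.
#' @param timepoints number of expression time points.
#' @param n_expression transcripts in a generated expression matrix.
#' @param archetype_mix sampling weights of the three temporal archetypes.
#' @param expression_noise_sdlog multiplicative lognormal noise (sdlog) on
#'   expression profiles; 0 gives exact archetype curves.
#' @param antisense_fraction fraction of transcripts given an antisense
#'   partner.
#' @param antisense_correlation target correlation of antisense partners;
#'   sign flips the profile, magnitude blends it toward flat.
#' @return a list of class `generator_config`.
#' @export
generatorConfig <- function(n_coding = 3000L, n_noncoding = 1000L,
                            seed = 42L,
                            coding_mfe_mean = -371, coding_mfe_sd = 80,
                            noncoding_mfe_mean = -134,
                            noncoding_mfe_sd = 50,
                            coding_len_meanlog = log(1500),
                            coding_len_sdlog = 0.45,
                            noncoding_len_meanlog = log(600),
                            noncoding_len_sdlog = 0.5,
                            coding_orf_shape = c(14, 6),
                            noncoding_orf_shape = c(4, 16),
                            coding_utr_frac_shape = c(2, 4),
                            noncoding_utr_frac_shape = c(5, 4),
                            coding_domain_range = 1:4,
                            coding_truncation_prob = 0.1,
                            noncoding_domain_zero_prob = 0.95,
                            gc_mean = 0.42, gc_sd = 0.04,
                            cpc_like_noise_sd = 1,
                            coding_mapman_prob = 0.85,
                            noncoding_mapman_prob = 0.05,
                            timepoints = 10L, n_expression = 300L,
                            archetype_mix = c(early = 1, mid_late = 1,
                                              DT = 1),
                            expression_noise_sdlog = 0.2,
                            antisense_fraction = 0.1,
                            antisense_correlation = 1) {
    cfg <- as.list(environment())
    stopifnot(cfg$n_coding > 0, cfg$n_noncoding > 0, cfg$timepoints >= 3,
              cfg$n_expression > 0)
    class(cfg) <- "generator_config"
    cfg
}

cpcLike <- function(orf_ratio, protein_len, noise_sd) {
    8 * orf_ratio + 1.2 * log10(protein_len + 1) - 5 +
        stats::rnorm(length(orf_ratio), 0, noise_sd)
}

#' Generate a labelled synthetic feature table
#'
#' Samples `n_coding + n_noncoding` feature rows from the class-conditional
#' distributions of [generatorConfig()], enforcing the feature-vector
#' consistency constraints (`utr5_ratio + orf_ratio <= 1`, `protein_len`
#' consistent with `orf_ratio * transcript_len / 3`, `truncation_ratio = 0`
#' without domains, `mfe <= 0`).
#'
#' @param config a [generatorConfig()].
#' @return list with `features` (data.frame: `transcript_id` +
#'   [CODEWISE_FEATURES]) and `labels` (factor coding/noncoding), coding
#'   rows first.
#' @export
generateFeatureTable <- function(config = generatorConfig()) {
    stopifnot(inherits(config, "generator_config"))
    withSeed(config$seed, {
        one_class <- function(n, coding) {
            len <- pmax(60L, round(stats::rlnorm(
                n,
                if (coding) config$coding_len_meanlog
                else config$noncoding_len_meanlog,
                if (coding) config$coding_len_sdlog
                else config$noncoding_len_sdlog)))
            osh <- if (coding) config$coding_orf_shape
                   else config$noncoding_orf_shape
            orf_ratio <- stats::rbeta(n, osh[1], osh[2])
            ush <- if (coding) config$coding_utr_frac_shape
                   else config$noncoding_utr_frac_shape
            utr5_ratio <- (1 - orf_ratio) * stats::rbeta(n, ush[1], ush[2])
            protein_len <- pmax(0L, round(orf_ratio * len / 3) - 1L)
            n_domains <- if (coding)
                sample(config$coding_domain_range, n, replace = TRUE)
            else ifelse(stats::runif(n) <
                        config$noncoding_domain_zero_prob, 0L, 1L)
            truncated <- stats::rbinom(n, n_domains,
                                       config$coding_truncation_prob)
            truncation_ratio <- ifelse(n_domains > 0,
                                       truncated / pmax(n_domains, 1L), 0)
            mfe <- pmin(0, stats::rnorm(
                n,
                if (coding) config$coding_mfe_mean
                else config$noncoding_mfe_mean,
                if (coding) config$coding_mfe_sd
                else config$noncoding_mfe_sd))
            gc <- pmin(0.8, pmax(0.2, stats::rnorm(n, config$gc_mean,
                                                   config$gc_sd)))
            data.frame(
                transcript_id = sprintf(
                    if (coding) "synth_c%05d" else "synth_n%05d",
                    seq_len(n)),
                transcript_len = len, orf_ratio = orf_ratio,
                utr5_ratio = utr5_ratio, protein_len = protein_len,
                gc_content = gc,
                ta_ratio = stats::rlnorm(n, 0, 0.25),
                gc_ratio = stats::rlnorm(n, 0, 0.25),
                n_domains = n_domains,
                truncation_ratio = truncation_ratio, mfe = mfe,
                in_mapman_bin = stats::rbinom(
                    n, 1, if (coding) config$coding_mapman_prob
                          else config$noncoding_mapman_prob),
                cpc_score = cpcLike(orf_ratio, protein_len,
                                    config$cpc_like_noise_sd),
                stringsAsFactors = FALSE)
        }
        features <- rbind(one_class(config$n_coding, TRUE),
                          one_class(config$n_noncoding, FALSE))
        labels <- factor(rep(c("coding", "noncoding"),
                             c(config$n_coding, config$n_noncoding)),
                         levels = c("coding", "noncoding"))
        list(features = features, labels = labels)
    })
}

NONSTOP_CODONS <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c(STOP_CODONS, "ATG"))

stripAtg <- function(s) gsub("ATG", "ATC", s, fixed = TRUE)

randomUtr <- function(len, stop_dense = FALSE) {
    if (len <= 0) return("")
    if (stop_dense) {
        n_cod <- ceiling(len / 3)
        cods <- ifelse(stats::runif(n_cod) < 0.3,
                       sample(STOP_CODONS, n_cod, replace = TRUE),
                       sample(NONSTOP_CODONS, n_cod, replace = TRUE))
        substr(stripAtg(paste(cods, collapse = "")), 1, len)
    } else {
        stripAtg(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""))
    }
}

makeDesignedTranscript <- function(len, orf_ratio, utr_frac) {
    # ATG...stop ORF of target length flanked by an ATG-free 5'-UTR and a
    # stop-dense 3' region, so the designed ORF is the longest by
    # construction (verified by the caller).
    orf_len <- max(9L, 3L * round(orf_ratio * len / 3))
    if (orf_len > len) orf_len <- 3L * (len %/% 3L)
    utr5 <- round(utr_frac * (len - orf_len))
    utr3 <- len - orf_len - utr5
    orf <- paste0("ATG",
                  paste(sample(NONSTOP_CODONS, orf_len / 3 - 2,
                               replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1))
    paste0(randomUtr(utr5), orf, randomUtr(utr3, stop_dense = TRUE))
}

#' Generate synthetic transcript sequences
#'
#' Coding sequences embed a designed `ATG`...stop ORF of target length
#' inside random UTRs built so no longer spurious ORF exists (the 5'-UTR
#' is ATG-free, the 3' region is seeded with stop codons); each realized
#' longest ORF is verified against the design and the flanks are resampled
#' on the rare violation. Noncoding sequences use the same construction
#' with short ORF targets, capping their ORF ratio near 0.2. Realized
#' ORF/5'-UTR ratios land within ±0.05 of the sampled targets.
#'
#' @param config a [generatorConfig()]; `n_coding`/`n_noncoding` rows are
#'   produced.
#' @return list with `transcripts` (a [TranscriptSet]; coding transcripts
#'   carry class code `"="` and a gene id, noncoding ones `"u"`/`"x"`) and
#'   `labels` (factor aligned with the set).
#' @export
generateTranscriptFasta <- function(config = generatorConfig()) {
    stopifnot(inherits(config, "generator_config"))
    withSeed(config$seed, {
        gen_class <- function(n, coding) {
            len <- pmax(120L, round(stats::rlnorm(
                n,
                if (coding) config$coding_len_meanlog
                else config$noncoding_len_meanlog,
                if (coding) config$coding_len_sdlog
                else config$noncoding_len_sdlog)))
            osh <- if (coding) config$coding_orf_shape
                   else config$noncoding_orf_shape
            ush <- if (coding) config$coding_utr_frac_shape
                   else config$noncoding_utr_frac_shape
            orf_ratio <- stats::rbeta(n, osh[1], osh[2])
            utr_frac <- stats::rbeta(n, ush[1], ush[2])
            vapply(seq_len(n), function(i) {
                target <- max(9L, 3L * round(orf_ratio[i] * len[i] / 3))
                for (try in 1:50) {
                    s <- makeDesignedTranscript(len[i], orf_ratio[i],
                                                utr_frac[i])
                    if (findLongestOrf(s)$orf_len ==
                        min(target, 3L * (len[i] %/% 3L)))
                        return(s)
                }
                stop("failed to realize designed ORF")
            }, character(1))
        }
        cod <- gen_class(config$n_coding, TRUE)
        nc <- gen_class(config$n_noncoding, FALSE)
        ids <- c(sprintf("synth_c%05d", seq_len(config$n_coding)),
                 sprintf("synth_n%05d", seq_len(config$n_noncoding)))
        genes <- c(sprintf("gene_c%05d", seq_len(config$n_coding)),
                   rep("", config$n_noncoding))
        codes <- c(rep("=", config$n_coding),
                   ifelse(stats::runif(config$n_noncoding) < 0.2,
                          "x", "u"))
        ts <- TranscriptSet(stats::setNames(c(cod, nc), ids),
                            gene_id = genes, class_code = codes)
        list(transcripts = ts,
             labels = factor(rep(c("coding", "noncoding"),
                                 c(config$n_coding, config$n_noncoding)),
                             levels = c("coding", "noncoding")))
    })
}

#' Generate domain hits consistent with a synthetic feature table
#'
#' @param features feature data.frame with `transcript_id`, `n_domains`,
#'   `truncation_ratio`.
#' @param seed integer seed for accession sampling.
#' @return domain-hit data.frame in the [readDomainHits()] layout.
#' @export
generateDomainHits <- function(features, seed = 1L) {
    pool <- data.frame(
        domain_accession = c("pfam00069", "cd00051", "pfam00004",
                             "cd00009", "pfam00076", "pfam00646",
                             "cd00018", "pfam00010"),
        domain_name = c("PKc", "EFh", "AAA", "AAA_2", "RRM_1", "F-box",
                        "AP2", "HLH"),
        stringsAsFactors = FALSE)
    withSeed(seed, {
        rows <- lapply(seq_len(nrow(features)), function(i) {
            k <- features$n_domains[i]
            if (k == 0) return(NULL)
            n_trunc <- round(features$truncation_ratio[i] * k)
            pick <- sample(nrow(pool), k, replace = TRUE)
            data.frame(transcript_id = features$transcript_id[i],
                       domain_accession = pool$domain_accession[pick],
                       domain_name = pool$domain_name[pick],
                       is_truncated = seq_len(k) <= n_trunc,
                       stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, rows)
        if (is.null(out))
            out <- data.frame(transcript_id = character(),
                              domain_accession = character(),
                              domain_name = character(),
                              is_truncated = logical(),
                              stringsAsFactors = FALSE)
        rownames(out) <- NULL
        out
    })
}

archetypeCurve <- function(name, timepoints) {
    t <- seq_len(timepoints) - 1L
    switch(name,
           early = 8 * exp(-0.4 * t) + 0.5,
           mid_late = 0.5 + 7 / (1 + exp(-1.5 * (t - timepoints / 3))),
           DT = c(rep(1, timepoints - 1L), 12),
           stop("unknown archetype: ", name))
}

#' Generate a synthetic temporal expression matrix
#'
#' Each transcript follows one of three developmental archetypes (early
#' decline, mid-to-late plateau, final-timepoint desiccation spike) scaled
#' by a random amplitude and perturbed by multiplicative lognormal noise;
#' all FPKM values are non-negative. A configured fraction of transcripts
#' receive an antisense partner whose profile shares (positive
#' correlation) or reverses (negative) the sense archetype, blended toward
#' flat as the target correlation magnitude decreases; with zero noise and
#' magnitude 1 the pair correlates exactly.
#'
#' @param config a [generatorConfig()]; uses `n_expression`, `timepoints`,
#'   `archetype_mix`, `expression_noise_sdlog`, `antisense_fraction`,
#'   `antisense_correlation` and `seed`.
#' @return list with `matrix` (FPKM; antisense rows suffixed `_as`),
#'   `archetypes` (named truth labels) and `pairs` (data.frame
#'   `sense_id`, `antisense_id`).
#' @export
generateExpressionMatrix <- function(config = generatorConfig()) {
    stopifnot(inherits(config, "generator_config"))
    withSeed(config$seed + 1L, {
        n <- config$n_expression
        tp <- config$timepoints
        arch_names <- names(config$archetype_mix)
        arch <- sample(arch_names, n, replace = TRUE,
                       prob = config$archetype_mix)
        ids <- sprintf("tx_%05d", seq_len(n))
        amp <- stats::rlnorm(n, 0, 0.5)
        base <- vapply(arch, archetypeCurve, numeric(tp), timepoints = tp)
        noise <- function(k) matrix(
            stats::rlnorm(k * tp, 0, config$expression_noise_sdlog),
            nrow = k)
        sense <- t(base) * amp * noise(n)
        rownames(sense) <- ids
        n_as <- round(config$antisense_fraction * n)
        pairs <- data.frame(sense_id = character(),
                            antisense_id = character(),
                            stringsAsFactors = FALSE)
        anti <- NULL
        if (n_as > 0) {
            pick <- sort(sample(n, n_as))
            rho <- config$antisense_correlation
            prof <- t(base)[pick, , drop = FALSE]
            if (rho < 0) prof <- (max(prof) + min(prof)) - prof
            prof <- abs(rho) * prof + (1 - abs(rho)) * rowMeans(prof)
            anti <- prof * amp[pick] * noise(n_as)
            rownames(anti) <- paste0(ids[pick], "_as")
            pairs <- data.frame(sense_id = ids[pick],
                                antisense_id = rownames(anti),
                                stringsAsFactors = FALSE)
        }
        mat <- rbind(sense, anti)
        colnames(mat) <- sprintf("T%02d", seq_len(tp))
        labels <- c(stats::setNames(arch, ids),
                    if (n_as > 0)
                        stats::setNames(arch[match(pairs$sense_id, ids)],
                                        pairs$antisense_id))
        list(matrix = mat, archetypes = labels, pairs = pairs)
    })
}

#' Write the benchmark preset to a directory
#'
#' Materializes the synthetic benchmark as plain-text files:
#' `features.tsv`, `labels.tsv`, `transcripts.fasta`, `domains.tsv`,
#' `expression.tsv` and `truth.tsv`.
#'
#' @param config a [generatorConfig()].
#' @param dir output directory (created if needed).
#' @param n_fasta number of sequences actually written to the FASTA
#'   (sequence construction is slower than feature sampling, so the
#'   sequence file is a subset preset; class ratio 3:1 preserved).
#' @return `dir`, invisibly.
#' @export
simulateBenchmark <- function(config = generatorConfig(), dir,
                              n_fasta = 40L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generateFeatureTable(config)
    writeFeatureTable(gen$features, file.path(dir, "features.tsv"))
    utils::write.table(
        data.frame(transcript_id = gen$features$transcript_id,
                   label = as.character(gen$labels)),
        file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    hits <- generateDomainHits(gen$features, seed = config$seed)
    utils::write.table(
        data.frame(Query = hits$transcript_id,
                   Accession = hits$domain_accession,
                   `Short name` = hits$domain_name,
                   Incomplete = ifelse(hits$is_truncated, "C", "-"),
                   check.names = FALSE),
        file.path(dir, "domains.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    fasta_cfg <- config
    fasta_cfg$n_coding <- max(3L, round(n_fasta * 0.75))
    fasta_cfg$n_noncoding <- max(1L, n_fasta - fasta_cfg$n_coding)
    fa <- generateTranscriptFasta(fasta_cfg)
    writeTranscriptFasta(fa$transcripts, file.path(dir, "transcripts.fasta"))
    expr <- generateExpressionMatrix(config)
    writeExpressionMatrix(expr$matrix, file.path(dir, "expression.tsv"))
    utils::write.table(
        data.frame(transcript_id = names(expr$archetypes),
                   archetype = as.character(expr$archetypes)),
        file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}
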