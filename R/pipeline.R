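#' @include synthetic-data.R
NULL

#' Read a flat key=value run-configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Numeric-looking values are converted. Thresholds are validated at parse
#' time (`threshold` must lie in (0, 1], `alpha` in (0, 1),
#' `train_frac` in (0, 1)).
#'
#' @param path configuration file.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    bad <- lengths(kv) != 3L
    if (any(bad)) stop("malformed config line(s): ",
                       paste(lines[bad], collapse = "; "))
    keys <- trimws(vapply(kv, `[`, "", 2))
    vals <- trimws(vapply(kv, `[`, "", 3))
    out <- lapply(vals, function(v) {
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
    })
    names(out) <- keys
    validateRunConfig(out)
    out
}

validateRunConfig <- function(config) {
    chk <- function(key, lo, hi, lo_open = TRUE, hi_open = FALSE) {
        v <- config[[key]]
        if (is.null(v)) return(invisible())
        ok <- is.numeric(v) &&
            (if (lo_open) v > lo else v >= lo) &&
            (if (hi_open) v < hi else v <= hi)
        if (!ok) stop("invalid ", key, ": ", v)
    }
    chk("threshold", 0, 1)
    chk("expressed_fpkm", 0, Inf, lo_open = FALSE, hi_open = TRUE)
    chk("alpha", 0, 1, hi_open = TRUE)
    chk("train_frac", 0, 1, hi_open = TRUE)
    chk("class_weight", 0, Inf, hi_open = TRUE)
    if (!is.null(config$k) && (!is.numeric(config$k) || config$k < 2))
        stop("invalid k: ", config$k)
    invisible(config)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the framework over a run configuration: with a `fasta`
#' input it translates (longest ORF), assembles the feature table (domain
#' hits, annotations and structure energy included when configured) and,
#' given a `model`, classifies coding potential; with an `expression`
#' input it applies the expressed filter, center-normalizes, clusters
#' (when `k` is set), builds the correlation-threshold network, ranks
#' hubs, and screens configured sense-antisense pairs. All inputs are
#' checked before any computation; partial outputs are removed on
#' failure; a `manifest.json` recording configuration, seed and outputs
#' is written. Outputs are deterministic given the seed.
#'
#' @param config named list (see [readRunConfig()]) or path to a config
#'   file. Recognized keys: `fasta`, `domains`, `annotations`, `model`,
#'   `expression`, `pairs`, `seed`, `k`, `threshold` (default 0.9),
#'   `edge_rule`, `alpha` (0.05), `expressed_fpkm` (1),
#'   `folding_backend` (`builtin`/`external`), `iterations` (500).
#' @param outDir output directory, created fresh for the run.
#' @return `outDir`, invisibly; outputs written there.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- readRunConfig(config)
    validateRunConfig(config)
    if (is.null(config$seed))
        stop("a seed is mandatory for pipeline runs")
    inputs <- unlist(config[intersect(
        c("fasta", "domains", "annotations", "model", "expression",
          "pairs"), names(config))])
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in))
        stop("missing input file(s): ", paste(missing_in, collapse = ", "))
    if (is.null(config$fasta) && is.null(config$expression))
        stop("nothing to do: provide a fasta and/or expression input")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    out <- function(name) {
        p <- file.path(outDir, name)
        written <<- c(written, p)
        p
    }
    ok <- FALSE
    on.exit(if (!ok) unlink(written), add = TRUE)

    seed <- as.integer(config$seed)
    threshold <- config$threshold %||% 0.9
    alpha <- config$alpha %||% 0.05
    edge_rule <- config$edge_rule %||% "signed_positive"
    manifest <- list(package = "codewise",
                     version = as.character(utils::packageVersion("codewise")),
                     seed = seed, config = config, outputs = list())

    if (!is.null(config$fasta)) {
        ts <- readTranscriptFasta(config$fasta)
        tr <- batchTranslate(ts, proteinPath = out("proteins.fasta"),
                             statsPath = out("translation_stats.tsv"))
        hits <- if (!is.null(config$domains))
            readDomainHits(config$domains) else NULL
        ann <- if (!is.null(config$annotations))
            readAnnotationTable(config$annotations) else NULL
        feats <- buildFeatureTable(
            ts, stats = tr$stats, hits = hits, annotations = ann,
            backend = getFoldingBackend(config$folding_backend %||%
                                        "builtin"))
        writeFeatureTable(feats, out("features.tsv"))
        if (!is.null(config$model)) {
            model <- readCodewiseModel(config$model)
            pred <- codewisePredict(model, feats)
            utils::write.table(pred, out("predictions.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
    }

    if (!is.null(config$expression)) {
        m <- readExpressionMatrix(config$expression)
        m <- filterExpressed(m, config$expressed_fpkm %||% 1)
        norm <- centerNormalize(m)
        sc <- NULL
        if (!is.null(config$k)) {
            cl <- kmeansCluster(norm, k = as.integer(config$k),
                                iterations = as.integer(
                                    config$iterations %||% 500),
                                seed = seed)
            cl <- assignSuperclusters(
                cl, stats::setNames(as.character(sort(unique(
                    cl$cluster_id))), sort(unique(cl$cluster_id))))
            utils::write.table(cl, out("clusters.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            sc <- cl
        }
        net <- suppressWarnings(buildNetwork(
            m, threshold = threshold, edgeRule = edge_rule,
            superclusters = sc))
        writeEdgeList(net, out("edges.tsv"))
        if (!is.null(sc)) {
            hubs <- do.call(rbind, lapply(
                unique(sc$supercluster_id), function(s)
                    cbind(supercluster_id = s,
                          findHubs(net, s, topN = 5L))))
            utils::write.table(hubs, out("hubs.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
        if (!is.null(config$pairs)) {
            pairs <- utils::read.delim(config$pairs,
                                       stringsAsFactors = FALSE)
            keep <- pairs$sense_id %in% rownames(m) &
                pairs$antisense_id %in% rownames(m)
            screen <- senseAntisenseScreen(m, pairs[keep, , drop = FALSE],
                                           alpha = alpha)
            utils::write.table(screen, out("antisense.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
    }

    manifest$outputs <- basename(written)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ok <- TRUE
    invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
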