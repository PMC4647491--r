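#' @include AllGenerics.R
NULL

#' Center and normalize expression rows
#'
#' Each row is mean-centered and scaled to unit sum of squares (the
#' GeneCluster-style preprocessing ahead of k-means). Constant rows become
#' all-zero and are flagged.
#'
#' @param m expression matrix (transcripts x time points, >= 2 columns).
#' @return matrix of the same shape; attribute `flagged` holds the ids of
#'   constant rows.
#' @export
centerNormalize <- function(m) {
    stopifnot(is.matrix(m), ncol(m) >= 2L)
    centered <- m - rowMeans(m)
    ss <- sqrt(rowSums(centered^2))
    flagged <- rownames(m)[ss == 0]
    ss[ss == 0] <- 1
    out <- centered / ss
    attr(out, "flagged") <- flagged
    out
}

#' K-means clustering of expression profiles
#'
#' Euclidean k-means (Lloyd iterations to convergence, capped at 300 per
#' restart) run as the best of `iterations` random restarts by
#' within-cluster sum of squares; deterministic for a given seed.
#'
#' @param m normalized expression matrix (see [centerNormalize()]).
#' @param k number of clusters, `2 <= k <= nrow(m)`.
#' @param iterations number of random restarts (default 500).
#' @param seed integer seed.
#' @return data.frame with `transcript_id`, `cluster_id` (1..k) and
#'   `supercluster_id` (`NA` until [assignSuperclusters()]).
#' @export
kmeansCluster <- function(m, k, iterations = 500L, seed = 1L) {
    stopifnot(is.matrix(m))
    if (k < 2L) stop("k must be at least 2")
    if (k > nrow(m)) stop("k exceeds the number of transcripts")
    fit <- withSeed(seed, suppressWarnings(
        stats::kmeans(m, centers = k, iter.max = 300L,
                      nstart = iterations, algorithm = "Lloyd")))
    data.frame(transcript_id = rownames(m),
               cluster_id = as.integer(fit$cluster),
               supercluster_id = NA_character_,
               stringsAsFactors = FALSE)
}

#' Group clusters into super-clusters
#'
#' @param assignments data.frame from [kmeansCluster()].
#' @param mapping named vector mapping every `cluster_id` (names) to a
#'   super-cluster label, e.g. `c("1" = "early", "2" = "DT")`.
#' @return the assignments with `supercluster_id` filled.
#' @export
assignSuperclusters <- function(assignments, mapping) {
    ids <- as.character(assignments$cluster_id)
    miss <- setdiff(unique(ids), names(mapping))
    if (length(miss))
        stop("mapping missing cluster id(s): ", paste(miss, collapse = ", "))
    assignments$supercluster_id <- as.character(mapping[ids])
    assignments
}

superclusterVector <- function(superclusters) {
    # accepts a named vector (transcript -> label) or an assignments
    # data.frame carrying supercluster_id
    if (is.data.frame(superclusters)) {
        stopifnot(all(c("transcript_id", "supercluster_id") %in%
                      colnames(superclusters)))
        stats::setNames(as.character(superclusters$supercluster_id),
                        superclusters$transcript_id)
    } else superclusters
}

#' Build the correlation-threshold co-expression network
#'
#' All-pairs Pearson correlation of expression profiles; an edge joins
#' transcripts `i`, `j` when `r_ij >= threshold` (`signed_positive`, the
#' default) or `|r_ij| >= threshold` (`absolute`). Constant rows cannot
#' form edges and are kept as isolated nodes with a warning.
#'
#' @param m expression matrix (>= 3 time points).
#' @param threshold edge-adjacency threshold (default 0.9).
#' @param edgeRule `"signed_positive"` or `"absolute"`.
#' @param superclusters optional super-cluster labels: named vector or
#'   assignments data.frame (see [assignSuperclusters()]).
#' @param geneIds optional named vector (transcript -> gene) used by hub
#'   deduplication.
#' @return a [CoexpressionNetwork].
#' @export
buildNetwork <- function(m, threshold = 0.9,
                         edgeRule = c("signed_positive", "absolute"),
                         superclusters = NULL, geneIds = NULL) {
    stopifnot(is.matrix(m), ncol(m) >= 3L)
    edgeRule <- match.arg(edgeRule)
    if (threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]")
    constant <- apply(m, 1L, function(r) stats::var(r) == 0)
    if (any(constant))
        warning("constant profile(s) excluded from edge formation: ",
                paste(rownames(m)[constant], collapse = ", "))
    r <- suppressWarnings(stats::cor(t(m)))
    keep <- if (edgeRule == "signed_positive") r >= threshold
            else abs(r) >= threshold
    keep[is.na(keep)] <- FALSE
    diag(keep) <- FALSE
    adj <- ifelse(keep, r, 0)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    sc <- superclusterVector(superclusters)
    igraph::V(g)$supercluster <-
        if (is.null(sc)) NA_character_
        else as.character(sc[igraph::V(g)$name])
    igraph::V(g)$gene <-
        if (is.null(geneIds)) NA_character_
        else as.character(geneIds[igraph::V(g)$name])
    methods::new("CoexpressionNetwork", graph = g, threshold = threshold,
                 edgeRule = edgeRule)
}

#' Construct a co-expression network from an explicit edge list
#'
#' Useful for worked examples and for importing externally thresholded
#' networks. Edge weights default to 1 and must satisfy the threshold
#' rule.
#'
#' @param edges data.frame with columns `id_a`, `id_b` and optionally
#'   `weight`.
#' @param nodes node ids; defaults to those appearing in `edges`, but can
#'   add isolated nodes.
#' @param superclusters optional named vector or assignments data.frame of
#'   super-cluster labels.
#' @param geneIds optional named vector (transcript -> gene).
#' @inheritParams buildNetwork
#' @return a [CoexpressionNetwork].
#' @export
networkFromEdges <- function(edges, nodes = NULL, superclusters = NULL,
                             geneIds = NULL, threshold = 0.9,
                             edgeRule = c("signed_positive", "absolute")) {
    edgeRule <- match.arg(edgeRule)
    stopifnot(all(c("id_a", "id_b") %in% colnames(edges)))
    if (is.null(edges$weight)) edges$weight <- 1
    all_nodes <- unique(c(edges$id_a, edges$id_b, nodes))
    g <- igraph::graph_from_data_frame(
        data.frame(from = edges$id_a, to = edges$id_b,
                   weight = edges$weight, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
    sc <- superclusterVector(superclusters)
    igraph::V(g)$supercluster <-
        if (is.null(sc)) NA_character_
        else as.character(sc[igraph::V(g)$name])
    igraph::V(g)$gene <-
        if (is.null(geneIds)) NA_character_
        else as.character(geneIds[igraph::V(g)$name])
    methods::new("CoexpressionNetwork", graph = g, threshold = threshold,
                 edgeRule = edgeRule)
}

scMembers <- function(network, supercluster) {
    g <- networkGraph(network)
    members <- igraph::V(g)$name[!is.na(igraph::V(g)$supercluster) &
                                 igraph::V(g)$supercluster == supercluster]
    if (!length(members))
        stop("super-cluster not found or empty: ", supercluster)
    members
}

#' Degree of connectivity of a node within a super-cluster
#'
#' For node `x` with `m` neighbors inside super-cluster `sc` of `n` nodes,
#' the degree of connectivity is `m / n` (a node connected to 5 nodes of a
#' 10-node super-cluster has degree 0.5).
#'
#' @param network a [CoexpressionNetwork] with super-cluster labels.
#' @param node transcript id.
#' @param supercluster super-cluster label (non-empty in the network).
#' @return data.frame row: `transcript_id`, `supercluster_id`, `m`, `n`,
#'   `degree`.
#' @export
degreeOfConnectivity <- function(network, node, supercluster) {
    g <- networkGraph(network)
    if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
    members <- scMembers(network, supercluster)
    nb <- igraph::neighbors(g, node)$name
    m <- length(intersect(nb, setdiff(members, node)))
    n <- length(members)
    data.frame(transcript_id = node, supercluster_id = supercluster,
               m = m, n = n, degree = m / n, stringsAsFactors = FALSE)
}

#' Median degree of connectivity of a super-cluster
#'
#' The member degrees are not normally distributed, so the super-cluster
#' is summarized by their median (even counts average the central pair).
#'
#' @inheritParams degreeOfConnectivity
#' @return scalar median degree.
#' @export
superclusterConnectivity <- function(network, supercluster) {
    members <- scMembers(network, supercluster)
    deg <- vapply(members, function(id)
        degreeOfConnectivity(network, id, supercluster)$degree, numeric(1))
    stats::median(deg)
}

#' Rank hub transcripts of a super-cluster
#'
#' Members sorted by degree of connectivity (descending; ties broken by
#' transcript id). With `dedupeByGene` at most one transcript per gene is
#' retained (the highest-ranked isoform), reflecting that distinct hubs
#' come from distinct genes. The `degree` column doubles as the fraction
#' of super-cluster nodes connected to the hub.
#'
#' @inheritParams degreeOfConnectivity
#' @param topN number of hubs to return.
#' @param dedupeByGene keep at most one transcript per gene.
#' @return data.frame: `transcript_id`, `gene_id`, `m`, `n`, `degree`.
#' @export
findHubs <- function(network, supercluster, topN = 5L,
                     dedupeByGene = TRUE) {
    g <- networkGraph(network)
    members <- scMembers(network, supercluster)
    rows <- do.call(rbind, lapply(members, function(id)
        degreeOfConnectivity(network, id, supercluster)))
    rows$gene_id <- as.character(
        igraph::vertex_attr(g, "gene", rows$transcript_id))
    rows <- rows[order(-rows$degree, rows$transcript_id), , drop = FALSE]
    if (dedupeByGene) {
        known <- !is.na(rows$gene_id) & nzchar(rows$gene_id)
        rows <- rows[!(known & duplicated(rows$gene_id)), , drop = FALSE]
    }
    out <- utils::head(rows, topN)
    rownames(out) <- NULL
    out[, c("transcript_id", "gene_id", "m", "n", "degree")]
}

#' Nearest-neighbor sub-network of a node
#'
#' The induced sub-network on a node of interest plus all nodes directly
#' connected to it, retaining super-cluster labels and edge weights.
#'
#' @inheritParams degreeOfConnectivity
#' @return a [CoexpressionNetwork] restricted to the node and its
#'   neighbors.
#' @export
nearestNeighbors <- function(network, node) {
    g <- networkGraph(network)
    if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
    keep <- union(node, igraph::neighbors(g, node)$name)
    methods::new("CoexpressionNetwork",
                 graph = igraph::induced_subgraph(g, keep),
                 threshold = network@threshold,
                 edgeRule = network@edgeRule)
}

#' Screen sense-antisense transcript pairs for correlated expression
#'
#' Pearson correlation of each pair's profiles across the time course with
#' a two-sided p-value from the t transform (`df = timepoints - 2`); a
#' pair is significant when `p < alpha`. A constant member leaves `r`
#' undefined and the pair flagged not significant with a reason.
#'
#' @param m expression matrix (>= 3 time points) containing all pair
#'   members.
#' @param pairs data.frame with columns `sense_id`, `antisense_id`.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `sense_id`, `antisense_id`, `r`, `p_value`,
#'   `significant`, `reason`; attribute `summary` holds the pair and
#'   significant counts.
#' @export
senseAntisenseScreen <- function(m, pairs, alpha = 0.05) {
    stopifnot(is.matrix(m), ncol(m) >= 3L,
              all(c("sense_id", "antisense_id") %in% colnames(pairs)))
    miss <- setdiff(unique(c(pairs$sense_id, pairs$antisense_id)),
                    rownames(m))
    if (length(miss))
        stop("pair member(s) absent from expression matrix: ",
             paste(miss, collapse = ", "))
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        x <- m[pairs$sense_id[i], ]
        y <- m[pairs$antisense_id[i], ]
        if (stats::var(x) == 0 || stats::var(y) == 0)
            return(data.frame(sense_id = pairs$sense_id[i],
                              antisense_id = pairs$antisense_id[i],
                              r = NA_real_, p_value = NA_real_,
                              significant = FALSE,
                              reason = "constant profile",
                              stringsAsFactors = FALSE))
        ct <- stats::cor.test(x, y, method = "pearson",
                              alternative = "two.sided")
        data.frame(sense_id = pairs$sense_id[i],
                   antisense_id = pairs$antisense_id[i],
                   r = unname(ct$estimate), p_value = ct$p.value,
                   significant = ct$p.value < alpha, reason = "",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "summary") <- c(n_pairs = nrow(out),
                              n_significant = sum(out$significant))
    out
}

#' Categorize the domain composition of a splice-variant group
#'
#' Compares the conserved-domain accession sets of all transcripts of one
#' gene: if any member has no domain hits the group is
#' `"no_known_domain"`; if all members share an identical accession set
#' (hit counts may differ) it is `"similar"`; otherwise `"disparate"`.
#'
#' @param transcriptIds ids of the group members (>= 2).
#' @param hits domain-hit data.frame covering the group (may be empty).
#' @return one of `"similar"`, `"disparate"`, `"no_known_domain"`.
#' @export
categorizeSvDomains <- function(transcriptIds, hits) {
    if (length(transcriptIds) < 2L)
        stop("a splice-variant group needs at least 2 transcripts")
    sets <- lapply(transcriptIds, function(id)
        sort(unique(hits$domain_accession[hits$transcript_id == id])))
    if (any(!lengths(sets))) return("no_known_domain")
    same <- all(vapply(sets[-1], identical, logical(1), y = sets[[1]]))
    if (same) "similar" else "disparate"
}

#' Export a network as a tab-separated edge list
#'
#' @param network a [CoexpressionNetwork].
#' @param path output file (columns `id_a`, `id_b`, `weight`).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
    utils::write.table(networkEdges(network), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a network as GraphML
#'
#' @param network a [CoexpressionNetwork].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphml <- function(network, path) {
    igraph::write_graph(networkGraph(network), path, format = "graphml")
    invisible(path)
}
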