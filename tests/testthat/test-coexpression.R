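test_that("center-normalization hits its closed forms and flags constants", {
    m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
    out <- centerNormalize(m)
    expect_equal(out["a", ], c(-1, 0, 1) / sqrt(2),
                 ignore_attr = TRUE)
    expect_equal(out["b", ], c(0, 0, 0), ignore_attr = TRUE)
    expect_identical(attr(out, "flagged"), "b")
    # contract: zero row means, sum of squares 0 or 1
    set.seed(3)
    r <- matrix(rexp(50), nrow = 5,
                dimnames = list(letters[1:5], NULL))
    nr <- centerNormalize(r)
    expect_equal(rowSums(nr), rep(0, 5), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(rowSums(nr^2), rep(1, 5), ignore_attr = TRUE)
})

test_that("k-means recovers well-separated groups and is deterministic", {
    set.seed(10)
    m <- rbind(matrix(rnorm(60, 0, 0.05), nrow = 10),
               matrix(rnorm(60, 5, 0.05), nrow = 10))
    rownames(m) <- sprintf("t%02d", 1:20)
    cl <- kmeansCluster(m, 2, iterations = 25, seed = 4)
    truth <- rep(1:2, each = 10)
    expect_equal(length(unique(paste(cl$cluster_id, truth))), 2L)
    expect_identical(cl, kmeansCluster(m, 2, iterations = 25, seed = 4))
    expect_error(kmeansCluster(m, 21), "exceeds")
    # degenerate k: every row its own cluster, zero within-cluster scatter
    small <- m[1:5, ] + matrix(seq_len(30), nrow = 5)
    cl5 <- kmeansCluster(small, 5, iterations = 5, seed = 1)
    expect_identical(sort(unique(cl5$cluster_id)), 1:5)
})

test_that("super-cluster assignment validates its mapping", {
    cl <- data.frame(transcript_id = c("a", "b", "c"),
                     cluster_id = c(1L, 2L, 1L),
                     supercluster_id = NA_character_)
    ident <- assignSuperclusters(cl, c("1" = "1", "2" = "2"))
    expect_identical(ident$supercluster_id, c("1", "2", "1"))
    merged <- assignSuperclusters(cl, c("1" = "early", "2" = "early"))
    expect_identical(unique(merged$supercluster_id), "early")
    expect_error(assignSuperclusters(cl, c("1" = "early")), "2")
})

test_that("network edges obey the threshold rule and match brute force", {
    set.seed(20)
    m <- matrix(rexp(300), nrow = 30,
                dimnames = list(sprintf("t%02d", 1:30), NULL))
    m[2, ] <- m[1, ] * 2            # r = 1 pair
    m[4, ] <- max(m[3, ]) - m[3, ]  # strongly anti-correlated pair
    for (rule in c("signed_positive", "absolute")) {
        net <- buildNetwork(m, threshold = 0.9, edgeRule = rule)
        got <- networkEdges(net)
        got_keys <- sort(paste(pmin(got$id_a, got$id_b),
                               pmax(got$id_a, got$id_b)))
        r <- cor(t(m))
        want_keys <- character()
        for (i in 1:29) for (j in (i + 1):30) {
            keep <- if (rule == "signed_positive") r[i, j] >= 0.9
                    else abs(r[i, j]) >= 0.9
            if (keep) want_keys <- c(want_keys,
                                     paste(rownames(m)[i], rownames(m)[j]))
        }
        expect_identical(got_keys, sort(want_keys))
        expect_true(all(abs(got$weight) >= 0.9))
        expect_false(igraph::is_directed(networkGraph(net)))
    }
    # identical profiles give weight 1; anti-correlation needs absolute mode
    sp <- networkEdges(buildNetwork(m, edgeRule = "signed_positive"))
    expect_equal(sp$weight[sp$id_a == "t01" & sp$id_b == "t02"], 1)
    expect_false(any(sp$id_a %in% c("t03", "t04") &
                     sp$id_b %in% c("t03", "t04")))
    ab <- networkEdges(buildNetwork(m, edgeRule = "absolute"))
    expect_true(any(ab$id_a == "t03" & ab$id_b == "t04"))
})

test_that("constant rows stay isolated with a warning", {
    m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 5, 5, 5))
    expect_warning(net <- buildNetwork(m), "constant")
    expect_true("c" %in% networkNodes(net))
    e <- networkEdges(net)
    expect_false("c" %in% c(e$id_a, e$id_b))
})

test_that("degree of connectivity follows the m/n definition", {
    # one node wired to 5 others inside a 10-node super-cluster
    edges <- data.frame(id_a = "hub", id_b = sprintf("n%d", 1:5))
    net <- networkFromEdges(edges, nodes = sprintf("n%d", 1:9),
                            superclusters = setNames(
                                rep("sc1", 10),
                                c("hub", sprintf("n%d", 1:9))))
    rec <- degreeOfConnectivity(net, "hub", "sc1")
    expect_identical(rec$m, 5L)
    expect_identical(rec$n, 10L)
    expect_identical(rec$degree, 0.5)
    expect_identical(degreeOfConnectivity(net, "n9", "sc1")$degree, 0)
    expect_error(degreeOfConnectivity(net, "hub", "nope"), "nope")
    # complete super-cluster: every member at (n-1)/n
    full <- expand.grid(id_a = letters[1:4], id_b = letters[1:4],
                        stringsAsFactors = FALSE)
    full <- full[full$id_a < full$id_b, ]
    cnet <- networkFromEdges(full, superclusters = setNames(
        rep("all", 4), letters[1:4]))
    for (v in letters[1:4])
        expect_equal(degreeOfConnectivity(cnet, v, "all")$degree, 3 / 4)
})

test_that("super-cluster connectivity is the median member degree", {
    edges <- data.frame(id_a = "a", id_b = "b")
    net <- networkFromEdges(edges, nodes = "c", superclusters = setNames(
        rep("s", 3), c("a", "b", "c")))
    # degrees: a=1/3, b=1/3, c=0 -> median 1/3
    expect_equal(superclusterConnectivity(net, "s"), 1 / 3)
    # sort-based oracle on a random graph
    set.seed(41)
    ids <- sprintf("v%02d", 1:12)
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.3
    net2 <- networkFromEdges(
        data.frame(id_a = pairs[keep, 1], id_b = pairs[keep, 2]),
        nodes = ids, superclusters = setNames(rep("s", 12), ids))
    degs <- sort(vapply(ids, function(v)
        degreeOfConnectivity(net2, v, "s")$degree, numeric(1)))
    expect_equal(superclusterConnectivity(net2, "s"),
                 mean(degs[6:7]))
})

test_that("hub ranking: star center, lexicographic ties, per-gene dedupe", {
    star <- networkFromEdges(
        data.frame(id_a = "center", id_b = sprintf("leaf%d", 1:4)),
        superclusters = setNames(rep("s", 5),
                                 c("center", sprintf("leaf%d", 1:4))))
    expect_identical(findHubs(star, "s", topN = 1)$transcript_id,
                     "center")
    # two tied nodes: lexicographically smaller id first
    tie <- networkFromEdges(
        data.frame(id_a = c("b", "a"), id_b = c("c", "c")),
        superclusters = setNames(rep("s", 3), c("a", "b", "c")))
    expect_identical(findHubs(tie, "s", topN = 3)$transcript_id[2:3],
                     c("a", "b"))
    # dedupe keeps the better-connected isoform of a gene
    iso <- networkFromEdges(
        data.frame(id_a = c("g1.1", "g1.1", "g1.2"),
                   id_b = c("x", "y", "x")),
        superclusters = setNames(rep("s", 4),
                                 c("g1.1", "g1.2", "x", "y")),
        geneIds = c(g1.1 = "g1", g1.2 = "g1", x = "gx", y = "gy"))
    hubs <- findHubs(iso, "s", topN = 4, dedupeByGene = TRUE)
    expect_identical(sum(hubs$gene_id == "g1"), 1L)
    expect_true("g1.1" %in% hubs$transcript_id)
    expect_false("g1.2" %in% hubs$transcript_id)
    nodedupe <- findHubs(iso, "s", topN = 4, dedupeByGene = FALSE)
    expect_true(all(c("g1.1", "g1.2") %in% nodedupe$transcript_id))
})

test_that("nearest neighbors induce the correct sub-network", {
    edges <- data.frame(id_a = c("center", "center", "center", "far1"),
                        id_b = c("a", "b", "c", "far2"))
    net <- networkFromEdges(edges, nodes = "iso")
    sub <- nearestNeighbors(net, "center")
    expect_setequal(networkNodes(sub), c("center", "a", "b", "c"))
    single <- nearestNeighbors(net, "iso")
    expect_identical(networkNodes(single), "iso")
    expect_error(nearestNeighbors(net, "ghost"), "unknown node")
    # adjacency-row oracle
    g <- networkGraph(net)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_setequal(setdiff(networkNodes(sub), "center"),
                    colnames(adj)[adj["center", ] > 0])
})

test_that("sense-antisense screen: perfect pairs, oracle r, constants", {
    set.seed(55)
    m <- matrix(rexp(10 * 12), nrow = 12,
                dimnames = list(sprintf("t%02d", 1:12), NULL))
    m["t02", ] <- m["t01", ]  # identical profiles
    pairs <- data.frame(sense_id = "t01", antisense_id = "t02")
    res <- senseAntisenseScreen(m, pairs)
    expect_equal(res$r, 1)
    expect_true(res$significant)

    # direct covariance-formula oracle over random pairs
    ids <- rownames(m)
    set.seed(56)
    rp <- data.frame(sense_id = sample(ids, 50, TRUE),
                     antisense_id = sample(ids, 50, TRUE))
    rp <- rp[rp$sense_id != rp$antisense_id, ]
    res2 <- senseAntisenseScreen(m, rp)
    for (i in seq_len(nrow(rp))) {
        x <- m[rp$sense_id[i], ]; y <- m[rp$antisense_id[i], ]
        r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
            sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
        expect_equal(res2$r[i], r_oracle, tolerance = 1e-12)
        tstat <- r_oracle * sqrt((ncol(m) - 2) / (1 - r_oracle^2))
        expect_equal(res2$p_value[i],
                     2 * pt(-abs(tstat), df = ncol(m) - 2),
                     tolerance = 1e-9)
    }

    mc <- rbind(m, const = rep(2, ncol(m)))
    resc <- senseAntisenseScreen(mc, data.frame(sense_id = "t01",
                                                antisense_id = "const"))
    expect_true(is.na(resc$r))
    expect_false(resc$significant)
    expect_match(resc$reason, "constant")
})

test_that("splice-variant domain categorization follows the set rules", {
    hits <- data.frame(
        transcript_id = c("v1", "v1", "v2", "v3", "v3", "v4"),
        domain_accession = c("PKc", "EFh", "PKc", "PKc", "PKc", "PKc"),
        domain_name = c("PKc", "EFh", "PKc", "PKc", "PKc", "PKc"),
        is_truncated = FALSE)
    expect_identical(categorizeSvDomains(c("v1", "v2"), hits), "disparate")
    expect_identical(categorizeSvDomains(c("v2", "v3"), hits), "similar")
    expect_identical(categorizeSvDomains(c("v4", "v5"), hits),
                     "no_known_domain")
    expect_error(categorizeSvDomains("v1", hits), "at least 2")
})

test_that("network exports round-trip as edge lists", {
    edges <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                        weight = c(0.95, 0.97))
    net <- networkFromEdges(edges)
    p <- withr::local_tempfile(fileext = ".tsv")
    writeEdgeList(net, p)
    back <- read.delim(p)
    expect_equal(nrow(back), 2L)
    expect_equal(sort(back$weight), c(0.95, 0.97))
    g <- withr::local_tempfile(fileext = ".graphml")
    writeGraphml(net, g)
    expect_gt(file.size(g), 0)
})
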