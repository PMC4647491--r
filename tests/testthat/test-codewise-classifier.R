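test_that("stratified split preserves class proportions and the partition", {
    labels <- rep(c("coding", "noncoding"), c(300, 100))
    sp <- stratifiedSplit(labels, trainFrac = 0.75, seed = 5)
    expect_identical(sort(c(sp$train, sp$test)), 1:400)
    expect_identical(as.integer(table(labels[sp$train])), c(225L, 75L))
    expect_identical(as.integer(table(labels[sp$test])), c(75L, 25L))
    sp2 <- stratifiedSplit(labels, trainFrac = 0.75, seed = 5)
    expect_identical(sp, sp2)
    expect_error(stratifiedSplit(labels, trainFrac = 1), "between 0 and 1")
    expect_error(stratifiedSplit(c("coding", "coding", "noncoding")),
                 "at least 2")
})

test_that("min-max scaler maps endpoints, constants and extrapolations", {
    df <- data.frame(orf_ratio = c(0, 5, 10))
    sc <- fitScaler(df, "orf_ratio")
    expect_equal(as.numeric(applyScaler(sc, df)), c(-1, 0, 1))
    expect_equal(as.numeric(applyScaler(sc, data.frame(orf_ratio = 12))),
                 1.4)
    cdf <- data.frame(orf_ratio = c(3, 3, 3))
    csc <- fitScaler(cdf, "orf_ratio")
    expect_equal(as.numeric(applyScaler(csc, cdf)), c(0, 0, 0))
})

test_that("a separable toy set trains to perfect symmetric accuracy", {
    toy <- toySeparable()
    m <- codewiseTrain(toy$features, toy$labels, "linear", seed = 1)
    rep <- codewiseEvaluate(m, toy$features, toy$labels)
    expect_equal(rep@accuracy, 1)
    flipped <- ifelse(toy$labels == "coding", "noncoding", "coding")
    m2 <- codewiseTrain(toy$features, flipped, "linear", seed = 1)
    expect_equal(codewiseEvaluate(m2, toy$features, flipped)@accuracy, 1)
    # a point deep in coding territory is confidently coding
    deep <- data.frame(orf_ratio = 0.95, mfe = 0.95 * 100 - 150)
    expect_gt(codewisePredict(m, deep)$coding_prob, 0.5)
})

test_that("predicted probabilities normalize and ignore row order", {
    toy <- toySeparable(n_per_class = 15)
    m <- codewiseTrain(toy$features, toy$labels, "rbf", seed = 2)
    pred <- codewisePredict(m, toy$features)
    expect_equal(pred$coding_prob + pred$noncoding_prob,
                 rep(1, nrow(pred)))
    perm <- sample(nrow(toy$features))
    pred_perm <- codewisePredict(m, toy$features[perm, ])
    expect_equal(pred_perm$coding_prob, pred$coding_prob[perm])
})

test_that("training refuses single-class input", {
    toy <- toySeparable()
    expect_error(codewiseTrain(toy$features,
                               rep("coding", length(toy$labels))),
                 "both")
})

test_that("evaluation report bounds, conservation and null AUC", {
    # perfect scores give accuracy and AUC of 1
    toy <- toySeparable()
    m <- codewiseTrain(toy$features, toy$labels, "linear", seed = 1)
    rep <- codewiseEvaluate(m, toy$features, toy$labels)
    expect_equal(rep@auc, 1)
    expect_equal(sum(rep@confusion), 40)
    # label-randomized scores have AUC near 0.5
    set.seed(404)
    scores <- runif(2000)
    labels <- rep(c("coding", "noncoding"), 1000)
    expect_lt(abs(rocAuc(scores, labels) - 0.5), 0.05)
    # single-class test set: AUC undefined
    expect_true(is.na(rocAuc(runif(5), rep("coding", 5))))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(19)
    scores <- c(rnorm(60, 1), rnorm(40))
    labels <- rep(c("coding", "noncoding"), c(60, 40))
    scores[5] <- scores[70]  # induce a tie across classes
    ref <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = scores, levels = c("noncoding",
        "coding"), direction = "<", quiet = TRUE)))
    expect_equal(rocAuc(scores, labels), ref, tolerance = 1e-12)
})

test_that("raising the noncoding class weight never lowers its rejection rate", {
    gen <- generateFeatureTable(generatorConfig(n_coding = 600,
                                                n_noncoding = 200,
                                                seed = 9,
                                                cpc_like_noise_sd = 3))
    sp <- stratifiedSplit(gen$labels, 0.75, seed = 3)
    tnr <- vapply(c(1, 3, 10), function(w) {
        m <- codewiseTrain(gen$features[sp$train, ],
                           gen$labels[sp$train], "linear",
                           classWeightNoncoding = w, seed = 3)
        codewiseEvaluate(m, gen$features[sp$test, ],
                         gen$labels[sp$test])@perClassRates[["tnr"]]
    }, numeric(1))
    expect_true(all(diff(tnr) >= 0))
})

test_that("the optional CPC-like feature barely moves test accuracy", {
    gen <- generateFeatureTable(generatorConfig(n_coding = 1500,
                                                n_noncoding = 500,
                                                seed = 21))
    sp <- stratifiedSplit(gen$labels, 0.75, seed = 2)
    with_cpc <- codewiseTrain(gen$features[sp$train, ],
                              gen$labels[sp$train], "linear", seed = 2)
    no_cpc <- codewiseTrain(
        gen$features[sp$train, setdiff(colnames(gen$features),
                                       "cpc_score")],
        gen$labels[sp$train], "linear", seed = 2)
    a1 <- codewiseEvaluate(with_cpc, gen$features[sp$test, ],
                           gen$labels[sp$test])@accuracy
    a2 <- codewiseEvaluate(no_cpc,
                           gen$features[sp$test,
                                        setdiff(colnames(gen$features),
                                                "cpc_score")],
                           gen$labels[sp$test])@accuracy
    expect_lt(abs(a1 - a2), 0.01)
})

test_that("models refuse prediction on mismatched feature schemas", {
    toy <- toySeparable()
    m <- codewiseTrain(toy$features, toy$labels, "linear", seed = 1)
    expect_error(codewisePredict(m, toy$features[, "orf_ratio",
                                                 drop = FALSE]),
                 "schema mismatch")
})

test_that("serialized models reproduce their decisions bit-identically", {
    toy <- toySeparable()
    m <- codewiseTrain(toy$features, toy$labels, "rbf", seed = 4)
    p <- withr::local_tempfile(fileext = ".rds")
    saveCodewiseModel(m, p)
    back <- readCodewiseModel(p)
    expect_identical(codewisePredict(back, toy$features),
                     codewisePredict(m, toy$features))
    expect_identical(featureSchema(back), featureSchema(m))
})

test_that("feature assessment: PCA variance fractions and separable LDA", {
    # two perfectly correlated features collapse onto PC1
    df <- data.frame(orf_ratio = seq(0, 1, length.out = 40))
    df$mfe <- df$orf_ratio * -300
    labels <- rep(c("coding", "noncoding"), each = 20)
    out <- suppressWarnings(assessFeatures(df, labels, seed = 6))
    expect_equal(out$pca$variance_fraction[1], 1, tolerance = 1e-8)
    expect_equal(sum(out$pca$variance_fraction), 1)
    toy <- toySeparable(n_per_class = 30)
    res <- assessFeatures(toy$features, toy$labels, seed = 8)
    expect_equal(res$lda$accuracy, 1)
    expect_equal(res$lda$auc, 1)
})
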