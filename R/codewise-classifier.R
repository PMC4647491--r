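#' @include feature-extraction.R
NULL

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    force(expr)
}

normalizeLabels <- function(labels) {
    if (is.numeric(labels))
        labels <- ifelse(labels > 0, "coding", "noncoding")
    labels <- as.character(labels)
    if (!all(labels %in% c("coding", "noncoding")))
        stop("labels must be coding/noncoding (or +1/-1)")
    factor(labels, levels = c("coding", "noncoding"))
}

schemaColumns <- function(features) {
    cols <- intersect(CODEWISE_FEATURES, colnames(features))
    keep <- vapply(cols, function(cl) !all(is.na(features[[cl]])),
                   logical(1))
    cols[keep]
}

#' Stratified train/test split
#'
#' Randomly partitions rows into training and test sets, preserving each
#' class's proportion within rounding (a 3:1 coding:noncoding set stays
#' 3:1 in both parts). Deterministic for a given seed.
#'
#' @param labels class labels (`"coding"`/`"noncoding"` or `+1`/`-1`).
#' @param trainFrac fraction of each class assigned to training; must
#'   leave both parts non-empty.
#' @param seed integer seed.
#' @return list with integer row indices `train` and `test` (a partition
#'   of `seq_along(labels)`).
#' @export
stratifiedSplit <- function(labels, trainFrac = 0.75, seed = 1L) {
    y <- normalizeLabels(labels)
    if (any(table(y) < 2L))
        stop("each class needs at least 2 members to split")
    if (trainFrac <= 0 || trainFrac >= 1)
        stop("trainFrac must be strictly between 0 and 1")
    train <- withSeed(seed, {
        unlist(lapply(levels(y), function(cl) {
            idx <- which(y == cl)
            sample(idx, round(trainFrac * length(idx)))
        }), use.names = FALSE)
    })
    train <- sort(train)
    test <- setdiff(seq_along(y), train)
    if (!length(train) || !length(test))
        stop("split leaves an empty partition; adjust trainFrac")
    list(train = train, test = test)
}

#' Fit a min-max feature scaler on training data
#'
#' Records each feature's training minimum and maximum; [applyScaler()]
#' maps min to -1 and max to +1 linearly. Test data scaled with training
#' bounds may fall outside `[-1, +1]`. A constant feature maps to 0.
#'
#' @param features data.frame containing the feature columns.
#' @param columns feature columns to scale (defaults to the recognized
#'   schema columns present and non-all-`NA`).
#' @return scaler data.frame with columns `feature`, `min`, `max`.
#' @export
fitScaler <- function(features, columns = schemaColumns(features)) {
    stopifnot(nrow(features) >= 1L, length(columns) >= 1L)
    data.frame(feature = columns,
               min = vapply(columns, function(cl)
                   min(features[[cl]], na.rm = TRUE), numeric(1)),
               max = vapply(columns, function(cl)
                   max(features[[cl]], na.rm = TRUE), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply a fitted min-max scaler
#'
#' @param scaler scaler from [fitScaler()].
#' @param features data.frame containing the scaler's feature columns.
#' @return numeric matrix of scaled features (rows as in `features`,
#'   columns in scaler order).
#' @export
applyScaler <- function(scaler, features) {
    miss <- setdiff(scaler$feature, colnames(features))
    if (length(miss))
        stop("features missing columns: ", paste(miss, collapse = ", "))
    out <- vapply(seq_len(nrow(scaler)), function(i) {
        x <- as.numeric(features[[scaler$feature[i]]])
        rng <- scaler$max[i] - scaler$min[i]
        if (rng == 0) rep(0, length(x))
        else (x - scaler$min[i]) / rng * 2 - 1
    }, numeric(nrow(features)))
    out <- matrix(out, nrow = nrow(features),
                  dimnames = list(NULL, scaler$feature))
    out
}

#' Train the weighted-SVM coding-potential classifier
#'
#' Fits the min-max scaler on the training features, then a support vector
#' machine (libsvm via \pkg{e1071}) with a class weight on the noncoding
#' minority class (default 3, mirroring the 3:1 coding:noncoding imbalance)
#' and sigmoid probability calibration on the decision values. Features
#' used are the recognized schema columns present in `features`; optional
#' columns that are entirely `NA` are dropped and the remaining schema is
#' recorded on the model.
#'
#' @param features unscaled feature data.frame (see [CODEWISE_FEATURES]).
#' @param labels class labels aligned with rows.
#' @param kernel `"linear"`, `"rbf"` or `"polynomial"`.
#' @param classWeightNoncoding weight of the noncoding class (coding
#'   weight is 1).
#' @param cost SVM regularization constant.
#' @param seed integer seed (probability calibration shuffles internally).
#' @return a [CodewiseModel].
#' @export
codewiseTrain <- function(features, labels,
                          kernel = c("linear", "rbf", "polynomial"),
                          classWeightNoncoding = 3, cost = 1, seed = 1L) {
    kernel <- match.arg(kernel)
    y <- normalizeLabels(labels)
    if (nlevels(droplevels(y)) < 2L)
        stop("training needs both coding and noncoding examples")
    cols <- schemaColumns(features)
    if (!length(cols)) stop("no recognized feature columns in input")
    x <- features[, cols, drop = FALSE]
    if (anyNA(x))
        stop("NA values in feature columns: ",
             paste(cols[vapply(x, anyNA, logical(1))], collapse = ", "))
    scaler <- fitScaler(features, cols)
    xs <- applyScaler(scaler, features)
    fit <- withSeed(seed, e1071::svm(
        x = xs, y = y,
        kernel = switch(kernel, rbf = "radial", kernel),
        cost = cost,
        class.weights = c(coding = 1, noncoding = classWeightNoncoding),
        probability = TRUE, scale = FALSE))
    methods::new("CodewiseModel", kernel = kernel,
                 classWeightNoncoding = classWeightNoncoding,
                 scaler = scaler, fit = fit, featureSchema = cols,
                 trainingSeed = as.integer(seed))
}

#' Predict coding potential with a fitted model
#'
#' @param model a [CodewiseModel].
#' @param features unscaled feature data.frame; must contain every feature
#'   in the model's schema (a model trained with an optional feature
#'   refuses tables lacking it) with no `NA` values.
#' @return data.frame with `transcript_id` (when present in `features`),
#'   `coding_prob`, `noncoding_prob` (summing to 1) and `label`.
#' @export
codewisePredict <- function(model, features) {
    stopifnot(methods::is(model, "CodewiseModel"))
    miss <- setdiff(model@featureSchema, colnames(features))
    if (length(miss))
        stop("feature schema mismatch; model requires missing column(s): ",
             paste(miss, collapse = ", "))
    x <- features[, model@featureSchema, drop = FALSE]
    if (anyNA(x)) stop("NA values in feature columns required by the model")
    xs <- applyScaler(model@scaler, features)
    pred <- stats::predict(model@fit, xs, probability = TRUE)
    prob <- attr(pred, "probabilities")
    coding_prob <- prob[, "coding"]
    out <- data.frame(
        coding_prob = as.numeric(coding_prob),
        noncoding_prob = as.numeric(prob[, "noncoding"]),
        label = ifelse(coding_prob >= 0.5, "coding", "noncoding"),
        stringsAsFactors = FALSE)
    if ("transcript_id" %in% colnames(features))
        out <- cbind(transcript_id = features$transcript_id, out,
                     stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Equivalent to the rank-sum (Mann-Whitney) statistic with tied scores
#' handled by averaging ranks.
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param labels class labels; `positive` names the positive class.
#' @param positive positive-class label.
#' @return AUC in `[0, 1]`, or `NA_real_` if a class is absent.
#' @export
rocAuc <- function(scores, labels, positive = "coding") {
    pos <- labels == positive
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on a labelled test set
#'
#' The coding class is the positive class: TP is a coding transcript
#' predicted coding, TN a noncoding transcript predicted noncoding. AUC is
#' the trapezoidal area under the ROC of the coding-class probabilities
#' and is `NA` for a single-class test set.
#'
#' @param model a [CodewiseModel].
#' @param features unscaled test features.
#' @param labels true labels aligned with rows.
#' @return an [EvaluationReport].
#' @export
codewiseEvaluate <- function(model, features, labels) {
    y <- normalizeLabels(labels)
    pred <- codewisePredict(model, features)
    tp <- sum(y == "coding" & pred$label == "coding")
    tn <- sum(y == "noncoding" & pred$label == "noncoding")
    fp <- sum(y == "noncoding" & pred$label == "coding")
    fn <- sum(y == "coding" & pred$label == "noncoding")
    conf <- c(TP = tp, TN = tn, FP = fp, FN = fn)
    methods::new("EvaluationReport",
                 accuracy = (tp + tn) / length(y),
                 auc = rocAuc(pred$coding_prob, as.character(y)),
                 confusion = conf,
                 perClassRates = c(
                     tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                     tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_))
}

#' Assess feature contributions with PCA and LDA
#'
#' Principal component analysis on the min-max-scaled features (variance
#' fractions sum to 1 over the returned components), and linear
#' discriminant analysis trained on a stratified split and evaluated on
#' the held-out part (accuracy and AUC of the coding posterior).
#'
#' @param features unscaled feature data.frame.
#' @param labels class labels aligned with rows.
#' @param trainFrac,seed split parameters for the LDA evaluation.
#' @return list with `pca` (`variance_fraction`, `loadings`) and `lda`
#'   (`accuracy`, `auc`).
#' @export
assessFeatures <- function(features, labels, trainFrac = 0.75, seed = 1L) {
    y <- normalizeLabels(labels)
    cols <- schemaColumns(features)
    if (length(cols) < 2L) stop("need at least 2 features")
    xs <- applyScaler(fitScaler(features, cols), features)
    if (nrow(xs) < ncol(xs))
        warning("fewer samples than features; PCA truncated to sample rank")
    keep <- apply(xs, 2, function(cl) stats::var(cl) > 0)
    pca <- stats::prcomp(xs[, keep, drop = FALSE], center = TRUE,
                         scale. = FALSE)
    varfrac <- pca$sdev^2 / sum(pca$sdev^2)
    split <- stratifiedSplit(y, trainFrac, seed)
    ld <- MASS::lda(xs[split$train, keep, drop = FALSE],
                    grouping = y[split$train])
    post <- stats::predict(ld, xs[split$test, keep, drop = FALSE])
    acc <- mean(post$class == y[split$test])
    auc <- rocAuc(post$posterior[, "coding"],
                  as.character(y[split$test]))
    list(pca = list(variance_fraction = varfrac,
                    loadings = pca$rotation),
         lda = list(accuracy = acc, auc = auc))
}

#' Save / load a fitted model
#'
#' The serialized model reproduces its decision outputs bit-identically.
#'
#' @param model a [CodewiseModel].
#' @param path file path for the model archive.
#' @return `path` (save) or the restored [CodewiseModel] (load).
#' @export
saveCodewiseModel <- function(model, path) {
    stopifnot(methods::is(model, "CodewiseModel"))
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveCodewiseModel
#' @export
readCodewiseModel <- function(path) {
    model <- readRDS(path)
    stopifnot(methods::is(model, "CodewiseModel"))
    methods::validObject(model)
    model
}
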