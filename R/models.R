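## The two binary classifiers (is the sample contaminated?; is the
## predicted contaminant correctly classified?) with the full training
## protocol: two-layer grouped/stratified split, gaussian/square/log10
## augmentation, correlation-aware feature selection, standard scaling
## fitted on the training partition only, and cross-validated grid search
## over a gradient-boosted tree ensemble with L1/L2/gamma regularization.

idColumns <- function() c("sample_id", "backend", "taxon_id", "species")
labelColumns <- function() c("sample_status", "correctness")

#' Numeric feature columns of a feature table
#'
#' All numeric columns that are neither identifiers nor labels.
#'
#' @param table a feature table.
#' @return character vector of column names.
#' @export
numericFeatureColumns <- function(table) {
    cand <- setdiff(names(table), c(idColumns(), labelColumns()))
    cand[vapply(table[cand], is.numeric, logical(1))]
}

#' Two-layer grouped, stratified train/test/evaluation split
#'
#' Layer 1 splits sample ids into (train+test) versus evaluation at
#' \code{ratio}; layer 2 splits (train+test) into train versus test at
#' the same ratio. Splits are grouped by \code{sample_id} (all rows of
#' a sample travel together) and stratified by \code{sample_status};
#' per-stratum counts use floor rounding. The evaluation partition is
#' untouched until final scoring.
#'
#' @param table feature table with \code{sample_id} and
#'   \code{sample_status} columns.
#' @param ratio proportion retained at each layer (0 < ratio < 1).
#' @param seed integer seed.
#' @return list of data.frames: \code{train}, \code{test},
#'   \code{evaluation}.
#' @export
splitTwoLayer <- function(table, ratio = 0.75, seed = 1L) {
    if (ratio <= 0 || ratio >= 1) stop("invalid-argument: ratio in (0,1)")
    samp <- unique(table[, c("sample_id", "sample_status")])
    if (nrow(samp) < 4L) stop("invalid-argument: need >= 4 distinct samples")
    set.seed(deriveSeed(seed, "split"))
    splitStrata <- function(ids, status, r) {
        keep <- character(0)
        for (s in sort(unique(status))) {
            sid <- ids[status == s]
            if (length(sid) < 2L)
                stop("stratification error: stratum sample_status=", s,
                     " has fewer than 2 samples")
            sid <- sample(sid)
            keep <- c(keep, sid[seq_len(floor(length(sid) * r))])
        }
        keep
    }
    tt <- splitStrata(samp$sample_id, samp$sample_status, ratio)
    evalIds <- setdiff(samp$sample_id, tt)
    sampTT <- samp[samp$sample_id %in% tt, , drop = FALSE]
    trainIds <- splitStrata(sampTT$sample_id, sampTT$sample_status, ratio)
    testIds <- setdiff(tt, trainIds)
    list(train = table[table$sample_id %in% trainIds, , drop = FALSE],
         test = table[table$sample_id %in% testIds, , drop = FALSE],
         evaluation = table[table$sample_id %in% evalIds, , drop = FALSE])
}

## add squared and log10 columns according to a derived-column recipe
deriveFeatureColumns <- function(rows, derived) {
    for (col in derived$sq)
        rows[[paste0(col, "_sq")]] <- rows[[col]]^2
    for (col in derived$log10)
        rows[[paste0(col, "_log10")]] <-
            log10(pmax(rows[[col]], .Machine$double.xmin))
    rows
}

#' Augment a training partition
#'
#' Three augmentations: (a) gaussian-noise-jittered copies of every
#' training row (per-feature sd times \code{noiseSd}), (b) squared
#' copies of each numeric feature as new columns, (c) log10 copies for
#' strictly positive features only (columns with non-positive values
#' are skipped). Labels and identifiers are copied unchanged.
#' Augmentation is applied to the training partition only; the derived
#' column recipe is returned so that prediction-time inputs get the
#' same columns.
#'
#' @param rows training rows.
#' @param noiseSd noise level as a fraction of each feature's sd.
#' @param copies number of jittered copies to append.
#' @param seed integer seed.
#' @param featureCols numeric feature columns (default: all).
#' @return list: \code{table} (augmented rows incl. derived columns),
#'   \code{derived} (recipe with elements \code{sq}, \code{log10}).
#' @export
augmentFeatures <- function(rows, noiseSd = 0.1, copies = 1L, seed = 1L,
                            featureCols = NULL) {
    if (noiseSd < 0) stop("invalid-argument: noiseSd must be >= 0")
    if (is.null(featureCols)) featureCols <- numericFeatureColumns(rows)
    set.seed(seed)
    out <- rows
    if (copies > 0L && nrow(rows) > 0L) {
        sds <- vapply(rows[featureCols], function(x)
            if (length(x) > 1L) sd(x) else 0, numeric(1))
        sds[is.na(sds)] <- 0
        for (cp in seq_len(copies)) {
            jit <- rows
            for (col in featureCols)
                jit[[col]] <- jit[[col]] +
                    rnorm(nrow(jit), 0, sds[[col]] * noiseSd)
            out <- rbind(out, jit)
        }
    }
    positive <- featureCols[vapply(rows[featureCols],
                                   function(x) all(x > 0), logical(1))]
    derived <- list(sq = featureCols, log10 = positive)
    list(table = deriveFeatureColumns(out, derived), derived = derived)
}

## mutual information between a (discretized) numeric feature and a
## binary label; quartile bins, natural-log units
labelMutualInfo <- function(x, y) {
    br <- unique(quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
    if (length(br) < 2L) return(0)
    bins <- cut(x, br, include.lowest = TRUE)
    tab <- table(bins, y)
    p <- tab / sum(tab)
    px <- rowSums(p)
    py <- colSums(p)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
        if (p[i, j] > 0)
            mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
    mi
}

#' Select a decorrelated, informative feature subset
#'
#' Two-stage rule: (1) for every feature pair with |Pearson r| > 0.9,
#' drop the member with the lower label mutual information; (2) rank
#' the survivors by single-tree importance and keep the top \code{m}.
#' Constant columns are dropped up front. Deterministic given input
#' column order and seed.
#'
#' @param rows training rows (labels present).
#' @param label label column name.
#' @param featureCols candidate columns (default: all numeric features).
#' @param m maximum number of features kept (default 15).
#' @param seed integer seed.
#' @return ordered character vector of selected columns.
#' @export
selectFeatures <- function(rows, label, featureCols = NULL, m = 15L,
                           seed = 1L) {
    if (is.null(featureCols)) featureCols <- numericFeatureColumns(rows)
    if (length(featureCols) < 2L)
        stop("invalid-argument: need >= 2 candidate features")
    y <- rows[[label]]
    keep <- featureCols[vapply(rows[featureCols],
                               function(x) length(unique(x)) > 1L,
                               logical(1))]
    if (length(keep) == 0L) stop("selection-failure: no informative features")
    mi <- vapply(keep, function(col) labelMutualInfo(rows[[col]], y),
                 numeric(1))
    cm <- suppressWarnings(cor(as.matrix(rows[keep])))
    cm[is.na(cm)] <- 0
    alive <- setNames(rep(TRUE, length(keep)), keep)
    for (i in seq_along(keep)) {
        if (!alive[i]) next
        for (j in seq_along(keep)) {
            if (j <= i || !alive[j] || !alive[i]) next
            if (abs(cm[i, j]) > 0.9) {
                # drop the less label-informative member; ties drop the
                # later column
                if (mi[j] > mi[i]) alive[i] <- FALSE else alive[j] <- FALSE
            }
        }
    }
    surv <- keep[alive[keep]]
    if (length(surv) == 0L) stop("selection-failure: no surviving features")
    set.seed(seed)
    df <- rows[, surv, drop = FALSE]
    df$.label <- factor(y)
    fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(cp = 0.001,
                                                       minsplit = 4L))
    imp <- setNames(rep(0, length(surv)), surv)
    vi <- fit$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- vi
    ord <- order(-imp, -mi[surv], seq_along(surv))
    head(surv[ord], m)
}

#' Fit / apply a standard scaler
#'
#' \code{fitScaler} computes per-feature (mean, sd) on the training
#' partition only; \code{applyScaler} standardizes new rows with the
#' stored parameters verbatim. A feature constant in training (sd 0)
#' scales to 0.
#'
#' @param rows training rows.
#' @param features feature columns to scale.
#' @return \code{fitScaler}: list with named numeric vectors
#'   \code{center} and \code{scale}.
#' @export
fitScaler <- function(rows, features) {
    center <- vapply(rows[features], mean, numeric(1))
    scale <- vapply(rows[features], function(x)
        if (length(x) > 1L) sd(x) else 0, numeric(1))
    scale[is.na(scale)] <- 0
    list(center = center, scale = scale)
}

#' @rdname fitScaler
#' @param scaler a scaler from \code{fitScaler} (or a
#'   \linkS4class{ModelBundle}).
#' @param newRows rows to standardize.
#' @return \code{applyScaler}: numeric matrix of z-scores, columns in
#'   feature order.
#' @export
applyScaler <- function(scaler, newRows) {
    if (is(scaler, "ModelBundle"))
        scaler <- list(center = scaler@scalerCenter,
                       scale = scaler@scalerScale)
    features <- names(scaler$center)
    miss <- setdiff(features, names(newRows))
    if (length(miss))
        stop("schema-mismatch: missing feature(s) ",
             paste(miss, collapse = ", "))
    x <- as.matrix(newRows[, features, drop = FALSE])
    z <- sweep(x, 2L, scaler$center, "-")
    nz <- scaler$scale > 0
    z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, scaler$scale[nz], "/")
    z[, !nz] <- 0
    z
}

#' Default hyperparameter grid
#'
#' Covers learning rate, tree depth, ensemble size and the three
#' regularizers (L1 \code{alpha}, L2 \code{lambda}, \code{gamma}).
#'
#' @return data.frame, one row per grid point.
#' @export
xgbGridDefault <- function() {
    expand.grid(eta = c(0.05, 0.1, 0.3), max_depth = c(3L, 5L, 7L),
                nrounds = c(100L, 300L), alpha = c(0, 1),
                lambda = c(1, 10), gamma = c(0, 1))
}

#' A compact grid for quick runs
#' @return data.frame, one row per grid point.
#' @export
xgbGridSmall <- function() {
    expand.grid(eta = c(0.1, 0.3), max_depth = c(3L, 5L),
                nrounds = 60L, alpha = c(0, 1), lambda = 1, gamma = 0)
}

xgbFit <- function(X, y, point, seed) {
    set.seed(seed)
    # exact greedy splits: thresholds at value midpoints, deterministic,
    # and cheap at feature-table scale
    params <- list(objective = "binary:logistic",
                   eta = point$eta, max_depth = point$max_depth,
                   alpha = point$alpha, lambda = point$lambda,
                   gamma = point$gamma, nthread = 1L,
                   tree_method = "exact", eval_metric = "logloss")
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = point$nrounds, verbose = 0)
}

#' Train one binary classifier
#'
#' Full protocol on the training partition: augmentation (gaussian
#' noise, squares, log10), feature selection, standard scaling, then a
#' grid search over gradient-boosted tree hyperparameters scored by
#' mean k-fold cross-validated accuracy (folds grouped by sample_id).
#' The final model is refit on the whole augmented training partition
#' at the chosen grid point. The test partition, when given, is scored
#' and recorded in the metadata; the evaluation partition must remain
#' untouched until final scoring.
#'
#' @param train,test feature-table partitions from
#'   \code{\link{splitTwoLayer}}.
#' @param label \code{"sample_status"} or \code{"correctness"}.
#' @param grid hyperparameter grid (data.frame; default
#'   \code{\link{xgbGridDefault}}).
#' @param config a \linkS4class{PipelineConfig} (supplies
#'   \code{cvFolds}).
#' @param seed integer seed; all stage seeds derive from it.
#' @param noiseSd,augmentCopies augmentation controls.
#' @param nFeatures maximum selected features.
#' @return a \linkS4class{ModelBundle}.
#' @export
trainClassifier <- function(train, test = NULL,
                            label = c("sample_status", "correctness"),
                            grid = xgbGridDefault(),
                            config = pipelineConfig(), seed = 1L,
                            noiseSd = 0.1, augmentCopies = 1L,
                            nFeatures = 15L) {
    label <- match.arg(label)
    y0 <- train[[label]]
    if (length(unique(y0)) < 2L)
        stop("degenerate-label: training labels contain a single class")
    aug <- augmentFeatures(train, noiseSd = noiseSd, copies = augmentCopies,
                           seed = deriveSeed(seed, "augment"))
    sel <- selectFeatures(aug$table, label, m = nFeatures,
                          seed = deriveSeed(seed, "select"))
    scaler <- fitScaler(aug$table, sel)
    X <- applyScaler(scaler, aug$table)
    y <- aug$table[[label]]

    # cv folds grouped by sample: jittered copies follow their sample
    sids <- sort(unique(aug$table$sample_id))
    set.seed(deriveSeed(seed, "cv"))
    foldOfSample <- setNames(sample(rep_len(seq_len(config@cvFolds),
                                            length(sids))), sids)
    fold <- foldOfSample[aug$table$sample_id]

    cvAcc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
        point <- grid[g, , drop = FALSE]
        accs <- numeric(0)
        for (f in sort(unique(fold))) {
            inTrain <- fold != f
            if (length(unique(y[inTrain])) < 2L || !any(!inTrain)) next
            fit <- xgbFit(X[inTrain, , drop = FALSE], y[inTrain], point,
                          seed = deriveSeed(seed, paste0("fold", f)))
            p <- predict(fit, xgboost::xgb.DMatrix(
                X[!inTrain, , drop = FALSE]))
            accs <- c(accs, mean(as.integer(p >= 0.5) == y[!inTrain]))
        }
        cvAcc[g] <- if (length(accs)) mean(accs) else 0
    }
    best <- which.max(cvAcc)
    finalFit <- xgbFit(X, y, grid[best, , drop = FALSE],
                       seed = deriveSeed(seed, "final"))
    bundle <- new("ModelBundle", model = finalFit,
                  scalerCenter = scaler$center, scalerScale = scaler$scale,
                  features = sel, derived = aug$derived, label = label,
                  metadata = list(seed = seed,
                                  grid_point = as.list(grid[best, ,
                                                            drop = FALSE]),
                                  cv_accuracy = cvAcc[best],
                                  cv_folds = config@cvFolds,
                                  fold_of_sample = as.list(foldOfSample)))
    if (!is.null(test) && nrow(test) > 0L)
        bundle@metadata$test_accuracy <- evaluateModel(bundle, test)$accuracy
    bundle
}

#' Predict rows with a trained bundle
#'
#' Derived columns are added from the bundle's recipe, scaling uses
#' the stored parameters, and the label is 1 when the probability is
#' at or above 0.5 (a tie at exactly 0.5 is called positive --
#' fail-safe toward flagging contamination).
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param rows feature rows containing all base feature columns.
#' @return data.frame: \code{probability}, \code{label}.
#' @export
predictRows <- function(bundle, rows) {
    rows <- deriveFeatureColumns(rows, bundle@derived)
    Z <- applyScaler(bundle, rows)
    if (nrow(Z) == 0L)
        return(data.frame(probability = numeric(0), label = integer(0)))
    p <- predict(bundle@model, xgboost::xgb.DMatrix(Z))
    data.frame(probability = p, label = as.integer(p >= 0.5))
}

#' Tabulate a confusion matrix and classification report
#'
#' @param truth,predictions binary vectors (0/1).
#' @return list: \code{confusion} (2x2, rows = truth 0/1, cols =
#'   predicted 0/1), per-class \code{precision}, \code{recall},
#'   \code{f1} (0/0 defined as 0), and \code{accuracy} (= trace / n).
#' @examples
#' evalReport(c(1, 1, 0, 0), c(1, 0, 0, 0))$accuracy
#' @export
evalReport <- function(truth, predictions) {
    if (length(truth) == 0L) stop("empty-evaluation: no rows")
    lv <- c(0L, 1L)
    cm <- table(factor(truth, levels = lv),
                factor(predictions, levels = lv))
    cm <- matrix(as.integer(cm), 2L, 2L,
                 dimnames = list(truth = lv, predicted = lv))
    safeDiv <- function(a, b) if (b == 0) 0 else a / b
    prec <- c(`0` = safeDiv(cm[1, 1], sum(cm[, 1])),
              `1` = safeDiv(cm[2, 2], sum(cm[, 2])))
    rec <- c(`0` = safeDiv(cm[1, 1], sum(cm[1, ])),
             `1` = safeDiv(cm[2, 2], sum(cm[2, ])))
    f1 <- mapply(function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r),
                 prec, rec)
    list(confusion = cm, precision = prec, recall = rec, f1 = f1,
         accuracy = sum(diag(cm)) / sum(cm))
}

#' Evaluate a bundle on labelled rows
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param rows labelled feature rows (must carry the bundle's label
#'   column).
#' @return an evaluation report, see \code{\link{evalReport}}.
#' @export
evaluateModel <- function(bundle, rows) {
    if (nrow(rows) == 0L) stop("empty-evaluation: no rows")
    if (!bundle@label %in% names(rows))
        stop("schema-mismatch: rows lack label column ", bundle@label)
    preds <- predictRows(bundle, rows)
    evalReport(rows[[bundle@label]], preds$label)
}

#' Persist / reload a model bundle
#'
#' The bundle is written as a directory of portable text files: the
#' model in JSON serialization, the scaler as TSV, the selected
#' feature list, and a JSON metadata file (label, derived-column
#' recipe, seed, grid point, cv accuracy, fold assignment).
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param dir target directory (created if needed).
#' @return \code{saveModelBundle}: the directory, invisibly;
#'   \code{loadModelBundle}: the reloaded \linkS4class{ModelBundle}.
#' @export
saveModelBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    xgboost::xgb.save(bundle@model, file.path(dir, "model.json"))
    # full-precision decimal serialization so reload is bit-for-bit
    write.table(data.frame(feature = names(bundle@scalerCenter),
                           center = sprintf("%.17g", bundle@scalerCenter),
                           scale = sprintf("%.17g", bundle@scalerScale)),
                file.path(dir, "scaler.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(bundle@features, file.path(dir, "features.txt"))
    jsonlite::write_json(list(label = bundle@label,
                              derived = bundle@derived,
                              metadata = bundle@metadata),
                         file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
    model <- xgboost::xgb.load(file.path(dir, "model.json"))
    sc <- read.table(file.path(dir, "scaler.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
    feats <- readLines(file.path(dir, "features.txt"))
    meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                                simplifyVector = TRUE)
    derived <- list(sq = as.character(meta$derived$sq),
                    log10 = as.character(meta$derived$log10))
    new("ModelBundle", model = model,
        scalerCenter = setNames(sc$center, sc$feature),
        scalerScale = setNames(sc$scale, sc$feature),
        features = feats, derived = derived, label = meta$label,
        metadata = as.list(meta$metadata))
}
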