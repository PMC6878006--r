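## Marker-trained classification: class-weighted RBF SVM with grid search
## by repeated stratified partitioning, and Platt-scaled confidence scores.

#' Inverse-frequency class weights
#'
#' Weights inversely proportional to the class frequencies in the training
#' set, normalized so the mean weight is 1, to counter class imbalance
#' (the soluble class is several times larger than the ribosomal classes).
#'
#' @param labels Character or factor vector of training class labels.
#' @return Named numeric weights, mean 1.
#' @export
#' @examples
#' computeClassWeights(c("A", "B", "B", "C", "C"))
computeClassWeights <- function(labels) {
    n <- table(as.character(labels))
    if (any(n == 0L) || length(n) == 0L)
        stop("every class must have at least one training member")
    w <- 1 / as.numeric(n)
    w <- w / mean(w)
    stats::setNames(w, names(n))
}

## One weighted RBF SVM fit; scale = FALSE (profiles share a common
## compositional scale; scaling would blow up near-empty channels).
.fitSvm <- function(x, y, cost, gamma, weights) {
    y <- droplevels(factor(y))
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               class.weights = weights[levels(y)], scale = FALSE,
               probability = FALSE)
}

## Platt sigmoid fit P(y = 1 | f) = 1 / (1 + exp(A f + B)) by Newton descent
## on the regularized cross-entropy, with the smoothed targets
## (N+ + 1)/(N+ + 2) and 1/(N- + 2) that keep the fit well-posed even for
## perfectly separated decision values.
.plattFit <- function(f, pos, maxIter = 100L, minStep = 1e-10,
                      sigma = 1e-12, tol = 1e-5) {
    prior1 <- sum(pos)
    prior0 <- sum(!pos)
    hi <- (prior1 + 1) / (prior1 + 2)
    lo <- 1 / (prior0 + 2)
    t <- ifelse(pos, hi, lo)
    A <- 0
    B <- log((prior0 + 1) / (prior1 + 1))
    obj <- function(A, B) {
        fApB <- f * A + B
        sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
                   (t - 1) * fApB + log1p(exp(fApB))))
    }
    fval <- obj(A, B)
    for (it in seq_len(maxIter)) {
        fApB <- f * A + B
        p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                    1 / (1 + exp(fApB)))
        q <- 1 - p
        d1 <- t - p
        d2 <- p * q
        g1 <- sum(f * d1)
        g2 <- sum(d1)
        if (abs(g1) < tol && abs(g2) < tol) break
        h11 <- sum(f * f * d2) + sigma
        h22 <- sum(d2) + sigma
        h21 <- sum(f * d2)
        det <- h11 * h22 - h21 * h21
        dA <- -(h22 * g1 - h21 * g2) / det
        dB <- -(-h21 * g1 + h11 * g2) / det
        gd <- g1 * dA + g2 * dB
        step <- 1
        while (step >= minStep) {
            newA <- A + step * dA
            newB <- B + step * dB
            newf <- obj(newA, newB)
            if (newf < fval + 1e-4 * step * gd) {
                A <- newA; B <- newB; fval <- newf
                break
            }
            step <- step / 2
        }
        if (step < minStep) break
    }
    c(A = A, B = B)
}

.plattPredict <- function(f, ab) {
    fApB <- f * ab[["A"]] + ab[["B"]]
    ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

## One-vs-one decision values for profile matrix `x`, columns named
## "classA/classB" (positive value favors classA).
.decisionValues <- function(svmFit, x) {
    pr <- predict(svmFit, x, decision.values = TRUE)
    attr(pr, "decision.values")
}

## Fit one Platt sigmoid per class pair on the training decision values.
.fitPlattPairs <- function(svmFit, x, y) {
    dv <- .decisionValues(svmFit, x)
    y <- as.character(y)
    lapply(stats::setNames(colnames(dv), colnames(dv)), function(pair) {
        cls <- strsplit(pair, "/", fixed = TRUE)[[1]]
        sel <- y %in% cls
        .plattFit(dv[sel, pair], y[sel] == cls[1])
    })
}

## Couple pairwise probabilities r[i, j] = P(class i | i vs j) into a
## k-class probability vector (Wu, Lin & Weng 2004, second approach; the
## fixed-point iteration used by libsvm).
.coupleProbs <- function(r) {
    k <- nrow(r)
    if (k == 2L) {
        p <- c(r[1, 2], r[2, 1])
        return(p / sum(p))
    }
    Q <- matrix(0, k, k)
    for (i in seq_len(k)) {
        Q[i, i] <- sum(r[-i, i]^2)
        for (j in seq_len(k)) if (j != i)
            Q[i, j] <- -r[j, i] * r[i, j]
    }
    p <- rep(1 / k, k)
    eps <- 0.005 / k
    for (it in 1:100) {
        Qp <- drop(Q %*% p)
        pQp <- sum(p * Qp)
        if (max(abs(Qp - pQp)) < eps) break
        for (i in seq_len(k)) {
            diff <- (-Qp[i] + pQp) / Q[i, i]
            p[i] <- p[i] + diff
            pQp <- (pQp + diff * (diff * Q[i, i] + 2 * Qp[i])) / (1 + diff)^2
            Qp <- (Qp + diff * Q[, i]) / (1 + diff)
            p <- p / (1 + diff)
        }
    }
    p / sum(p)
}

## Class-membership probability matrix for new profiles.
.probMatrix <- function(svmFit, platt, classes, x) {
    dv <- .decisionValues(svmFit, x)
    k <- length(classes)
    probs <- matrix(NA_real_, nrow(x), k,
                    dimnames = list(rownames(x), classes))
    rPair <- vapply(colnames(dv),
                    function(pair) .plattPredict(dv[, pair], platt[[pair]]),
                    numeric(nrow(x)))
    rPair <- matrix(rPair, nrow = nrow(x),
                    dimnames = list(rownames(x), colnames(dv)))
    pairCls <- strsplit(colnames(dv), "/", fixed = TRUE)
    for (n in seq_len(nrow(x))) {
        r <- matrix(0.5, k, k, dimnames = list(classes, classes))
        for (j in seq_along(pairCls)) {
            a <- pairCls[[j]][1]; b <- pairCls[[j]][2]
            pr <- min(max(rPair[n, j], 1e-7), 1 - 1e-7)
            r[a, b] <- pr
            r[b, a] <- 1 - pr
        }
        probs[n, ] <- .coupleProbs(r)
    }
    probs
}

## Mean inner-CV macro-F1 for every (cost, gamma) pair, on one training set.
.innerGridSearch <- function(x, y, grid, weights, k) {
    folds <- .stratifiedFolds(y, k)
    perf <- matrix(NA_real_, nrow(grid), k)
    for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L || !any(!tr)) next
        for (g in seq_len(nrow(grid))) {
            fit <- .fitSvm(x[tr, , drop = FALSE], y[tr],
                           grid$cost[g], grid$gamma[g], weights)
            pred <- predict(fit, x[!tr, , drop = FALSE])
            perf[g, f] <- .macroF1(y[!tr], as.character(pred))
        }
    }
    rowMeans(perf, na.rm = TRUE)
}

#' Tune and train the localization SVM
#'
#' Grid search over cost x gamma by repeated stratified partitioning: in
#' each of \code{cvOuterRounds} rounds the markers are split 80/20 with
#' class stratification, an inner \code{cvInnerFolds}-fold cross-validation
#' on the 80\% selects the best (cost, gamma) by mean macro-F1, and that
#' choice is evaluated on the held-out 20\%. The final hyperparameters are
#' the pair selected most often across rounds (ties broken by smallest cost,
#' then smallest gamma), refit on all markers with inverse-frequency class
#' weights and a Platt probability model. The mean held-out macro-F1 across
#' rounds estimates generalization performance.
#'
#' @param profiles A \linkS4class{FractionProfileSet}.
#' @param markers A \linkS4class{MarkerSet}; only markers present in
#'   \code{profiles} are used, and every class needs at least 2 of them.
#' @param spec A \linkS4class{ClassifierSpec}.
#' @return A \linkS4class{TrainedClassifier}.
#' @export
tuneAndTrain <- function(profiles, markers, spec = classifierSpec()) {
    validObject(spec)
    tr <- intersectWithProfiles(markers, profiles, minPerClass = 2L)
    ids <- proteinIds(tr$training)
    x <- profileMatrix(profiles)[ids, , drop = FALSE]
    y <- factor(unname(markerClasses(tr$training)),
                levels = classLabels(markers))
    y <- droplevels(y)
    if (nlevels(y) < 2L)
        stop("at least 2 classes with markers are required")

    weights <- if (length(spec@classWeights)) spec@classWeights else
        computeClassWeights(y)
    ## deterministic tie-break order: smallest cost, then smallest gamma
    grid <- expand.grid(gamma = sort(spec@gammaGrid),
                        cost = sort(spec@costGrid))[, c("cost", "gamma")]
    grid <- grid[order(grid$cost, grid$gamma), ]

    res <- .withSeed(spec@seed, {
        rounds <- lapply(seq_len(spec@cvOuterRounds), function(r) {
            idx <- .stratifiedSplit(y, 0.8)
            best <- if (nrow(grid) == 1L) 1L else {
                f1 <- .innerGridSearch(x[idx, , drop = FALSE], y[idx], grid,
                                       weights, spec@cvInnerFolds)
                if (all(!is.finite(f1))) 1L else which.max(f1)
            }
            fit <- .fitSvm(x[idx, , drop = FALSE], y[idx],
                           grid$cost[best], grid$gamma[best], weights)
            pred <- predict(fit, x[-idx, , drop = FALSE])
            data.frame(cost = grid$cost[best], gamma = grid$gamma[best],
                       macroF1 = .macroF1(y[-idx], as.character(pred)))
        })
        perRound <- do.call(rbind, rounds)
        ## modal selection; ties resolved by grid order (cost, then gamma)
        key <- paste(perRound$cost, perRound$gamma)
        gridKey <- paste(grid$cost, grid$gamma)
        counts <- table(factor(key, levels = gridKey))
        pick <- which.max(as.integer(counts))
        model <- .fitSvm(x, y, grid$cost[pick], grid$gamma[pick], weights)
        list(model = model, cost = grid$cost[pick], gamma = grid$gamma[pick],
             perRound = perRound)
    })

    new("TrainedClassifier", model = res$model,
        platt = .fitPlattPairs(res$model, x, y), classes = levels(y),
        cost = res$cost, gamma = res$gamma,
        classWeights = weights[levels(y)],
        cvMacroF1 = mean(res$perRound$macroF1), perRound = res$perRound,
        seed = spec@seed, trainingHash = .hashTraining(x, y))
}

.hashTraining <- function(x, y) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(list(round(x, 12), as.character(y)), f)
    unname(tools::md5sum(f))
}

#' Score all proteins with a trained classifier
#'
#' Every protein — markers included — receives Platt-scaled (pairwise
#' coupled) class membership probabilities summing to 1. The predicted
#' class is the argmax, and its probability is the protein's confidence
#' score on [0, 1].
#'
#' @param model A \linkS4class{TrainedClassifier}.
#' @param profiles A \linkS4class{FractionProfileSet} (same channel
#'   dimension as the training profiles).
#' @return data.frame with columns \code{protein_id},
#'   \code{predicted_class}, \code{score}, and one \code{score_<class>}
#'   column per class.
#' @export
scoreAll <- function(model, profiles) {
    x <- if (is(profiles, "FractionProfileSet")) profileMatrix(profiles)
         else as.matrix(profiles)
    if (ncol(x) != ncol(model@model$SV))
        stop("profile dimension (", ncol(x),
             ") does not match the trained model (", ncol(model@model$SV), ")")
    probs <- .probMatrix(model@model, model@platt, model@classes, x)
    win <- max.col(probs, ties.method = "first")
    out <- data.frame(protein_id = rownames(x),
                      predicted_class = model@classes[win],
                      score = probs[cbind(seq_len(nrow(probs)), win)],
                      stringsAsFactors = FALSE, row.names = NULL)
    probDf <- as.data.frame(probs, row.names = NULL)
    names(probDf) <- paste0("score_", colnames(probs))
    cbind(out, probDf)
}

#' Write a score table to CSV
#'
#' @param scores data.frame from \code{\link{scoreAll}}.
#' @param path Output .csv/.tsv path.
#' @return The path, invisibly.
#' @export
writeScores <- function(scores, path) {
    .writeDelim(scores, path)
    invisible(path)
}
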