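# Internal numerical and bookkeeping helpers.

#' @importFrom stats rgamma median prcomp quantile rlnorm runif predict
#'   setNames var
#' @importFrom methods new validObject is slot
NULL

## Dirichlet sampler via normalized gamma draws.  `alpha` may contain very
## large values (zero-noise limit); rgamma handles shape up to ~1e15.
.rdirichlet <- function(n, alpha) {
    k <- length(alpha)
    x <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
                nrow = n, ncol = k)
    ## guard against all-zero rows when every alpha is tiny
    zero <- rowSums(x) == 0
    if (any(zero))
        x[zero, ] <- 1 / k
    x / rowSums(x)
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
        if (has)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    expr
}

## Macro-averaged F1 over the classes present in `truth`.  Classes with an
## undefined precision or recall contribute 0, the usual convention.
.macroF1 <- function(truth, pred) {
    classes <- sort(unique(as.character(truth)))
    truth <- as.character(truth)
    pred <- as.character(pred)
    f1 <- vapply(classes, function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fp <- sum(truth != cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        if (tp == 0) return(0)
        p <- tp / (tp + fp)
        r <- tp / (tp + fn)
        2 * p * r / (p + r)
    }, numeric(1))
    mean(f1)
}

## Stratified index split: returns indices of a `prop` fraction per class,
## each class contributing at least one element to both sides.
.stratifiedSplit <- function(labels, prop = 0.8) {
    idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
        n <- length(i)
        k <- max(1L, min(n - 1L, round(prop * n)))
        sample(i, k)
    }), use.names = FALSE)
    sort(idx)
}

## Stratified k-fold assignment (vector of fold ids, 1..k).
.stratifiedFolds <- function(labels, k) {
    folds <- integer(length(labels))
    for (i in split(seq_along(labels), labels)) {
        folds[sample(i)] <- rep_len(seq_len(k), length(i))
    }
    folds
}

.normalizeIds <- function(ids) tolower(trimws(as.character(ids)))

## Delimiter from file extension: .csv -> ",", .tsv/.txt -> tab.
.delimFor <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext, csv = ",", tsv = "\t", txt = "\t",
           stop("unsupported table extension: '", ext, "' (use .csv or .tsv)"))
}

.readDelim <- function(path) {
    utils::read.table(path, header = TRUE, sep = .delimFor(path),
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8")
}

.writeDelim <- function(df, path) {
    utils::write.table(df, path, sep = .delimFor(path), row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
}
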