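#' @include AllClasses.R accessors.R
NULL

#' Manhattan distance
#'
#' City-block distance \eqn{\sum_i |a_i - b_i|}, the metric used by the
#' activity classifier.
#'
#' @param a,b numeric vectors of equal length.
#' @return A non-negative scalar.
#' @examples
#' manhattanDist(c(0, 0), c(1, 2))
#' @export
manhattanDist <- function(a, b) {
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  sum(abs(a - b))
}

# k nearest neighbours of one query given its distances to all training
# rows. Distance ties are broken by the lower training-row index (order()
# is stable); vote ties by the class of the nearest member among the tied
# classes. Distances are snapped to 12 significant digits first so that
# mathematically equal distances are recognized as ties regardless of
# floating-point summation order.
.knnVote <- function(d, labels, k) {
  nb <- order(signif(d, 12))[seq_len(k)]
  labs <- labels[nb]
  counts <- table(labs)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1L) return(tied)
  labs[labs %in% tied][1L]
}

#' k-nearest-neighbour activity classification
#'
#' Classifies query vectors by majority vote among their `k` nearest
#' training columns under the Manhattan metric. Ties in distance are broken
#' deterministically by the lower training-column index; ties in the vote by
#' the class of the nearest member among the tied classes. To keep the
#' tie-break reproducible across arithmetically equivalent distance
#' computations, distances are compared after rounding to 12 significant
#' digits.
#'
#' @param train a [FeatureSet-class] (training columns), or a plain numeric
#'   matrix with one training vector per column plus `labels`.
#' @param query a numeric vector, or a matrix with one query per column.
#' @param k neighbourhood size (`1 <= k <=` number of training columns).
#' @param labels training labels, required when `train` is a plain matrix.
#' @return Character vector of predicted labels, one per query.
#' @examples
#' x <- cbind(a = c(0, 0), b = c(1, 1), c = c(4, 4))
#' knnClassify(x, c(3.6, 3.6), k = 1, labels = c("lo", "lo", "hi"))
#' @export
knnClassify <- function(train, query, k = 1, labels = NULL) {
  if (is(train, "FeatureSet")) {
    labels <- activityLabels(train)
    train <- featureMatrix(train)
  }
  if (is.null(labels) || length(labels) != ncol(train))
    stop("'labels' must give one label per training column")
  if (ncol(train) == 0L) stop("empty training set")
  if (k < 1L || k > ncol(train))
    stop("'k' must lie in [1, ", ncol(train), "]")
  if (!is.matrix(query)) query <- matrix(query, ncol = 1L)
  if (nrow(query) != nrow(train))
    stop("dimension mismatch: queries have ", nrow(query),
         " features, training columns ", nrow(train))
  labels <- as.character(labels)
  vapply(seq_len(ncol(query)), function(j) {
    d <- colSums(abs(train - query[, j]))
    .knnVote(d, labels, k)
  }, character(1L))
}

#' Leave-one-out selection of the neighbourhood size k
#'
#' For every candidate `k`, predicts each column of the dataset from all
#' remaining columns (leave-one-out) and reports the accuracy; the best `k`
#' is the accuracy maximizer, with the smaller `k` winning ties.
#'
#' @param data a [FeatureSet-class] or a feature matrix (columns = samples)
#'   with `labels`.
#' @param kCandidates integer vector of candidate neighbourhood sizes, each
#'   below the dataset size.
#' @param labels labels, required for a plain matrix.
#' @return A list with `bestK` and `accuracy` (named numeric, one LOO
#'   accuracy per candidate).
#' @examples
#' x <- cbind(matrix(0, 2, 3), matrix(5, 2, 3))
#' looSelectK(x, kCandidates = c(1, 3), labels = rep(c("a", "b"), each = 3))
#' @export
looSelectK <- function(data, kCandidates = c(1, 3, 5, 7), labels = NULL) {
  if (is(data, "FeatureSet")) {
    labels <- activityLabels(data)
    data <- featureMatrix(data)
  }
  n <- ncol(data)
  if (n < 2L) stop("leave-one-out needs at least 2 columns")
  kCandidates <- sort(as.integer(kCandidates))
  if (any(kCandidates >= n))
    stop("every candidate k must be below the dataset size ", n)
  labels <- as.character(labels)
  D <- matrix(0, n, n)
  for (j in seq_len(n)) D[, j] <- colSums(abs(data - data[, j]))
  acc <- vapply(kCandidates, function(k) {
    hits <- vapply(seq_len(n), function(i) {
      others <- setdiff(seq_len(n), i)
      .knnVote(D[others, i], labels[others], k) == labels[i]
    }, logical(1L))
    mean(hits)
  }, numeric(1L))
  names(acc) <- kCandidates
  list(bestK = kCandidates[which.max(acc)], accuracy = acc)
}

#' Stratified train/test split of a feature set
#'
#' Draws `nTrain` columns without replacement, stratified proportionally by
#' activity (per-class quotas by largest remainder), and returns the
#' complement as the test set. The split is a deterministic function of the
#' labels and the seed, so the same seed reproduces the same segment split
#' for every sensor of a cohort.
#'
#' @param data a [FeatureSet-class].
#' @param nTrain number of training columns (0 < nTrain < dataset size).
#' @param seed RNG seed for the draw.
#' @param stratify if `FALSE`, draw uniformly without stratification.
#' @return A list with `train` and `test` (both [FeatureSet-class]) and the
#'   sorted `trainIndex`.
#' @export
splitTrainTest <- function(data, nTrain, seed = 1, stratify = TRUE) {
  stopifnot(is(data, "FeatureSet"))
  n <- ncol(data)
  if (nTrain < 1L || nTrain >= n)
    stop("'nTrain' must lie strictly between 0 and the dataset size ", n)
  labels <- as.character(activityLabels(data))
  idx <- .withLocalSeed(seed, {
    if (!stratify) {
      sample(n, nTrain)
    } else {
      classes <- sort(unique(labels))
      sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1L))
      exact <- nTrain * sizes / n
      quota <- floor(exact)
      rem <- nTrain - sum(quota)
      if (rem > 0L) {
        extra <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
        quota[extra] <- quota[extra] + 1L
      }
      unlist(lapply(seq_along(classes), function(ci) {
        pool <- which(labels == classes[ci])
        pool[sample(length(pool), quota[ci])]
      }), use.names = FALSE)
    }
  })
  idx <- sort(idx)
  list(train = data[, idx], test = data[, -idx], trainIndex = idx)
}
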