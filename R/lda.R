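#' Train the person-dependent attention discriminant
#'
#' Fits a two-class linear discriminant (Gaussian classes, shared pooled
#' within-class covariance, empirical class priors, no shrinkage):
#' \deqn{w = \Sigma^{-1} (\mu_{int} - \mu_{ext}), \quad
#'       b = -w' (\mu_{int} + \mu_{ext}) / 2 +
#'           \log(\pi_{int} / \pi_{ext}),}
#' predicting \emph{internal} iff \eqn{w'x + b > 0} (ties to external).
#' Zero-variance features are dropped with a warning before inversion
#' (their weight is fixed at 0); a singular pooled covariance falls back
#' to the Moore--Penrose pseudo-inverse with a warning.
#'
#' @param x numeric matrix, one feature vector per row (typically from
#'   \code{\link{featureMatrix}}), or a \linkS4class{BandPowerSession}.
#' @param labels per-row attention labels (\code{"internal"} /
#'   \code{"external"}); taken from the session when \code{x} is one.
#' @return An \linkS4class{AttentionLda}.
#' @export
#' @examples
#' sess <- synthesizeBandPower(makeSessionPlan(2, 20, 20, seed = 3))
#' model <- trainAttentionLda(sess)
#' model
trainAttentionLda <- function(x, labels = NULL) {
  if (methods::is(x, "BandPowerSession")) {
    if (is.null(labels)) labels <- frameLabels(x)
    x <- featureMatrix(x)
  }
  stopIfNot(is.matrix(x) && is.numeric(x), "'x' must be a numeric matrix")
  labels <- as.character(labels)
  stopIfNot(length(labels) == nrow(x),
            "'labels' must have one entry per row of 'x'")
  stopIfNot(all(labels %in% attentionLevels()),
            "labels must be 'internal' or 'external'")
  counts <- table(factor(labels, levels = attentionLevels()))
  if (any(counts == 0L))
    stop("both classes must be present in the training data", call. = FALSE)
  if (any(counts < 2L))
    stop("need at least 2 samples per class", call. = FALSE)
  n <- nrow(x)
  d0 <- ncol(x)
  if (n <= d0)
    warning(sprintf("only %d samples for %d features; estimates will be unstable",
                    n, d0))
  featOrder <- colnames(x)
  if (is.null(featOrder)) featOrder <- paste0("f", seq_len(d0))

  v <- apply(x, 2, sd)
  keep <- v > 0
  dropped <- featOrder[!keep]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  xk <- x[, keep, drop = FALSE]
  d <- ncol(xk)
  if (d == 0L) stop("no features with non-zero variance", call. = FALSE)

  int <- labels == "internal"
  muInt <- colMeans(xk[int, , drop = FALSE])
  muExt <- colMeans(xk[!int, , drop = FALSE])
  cInt <- crossprod(sweep(xk[int, , drop = FALSE], 2, muInt))
  cExt <- crossprod(sweep(xk[!int, , drop = FALSE], 2, muExt))
  sigma <- (cInt + cExt) / (n - 2)
  sigma <- (sigma + t(sigma)) / 2

  wk <- tryCatch(solve(sigma, muInt - muExt), error = function(e) {
    warning("pooled covariance is singular; using pseudo-inverse")
    as.vector(MASS::ginv(sigma) %*% (muInt - muExt))
  })
  priors <- as.numeric(counts) / n
  names(priors) <- attentionLevels()
  bias <- -sum(wk * (muInt + muExt)) / 2 +
    log(priors[["internal"]] / priors[["external"]])

  weights <- numeric(d0)
  weights[keep] <- wk
  means <- matrix(0, nrow = 2, ncol = d0,
                  dimnames = list(attentionLevels(), featOrder))
  means["external", keep] <- muExt
  means["internal", keep] <- muInt
  covFull <- matrix(0, nrow = d0, ncol = d0,
                    dimnames = list(featOrder, featOrder))
  covFull[keep, keep] <- sigma
  methods::new("AttentionLda", weights = weights, bias = as.numeric(bias),
               means = means, covariance = covFull, priors = priors,
               featureOrder = featOrder, dropped = dropped)
}

#' Predict attentional state
#'
#' Applies the affine discriminant to one or more feature vectors. The
#' state is \code{"internal"} iff the score is strictly positive; a score
#' of exactly 0 is called \code{"external"} (bias toward not pausing).
#'
#' @param object an \linkS4class{AttentionLda}.
#' @param newdata numeric vector of length d, a frames x d matrix, or a
#'   \linkS4class{BandPowerSession}. Column names, when present, must
#'   match the model's feature order.
#' @param ... unused.
#' @return A data.frame with columns \code{state} and \code{score}, one
#'   row per input vector.
#' @export
setMethod("predict", "AttentionLda", function(object, newdata, ...) {
  if (methods::is(newdata, "BandPowerSession"))
    newdata <- featureMatrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  d <- length(object@featureOrder)
  if (ncol(newdata) != d)
    stop(sprintf("feature vector length %d does not match model dimension %d",
                 ncol(newdata), d), call. = FALSE)
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object@featureOrder))
    stop("feature order of 'newdata' does not match the model", call. = FALSE)
  score <- as.vector(newdata %*% object@weights) + object@bias
  data.frame(state = ifelse(score > 0, "internal", "external"),
             score = score, stringsAsFactors = FALSE)
})

#' Cross-validated calibration accuracy
#'
#' Splits the labeled feature vectors into k folds, trains on k-1 folds
#' and scores the held-out fold, and averages accuracy across folds --
#' the quality gate applied to a user's calibration session before online
#' use. The default \code{"shuffled"} scheme assigns frames to folds at
#' random (seeded); because consecutive analysis windows overlap by 90\%,
#' shuffled folds share signal content between train and test and the
#' resulting accuracy is optimistic. The \code{"contiguous"} scheme uses
#' k temporal blocks and is the leakage-safe alternative.
#'
#' @inheritParams trainAttentionLda
#' @param k number of folds (default 5).
#' @param scheme \code{"shuffled"} (default) or \code{"contiguous"}.
#' @param seed RNG seed for the shuffle (default 0).
#' @return A \linkS4class{CalibrationResult}.
#' @export
#' @examples
#' sess <- synthesizeBandPower(makeSessionPlan(2, 20, 20, seed = 3))
#' crossValidate(sess, k = 5)
crossValidate <- function(x, labels = NULL, k = 5,
                          scheme = c("shuffled", "contiguous"), seed = 0) {
  if (methods::is(x, "BandPowerSession")) {
    if (is.null(labels)) labels <- frameLabels(x)
    x <- featureMatrix(x)
  }
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  n <- nrow(x)
  stopIfNot(n >= k, "need at least k feature vectors")
  base <- rep(seq_len(k), length.out = n)
  fold <- base
  if (scheme == "shuffled") {
    ok <- FALSE
    withSeed(childSeed(seed, "cvshuffle"), {
      for (try in 1:100) {
        fold <- base[sample.int(n)]  # random fold assignment
        ok <- all(vapply(seq_len(k), function(f)
          length(unique(labels[fold != f])) == 2L, logical(1)))
        if (ok) break
      }
    })
    if (!ok) stop("could not build folds with both classes in every training set",
                  call. = FALSE)
  } else {
    fold <- ceiling(seq_len(n) / (n / k))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == 2L, logical(1)))
    if (!ok) stop("contiguous folds leave a training set single-class",
                  call. = FALSE)
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- suppressWarnings(trainAttentionLda(x[tr, , drop = FALSE], labels[tr]))
    p <- predict(m, x[!tr, , drop = FALSE])
    mean(p$state == labels[!tr])
  }, numeric(1))
  bal <- as.numeric(table(factor(labels, levels = attentionLevels()))) / n
  methods::new("CalibrationResult", foldAccuracy = acc,
               meanAccuracy = mean(acc), scheme = scheme, n = as.integer(n),
               classBalance = setNames(bal, attentionLevels()),
               seed = as.integer(seed))
}
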