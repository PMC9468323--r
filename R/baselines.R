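#' SVM baseline on static connectivity vectors
#'
#' Maximum-margin classifier (linear kernel by default) on whole-course
#' functional-connectivity feature vectors, the conventional static
#' baseline against which the dynamic sequence classifier is compared.
#'
#' @param x n x d matrix of static feature vectors.
#' @param labels class labels (>= 2 classes present).
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost soft-margin cost.
#' @param seed integer seed (probability-model fitting is randomised).
#' @return object of class `"svm_baseline"` wrapping the e1071 fit.
#' @export
train_svm_baseline <- function(x, labels, kernel = "linear", cost = 1,
                               seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("degenerate labels: training set contains a single class")
  fit <- withr::with_seed(seed, {
    e1071::svm(as.matrix(x), labels, kernel = kernel, cost = cost,
               probability = TRUE)
  })
  structure(list(fit = fit, classes = levels(labels)),
            class = "svm_baseline")
}

#' @export
predict.svm_baseline <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  pr <- predict(object$fit, as.matrix(newdata), probability = TRUE)
  if (type == "class")
    return(factor(as.character(pr), levels = object$classes))
  attr(pr, "probabilities")[, object$classes, drop = FALSE]
}

#' Random-forest baseline on static connectivity vectors
#'
#' @param x n x d matrix of static feature vectors.
#' @param labels class labels (>= 2 classes present).
#' @param ntree number of trees (default 100).
#' @param seed integer seed; fits are deterministic given the seed.
#' @return object of class `"rf_baseline"`.
#' @export
train_rf_baseline <- function(x, labels, ntree = 100L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("degenerate labels: training set contains a single class")
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(as.matrix(x), labels, ntree = ntree)
  })
  structure(list(fit = fit, classes = levels(labels)),
            class = "rf_baseline")
}

#' @export
predict.rf_baseline <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "class")
    return(factor(as.character(predict(object$fit, as.matrix(newdata))),
                  levels = object$classes))
  predict(object$fit, as.matrix(newdata),
          type = "prob")[, object$classes, drop = FALSE]
}
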