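#' Train an extreme learning machine classifier
#'
#' Single-hidden-layer feed-forward network in which the input weights `w`
#' and biases `b` are drawn at random (uniform on [-1, 1]) and only the
#' output weights `beta` are fitted, in closed form, by least squares:
#' `H = activation(X w + b)`, `beta = pinv(H) T` with `T` the one-hot target
#' matrix. The Moore-Penrose pseudoinverse makes the fit robust to a
#' rank-deficient hidden matrix (e.g. from constant features). Refitting
#' with the same seed reproduces `beta` exactly.
#'
#' @param X numeric feature matrix (rows = samples), typically normalized to
#'   `[0, 1]`.
#' @param y label vector (factor, character or integer), at least 2 classes.
#' @param hidden number of hidden nodes L.
#' @param activation `"sigmoid"` (default), `"tanh"` or `"relu"`.
#' @param seed RNG seed for the random input layer.
#' @return an object of class `elm` with elements `input_weights`
#'   (features x L), `biases` (L), `output_weights` (L x classes),
#'   `class_labels` (ordered), `activation`, `hidden`, `seed`.
#' @export
train_elm <- function(X, y, hidden = 50, activation = "sigmoid", seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_glowsel("need at least 2 training rows")
  if (!all(is.finite(X))) stop_glowsel("non-finite values in feature matrix")
  if (length(y) != nrow(X)) stop_glowsel("length(y) must equal nrow(X)")
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L)
    stop_glowsel("training labels contain a single class ('%s')", classes[1L])
  if (!is_count(hidden)) stop_glowsel("hidden must be a positive integer")
  act <- match_activation(activation)

  p <- ncol(X)
  with_seed(seed, {
    w <- matrix(runif(p * hidden, -1, 1), nrow = p)
    b <- runif(hidden, -1, 1)
  })
  H <- act(sweep(X %*% w, 2, b, `+`))
  Tmat <- outer(as.character(y), classes, `==`) * 1
  beta <- pinv(H) %*% Tmat

  structure(list(input_weights = w, biases = b, output_weights = beta,
                 class_labels = classes, activation = activation,
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "elm")
}

# Moore-Penrose pseudoinverse by SVD. The rank cutoff max(dim) * eps
# (relative to the largest singular value) discards only numerically zero
# directions, so a full-rank square hidden matrix interpolates its targets
# exactly while rank-deficient ones (e.g. from constant features) stay stable.
pinv <- function(A, tol = max(dim(A)) * .Machine$double.eps) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d[1], 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

match_activation <- function(name) {
  switch(name,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = tanh,
    relu = function(z) pmax(z, 0),
    stop_glowsel("unknown activation '%s'", name))
}

elm_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$input_weights))
    stop_glowsel("feature dimension %d does not match model (%d)",
                 ncol(X), nrow(model$input_weights))
  act <- match_activation(model$activation)
  H <- act(sweep(X %*% model$input_weights, 2, model$biases, `+`))
  H %*% model$output_weights
}

#' Predict activity labels with a trained ELM
#'
#' Each sample is assigned the class with the maximal output-node score;
#' ties are broken in favour of the earlier class in the model's stored
#' class order.
#'
#' @param object an `elm` model.
#' @param newdata feature matrix with the training dimensionality (may have
#'   zero rows).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.elm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(character(0))
  S <- elm_scores(object, newdata)
  object$class_labels[max.col(S, ties.method = "first")]
}

#' Serialize / restore an ELM model as JSON
#'
#' The container stores the seed, the drawn input layer, the fitted output
#' weights and the label order, so a selection made against a model can be
#' reproduced across runs.
#'
#' @param model an `elm`.
#' @param path file path.
#' @export
write_elm_json <- function(model, path) {
  payload <- list(
    input_weights = model$input_weights, biases = model$biases,
    output_weights = model$output_weights, class_labels = model$class_labels,
    activation = model$activation, hidden = model$hidden, seed = model$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_elm_json
#' @export
read_elm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    input_weights = as.matrix(p$input_weights),
    biases = as.numeric(p$biases),
    output_weights = as.matrix(p$output_weights),
    class_labels = as.character(p$class_labels), activation = p$activation,
    hidden = as.integer(p$hidden), seed = as.integer(p$seed)),
    class = "elm")
}
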