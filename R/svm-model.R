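# Final RBF-kernel SVM: grid-searched training, prediction, persistence.
# The fit itself is delegated to the LIBSVM binding in e1071.

#' Default parameter grid
#'
#' The 16-point grid 2^-7, 2^-6, ..., 2^8 used for both the cost C and the
#' kernel width gamma, giving 16 x 16 = 256 (C, gamma) pairs.
#'
#' @return Numeric vector of length 16.
#' @export
default_grid <- function() 2 ^ (-7:8)

# internal: deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        stop(sprintf("class '%s' has %d samples: fewer than %d folds",
                     cls, length(idx), folds), call. = FALSE)
      }
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Grid-searched RBF-SVM training
#'
#' Evaluates every (C, gamma) pair of the supplied grids by stratified
#' k-fold cross-validation (selection metric: accuracy, or MCC via
#' `criterion`), then refits the best pair on all data. Ties resolve to the
#' smaller C, then the smaller gamma.
#'
#' @param X Numeric matrix already restricted to the selected features.
#' @param y Labels.
#' @param C_grid,gamma_grid Parameter grids (default [default_grid()]).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param criterion Model-selection metric: `"accuracy"` (default) or
#'   `"mcc"`.
#' @param scale Standardize features inside the SVM (default FALSE).
#' @param selected_feature_indices Optional descriptor indices the columns
#'   of `X` correspond to (stored for prediction-time validation).
#' @param descriptors Optional descriptor table; its checksum is stored so
#'   saved models refuse to run against a different feature layout.
#' @return A `pup_svm` object with elements `fit`, `C`, `gamma`,
#'   `cv_score`, `grid` (tibble of all evaluated pairs), `seed`,
#'   `selected_feature_indices`, `descriptor_checksum`, `fold_hash`.
#' @importFrom e1071 svm
#' @export
grid_search_train <- function(X, y, C_grid = default_grid(),
                              gamma_grid = default_grid(), folds = 5,
                              seed = 1, criterion = c("accuracy", "mcc"),
                              scale = FALSE,
                              selected_feature_indices = NULL,
                              descriptors = NULL) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  y <- factor(norm_labels(y), levels = c("positive", "negative"))
  stopifnot(nrow(X) == length(y))
  if (any(table(y) == 0L)) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  fold_of <- stratified_folds(y, folds, seed)
  C_grid <- sort(C_grid)
  gamma_grid <- sort(gamma_grid)

  score_pair <- function(C, gamma) {
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold_of != f
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = gamma, scale = scale)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      if (criterion == "accuracy") {
        mean(pred == y[!tr])
      } else {
        metrics(counts_from_labels(as.character(y[!tr]),
                                   as.character(pred)))$MCC
      }
    }, numeric(1))
    mean(per_fold)
  }

  grid <- tidyr::expand_grid(C = C_grid, gamma = gamma_grid)
  grid$cv_score <- purrr::map2_dbl(grid$C, grid$gamma, score_pair)
  best <- which.max(grid$cv_score)  # grid ordered C asc then gamma asc
  fit <- e1071::svm(X, y, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], scale = scale)
  structure(list(
    fit = fit, n_features = ncol(X),
    C = grid$C[best], gamma = grid$gamma[best],
    cv_score = grid$cv_score[best], criterion = criterion, grid = grid,
    seed = seed, fold_hash = sum(fold_of * seq_along(fold_of)),
    selected_feature_indices = selected_feature_indices,
    descriptor_checksum = if (!is.null(descriptors))
      descriptor_checksum(descriptors) else NA_character_
  ), class = "pup_svm")
}

#' @export
print.pup_svm <- function(x, ...) {
  cat(sprintf(
    "<pup_svm> RBF SVM: C=%g gamma=%g (CV %s %.3f over %d grid pairs)\n",
    x$C, x$gamma, x$criterion, x$cv_score, nrow(x$grid)))
  invisible(x)
}

#' Predict with a trained SVM model
#'
#' @param object A `pup_svm` model.
#' @param X Numeric matrix whose columns match the model's selected
#'   features.
#' @param ... Unused.
#' @return Tibble with `label` and real-valued decision `score` per row
#'   (positive score = positive call).
#' @export
predict.pup_svm <- function(object, X, ...) {
  X <- as.matrix(X)
  expected <- if (!is.null(object$selected_feature_indices)) {
    length(object$selected_feature_indices)
  } else {
    object$n_features
  }
  if (ncol(X) != expected) {
    stop(sprintf("feature matrix has %d columns; model expects %d (indices %s)",
                 ncol(X), expected,
                 paste(utils::head(object$selected_feature_indices, 10),
                       collapse = ",")), call. = FALSE)
  }
  if (nrow(X) == 0L) {
    return(tibble::tibble(label = character(), score = numeric()))
  }
  colnames(X) <- colnames(object$fit$SV) %||% colnames(X)
  pred <- stats::predict(object$fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  # decision values are oriented to the first factor level ("positive")
  tibble::tibble(label = as.character(pred), score = unname(dv))
}

#' Model metadata at a glance
#'
#' @param x A `pup_svm` model.
#' @param ... Unused.
#' @return One-row tibble: `C`, `gamma`, `cv_score`, `criterion`,
#'   `n_features`, `n_support_vectors`, `grid_pairs`.
#' @export
glance.pup_svm <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, cv_score = x$cv_score,
                 criterion = x$criterion,
                 n_features = ncol(x$fit$SV),
                 n_support_vectors = nrow(x$fit$SV),
                 grid_pairs = nrow(x$grid))
}

#' Tidy the grid-search surface
#'
#' @param x A `pup_svm` model.
#' @param ... Unused.
#' @return Tibble of all evaluated `(C, gamma)` pairs with their CV score.
#' @export
tidy.pup_svm <- function(x, ...) x$grid

#' Save / load a trained model
#'
#' The model file embeds a checksum of its own payload; a tampered or
#' truncated file refuses to load. A descriptor-table checksum stored at
#' training time guards against applying the model to a different feature
#' layout.
#'
#' @param model A `pup_svm` object.
#' @param path File path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  payload <- serialize(model, NULL)
  saveRDS(list(payload = payload, checksum = payload_checksum(payload)),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !all(c("payload", "checksum") %in% names(obj)) ||
      !identical(payload_checksum(obj$payload), obj$checksum)) {
    stop("model file is corrupt or has been modified; refusing to load",
         call. = FALSE)
  }
  unserialize(obj$payload)
}

# internal: md5 of a raw payload
payload_checksum <- function(payload) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(payload, tmp)
  unname(tools::md5sum(tmp))
}
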