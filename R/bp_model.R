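# ---- feature selection ------------------------------------------------------

#' Forward stepwise feature selection by cross-validated error
#'
#' Greedy forward selection: starting from the intercept-only model, at each
#' step the candidate whose addition most reduces the k-fold
#' cross-validated mean squared error is added, stopping when no candidate
#' improves the CV error by at least \code{min_improve} (relative). Fold
#' assignment is drawn once from \code{seed}, so the path is deterministic.
#' Constant columns are dropped with a warning before selection.
#'
#' @param feature_table data.frame of candidate regressors (numeric columns).
#' @param targets Numeric response (same length as rows).
#' @param k Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param max_features Cap on the selected-set size.
#' @param min_improve Minimum relative CV-error improvement to keep adding.
#' @return List with \code{selected} (character), \code{path} (data.frame of
#'   step, feature, cv_mse), \code{dropped_constant}.
#' @export
select_features <- function(feature_table, targets, k = 5, seed = 1L,
                            max_features = 8, min_improve = 1e-3) {
  X <- as.data.frame(feature_table)
  X <- X[vapply(X, is.numeric, logical(1))]
  keep <- vapply(X, function(col) stats::sd(col, na.rm = TRUE) > 0, logical(1))
  keep[is.na(keep)] <- FALSE
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(names(X)[!keep], collapse = ", "))
  X <- X[keep]
  cc <- stats::complete.cases(X) & is.finite(targets)
  X <- X[cc, , drop = FALSE]; y <- targets[cc]
  n <- nrow(X)
  if (n < 2 * k) stop("too few complete cases for ", k, "-fold selection")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  cv_mse <- function(vars) {
    fold_mse <- numeric(k)
    d <- data.frame(y = y, X[vars], check.names = FALSE)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- stats::lm(y ~ ., data = d[tr, , drop = FALSE])
      pr <- stats::predict(fit, newdata = d[!tr, , drop = FALSE])
      fold_mse[f] <- mean((pr - y[!tr])^2)
    }
    c(mse = mean(fold_mse), se = stats::sd(fold_mse) / sqrt(k))
  }
  selected <- character(0)
  cur <- cv_mse(selected)
  path <- data.frame(step = 0L, feature = "(intercept)", cv_mse = cur[["mse"]])
  repeat {
    if (length(selected) >= max_features) break
    cand <- setdiff(names(X), selected)
    if (!length(cand)) break
    scores <- vapply(cand, function(v) cv_mse(c(selected, v)), numeric(2))
    best <- which.min(scores["mse", ])
    # one-standard-error stopping: a candidate must beat the current CV
    # error by more than its own fold-to-fold standard error, so that
    # chance improvements from noise features are not admitted
    if (scores["mse", best] + scores["se", best] >=
          cur[["mse"]] * (1 - min_improve)) break
    selected <- c(selected, cand[best])
    cur <- scores[, best]
    path <- rbind(path, data.frame(step = length(selected),
                                   feature = cand[best],
                                   cv_mse = cur[["mse"]]))
  }
  list(selected = selected, path = path,
       dropped_constant = names(keep)[!keep])
}

# ---- model fit --------------------------------------------------------------

#' Calibrate the linear-regression BP model
#'
#' Ordinary least squares of the cuff target on the selected pulse-wave
#' features: BP = A0 + A1 F1 + ... + An Fn. Feature selection (forward
#' stepwise by cross-validated error) runs first unless an explicit feature
#' set is supplied. Separate models are fitted for systolic and diastolic
#' pressure by calling this once per target.
#'
#' @param feature_table data.frame of record-level features (one row per
#'   subject).
#' @param targets Cuff reference values (mmHg), one per row.
#' @param target_name \code{"sbp"} or \code{"dbp"}.
#' @param features Optional explicit character vector of regressors
#'   (bypasses selection).
#' @param min_n Minimum complete-case training size (default 30).
#' @param seed Seed for the selection fold assignment.
#' @param ... Passed to \code{\link{select_features}}.
#' @return Object of class \code{"bp_model"}: intercept, coefficients,
#'   feature names, and training diagnostics (n, residual sd, coefficient
#'   standard errors, selection path).
#' @export
fit_bp_model <- function(feature_table, targets, target_name = "sbp",
                         features = NULL, min_n = 30, seed = 1L, ...) {
  X <- as.data.frame(feature_table)
  X <- X[vapply(X, is.numeric, logical(1))]
  X$n_beats <- NULL; X$subject <- NULL
  sel_path <- NULL
  if (is.null(features)) {
    sel <- select_features(X, targets, seed = seed, ...)
    features <- sel$selected
    sel_path <- sel$path
    if (!length(features))
      stop("feature selection retained no regressors; supply `features`")
  }
  missing_cols <- setdiff(features, names(X))
  if (length(missing_cols))
    stop("unknown feature(s): ", paste(missing_cols, collapse = ", "))
  d <- data.frame(y = targets, X[features], check.names = FALSE)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < min_n)
    stop("need at least ", min_n, " complete training subjects, have ",
         nrow(d))
  if (nrow(d) <= length(features))
    stop("refusing to fit an unregularized model with n <= p")
  mm <- stats::model.matrix(~ ., data = d[features])
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = d)
  cf <- stats::coef(fit)
  sm <- summary(fit)
  structure(list(
    target = target_name,
    intercept = unname(cf[1]),
    coefficients = stats::setNames(unname(cf[-1]), features),
    features = features,
    diagnostics = list(n = nrow(d), residual_sd = sm$sigma,
                       coef_se = stats::setNames(unname(sm$coefficients[, 2]),
                                                 c("(Intercept)", features)),
                       conf_int = stats::confint(fit),
                       selection_path = sel_path),
    units = "mmHg"), class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> target %s: BP = %.4g", toupper(x$target),
              x$intercept))
  for (f in x$features)
    cat(sprintf(" %+.4g*%s", x$coefficients[[f]], f))
  cat(sprintf("\n  n = %d, residual sd = %.3g mmHg\n",
              x$diagnostics$n, x$diagnostics$residual_sd))
  invisible(x)
}

#' Predict blood pressure from features
#'
#' Affine evaluation of the calibrated model. Predictions outside the
#' physiological range [40, 260] mmHg are clamped with a warning.
#'
#' @param object A \code{\link{fit_bp_model}} result.
#' @param newdata data.frame (or named vector) containing every selected
#'   feature.
#' @param ... Unused.
#' @return Numeric vector of predicted BP (mmHg).
#' @export
predict.bp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop("missing selected feature(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(newdata[object$features])
  pred <- drop(object$intercept + X %*% object$coefficients)
  out_of_range <- is.finite(pred) & (pred < 40 | pred > 260)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " prediction(s) clamped to the [40, 260] mmHg range")
    pred <- pmin(pmax(pred, 40), 260)
  }
  unname(pred)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a BP model to versioned JSON
#' @param model A \code{\link{fit_bp_model}} result.
#' @param path Output path.
#' @export
write_bp_model <- function(model, path) {
  stopifnot(inherits(model, "bp_model"))
  jsonlite::write_json(list(
    schema_version = "1.0", target = model$target, units = model$units,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    features = model$features,
    n = model$diagnostics$n, residual_sd = model$diagnostics$residual_sd),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a BP model from JSON
#' @param path Path written by \code{\link{write_bp_model}}.
#' @return A \code{"bp_model"} object.
#' @export
read_bp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(target = j$target,
                 intercept = j$intercept,
                 coefficients = unlist(j$coefficients),
                 features = j$features,
                 diagnostics = list(n = j$n, residual_sd = j$residual_sd),
                 units = j$units), class = "bp_model")
}
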