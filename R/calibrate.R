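#' @title Score calibration by logistic regression
#' @description Per-(rank, order) logistic models map a read's raw
#'   log-likelihood score and its length to the probability that the
#'   implied taxon assignment at that rank is correct. Hyperparameters
#'   (inverse regularization strength C, optimizer tolerance, penalty norm,
#'   intercept fitting) are chosen by cross-validated sequential search.
#'   Models are persisted as self-contained JSON.
#' @name calibrate
NULL

#' Hyperparameter search space
#'
#' @param C_range Inverse regularization strength, log-uniform (default
#'   \code{[1e-6, 1e5]}).
#' @param tol_range Optimizer convergence tolerance, log-uniform (default
#'   \code{[1e-7, 1e-2]}).
#' @param penalty Candidate penalty norms, subset of \code{c("l1", "l2")}.
#' @param fit_intercept Candidate intercept choices.
#' @param max_iter Iteration cap held constant across the search.
#' @return A list of class \code{hyperparameter_space}.
#' @export
hyperparameter_space <- function(C_range = c(1e-6, 1e5),
                                 tol_range = c(1e-7, 1e-2),
                                 penalty = c("l1", "l2"),
                                 fit_intercept = c(TRUE, FALSE),
                                 max_iter = 15000L) {
    stopifnot(all(C_range > 0), C_range[1] < C_range[2],
              all(tol_range > 0), tol_range[1] < tol_range[2],
              all(penalty %in% c("l1", "l2")), max_iter >= 1)
    structure(list(C_range = C_range, tol_range = tol_range,
                   penalty = penalty, fit_intercept = fit_intercept,
                   max_iter = as.integer(max_iter)),
              class = "hyperparameter_space")
}

standardize_features <- function(dataset) {
    ms <- mean(dataset$raw_score); ss <- stats::sd(dataset$raw_score)
    ml <- mean(dataset$read_length); sl <- stats::sd(dataset$read_length)
    if (!is.finite(ss) || ss == 0) { ss <- 1
        warning("raw_score has zero variance; standardized with sd = 1") }
    if (!is.finite(sl) || sl == 0) { sl <- 1
        warning("read_length has zero variance; standardized with sd = 1") }
    list(score = c(mean = ms, sd = ss), length = c(mean = ml, sd = sl))
}

#' Fit a penalized logistic calibration model
#'
#' Features (raw score, read length) are standardized (constants stored on
#' the model so predictions are self-contained) and a penalized logistic
#' regression is fit by coordinate descent. The inverse regularization
#' strength C follows the convention that larger C means weaker
#' regularization; the penalty term equals \code{1/C} times the L1 or
#' squared-L2 norm of the coefficients on the summed log-loss scale.
#'
#' @param dataset Training dataset (columns \code{raw_score},
#'   \code{read_length}, logical \code{label}; both label classes must be
#'   present and n >= 20).
#' @param penalty \code{"l1"} or \code{"l2"}.
#' @param C Inverse regularization strength.
#' @param tol Optimizer convergence tolerance.
#' @param fit_intercept Whether to fit an intercept.
#' @param max_iter Iteration cap; non-convergence is flagged in the model
#'   metadata.
#' @param rank,order Annotations carried on the model.
#' @return An object of class \code{score_model}.
#' @export
fit_logistic <- function(dataset, penalty = "l2", C = 1, tol = 1e-4,
                         fit_intercept = TRUE, max_iter = 15000L,
                         rank = dataset$rank[1], order = dataset$order[1]) {
    if (nrow(dataset) < 20) stop("need at least 20 training examples")
    y <- as.logical(dataset$label)
    if (length(unique(y)) < 2)
        stop("training data contains a single label class")
    if (!all(is.finite(dataset$raw_score)) ||
        !all(is.finite(dataset$read_length)))
        stop("non-finite feature values in training data")
    std <- standardize_features(dataset)
    x <- cbind(score = (dataset$raw_score - std$score["mean"]) /
                   std$score["sd"],
               length = (dataset$read_length - std$length["mean"]) /
                   std$length["sd"])
    n <- nrow(x)
    lambda <- 1 / (C * n)
    fit <- glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                          family = "binomial",
                          alpha = if (penalty == "l1") 1 else 0,
                          lambda = lambda * c(16, 8, 4, 2, 1),
                          intercept = fit_intercept, standardize = FALSE,
                          thresh = tol, maxit = max_iter)
    cf <- as.matrix(stats::coef(fit, s = lambda))
    structure(list(
        rank = if (is.null(rank)) NA_character_ else as.character(rank),
        order = if (is.null(order)) NA_integer_ else as.integer(order),
        intercept = unname(cf[1, 1]),
        coef = c(score = unname(cf[2, 1]), length = unname(cf[3, 1])),
        standardize = std,
        meta = list(n = n, penalty = penalty, C = C, tol = tol,
                    fit_intercept = fit_intercept, max_iter = max_iter,
                    converged = fit$npasses < max_iter)),
        class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
    cat("Score calibration model (rank ", x$rank, ", order ", x$order,
        "): p = sigmoid(", signif(x$intercept, 4), " + ",
        signif(x$coef["score"], 4), "*z_score + ",
        signif(x$coef["length"], 4), "*z_length)\n", sep = "")
    invisible(x)
}

#' Predict the probability that an assignment is correct
#'
#' Sigmoid of the standardized linear predictor; vectorized over inputs.
#'
#' @param model A \code{score_model}.
#' @param raw_score Raw log-likelihood score(s).
#' @param read_length Read length(s).
#' @return Probability in \code{[0, 1]}.
#' @export
predict_probability <- function(model, raw_score, read_length) {
    zs <- (raw_score - model$standardize$score["mean"]) /
        model$standardize$score["sd"]
    zl <- (read_length - model$standardize$length["mean"]) /
        model$standardize$length["sd"]
    eta <- model$intercept + model$coef["score"] * zs +
        model$coef["length"] * zl
    unname(stats::plogis(eta))
}

sample_loguniform <- function(n, range) {
    exp(runif(n, log(range[1]), log(range[2])))
}

#' Cross-validated hyperparameter search
#'
#' Random sequential search over the space: each candidate is scored by
#' 3-fold cross-validated classification accuracy (folds drawn once per
#' search from the seeded RNG stream), and the best candidate is refit on
#' all data. Reproducible under a fixed seed.
#'
#' @param dataset Training dataset as for \code{\link{fit_logistic}}.
#' @param space A \code{\link{hyperparameter_space}}.
#' @param n_folds Number of CV folds (default 3).
#' @param budget Number of candidates evaluated (default 60).
#' @param seed Integer seed for candidate draws and fold assignment.
#' @return List with \code{model} (the refit best \code{score_model}) and
#'   \code{log} (data frame of every candidate with its CV accuracy).
#' @export
cv_search <- function(dataset, space = hyperparameter_space(),
                      n_folds = 3L, budget = 60L, seed = 1L) {
    if (nrow(dataset) == 0) stop("empty dataset")
    stopifnot(budget >= 1)
    set.seed(seed)
    n <- nrow(dataset)
    folds <- sample(rep_len(seq_len(n_folds), n))
    cand <- data.frame(
        C = sample_loguniform(budget, space$C_range),
        tol = sample_loguniform(budget, space$tol_range),
        penalty = sample(space$penalty, budget, replace = TRUE),
        fit_intercept = sample(space$fit_intercept, budget, replace = TRUE),
        stringsAsFactors = FALSE)
    acc <- numeric(budget)
    for (i in seq_len(budget)) {
        correct <- 0L
        for (f in seq_len(n_folds)) {
            tr <- dataset[folds != f, ]
            te <- dataset[folds == f, ]
            m <- try(fit_logistic(tr, penalty = cand$penalty[i],
                                  C = cand$C[i], tol = cand$tol[i],
                                  fit_intercept = cand$fit_intercept[i],
                                  max_iter = space$max_iter),
                     silent = TRUE)
            if (inherits(m, "try-error")) { correct <- NA_integer_; break }
            p <- predict_probability(m, te$raw_score, te$read_length)
            correct <- correct + sum((p >= 0.5) == te$label)
        }
        acc[i] <- if (is.na(correct)) NA_real_ else correct / n
    }
    cand$cv_accuracy <- acc
    best <- which.max(acc)  # ties and NAs: first best candidate wins
    model <- fit_logistic(dataset, penalty = cand$penalty[best],
                          C = cand$C[best], tol = cand$tol[best],
                          fit_intercept = cand$fit_intercept[best],
                          max_iter = space$max_iter)
    model$meta$seed <- seed
    model$meta$cv_accuracy <- acc[best]
    list(model = model, log = cand)
}

MODEL_JSON_VERSION <- "1.0"

#' Save or load a calibration model as JSON
#'
#' The JSON schema is
#' \code{\{version, rank, order, intercept, coef: \{score, length\},
#' standardize: \{score: [mean, sd], length: [mean, sd]\}, meta\}}; a round
#' trip reproduces predictions to within 1e-12.
#'
#' @param model A \code{score_model}.
#' @param path JSON path.
#' @return \code{save_model_json} invisibly returns \code{path};
#'   \code{load_model_json} returns the \code{score_model}.
#' @export
save_model_json <- function(model, path) {
    obj <- list(version = MODEL_JSON_VERSION, rank = model$rank,
                order = model$order, intercept = model$intercept,
                coef = as.list(model$coef),
                standardize = lapply(model$standardize, unname),
                meta = model$meta)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    required <- c("version", "rank", "order", "intercept", "coef",
                  "standardize")
    missing <- setdiff(required, names(obj))
    if (length(missing) > 0)
        stop("model JSON missing required field(s): ",
             paste(missing, collapse = ", "))
    if (!identical(as.character(obj$version), MODEL_JSON_VERSION))
        stop("unsupported model JSON version '", obj$version,
             "' (expected ", MODEL_JSON_VERSION, ")")
    structure(list(
        rank = obj$rank, order = as.integer(obj$order),
        intercept = obj$intercept,
        coef = c(score = obj$coef$score, length = obj$coef$length),
        standardize = list(
            score = c(mean = obj$standardize$score[1],
                      sd = obj$standardize$score[2]),
            length = c(mean = obj$standardize$length[1],
                       sd = obj$standardize$length[2])),
        meta = obj$meta), class = "score_model")
}
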