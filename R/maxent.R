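#' Presence-background maximum-entropy species distribution model
#'
#' The growth-suitability stage is a maximum-entropy (Gibbs) model over the
#' landscape: among all probability distributions on the background cells
#' whose feature expectations match those observed at the presence sites,
#' it selects the one of maximum entropy, which has the log-linear form
#' `p(x) proportional to exp(lambda . f(x))`. Fitting minimizes the
#' L1-regularized negative log-likelihood by proximal gradient descent
#' with backtracking, so the regularized objective decreases monotonically.
#'
#' Feature classes default to linear + quadratic on each variable (scaled
#' to \[0, 1\] over the training range); hinge features are available but
#' off by default, reflecting the small-sample regime this model is chosen
#' for.
#'
#' @param presence data frame of variable values at presence sites (one
#'   column per ecological factor).
#' @param background data frame of the same variables at background cells
#'   (>= 10 rows).
#' @param features feature classes, subset of
#'   `c("linear", "quadratic", "hinge")`.
#' @param beta L1 regularization weight per feature class; a single number
#'   or a named vector like `c(linear = 0.1, quadratic = 0.1)`.
#' @param n_hinge number of hinge knots per variable when `"hinge"` is in
#'   `features`.
#' @param max_iter,tol optimizer budget: stop when the generalized-gradient
#'   infinity norm drops below `tol` (default 1e-6) or after `max_iter`
#'   iterations (default 500; non-convergence is flagged with a warning and
#'   the best iterate returned).
#' @return A `maxent_model` object.
#' @export
fit_maxent <- function(presence, background,
                       features = c("linear", "quadratic"),
                       beta = 0.1, n_hinge = 4,
                       max_iter = 500, tol = 1e-6) {
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  vars <- names(background)
  if (!all(vars %in% names(presence)))
    stop("presence and background must share the same variable columns", call. = FALSE)
  presence <- presence[, vars, drop = FALSE]
  if (nrow(presence) < 1L) stop("need at least 1 presence row", call. = FALSE)
  if (nrow(background) < 10L) stop("need at least 10 background rows", call. = FALSE)
  if (anyNA(presence) || anyNA(background))
    stop("missing values in presence or background data", call. = FALSE)

  combined <- rbind(presence, background)
  const <- vapply(combined, function(v) diff(range(v)) == 0, TRUE)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(vars[const], collapse = ", "), call. = FALSE)
    vars <- vars[!const]
    presence <- presence[, vars, drop = FALSE]
    background <- background[, vars, drop = FALSE]
    combined <- combined[, vars, drop = FALSE]
  }

  fs <- make_feature_set(combined, features = features, n_hinge = n_hinge)
  m <- length(fs$features)
  Fp <- expand_features(fs, presence)$mat
  Fb <- expand_features(fs, background)$mat

  beta_vec <- if (m == 0L) numeric(0) else {
    b <- if (length(beta) == 1L && is.null(names(beta)))
      rep(beta, m)
    else {
      cls <- vapply(fs$features, `[[`, "", "type")
      bb <- beta[cls]
      if (anyNA(bb)) stop("`beta` must name every feature class in use", call. = FALSE)
      as.numeric(bb)
    }
    # scale the per-class multiplier by the feature's presence-sample
    # standard error, the classic Maxent tightening of the L1 bound
    v <- apply(Fp, 2, stats::var)
    v[!is.finite(v)] <- 0
    se <- sqrt(pmax(v, 1e-6) / nrow(Fp))
    b * se
  }

  fbar <- if (m) colMeans(Fp) else numeric(0)
  nb <- nrow(Fb)

  log_mean_exp <- function(eta) {
    mx <- max(eta)
    mx + log(mean(exp(eta - mx)))
  }
  smooth_obj <- function(l) {
    eta <- if (m) drop(Fb %*% l) else rep(0, nb)
    -sum(fbar * l) + log_mean_exp(eta)
  }
  smooth_grad <- function(l) {
    eta <- if (m) drop(Fb %*% l) else rep(0, nb)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    drop(crossprod(Fb, w)) - fbar
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  lambda <- rep(0, m)
  obj_trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  if (m > 0L) {
    f_l <- smooth_obj(lambda)
    obj_trace <- f_l + sum(beta_vec * abs(lambda))
    step <- 1
    for (it in seq_len(max_iter)) {
      iters <- it
      g <- smooth_grad(lambda)
      # generalized gradient: optimality residual of the L1 problem
      res <- ifelse(lambda > 0, abs(g + beta_vec),
              ifelse(lambda < 0, abs(g - beta_vec),
                     pmax(abs(g) - beta_vec, 0)))
      if (max(res) < tol) { converged <- TRUE; break }
      repeat {
        cand <- soft(lambda - step * g, step * beta_vec)
        dlt <- cand - lambda
        f_c <- smooth_obj(cand)
        if (f_c <= f_l + sum(g * dlt) + sum(dlt^2) / (2 * step) + 1e-14) break
        step <- step / 2
        if (step < 1e-12) break
      }
      lambda <- cand
      f_l <- f_c
      obj_trace <- c(obj_trace, f_l + sum(beta_vec * abs(lambda)))
      step <- min(step * 2, 1e3)
    }
    if (!converged)
      warning("maxent optimizer did not reach tolerance; returning best iterate",
              call. = FALSE)
  } else converged <- TRUE

  eta_b <- if (m) drop(Fb %*% lambda) else rep(0, nb)
  log_sum_b <- { mx <- max(eta_b); mx + log(sum(exp(eta_b - mx))) }
  p_b <- exp(eta_b - log_sum_b)
  entropy <- -sum(p_b * log(pmax(p_b, 1e-300)))

  structure(list(
    feature_set = fs,
    lambda = stats::setNames(lambda, vapply(fs$features, feature_name, "")),
    beta = beta_vec,
    variables = vars,
    bg_means = colMeans(background),
    log_sum_background = log_sum_b,
    n_background = nb,
    entropy = entropy,
    converged = converged,
    iterations = iters,
    objective_trace = obj_trace
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d variable(s), %d feature(s), %d background cell(s)\n",
              length(x$variables), length(x$lambda), x$n_background))
  cat(sprintf("  converged: %s after %d iteration(s); entropy %.4f\n",
              x$converged, x$iterations, x$entropy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(term = names(x$lambda), estimate = unname(x$lambda))
}

#' @exportS3Method generics::glance
glance.maxent_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$lambda),
                 n_background = x$n_background,
                 entropy = x$entropy,
                 iterations = x$iterations,
                 converged = x$converged,
                 objective = if (length(x$objective_trace))
                   x$objective_trace[length(x$objective_trace)] else 0)
}

# ---- feature machinery -----------------------------------------------------

make_feature_set <- function(data, features = c("linear", "quadratic"),
                             n_hinge = 4) {
  # an empty feature set is legal: maxent with no constraints is uniform
  if (length(features))
    features <- match.arg(features, c("linear", "quadratic", "hinge"),
                          several.ok = TRUE)
  ranges <- lapply(data, range)
  feats <- list()
  for (v in names(data)) {
    if ("linear" %in% features)
      feats[[length(feats) + 1L]] <- list(variable = v, type = "linear")
    if ("quadratic" %in% features)
      feats[[length(feats) + 1L]] <- list(variable = v, type = "quadratic")
    if ("hinge" %in% features && n_hinge >= 1L)
      for (k in seq_len(n_hinge) / (n_hinge + 1))
        feats[[length(feats) + 1L]] <- list(variable = v, type = "hinge", knot = k)
  }
  list(features = feats, ranges = ranges)
}

feature_name <- function(f) {
  if (f$type == "hinge") sprintf("hinge(%s, %.3f)", f$variable, f$knot)
  else sprintf("%s(%s)", f$type, f$variable)
}

# data -> n x m feature matrix, values scaled into [0, 1]; out-of-range
# values are clamped and counted.
expand_features <- function(fs, data, clamp = TRUE) {
  n <- nrow(data)
  m <- length(fs$features)
  mat <- matrix(0, n, m)
  clamped <- 0L
  scaled <- list()
  for (v in names(fs$ranges)) {
    r <- fs$ranges[[v]]
    s <- if (diff(r) > 0) (data[[v]] - r[1]) / diff(r) else rep(0.5, n)
    if (clamp) {
      out <- s < 0 | s > 1
      clamped <- clamped + sum(out, na.rm = TRUE)
      s <- pmin(pmax(s, 0), 1)
    }
    scaled[[v]] <- s
  }
  for (j in seq_len(m)) {
    f <- fs$features[[j]]
    s <- scaled[[f$variable]]
    mat[, j] <- switch(f$type,
      linear = s,
      quadratic = s^2,
      hinge = pmax(0, (s - f$knot) / (1 - f$knot))
    )
  }
  list(mat = mat, n_clamped = clamped)
}

model_eta <- function(model, data, warn_clamp = FALSE) {
  ex <- expand_features(model$feature_set, data)
  if (warn_clamp && ex$n_clamped > 0)
    warning(ex$n_clamped, " value(s) outside the training range were clamped",
            call. = FALSE)
  if (length(model$lambda)) drop(ex$mat %*% model$lambda) else rep(0, nrow(data))
}

#' Predict suitability from a fitted maxent model
#'
#' `type = "raw"` returns the normalized Gibbs density relative to the
#' training background (raw values sum to 1 over the background cells).
#' `type = "logistic"` applies the classic Maxent display transform
#' `tau * r / (1 - tau + tau * r)` with `tau = 0.5`, where `r` is the raw
#' density scaled by `exp(H)` (H = entropy of the background distribution),
#' yielding values in \[0, 1\] with 0.5 at a typical background cell.
#' Values outside the training range are clamped (with a warning).
#'
#' @param object a `maxent_model`.
#' @param newdata a data frame of variable columns, or a named list of
#'   aligned [eco_raster()] layers covering the model's variables.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return A numeric vector (data-frame input) or an `eco_raster`
#'   (raster input).
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw"),
                                 ...) {
  type <- match.arg(type)
  if (is.list(newdata) && all(vapply(newdata, is_eco_raster, TRUE)) &&
      !is.data.frame(newdata)) {
    if (!all(object$variables %in% names(newdata)))
      stop("raster list must cover variables: ",
           paste(object$variables, collapse = ", "), call. = FALSE)
    tmpl <- newdata[[object$variables[1]]]
    df <- as.data.frame(lapply(newdata[object$variables],
                               function(r) as.vector(r$values)))
    names(df) <- object$variables
    ok <- stats::complete.cases(df)
    vals <- rep(NA_real_, nrow(df))
    if (any(ok))
      vals[ok] <- predict.maxent_model(object, df[ok, , drop = FALSE], type = type)
    out <- tmpl
    out$values <- matrix(vals, nrow(tmpl$values), ncol(tmpl$values))
    return(out)
  }
  newdata <- as.data.frame(newdata)
  eta <- model_eta(object, newdata, warn_clamp = TRUE)
  raw <- exp(eta - object$log_sum_background)
  if (type == "raw") return(raw)
  r <- raw * exp(object$entropy)
  tau <- 0.5
  tau * r / (1 - tau + tau * r)
}

#' Rank-based AUC of presence versus background scores
#'
#' The Mann-Whitney statistic: the probability that a randomly chosen
#' presence site scores higher than a randomly chosen background site,
#' ties counting one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 1L) stop("need at least one presence score", call. = FALSE)
  if (nb < 1L) stop("need at least one background score", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Train/test AUC of a maxent model
#'
#' Splits the presence rows into training and test sets (default 75/25,
#' fixed seed), fits on the training set and reports the AUC of each set
#' against the background.
#'
#' @inheritParams fit_maxent
#' @param train_frac fraction of presences used for training.
#' @param seed RNG seed for the split.
#' @param ... passed to [fit_maxent()].
#' @return A list with elements `model`, `auc_train`, `auc_test`.
#' @export
maxent_evaluate <- function(presence, background, train_frac = 0.75,
                            seed = 1L, ...) {
  presence <- as.data.frame(presence)
  n <- nrow(presence)
  set.seed(seed)
  tr <- sample.int(n, size = max(1L, round(train_frac * n)))
  model <- fit_maxent(presence[tr, , drop = FALSE], background, ...)
  sc_bg <- predict(model, background, type = "raw")
  sc_tr <- predict(model, presence[tr, , drop = FALSE], type = "raw")
  auc_train <- auc_score(sc_tr, sc_bg)
  te <- setdiff(seq_len(n), tr)
  auc_test <- if (length(te)) {
    sc_te <- predict(model, presence[te, , drop = FALSE], type = "raw")
    auc_score(sc_te, sc_bg)
  } else NA_real_
  list(model = model, auc_train = auc_train, auc_test = auc_test)
}

#' Percent contribution by permutation importance
#'
#' Measures each variable's contribution as the drop in training AUC when
#' that variable's values are permuted across all presence and background
#' rows (mean of `n_perm` permutations, fixed seed), normalized so the
#' contributions sum to 100.
#'
#' @param model a `maxent_model`.
#' @param presence,background the training data frames.
#' @param n_perm permutations per variable (default 10).
#' @param seed RNG seed.
#' @return A tibble with columns `variable` and `contribution` (percent).
#' @export
percent_contribution <- function(model, presence, background,
                                 n_perm = 10, seed = 1L) {
  presence <- as.data.frame(presence)[, model$variables, drop = FALSE]
  background <- as.data.frame(background)[, model$variables, drop = FALSE]
  np <- nrow(presence)
  combined <- rbind(presence, background)
  base_auc <- auc_score(model_eta(model, presence), model_eta(model, background))
  set.seed(seed)
  drops <- vapply(model$variables, function(v) {
    mean(vapply(seq_len(n_perm), function(i) {
      perm <- combined
      perm[[v]] <- sample(perm[[v]])
      eta <- model_eta(model, perm)
      max(0, base_auc - auc_score(eta[seq_len(np)], eta[-seq_len(np)]))
    }, 0))
  }, 0)
  if (sum(drops) <= 0) {
    warning("no permutation produced an AUC drop; contributions set equal",
            call. = FALSE)
    drops <- rep(1, length(drops))
  }
  tibble::tibble(variable = model$variables,
                 contribution = 100 * drops / sum(drops))
}

#' Response curve of one variable
#'
#' Predicted (logistic) suitability along an even grid over the variable's
#' training range, with every other variable held at its background mean.
#'
#' @param model a `maxent_model`.
#' @param variable variable name.
#' @param n_grid number of grid points (default 100).
#' @return A tibble of class `response_curve` with columns `value` and
#'   `response`, and the variable name in attribute `"variable"`.
#' @export
response_curve <- function(model, variable, n_grid = 100) {
  if (!variable %in% model$variables)
    stop("unknown variable: ", variable, call. = FALSE)
  r <- model$feature_set$ranges[[variable]]
  grid <- seq(r[1], r[2], length.out = n_grid)
  df <- as.data.frame(lapply(model$bg_means, rep, times = n_grid))
  df[[variable]] <- grid
  resp <- predict(model, df, type = "logistic")
  out <- tibble::tibble(value = grid, response = resp)
  class(out) <- c("response_curve", class(out))
  attr(out, "variable") <- variable
  out
}

#' Optimal factor range from a response curve
#'
#' The smallest and largest grid values whose response reaches at least
#' `fraction` of the curve's maximum. A warning is raised when the
#' high-response region is non-contiguous (the returned interval then
#' spans the gaps).
#'
#' @param curve a [response_curve()].
#' @param fraction fraction of the maximum response (0 < fraction < 1,
#'   default 0.8).
#' @return Named numeric vector `c(low, high)` in the variable's units.
#' @export
optimal_range <- function(curve, fraction = 0.8) {
  stopifnot(fraction > 0, fraction < 1)
  thr <- fraction * max(curve$response)
  hit <- which(curve$response >= thr)
  if (!length(hit)) stop("no grid point reaches the response threshold", call. = FALSE)
  if (any(diff(hit) > 1L))
    warning("high-response region is non-contiguous; returning its envelope",
            call. = FALSE)
  c(low = curve$value[min(hit)], high = curve$value[max(hit)])
}

#' @exportS3Method ggplot2::autoplot
autoplot.response_curve <- function(object, fraction = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "variable"), y = "relative suitability") +
    ggplot2::ylim(0, 1)
  if (!is.null(fraction))
    p <- p + ggplot2::geom_hline(yintercept = fraction * max(object$response),
                                 linetype = 2)
  p
}

#' Select the most influential factors
#'
#' Keeps the top `k` variables by percent contribution (default 5), or all
#' variables above `min_percent` when given. Ties break deterministically
#' by variable name.
#'
#' @param contributions tibble with `variable` and `contribution` columns.
#' @param k number of variables to keep (ignored when `min_percent` given).
#' @param min_percent optional contribution floor in percent.
#' @return Character vector of selected variable names.
#' @export
select_factors <- function(contributions, k = 5, min_percent = NULL) {
  ord <- contributions[order(-contributions$contribution, contributions$variable), ]
  if (!is.null(min_percent)) return(ord$variable[ord$contribution >= min_percent])
  ord$variable[seq_len(min(k, nrow(ord)))]
}

#' Serialize a maxent model to a JSON text file
#'
#' Writes the feature descriptors, scaling ranges, coefficients and
#' normalizing constants; [read_maxent()] restores a model that predicts
#' identically.
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_maxent <- function(model, path) {
  obj <- list(
    variables = model$variables,
    ranges = model$feature_set$ranges,
    features = model$feature_set$features,
    lambda = as.list(model$lambda),
    beta = model$beta,
    bg_means = as.list(model$bg_means),
    log_sum_background = model$log_sum_background,
    n_background = model$n_background,
    entropy = model$entropy,
    converged = model$converged,
    iterations = model$iterations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fs <- list(
    features = lapply(obj$features, function(f) {
      f$variable <- as.character(f$variable); f$type <- as.character(f$type)
      if (!is.null(f$knot)) f$knot <- as.numeric(f$knot)
      f
    }),
    ranges = lapply(obj$ranges, function(r) as.numeric(unlist(r)))
  )
  structure(list(
    feature_set = fs,
    lambda = unlist(obj$lambda),
    beta = as.numeric(unlist(obj$beta)),
    variables = as.character(unlist(obj$variables)),
    bg_means = unlist(obj$bg_means),
    log_sum_background = as.numeric(obj$log_sum_background),
    n_background = as.integer(obj$n_background),
    entropy = as.numeric(obj$entropy),
    converged = as.logical(obj$converged),
    iterations = as.integer(obj$iterations),
    objective_trace = numeric(0)
  ), class = "maxent_model")
}
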