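#' Fit a stepwise binary logistic suitability model for one class
#'
#' Fits a maximum-likelihood binary logistic regression of "cell is / is not
#' the class" on standardized drivers, with stepwise driver selection: at each
#' forward step the candidate with the smallest Wald p-value is added if
#' p < `p_enter`; any selected driver whose p-value rises above `p_remove` is
#' then dropped; the cycle repeats to a fixpoint. Coefficients are reported on
#' the standardized scale. In-sample ROC (AUC) of the fitted probability
#' surface is recorded on the model.
#'
#' Under perfect separation (or glm non-convergence) the fit falls back to a
#' lightly ridge-penalized logistic regression (penalty 1e-6 on the slopes),
#' with a warning.
#'
#' @param map A [land_use_map].
#' @param drivers A [driver_stack] aligned with `map`.
#' @param class_code Class code 1..6 (or class name).
#' @param p_enter,p_remove Stepwise entry/removal Wald p-value thresholds.
#' @return A `logistic_model` object.
#' @export
fit_logistic <- function(map, drivers, class_code, p_enter = 0.05,
                         p_remove = 0.10) {
  stopifnot(inherits(map, "land_use_map"), inherits(drivers, "driver_stack"))
  if (is.character(class_code)) class_code <- landuse_classes[[class_code]]
  class_code <- as.integer(class_code)
  keep <- !map$mask & !drivers$mask
  y <- as.integer(map$codes == class_code)[as.vector(keep)]
  share <- mean(y)
  if (share < 0.01 || share > 0.99)
    stop("class ", class_code, " covers ", sprintf("%.1f%%", 100 * share),
         " of cells; outside the 1-99% fitting bounds", call. = FALSE)
  std <- standardize_drivers(drivers)
  X <- std$X[as.vector(keep), , drop = FALSE]
  candidates <- colnames(X)

  fit_one <- function(vars) {
    if (!length(vars)) {
      f <- glm(y ~ 1, family = binomial())
      return(list(fit = f, coefs = coef(f), p = numeric(0), ridge = FALSE))
    }
    dat <- data.frame(y = y, X[, vars, drop = FALSE])
    sep <- FALSE
    f <- withCallingHandlers(
      glm(y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep || !f$converged) {
      rr <- ridge_logistic(cbind(1, X[, vars, drop = FALSE]), y, lambda = 1e-6)
      co <- setNames(rr$beta, c("(Intercept)", vars))
      # separation means a driver explains the class perfectly: the penalized
      # Wald statistic degenerates, so treat the evidence as overwhelming
      # (p = 0) rather than dropping a perfectly separating driver
      return(list(fit = NULL, coefs = co,
                  p = setNames(rep(0, length(vars)), vars), ridge = TRUE))
    }
    s <- summary(f)$coefficients
    list(fit = f, coefs = coef(f),
         p = setNames(s[-1, "Pr(>|z|)"], rownames(s)[-1]), ridge = FALSE)
  }

  selected <- character(0)
  ridge_used <- FALSE
  repeat {
    changed <- FALSE
    # forward: try each remaining candidate, add the smallest-p one if < p_enter
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      pvals <- vapply(remaining, function(v) {
        m <- fit_one(c(selected, v))
        unname(m$p[v]) %|NA|% 1
      }, numeric(1))
      best <- names(which.min(pvals))
      if (pvals[best] < p_enter) {
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    # backward: drop any selected driver with p > p_remove (worst first)
    repeat {
      if (!length(selected)) break
      m <- fit_one(selected)
      worst <- names(which.max(m$p))
      if (length(worst) && m$p[worst] > p_remove) {
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  final <- fit_one(selected)
  ridge_used <- final$ridge
  if (ridge_used)
    warning("perfect separation detected; ridge-penalized fit used for class ",
            class_code, call. = FALSE)
  coefs <- final$coefs
  model <- structure(
    list(class_code = class_code,
         class_name = landuse_labels[class_code],
         intercept = unname(coefs["(Intercept)"]),
         coefficients = coefs[setdiff(names(coefs), "(Intercept)")],
         selected_drivers = selected,
         center = std$center, scale = std$scale,
         p_values = final$p,
         ridge = ridge_used,
         n = length(y), share = share,
         roc = NA_real_),
    class = "logistic_model")
  surf <- probability_surface(model, drivers)
  labels <- grid_raster(
    ifelse(map$mask, NA_real_, as.numeric(map$codes == class_code)),
    map$cell_size_km, map$mask)
  model$roc <- roc_auc(surf, labels)
  model
}

# internal: IRLS logistic regression with a ridge penalty on the slopes
# (intercept unpenalized); X includes the intercept column. Returns
# coefficients and Wald p-values from the penalized information matrix.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> class %d (%s): %d driver(s), ROC %.3f%s\n",
              x$class_code, x$class_name, length(x$selected_drivers), x$roc,
              if (x$ridge) " [ridge fallback]" else ""))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a fitted suitability model
#'
#' @param x A `logistic_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `p.value`.
#' @exportS3Method generics::tidy
tidy.logistic_model <- function(x, ...) {
  terms <- c("(Intercept)", names(x$coefficients))
  tibble::tibble(
    term = terms,
    estimate = c(x$intercept, unname(x$coefficients)),
    p.value = c(NA_real_, unname(x$p_values[names(x$coefficients)]))
  )
}

#' @rdname tidy.logistic_model
#' @return `glance()`: a one-row tibble with `class_code`, `class_name`,
#'   `n_drivers`, `roc`, `n`, `share`, `ridge`.
#' @exportS3Method generics::glance
glance.logistic_model <- function(x, ...) {
  tibble::tibble(
    class_code = x$class_code, class_name = x$class_name,
    n_drivers = length(x$selected_drivers), roc = x$roc,
    n = x$n, share = x$share, ridge = x$ridge
  )
}

#' Suitability probability surface from a fitted model
#'
#' Per-cell inverse-logit of the model's linear predictor, using the
#' standardization (centers/scales) stored at fitting time.
#'
#' @param model A `logistic_model`.
#' @param drivers A [driver_stack] containing every selected driver.
#' @return A [grid_raster] of probabilities in `[0, 1]`.
#' @export
probability_surface <- function(model, drivers) {
  stopifnot(inherits(model, "logistic_model"), inherits(drivers, "driver_stack"))
  miss <- setdiff(names(model$coefficients), names(drivers$layers))
  if (length(miss))
    stop("driver(s) missing from stack: ", paste(miss, collapse = ", "),
         call. = FALSE)
  eta <- matrix(model$intercept, nrow(drivers$mask), ncol(drivers$mask))
  for (d in names(model$coefficients)) {
    z <- (drivers$layers[[d]]$values - model$center[[d]]) / model$scale[[d]]
    eta <- eta + model$coefficients[[d]] * z
  }
  p <- plogis(eta)
  p[drivers$mask] <- NA_real_
  grid_raster(p, drivers$cell_size_km, drivers$mask)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' cell outranks a randomly chosen negative cell, ties counted one half.
#' Invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric vector or [grid_raster] of scores.
#' @param labels Binary (0/1) vector or raster, aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (inherits(scores, "grid_raster")) scores <- raster_values(scores)
  if (inherits(labels, "grid_raster")) labels <- raster_values(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both label values must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit suitability models for all six classes
#'
#' @inheritParams fit_logistic
#' @return Named list of `logistic_model`s (classes absent from the fitting
#'   bounds are skipped with a warning).
#' @export
fit_all_classes <- function(map, drivers, p_enter = 0.05, p_remove = 0.10) {
  models <- list()
  for (k in landuse_labels) {
    m <- tryCatch(fit_logistic(map, drivers, k, p_enter, p_remove),
                  error = function(e) {
                    warning("class ", k, " skipped: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) models[[k]] <- m
  }
  models
}

#' Serialize fitted suitability models to/from YAML
#'
#' @param models Named list of `logistic_model`s.
#' @param path YAML file path.
#' @return `write_models_yaml` the path invisibly; `read_models_yaml` the
#'   model list.
#' @export
write_models_yaml <- function(models, path) {
  out <- lapply(models, function(m) list(
    class_code = m$class_code, class_name = m$class_name,
    intercept = m$intercept,
    coefficients = as.list(m$coefficients),
    selected_drivers = as.list(m$selected_drivers),
    center = as.list(m$center), scale = as.list(m$scale),
    roc = m$roc, n = m$n, share = m$share, ridge = m$ridge
  ))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_models_yaml
#' @export
read_models_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) {
    structure(
      list(class_code = as.integer(m$class_code), class_name = m$class_name,
           intercept = as.numeric(m$intercept),
           coefficients = unlist(m$coefficients) %||% setNames(numeric(0), character(0)),
           selected_drivers = unlist(m$selected_drivers) %||% character(0),
           center = unlist(m$center), scale = unlist(m$scale),
           p_values = NULL, ridge = isTRUE(m$ridge),
           n = as.integer(m$n), share = as.numeric(m$share),
           roc = as.numeric(m$roc)),
      class = "logistic_model")
  })
}
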