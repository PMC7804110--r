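# Covariate screening: multivariable linear regression of average layer
# thickness on demographics with backward step-wise elimination. The
# covariate(s) surviving at alpha decide how eyes are grouped for spatial
# clustering: by age-interval cohorts, by sex, or as a single whole cohort.

#' Encode demographic covariates as a design tibble
#'
#' Dichotomous coding: sex female = 1, male = 0; Asian ethnicity = 1, White
#' = 0, with "Other" ethnicity carried as a second indicator so no eyes are
#' dropped. Age, spherical-equivalent refraction and BCVA enter untransformed.
#' Covariates constant across the cohort are dropped with a warning.
#'
#' @param ds A `grid_dataset` (or any tibble with the demographic columns).
#' @return A tibble of numeric covariate columns, one row per eye.
#' @export
encode_covariates <- function(ds) {
  df <- tibble::as_tibble(ds)
  design <- tibble::tibble(
    age = as.numeric(df$age),
    sex = as.numeric(df$sex == "F"),
    asian = as.numeric(df$ethnicity == "Asian"),
    other = as.numeric(df$ethnicity == "Other"),
    se_refraction = as.numeric(df$se_refraction),
    bcva = as.numeric(df$bcva)
  )
  constant <- vapply(design, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(names(design)[constant], collapse = ", "), call. = FALSE)
    design <- design[, !constant, drop = FALSE]
  }
  design
}

#' Backward step-wise elimination on a linear model
#'
#' Fits an ordinary least-squares model of `response` on all columns of
#' `design`, then repeatedly removes the covariate with the largest p-value
#' `>= alpha` and refits, stopping when every remaining covariate has
#' `p < alpha` or none remain. One covariate is removed per step. Inference
#' is the usual two-sided t-test on OLS coefficients with 95% confidence
#' intervals from the final fit.
#'
#' @param response Numeric response (per-eye mean layer thickness, um).
#' @param design Covariate tibble from [encode_covariates()].
#' @param alpha Retention threshold (default 0.05).
#' @return A `screen_result`: list with `retained` (tibble of `term`,
#'   `estimate`, `conf.low`, `conf.high`, `p.value`), `steps` (elimination
#'   order), and `grouping_decision` (`"age"`, `"sex"` or `"whole"`).
#' @export
backward_eliminate <- function(response, design, alpha = 0.05) {
  stopifnot(is.numeric(response), nrow(design) == length(response))
  if (length(response) <= ncol(design) + 1L) {
    stop("need more observations than covariates + 1", call. = FALSE)
  }
  x <- as.matrix(design)
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1L) {
    drop_idx <- qrx$pivot[seq(qrx$rank + 1L, ncol(x) + 1L)] - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(x)[drop_idx], collapse = ", "), call. = FALSE)
  }
  terms_left <- colnames(design)
  steps <- character()
  repeat {
    df <- tibble::as_tibble(design[, terms_left, drop = FALSE])
    df$.y <- response
    fit <- lm(.y ~ ., data = df)
    coefs <- summary(fit)$coefficients
    pvals <- coefs[setdiff(rownames(coefs), "(Intercept)"), 4]
    names(pvals) <- setdiff(rownames(coefs), "(Intercept)")
    if (length(pvals) == 0L || max(pvals) < alpha) break
    worst <- names(pvals)[which.max(pvals)]
    steps <- c(steps, worst)
    terms_left <- setdiff(terms_left, worst)
    if (length(terms_left) == 0L) {
      fit <- NULL
      break
    }
  }
  retained <- if (length(terms_left) && !is.null(fit)) {
    ci <- stats::confint(fit, level = 0.95)
    coefs <- summary(fit)$coefficients
    keep <- setdiff(rownames(coefs), "(Intercept)")
    tibble::tibble(term = keep, estimate = coefs[keep, 1],
                   conf.low = ci[keep, 1], conf.high = ci[keep, 2],
                   p.value = coefs[keep, 4])
  } else {
    tibble::tibble(term = character(), estimate = numeric(),
                   conf.low = numeric(), conf.high = numeric(),
                   p.value = numeric())
  }
  decision <- if ("age" %in% retained$term) "age"
              else if ("sex" %in% retained$term) "sex"
              else "whole"
  structure(list(retained = retained, steps = steps,
                 grouping_decision = decision, alpha = alpha),
            class = "screen_result")
}

#' Screen demographics against average layer thickness
#'
#' Convenience wrapper: computes per-eye mean thickness with
#' [layer_mean_thickness()], encodes covariates, and runs
#' [backward_eliminate()].
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param alpha Retention threshold (default 0.05).
#' @return A `screen_result` (see [backward_eliminate()]), with the layer
#'   name attached.
#' @export
screen_covariates <- function(ds, alpha = 0.05) {
  response <- layer_mean_thickness(ds)$mean_um
  out <- backward_eliminate(response, encode_covariates(ds), alpha = alpha)
  out$layer <- attr(ds, "layer")
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result>%s grouping decision: %s\n",
              if (!is.null(x$layer)) paste0(" layer ", x$layer, ";") else "",
              x$grouping_decision))
  if (nrow(x$retained)) print(x$retained) else cat("  no covariates retained\n")
  invisible(x)
}

#' @rdname backward_eliminate
#' @param x A `screen_result`.
#' @param ... Unused.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$retained

#' @rdname backward_eliminate
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(layer = x$layer %||% NA_character_,
                 grouping_decision = x$grouping_decision,
                 n_retained = nrow(x$retained),
                 n_eliminated = length(x$steps))
}

#' Write a screen result as JSON
#'
#' @param x A `screen_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(x, path) {
  jsonlite::write_json(
    list(layer = x$layer, grouping_decision = x$grouping_decision,
         retained = x$retained, eliminated = x$steps),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
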