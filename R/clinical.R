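#' Univariate screening of clinical covariates
#'
#' Chooses the test per variable: categorical variables get a chi-square
#' test (Fisher's exact test when any expected cell count is below 5);
#' continuous variables get a two-sample t-test when both label groups
#' pass a Shapiro-Wilk normality check, and a Mann-Whitney U test
#' otherwise. A variable is flagged when p < `alpha`. Constant variables
#' are never flagged and carry a note.
#'
#' @param table An imputed clinical table.
#' @param alpha Screening level (default 0.05).
#' @return Tibble: `variable`, `test`, `p_value`, `flagged`, `note`.
#' @export
screen_clinical <- function(table, alpha = 0.05) {
  table <- validate_clinical_table(table)
  y <- table$label
  vars <- setdiff(names(table), c("sample_id", "label"))
  types <- clinical_variables()
  purrr::map_dfr(vars, function(v) {
    x <- table[[v]]
    if (anyNA(x)) abort(sprintf("variable '%s' has missing values; impute first", v))
    type <- types$type[match(v, types$variable)]
    if (is.na(type)) type <- if (is.numeric(x) && length(unique(x)) > 4)
      "continuous" else "categorical"
    if (length(unique(x)) < 2) {
      return(tibble(variable = v, test = "none", p_value = NA_real_,
                    flagged = FALSE, note = "constant variable"))
    }
    if (type == "categorical") {
      tab <- base::table(x, y)
      suppressWarnings({
        expected <- chisq.test(tab, correct = FALSE)$expected
        if (any(expected < 5)) {
          p <- fisher.test(tab)$p.value
          test <- "fisher"; note <- "expected cell < 5"
        } else {
          p <- chisq.test(tab, correct = FALSE)$p.value
          test <- "chi-square"; note <- NA_character_
        }
      })
    } else {
      norm_ok <- all(vapply(c(0, 1), function(l) {
        g <- x[y == l]
        length(unique(g)) > 2 && shapiro.test(g)$p.value >= 0.05
      }, logical(1)))
      if (norm_ok) {
        p <- t.test(x[y == 1], x[y == 0])$p.value
        test <- "t"; note <- NA_character_
      } else {
        p <- suppressWarnings(wilcox.test(x[y == 1], x[y == 0])$p.value)
        test <- "mann-whitney"; note <- NA_character_
      }
    }
    tibble(variable = v, test = test, p_value = p, flagged = p < alpha,
           note = note)
  })
}

# Logistic fit on a plain numeric design; returns per-term estimate/se/p.
# On separation or non-convergence, refits with a weak ridge penalty
# (IRLS with penalty `ridge` on the non-intercept terms) and warns.
logistic_terms <- function(X, y, ridge_fallback = 1e-4) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  form <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (!sep) {
    sm <- summary(fit)$coefficients
    rownames(sm) <- gsub("^`|`$", "", rownames(sm))
    terms <- tibble(term = rownames(sm)[-1],
                    estimate = sm[-1, 1], se = sm[-1, 2],
                    p_value = sm[-1, 4])
    aliased <- setdiff(colnames(X), terms$term)
    if (length(aliased)) {  # collinear terms dropped by glm: prune them
      terms <- bind_rows(terms, tibble(term = aliased, estimate = NA_real_,
                                       se = NA_real_, p_value = 1))
    }
    return(list(terms = terms,
                intercept = sm[1, 1], separation = FALSE, fit = fit))
  }
  warn("separation or non-convergence detected; refitting with a weak ridge penalty")
  rf <- ridge_logistic(cbind(1, as.matrix(X)), y, ridge_fallback)
  list(terms = tibble(term = colnames(X), estimate = rf$coef[-1],
                      se = rf$se[-1], p_value = rf$p[-1]),
       intercept = rf$coef[1], separation = TRUE, fit = NULL)
}

# Penalized IRLS (ridge on all but the first, intercept, column); Wald
# p-values from the penalized information matrix.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + pen
    gr <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, gr)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  list(coef = drop(beta), se = se, p = 2 * pnorm(-abs(z)))
}

#' Staged univariate/multivariate logistic selection
#'
#' Round (a): a univariate logistic regression per candidate (the
#' Radiomics Score always enters as a candidate), dropping candidates
#' with p >= `alpha`. Round (b): one multivariate logistic fit on the
#' survivors, dropping terms with p >= `alpha`; the fit is repeated until
#' every multivariate p is below `alpha` or nothing remains. This
#' generalizes the published two-round trace (Renin excluded
#' univariately; Aldo-max and BL-TG excluded multivariately) to data of
#' any structure.
#'
#' @param data Tibble containing `label`, the candidate clinical columns
#'   and an `RS` column.
#' @param candidates Candidate variable names (`"RS"` is added if absent).
#' @param alpha Retention level.
#' @return List: `retained` names, `univariate` and `multivariate` trace
#'   tibbles (one row per term and round).
#' @export
staged_logistic_selection <- function(data, candidates, alpha = 0.05) {
  candidates <- unique(candidates)
  if (!"RS" %in% candidates) candidates <- c(candidates, "RS")
  missing <- setdiff(c("label", candidates), names(data))
  if (length(missing)) abort(sprintf("column '%s' absent from data", missing[1]))
  y <- assert_binary_labels(data$label)
  uni <- purrr::map_dfr(candidates, function(v) {
    lt <- logistic_terms(as.matrix(data[v]), y)
    mutate(lt$terms, round = 1L)
  })
  keep <- uni$term[uni$p_value < alpha]
  multi <- tibble(term = character(), estimate = numeric(), se = numeric(),
                  p_value = numeric(), round = integer())
  round_i <- 1L
  while (length(keep) >= 1) {
    lt <- logistic_terms(as.matrix(data[keep]), y)
    multi <- bind_rows(multi, mutate(lt$terms, round = round_i))
    bad <- lt$terms$term[lt$terms$p_value >= alpha]
    if (!length(bad)) break
    keep <- setdiff(keep, bad)
    round_i <- round_i + 1L
  }
  list(retained = keep, univariate = uni, multivariate = multi)
}

#' Fit the Clinical-Radiomic model
#'
#' Maximum-likelihood logistic regression of the label on the retained
#' clinical covariates plus the Radiomics Score; the Clinical-Radiomic
#' Score of a sample is the fitted probability. The Youden cutoff is
#' computed on the derivation data; a different operating cutoff (e.g.
#' the specificity-oriented 0.440) can be set with `adjusted_cutoff`.
#'
#' @param data Tibble with `label`, the retained clinical columns and
#'   `RS`.
#' @param retained Covariate names to enter (must include `"RS"`).
#' @param adjusted_cutoff Optional fixed operating cutoff in (0, 1).
#' @return A `clin_rad_model`.
#' @export
fit_clin_rad <- function(data, retained, adjusted_cutoff = NULL) {
  if (!"RS" %in% retained) abort("`retained` must include \"RS\"")
  y <- assert_binary_labels(data$label)
  lt <- logistic_terms(as.matrix(data[retained]), y)
  beta <- setNames(lt$terms$estimate, lt$terms$term)
  eta <- drop(as.matrix(data[retained]) %*% beta) + lt$intercept
  prob <- stats::plogis(eta)
  yc <- youden_cutoff(prob, y)
  ranges <- purrr::map_dfr(retained, function(v) {
    tibble(term = v, min = min(data[[v]]), max = max(data[[v]]))
  })
  structure(list(terms = lt$terms, intercept = lt$intercept,
                 covariates = retained, ranges = ranges,
                 youden_cutoff = yc$cutoff,
                 adjusted_cutoff = adjusted_cutoff,
                 cutoff = adjusted_cutoff %||% yc$cutoff,
                 separation = lt$separation,
                 derivation_scores = setNames(prob, data$sample_id %||% NULL),
                 derivation_labels = y),
            class = "clin_rad_model")
}

#' @export
print.clin_rad_model <- function(x, ...) {
  cat(sprintf("<clin_rad_model: %s | cutoff %.3f%s>\n",
              paste(x$covariates, collapse = " + "), x$cutoff,
              if (!is.null(x$adjusted_cutoff)) " (adjusted)" else " (Youden)"))
  print(x$terms)
  invisible(x)
}

#' Clinical-Radiomic Score for new samples
#'
#' @param model A `clin_rad_model`.
#' @param data Tibble with the model's covariate columns (incl. `RS`).
#' @return Fitted probabilities in (0, 1).
#' @export
predict_clin_rad <- function(model, data) {
  stopifnot(inherits(model, "clin_rad_model"))
  missing <- setdiff(model$covariates, names(data))
  if (length(missing)) abort(sprintf("column '%s' absent from data", missing[1]))
  beta <- setNames(model$terms$estimate, model$terms$term)
  eta <- drop(as.matrix(data[model$covariates]) %*% beta[model$covariates]) +
    model$intercept
  stats::plogis(eta)
}

#' Nomogram export of a Clinical-Radiomic model
#'
#' Linearizes the logistic model into per-variable point axes: variable
#' `v` at value `x` contributes
#' `points_v(x) = 100 * beta_v * (x - ref_v) / M`, where `ref_v` is the
#' value of `v` minimizing its contribution over the derivation range
#' (the minimum for positive coefficients, the maximum for negative
#' ones, so points are non-negative) and
#' `M = max_w |beta_w| * range_w`. Total points map back to the
#' predicted probability by inverting the logistic link exactly.
#'
#' @param model A `clin_rad_model`.
#' @param n_grid Grid points per variable axis.
#' @param n_total Grid points on the total-points axis.
#' @return A `nomogram` list: `axes` tibble (variable, value, points),
#'   `total` tibble (total_points, probability), and the scaling
#'   constants.
#' @export
export_nomogram <- function(model, n_grid = 11, n_total = 101) {
  stopifnot(inherits(model, "clin_rad_model"))
  beta <- setNames(model$terms$estimate, model$terms$term)
  rng <- model$ranges
  span <- rng$max - rng$min
  if (any(span == 0)) {
    abort(sprintf("variable '%s' has zero range in the derivation data",
                  rng$term[span == 0][1]))
  }
  M <- max(abs(beta[rng$term]) * span)
  ref <- ifelse(beta[rng$term] >= 0, rng$min, rng$max)
  names(ref) <- rng$term
  axes <- purrr::map_dfr(rng$term, function(v) {
    vals <- seq(rng$min[rng$term == v], rng$max[rng$term == v],
                length.out = n_grid)
    tibble(variable = v, value = vals,
           points = 100 * beta[v] * (vals - ref[v]) / M)
  })
  base_eta <- model$intercept + sum(beta[rng$term] * ref)
  tmax <- sum(100 * abs(beta[rng$term]) * span / M)
  total <- tibble(total_points = seq(0, tmax, length.out = n_total))
  total$probability <- stats::plogis(base_eta + total$total_points * M / 100)
  structure(list(axes = axes, total = total, scale = M, reference = ref,
                 base_eta = base_eta),
            class = "nomogram")
}

#' Probability at a given total-points value
#'
#' @param nomogram A `nomogram`.
#' @param total_points Total points value(s).
#' @return Predicted probability.
#' @export
nomogram_probability <- function(nomogram, total_points) {
  stats::plogis(nomogram$base_eta + total_points * nomogram$scale / 100)
}
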