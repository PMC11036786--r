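# Forward-backward stepwise selection on a linear model using partial-F
# p-values (entry p < entry_p, removal p >= removal_p), the convention of
# p-based stepwise routines. Returns the selected term names.
stepwise_select <- function(data, response, candidates,
                            entry_p = 0.05, removal_p = 0.10,
                            max_steps = 100L) {
  selected <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      cur_f <- reformulate(if (length(selected)) selected else "1",
                           response = response)
      fit <- lm(cur_f, data = data)
      scope <- reformulate(c(selected, pool), response = response)
      a <- add1(fit, scope = scope, test = "F")
      cand <- rownames(a)[-1L]
      pv <- a[["Pr(>F)"]][-1L]
      ok <- which(!is.na(pv))
      if (length(ok) > 0L) {
        best <- ok[which.min(pv[ok])]
        if (pv[best] < entry_p) {
          selected <- c(selected, cand[best])
          changed <- TRUE
        }
      }
    }
    # backward
    if (length(selected) > 0L) {
      fit <- lm(reformulate(selected, response = response), data = data)
      dr <- drop1(fit, test = "F")
      terms <- rownames(dr)[-1L]
      pv <- dr[["Pr(>F)"]][-1L]
      worst <- which.max(pv)
      if (length(worst) == 1L && !is.na(pv[worst]) &&
          pv[worst] >= removal_p) {
        selected <- setdiff(selected, terms[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

#' Regress cognition on regional nonrandomness
#'
#' Three-stage procedure relating a global cognitive score (MMSE-like) to
#' per-region structural nonrandomness indices within the case group:
#' \enumerate{
#'   \item Prescreen: univariate linear regression of the score on each
#'     region's index; regions with slope p below \code{prescreen_p}
#'     (default 0.1) are kept.
#'   \item Selection: kept indices are z-scored across the case-group
#'     subjects, then forward-backward stepwise selection (partial-F entry
#'     p < \code{entry_p}, removal p >= \code{removal_p}) picks the model.
#'   \item Adjustment: the selected model is refit with age, sex and
#'     education as covariates; per-region beta, SE and p are reported at
#'     \code{alpha}.
#' }
#'
#' @param indices numeric matrix, subjects x regions, of nonrandomness
#'   indices for the case group; column names identify regions.
#' @param subjects data.frame aligned with \code{indices} rows, with
#'   columns \code{cognitive_score}, \code{age}, \code{sex},
#'   \code{education} (no missing values).
#' @param prescreen_p univariate screening threshold (default 0.1).
#' @param alpha significance level for the adjusted model (default 0.05).
#' @param entry_p,removal_p stepwise entry/removal p thresholds
#'   (defaults 0.05 / 0.10).
#' @param min_subjects minimum case-group size (default 10).
#' @return A \code{cognition_regression} object: prescreen table, selected
#'   regions, the stepwise and covariate-adjusted \code{lm} fits, a
#'   coefficient table (beta on the z-scored index scale, SE, p,
#'   significant), and the thresholds used.
#' @export
cognition_regression <- function(indices, subjects,
                                 prescreen_p = 0.1, alpha = 0.05,
                                 entry_p = 0.05, removal_p = 0.10,
                                 min_subjects = 10L) {
  indices <- as.matrix(indices)
  n <- nrow(indices)
  if (n < min_subjects)
    stop(sprintf("insufficient data: %d case subjects, need >= %d",
                 n, min_subjects), call. = FALSE)
  if (nrow(subjects) != n)
    stop("subjects table and index matrix disagree on subject count",
         call. = FALSE)
  need <- c("cognitive_score", "age", "sex", "education")
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0L)
    stop(sprintf("subjects table missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyNA(indices) || anyNA(subjects[need]))
    stop("missing values among regression entrants", call. = FALSE)
  if (is.null(colnames(indices)))
    colnames(indices) <- sprintf("region_%d", seq_len(ncol(indices)))
  regions <- colnames(indices)
  score <- subjects$cognitive_score

  # stage 1: univariate prescreen (a constant score admits no association)
  pre_p <- if (sd(score) == 0) rep(NA_real_, ncol(indices)) else
    apply(indices, 2L, function(x) {
      if (sd(x) == 0) return(NA_real_)
      f <- lm(score ~ x)
      summary(f)$coefficients["x", "Pr(>|t|)"]
    })
  prescreen <- data.frame(region = regions, p = unname(pre_p),
                          kept = !is.na(pre_p) & pre_p < prescreen_p)
  kept <- regions[prescreen$kept]

  empty_report <- function() {
    structure(list(prescreen = prescreen, selected = character(0),
                   model = NULL, adjusted = NULL,
                   coefficients = data.frame(region = character(0),
                                             beta = numeric(0),
                                             se = numeric(0),
                                             p = numeric(0),
                                             significant = logical(0)),
                   scaling = NULL,
                   thresholds = list(prescreen_p = prescreen_p,
                                     alpha = alpha, entry_p = entry_p,
                                     removal_p = removal_p),
                   n = n),
              class = "cognition_regression")
  }
  if (length(kept) == 0L) return(empty_report())

  # stage 2: z-score kept indices over the case group, stepwise selection
  centers <- colMeans(indices[, kept, drop = FALSE])
  scales <- apply(indices[, kept, drop = FALSE], 2L, sd)
  z <- scale(indices[, kept, drop = FALSE], center = centers,
             scale = scales)
  safe <- make.names(kept, unique = TRUE)
  dd <- data.frame(cognitive_score = score, z)
  names(dd) <- c("cognitive_score", safe)
  selected_safe <- stepwise_select(dd, "cognitive_score", safe,
                                   entry_p = entry_p,
                                   removal_p = removal_p)
  selected <- kept[match(selected_safe, safe)]
  if (length(selected) == 0L) return(empty_report())

  model <- lm(reformulate(selected_safe, response = "cognitive_score"),
              data = dd)

  # stage 3: covariate adjustment (age, sex, education)
  dd_adj <- cbind(dd, subjects[, c("age", "sex", "education")])
  if (!is.numeric(dd_adj$sex)) dd_adj$sex <- factor(dd_adj$sex)
  adj_f <- reformulate(c(selected_safe, "age", "sex", "education"),
                       response = "cognitive_score")
  adjusted <- lm(adj_f, data = dd_adj)
  cc <- summary(adjusted)$coefficients
  aliased <- setdiff(selected_safe, rownames(cc))
  if (length(aliased) > 0L)
    warning(sprintf("rank-deficient design: dropped %s",
                    paste(kept[match(aliased, safe)], collapse = ", ")),
            call. = FALSE)
  keep_rows <- intersect(selected_safe, rownames(cc))
  coefs <- data.frame(region = kept[match(keep_rows, safe)],
                      beta = cc[keep_rows, "Estimate"],
                      se = cc[keep_rows, "Std. Error"],
                      p = cc[keep_rows, "Pr(>|t|)"],
                      row.names = NULL)
  coefs$significant <- coefs$p < alpha

  structure(list(prescreen = prescreen, selected = selected,
                 model = model, adjusted = adjusted,
                 coefficients = coefs,
                 scaling = list(center = centers, scale = scales),
                 thresholds = list(prescreen_p = prescreen_p,
                                   alpha = alpha, entry_p = entry_p,
                                   removal_p = removal_p),
                 n = n),
            class = "cognition_regression")
}

#' @export
print.cognition_regression <- function(x, ...) {
  cat("Cognition ~ regional nonrandomness (n = ", x$n, ")\n", sep = "")
  cat("  prescreened: ", sum(x$prescreen$kept), " of ",
      nrow(x$prescreen), " regions (p < ",
      format(x$thresholds$prescreen_p), ")\n", sep = "")
  if (length(x$selected) == 0L) {
    cat("  no region selected\n")
    return(invisible(x))
  }
  cat("  selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  covariate-adjusted coefficients (z-scored indices):\n")
  print.data.frame(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cognition_regression <- function(object, ...) {
  if (is.null(object$adjusted)) {
    cat("Empty selection; nothing to summarise beyond the prescreen.\n")
    return(invisible(object$prescreen))
  }
  summary(object$adjusted)
}

#' @export
coef.cognition_regression <- function(object, ...) {
  setNames(object$coefficients$beta, object$coefficients$region)
}
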