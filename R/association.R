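# Association analyses relating M1 inter-parcel correlations to diagnosis:
# per-subtype summary statistics, three nested multinomial models per pair
# (likelihood-ratio tested), and per-pair binary logistic regressions.

conn_matrix <- function(features) {
  X <- as.matrix(as.data.frame(features)[, m1_pair_labels(), drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Per-subtype means and SDs of inter-parcel correlations
#'
#' Sample mean and SD of each of the 10 canonical parcel-pair correlations
#' for the overall sample and for the TD, ADHD-combined, and
#' ADHD-inattentive groups (groups absent from the data are omitted with a
#' warning).
#'
#' @param features matrix/data.frame with the 10 canonical pair columns.
#' @param labels diagnosis labels.
#' @return Long data.frame with columns `group`, `pair`, `mean`, `sd`, `n`.
#' @export
subtype_correlation_summary <- function(features, labels) {
  X <- conn_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  groups <- list(OVERALL = rep(TRUE, nrow(X)),
                 TD = labels == "TD",
                 COMBINED = labels == "COMBINED",
                 INATTENTIVE = labels == "INATTENTIVE")
  res <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (sum(sel) < 2L) {
      warning("group ", g, " has fewer than 2 subjects; omitted")
      next
    }
    res[[g]] <- data.frame(
      group = g, pair = m1_pair_labels(),
      mean = colMeans(X[sel, , drop = FALSE]),
      sd = apply(X[sel, , drop = FALSE], 2L, stats::sd),
      n = sum(sel), row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

multinom_deviance <- function(formula, data) {
  fit <- nnet::multinom(formula, data = data, trace = FALSE, maxit = 500L)
  list(deviance = fit$deviance, converged = fit$convergence == 0)
}

#' Nested multinomial models of diagnosis on each parcel-pair correlation
#'
#' Three-level outcome (TD, ADHD combined, ADHD inattentive; the rare
#' hyperactive subtype is excluded). For each of the 10 pairs, three
#' likelihood-ratio tests of the pair's coefficients: Model 1 adjusts for
#' nothing, Model 2 for age, composite IQ, gender, and handedness, Model 3
#' additionally for site. The likelihood-ratio statistic is the deviance
#' difference of the nested fits on a chi-square with (levels - 1) degrees
#' of freedom.
#'
#' @param features matrix/data.frame with the 10 canonical pair columns.
#' @param covariates data.frame with `age`, `iq_composite`, `gender`,
#'   `handedness`, `site` (no missing values).
#' @param labels diagnosis labels.
#' @return data.frame with columns `pair`, `model`, `p_value`, `flag`
#'   (`""`, `"degenerate"`, or `"nonconvergence"`).
#' @export
subtype_association_models <- function(features, covariates, labels) {
  X <- conn_matrix(features)
  labels <- as.character(labels)
  keep <- labels %in% c("TD", "COMBINED", "INATTENTIVE")
  X <- X[keep, , drop = FALSE]
  cov <- as.data.frame(covariates)[keep, , drop = FALSE]
  need <- c("age", "iq_composite", "gender", "handedness", "site")
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols)) {
    stop("covariates lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(cov[need])) stop("covariates contain missing values; impute first")
  y <- droplevels(factor(labels[keep], levels = c("TD", "COMBINED", "INATTENTIVE")))
  if (nlevels(y) < 2L) stop("need at least two outcome levels")
  df_pair <- nlevels(y) - 1L
  rhs <- list(`1` = "1",
              `2` = "age + iq_composite + gender + handedness",
              `3` = "age + iq_composite + gender + handedness + site")
  out <- list()
  for (pair in m1_pair_labels()) {
    d <- data.frame(y = y, x = X[, pair], cov[need])
    degenerate <- stats::sd(d$x) == 0
    for (m in names(rhs)) {
      p <- NA_real_; flag <- ""
      if (degenerate) {
        flag <- "degenerate"
      } else {
        res <- tryCatch({
          f0 <- multinom_deviance(stats::as.formula(paste("y ~", rhs[[m]])), d)
          f1 <- multinom_deviance(stats::as.formula(paste("y ~ x +", rhs[[m]])), d)
          lr <- f0$deviance - f1$deviance
          list(p = stats::pchisq(max(lr, 0), df = df_pair, lower.tail = FALSE),
               ok = f0$converged && f1$converged)
        }, error = function(e) NULL)
        if (is.null(res)) {
          flag <- "nonconvergence"
        } else {
          p <- res$p
          if (!res$ok) flag <- "nonconvergence"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        pair = pair, model = paste0("Model", m), p_value = p, flag = flag,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Per-pair logistic regressions of ADHD status
#'
#' Binary outcome (TD = 0, any ADHD = 1). Each of the 10 models contains one
#' parcel-pair correlation plus the four demographic covariates (age,
#' composite IQ, gender, handedness); site can optionally be added for a
#' direction-stability check.
#'
#' @param features matrix/data.frame with the 10 canonical pair columns.
#' @param covariates data.frame with `age`, `iq_composite`, `gender`,
#'   `handedness` (and `site` if `include_site`).
#' @param labels diagnosis labels (collapsed to TD vs ADHD) or a 0/1 vector.
#' @param include_site add site to the adjustment set.
#' @return data.frame with columns `pair`, `estimate`, `direction`,
#'   `p_value`, `converged`.
#' @export
pairwise_logistic_models <- function(features, covariates, labels,
                                     include_site = FALSE) {
  X <- conn_matrix(features)
  if (is.numeric(labels)) {
    y <- as.integer(labels != 0)
  } else {
    y <- as.integer(as.character(labels) != "TD")
  }
  stopifnot(length(y) == nrow(X))
  cov <- as.data.frame(covariates)
  need <- c("age", "iq_composite", "gender", "handedness",
            if (include_site) "site")
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols)) {
    stop("covariates lack columns: ", paste(missing_cols, collapse = ", "))
  }
  rhs <- paste(c("x", need), collapse = " + ")
  out <- lapply(m1_pair_labels(), function(pair) {
    d <- data.frame(y = y, x = X[, pair], cov[need])
    fit <- tryCatch(
      suppressWarnings(stats::glm(stats::as.formula(paste("y ~", rhs)),
                                  family = stats::binomial(), data = d)),
      error = function(e) NULL
    )
    if (is.null(fit) || !"x" %in% rownames(summary(fit)$coefficients)) {
      return(data.frame(pair = pair, estimate = NA_real_, direction = NA_integer_,
                        p_value = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    co <- summary(fit)$coefficients["x", ]
    data.frame(pair = pair, estimate = unname(co["Estimate"]),
               direction = as.integer(sign(co["Estimate"])),
               p_value = unname(co["Pr(>|z|)"]),
               converged = fit$converged && abs(co["Estimate"]) < 50,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
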