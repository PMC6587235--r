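#' Intraclass correlation coefficient from a complete ratings table
#'
#' Estimates the ICC by the two-way ANOVA decomposition of a complete
#' subjects x raters design into between-subject (`MSR`), between-rater
#' (`MSC`) and residual (`MSE`) mean squares.  The default form is the
#' two-way random-effects, absolute-agreement, single-measures ICC
#' (appropriate when raters are interchangeable):
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' The consistency form (two-way mixed, single measures) drops the rater
#' variance term.  Confidence intervals use the standard F-distribution
#' intervals for each form, with a Satterthwaite degrees-of-freedom
#' approximation for the absolute-agreement case.
#'
#' @param ratings long-format data frame with columns `subject_id`,
#'   `rater_id`, `value` (a `variable` column is allowed if constant), or
#'   an n x k numeric matrix (subjects in rows).
#' @param model `"two_way_random_absolute_single"` (default) or
#'   `"two_way_mixed_consistency_single"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class `reliability_result`: a list with `icc`,
#'   `ci_low`, `ci_high`, `band`, `n_subjects`, `k_raters`, `model`, the
#'   three mean squares, and the grand mean.
#' @examples
#' set.seed(1)
#' r <- simulate_ratings(mu = 12, sigma_subject = 3, sigma_rater = 0.5,
#'                       sigma_error = 0.5, n_subjects = 13, k_raters = 2,
#'                       seed = 1)
#' icc(r)
#' @export
icc <- function(ratings,
                model = c("two_way_random_absolute_single",
                          "two_way_mixed_consistency_single"),
                conf_level = 0.95) {
  model <- match.arg(model)
  Y <- ratings_matrix(ratings)
  n <- nrow(Y); k <- ncol(Y)
  ms <- anova_mean_squares(Y)

  if (ms$MSR < 1e-300 && ms$MSE < 1e-300 && ms$MSC < 1e-300) {
    stop("ratings have zero total variance; ICC is undefined", call. = FALSE)
  }

  est <- switch(model,
    two_way_random_absolute_single =
      (ms$MSR - ms$MSE) /
        (ms$MSR + (k - 1) * ms$MSE + k * (ms$MSC - ms$MSE) / n),
    two_way_mixed_consistency_single =
      (ms$MSR - ms$MSE) / (ms$MSR + (k - 1) * ms$MSE))

  ci <- icc_confint(est, ms, n, k, model, conf_level)

  res <- list(icc = est,
              ci_low = min(ci[1], est), ci_high = max(ci[2], est),
              band = classify_icc(min(est, 1)),
              n_subjects = n, k_raters = k, model = model,
              conf_level = conf_level,
              MSR = ms$MSR, MSC = ms$MSC, MSE = ms$MSE,
              grand_mean = ms$grand_mean)
  class(res) <- "reliability_result"
  res
}

icc_confint <- function(est, ms, n, k, model, conf_level) {
  alpha <- 1 - conf_level
  # Perfect agreement: the F intervals degenerate (zero residual variance).
  if (ms$MSE < 1e-300) return(c(est, est))
  if (model == "two_way_mixed_consistency_single") {
    F0 <- ms$MSR / ms$MSE
    df2 <- (n - 1) * (k - 1)
    FL <- F0 / qf(1 - alpha / 2, n - 1, df2)
    FU <- F0 * qf(1 - alpha / 2, df2, n - 1)
    c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    r <- est
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * ms$MSC + b * ms$MSE)^2 /
      ((a * ms$MSC)^2 / (k - 1) + (b * ms$MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    low <- n * (ms$MSR - FL * ms$MSE) /
      (FL * (k * ms$MSC + (k * n - k - n) * ms$MSE) + n * ms$MSR)
    high <- n * (FU * ms$MSR - ms$MSE) /
      (k * ms$MSC + (k * n - k - n) * ms$MSE + n * FU * ms$MSR)
    c(low, high)
  }
}

anova_mean_squares <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  m <- mean(Y)
  mi <- rowMeans(Y)
  mj <- colMeans(Y)
  SSR <- k * sum((mi - m)^2)
  SSC <- n * sum((mj - m)^2)
  SST <- sum((Y - m)^2)
  SSE <- max(SST - SSR - SSC, 0)
  list(MSR = SSR / (n - 1),
       MSC = SSC / (k - 1),
       MSE = SSE / ((n - 1) * (k - 1)),
       grand_mean = m)
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f  %g%% CI [%.3f, %.3f]  (%s)\n",
              x$model, x$icc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$band))
  cat(sprintf("  n = %d subjects, k = %d raters\n", x$n_subjects, x$k_raters))
  if (!is.null(x$sem)) {
    cat(sprintf("  SEM = %.4g, MDC = %.4g\n", x$sem, x$mdc))
  }
  invisible(x)
}

#' Qualitative band for an ICC value
#'
#' Classifies the ICC on the conventional verbal scale: poor below 0.20,
#' fair 0.21-0.40, moderate 0.41-0.60, good 0.61-0.80, very good
#' 0.81-1.00.  The published cut-points leave gaps (e.g. between 0.20 and
#' 0.21), so the implementation uses half-open intervals at the midpoints
#' (0.205, 0.405, 0.605, 0.805) so that every real value gets a band.
#'
#' @param icc_value numeric ICC value(s), each at most 1.
#' @return character vector of bands.
#' @examples
#' classify_icc(c(0, 0.78, 0.93))
#' @export
classify_icc <- function(icc_value) {
  if (any(icc_value > 1 + 1e-12, na.rm = TRUE)) {
    stop("ICC values cannot exceed 1", call. = FALSE)
  }
  bands <- c("poor", "fair", "moderate", "good", "very_good")
  bands[findInterval(icc_value, c(0.205, 0.405, 0.605, 0.805)) + 1L]
}

#' Standard error of measurement
#'
#' The error attached to a single measurement, in the units of the
#' measure.  The default classic formula is the pooled standard deviation
#' of all measurements times `sqrt(1 - ICC)`; the ANOVA variant takes the
#' square root of the residual mean square of the two-way decomposition.
#'
#' @param ratings a ratings table or matrix as in [icc()].
#' @param icc_value the ICC to plug in (required by `"sd_sqrt"`).
#' @param method `"sd_sqrt"` (default) or `"anova_error"`.
#' @return SEM in measurement units.
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.1))
#' sem(m, icc(m)$icc)
#' @export
sem <- function(ratings, icc_value = NULL,
                method = c("sd_sqrt", "anova_error")) {
  method <- match.arg(method)
  Y <- ratings_matrix(ratings)
  if (method == "anova_error") {
    return(sqrt(anova_mean_squares(Y)$MSE))
  }
  if (is.null(icc_value)) {
    stop("icc_value is required for the sd_sqrt method", call. = FALSE)
  }
  if (!is.finite(icc_value) || icc_value > 1 || icc_value < -1) {
    stop("icc_value must lie in [-1, 1]", call. = FALSE)
  }
  sd(as.vector(Y)) * sqrt(1 - icc_value)
}

#' Minimal detectable change
#'
#' The smallest change between repeated measurements that exceeds
#' measurement error: `MDC = z * sqrt(2) * SEM`.  The default multiplier
#' is `z = 1` (MDC = sqrt(2) x SEM), the relationship this package's
#' reference reliability tables follow; the conventional MDC95 is obtained
#' with `z = qnorm(0.975)`.
#'
#' @param sem_value non-negative SEM value(s).
#' @param z normal-quantile multiplier (default 1).
#' @return MDC in measurement units.
#' @examples
#' round(mdc(1.74), 2)   # 2.46
#' @export
mdc <- function(sem_value, z = 1) {
  if (any(!is.finite(sem_value)) || any(sem_value < 0)) {
    stop("sem_value must be non-negative and finite", call. = FALSE)
  }
  z * sqrt(2) * sem_value
}

#' Concurrent validity between two measurement methods
#'
#' Treats the two methods as the two "raters" of a two-column ratings
#' design and runs [icc()] on it, pairing observations by subject.
#'
#' @param method_a,method_b numeric vectors named by subject, or data
#'   frames with columns `subject_id` and `value`.
#' @param model,conf_level passed to [icc()].
#' @return A `reliability_result` as from [icc()].
#' @export
concurrent_validity <- function(method_a, method_b,
                                model = "two_way_random_absolute_single",
                                conf_level = 0.95) {
  a <- method_values(method_a, "method_a")
  b <- method_values(method_b, "method_b")
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) {
      stop("unnamed method vectors must have equal length", call. = FALSE)
    }
  } else {
    if (!setequal(names(a), names(b))) {
      stop("methods measure different subject sets; cannot pair", call. = FALSE)
    }
    b <- b[names(a)]
  }
  icc(cbind(a, b), model = model, conf_level = conf_level)
}

method_values <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("subject_id", "value") %in% names(x))) {
      stop(sprintf("%s needs columns subject_id, value", what), call. = FALSE)
    }
    if (anyDuplicated(x$subject_id)) {
      stop(sprintf("%s has duplicated subjects", what), call. = FALSE)
    }
    stats::setNames(x$value, as.character(x$subject_id))
  } else {
    stats::setNames(as.numeric(x), names(x))
  }
}

#' Sample size for an ICC reliability study
#'
#' Smallest number of subjects for which a one-sided test of
#' `H0: ICC = rho0` against the expected `rho1 > rho0`, at level `alpha`,
#' reaches the requested power, using the variance-stabilising
#' transformation of the ICC for `k` replicates,
#' `u(rho) = log((1 + (k-1) rho) / (1 - rho)) / 2`, with approximate
#' variance `k / (2 (k-1) (n-2))`.
#'
#' @param rho0 null (minimally acceptable) ICC.
#' @param rho1 expected ICC, greater than `rho0`.
#' @param alpha one-sided type-I error rate.
#' @param power target power.
#' @param k observations (raters/sessions) per subject.
#' @return Required number of subjects (integer, rounded up).
#' @examples
#' sample_size_icc(rho0 = 0.75, rho1 = 0.95, alpha = 0.05, power = 0.80, k = 2)
#' @export
sample_size_icc <- function(rho0, rho1, alpha = 0.05, power = 0.80, k = 2) {
  if (!(rho0 >= 0 && rho0 < rho1 && rho1 < 1)) {
    stop("need 0 <= rho0 < rho1 < 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must be in (0, 0.5)",
                                        call. = FALSE)
  if (!(power > 0.5 && power < 1)) stop("power must be in (0.5, 1)",
                                        call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  u <- function(rho) 0.5 * log((1 + (k - 1) * rho) / (1 - rho))
  zq <- qnorm(1 - alpha) + qnorm(power)
  n <- 2 + k * zq^2 / (2 * (k - 1) * (u(rho1) - u(rho0))^2)
  as.integer(ceiling(n - 1e-9))
}

#' Full reliability summary of a ratings table
#'
#' Convenience wrapper combining [icc()], [sem()] and [mdc()] for each
#' variable of a long-format ratings table, mirroring the column layout of
#' published reliability tables (ICC, CI, band, mean, SEM, MDC).
#'
#' @param ratings long-format data frame with columns `subject_id`,
#'   `rater_id`, `variable`, `value`.
#' @param model,conf_level passed to [icc()].
#' @param sem_method passed to [sem()].
#' @param z passed to [mdc()].
#' @return A data frame with one row per variable.
#' @export
reliability_table <- function(ratings,
                              model = "two_way_random_absolute_single",
                              sem_method = "sd_sqrt",
                              conf_level = 0.95, z = 1) {
  stopifnot(is.data.frame(ratings),
            all(c("subject_id", "rater_id", "value") %in% names(ratings)))
  if (!"variable" %in% names(ratings)) ratings$variable <- "value"
  vars <- unique(ratings$variable)
  rows <- lapply(vars, function(v) {
    sub <- ratings[ratings$variable == v, ]
    fit <- icc(sub, model = model, conf_level = conf_level)
    s <- sem(sub, fit$icc, method = sem_method)
    data.frame(variable = v,
               icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
               band = fit$band, mean = fit$grand_mean,
               sem = s, mdc = mdc(s, z = z),
               n_subjects = fit$n_subjects, k_raters = fit$k_raters,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Accepts long data frame (subject_id, rater_id, value) or an n x k matrix;
# enforces a complete design with each cell observed exactly once.
ratings_matrix <- function(ratings) {
  if (is.matrix(ratings)) {
    Y <- ratings
  } else if (is.data.frame(ratings)) {
    need <- c("subject_id", "rater_id", "value")
    if (!all(need %in% names(ratings))) {
      stop("ratings need columns subject_id, rater_id, value", call. = FALSE)
    }
    if ("variable" %in% names(ratings) &&
        length(unique(ratings$variable)) > 1L) {
      stop("ratings contain multiple variables; subset to one (or use reliability_table)",
           call. = FALSE)
    }
    subj <- factor(ratings$subject_id)
    rat <- factor(ratings$rater_id)
    tab <- table(subj, rat)
    if (any(tab != 1L)) {
      stop("incomplete ratings design: each (subject, rater) cell must appear exactly once",
           call. = FALSE)
    }
    Y <- matrix(NA_real_, nlevels(subj), nlevels(rat),
                dimnames = list(levels(subj), levels(rat)))
    Y[cbind(as.integer(subj), as.integer(rat))] <- ratings$value
  } else {
    stop("ratings must be a data frame or matrix", call. = FALSE)
  }
  if (anyNA(Y)) stop("ratings contain missing cells", call. = FALSE)
  if (nrow(Y) < 2L || ncol(Y) < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  storage.mode(Y) <- "double"
  Y
}
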