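# Paired 2D-versus-3D validation statistics: per-angle descriptives,
# normality screening and the paired Student's t-test, reported in the
# shape of a method-agreement table. The statistics are computed from
# their formulas; general-purpose library routines serve only as
# independent cross-checks in the test suite.

#' Mean and sample SD of a set of angle measurements
#'
#' @param values Numeric vector, n >= 2.
#' @return A tibble with columns `mean`, `sd`, `n`.
#' @export
angle_descriptives <- function(values) {
  check_values(values, min_n = 2)
  n <- length(values)
  m <- sum(values) / n
  s <- sqrt(sum((values - m)^2) / (n - 1))
  tibble(mean = m, sd = s, n = n)
}

check_values <- function(values, min_n) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("Values must be finite numbers.", class = "trk_error_insufficient_data")
  }
  if (length(values) < min_n) {
    abort(sprintf("Insufficient data: need at least %d values, got %d.",
                  min_n, length(values)),
          class = "trk_error_insufficient_data")
  }
  invisible(values)
}

#' Kolmogorov-Smirnov normality check with estimated parameters
#'
#' Computes the one-sample KS distance between the empirical CDF and the
#' normal CDF with the sample mean and SD. Because the parameters are
#' estimated, the default p-value uses the Lilliefors correction: a seeded
#' Monte-Carlo null distribution of the same statistic for samples up to
#' n = 500, and the Dallal-Wilkinson closed-form approximation beyond.
#' `method = "naive"` returns the uncorrected (anticonservative)
#' Kolmogorov asymptotic p instead. The statistic is returned for any
#' n >= 3 with positive SD; a p-value requires n >= 4.
#'
#' @param values Numeric vector.
#' @param method `"lilliefors"` (default) or `"naive"`.
#' @param B Monte-Carlo replicates for the Lilliefors p.
#' @param mc_seed Seed of the Monte-Carlo null (fixed for reproducibility).
#' @return A tibble with columns `statistic`, `p_value` (NA when n < 4),
#'   `n`, `method`.
#' @export
ks_normality <- function(values, method = c("lilliefors", "naive"),
                         B = 10000, mc_seed = 20230713) {
  method <- match.arg(method)
  check_values(values, min_n = 3)
  n <- length(values)
  if (sd(values) < .Machine$double.eps^0.5) {
    abort("Zero variance: the KS normality statistic is undefined.",
          class = "trk_error_zero_variance")
  }
  D <- lilliefors_statistic(values)
  p <- NA_real_
  if (n >= 4) {
    p <- if (method == "naive") {
      kolmogorov_p(sqrt(n) * D)
    } else if (n <= 500) {
      withr::with_seed(mc_seed, {
        null_D <- vapply(seq_len(B), function(b) {
          lilliefors_statistic(rnorm(n))
        }, 0)
        (1 + sum(null_D >= D)) / (B + 1)
      })
    } else {
      dallal_wilkinson_p(D, n)
    }
  }
  tibble(statistic = D, p_value = p, n = n, method = method)
}

# sup-distance between the ECDF and the fitted normal CDF.
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean = mean(x), sd = sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

# Asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2).
kolmogorov_p <- function(lambda) {
  if (lambda < 1e-6) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

# Dallal & Wilkinson (1986) approximation to the Lilliefors p-value.
dallal_wilkinson_p <- function(D, n) {
  nd <- if (n > 100) 100 else n
  Kd <- if (n > 100) D * (n / 100)^0.49 else D
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) -
             0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  min(1, max(0, p))
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test on elementwise differences `d = values_2d -
#' values_3d`: `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom. Swapping the inputs negates `t` and preserves `p`. A constant
#' difference vector (all pairs shifted identically, including the
#' identical-inputs case) has zero variance and is refused.
#'
#' @param values_2d,values_3d Numeric vectors of equal length n >= 2.
#' @return A tibble with columns `t`, `df`, `p_value`, `mean_diff`,
#'   `sd_diff`, `n`.
#' @export
paired_t <- function(values_2d, values_3d) {
  if (length(values_2d) != length(values_3d)) {
    abort("Paired samples must have equal lengths.",
          class = "trk_error_length_mismatch")
  }
  check_values(values_2d, min_n = 2)
  check_values(values_3d, min_n = 2)
  d <- values_2d - values_3d
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d < .Machine$double.eps^0.5) {
    msg <- if (all(abs(d) < .Machine$double.eps^0.5)) {
      "Zero variance of differences: the two samples are identical."
    } else {
      "Zero variance of differences: the samples differ by a constant shift."
    }
    abort(msg, class = "trk_error_zero_variance")
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  tibble(t = t_stat, df = n - 1,
         p_value = 2 * pt(-abs(t_stat), df = n - 1),
         mean_diff = mean(d), sd_diff = sd_d, n = n)
}

#' Paired 2D-versus-3D cohort comparison
#'
#' Runs the full method-agreement procedure per variable: descriptives of
#' the 2D and 3D measurements, KS normality of each, and the paired
#' t-test, flagged at `alpha`. Per-variable failures (zero variance,
#' insufficient data) are collected into the `note` column, not thrown.
#'
#' @param data A tibble with columns `variable`, `value_2d`, `value_3d`
#'   (one row per subject and variable), e.g. from [cohort_angle_table()].
#' @param alpha Significance level.
#' @param ks_method Passed to [ks_normality()].
#' @return A `cohort_comparison` tibble: one row per variable with means,
#'   SDs, normality p-values, `t`, `df`, `p_value`, `significant`, `note`.
#' @export
compare_2d_3d_cohort <- function(data, alpha = 0.05,
                                 ks_method = c("lilliefors", "naive")) {
  ks_method <- match.arg(ks_method)
  if (!all(c("variable", "value_2d", "value_3d") %in% names(data))) {
    abort("`data` needs columns variable, value_2d, value_3d.",
          class = "trk_error_malformed")
  }
  rows <- lapply(split(data, data$variable), function(dd) {
    out <- tibble(variable = dd$variable[1], n = nrow(dd),
                  mean_2d = NA_real_, sd_2d = NA_real_,
                  mean_3d = NA_real_, sd_3d = NA_real_,
                  ks_p_2d = NA_real_, ks_p_3d = NA_real_,
                  t = NA_real_, df = NA_real_, p_value = NA_real_,
                  significant = NA, note = NA_character_)
    tryCatch({
      d2 <- angle_descriptives(dd$value_2d)
      d3 <- angle_descriptives(dd$value_3d)
      out$mean_2d <- d2$mean; out$sd_2d <- d2$sd
      out$mean_3d <- d3$mean; out$sd_3d <- d3$sd
      out$ks_p_2d <- ks_normality(dd$value_2d, method = ks_method)$p_value
      out$ks_p_3d <- ks_normality(dd$value_3d, method = ks_method)$p_value
      tt <- paired_t(dd$value_2d, dd$value_3d)
      out$t <- tt$t; out$df <- tt$df; out$p_value <- tt$p_value
      out$significant <- tt$p_value < alpha
    }, error = function(e) out$note <<- conditionMessage(e))
    out
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(variable = character(), n = integer(),
           mean_2d = double(), sd_2d = double(),
           mean_3d = double(), sd_3d = double(),
           ks_p_2d = double(), ks_p_3d = double(),
           t = double(), df = double(), p_value = double(),
           significant = logical(), note = character())
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("cohort_comparison", class(tibble()))
  out
}

#' Measure the paired 2D/3D angle table of a cohort
#'
#' Runs the 2D vertex-angle analysis and the 3D trace-convention analysis
#' on every subject of a generated cohort and assembles the long paired
#' table consumed by [compare_2d_3d_cohort()]. Subjects whose geometry
#' fails are skipped with a warning.
#'
#' @param cohort A cohort tibble from [generate_cohort()], or any tibble
#'   with list-columns `lm3d` and `lm2d`.
#' @param convention 3D angle convention.
#' @return A tibble with columns `subject`, `variable`, `value_2d`,
#'   `value_3d`.
#' @export
cohort_angle_table <- function(cohort, convention = c("trace", "dihedral")) {
  convention <- match.arg(convention)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    tryCatch({
      a3 <- measure_angles_3d(build_individual_track_3d(cohort$lm3d[[i]]),
                              convention = convention)
      a2 <- measure_angles_2d(build_individual_track_2d(cohort$lm2d[[i]]))
      tibble(subject = cohort$subject[i] %||% i,
             variable = a2$angle,
             value_2d = a2$value,
             value_3d = a3$value[match(a2$angle, a3$angle)])
    }, error = function(e) {
      warn(sprintf("Skipping subject %s: %s", i, conditionMessage(e)))
      NULL
    })
  })
  kept <- dplyr::bind_rows(rows)
  if (!nrow(kept)) {
    abort("No analyzable subjects in the cohort.",
          class = "trk_error_insufficient_data")
  }
  kept
}
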