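TABLE1_MD5 <- "7e6039e3a508bbeccde09e9f58679310"

#' Load the packaged RF-ablation record table
#'
#' Twelve in-vivo radiofrequency ablations on three sheep: delivered power
#' (W), duration (s), energy (J), maximal temperature rise (degC) and the 2D
#' lesion dimensions measured on thermal-dose maps and on post-ablation
#' T1-weighted images (mm, printed to 0.5 mm). The invariant
#' `energy = power * duration` is validated on load, as is the file checksum.
#'
#' @param path CSV path; defaults to the packaged fixture
#'   `table1_ablations.csv`.
#' @param verify_checksum validate the packaged file's MD5 (set `FALSE` for
#'   user-supplied tables).
#' @return A tibble of 12 `AblationRecord` rows with columns `sheep_id`,
#'   `rfa_id`, `power_w`, `duration_s`, `energy_j`, `temp_max_c`,
#'   `td_d1_mm`, `td_d2_mm`, `t1w_d1_mm`, `t1w_d2_mm`.
#' @export
load_table1 <- function(path = system.file("extdata", "table1_ablations.csv",
                                           package = "cardiotherm"),
                        verify_checksum = missing(path)) {
  if (verify_checksum) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE1_MD5)) {
      stop("ablation table fixture is corrupted (checksum mismatch)",
           call. = FALSE)
    }
  }
  d <- tibble::as_tibble(utils::read.csv(path))
  need <- c("sheep_id", "rfa_id", "power_w", "duration_s", "energy_j",
            "temp_max_c", "td_d1_mm", "td_d2_mm", "t1w_d1_mm", "t1w_d2_mm")
  if (!all(need %in% names(d))) {
    stop("ablation table is missing required columns", call. = FALSE)
  }
  if (any(d$energy_j != d$power_w * d$duration_s)) {
    stop("ablation table violates energy = power x duration", call. = FALSE)
  }
  dims <- d[c("td_d1_mm", "td_d2_mm", "t1w_d1_mm", "t1w_d2_mm")]
  if (any(as.matrix(dims) <= 0)) {
    stop("lesion dimensions must be positive", call. = FALSE)
  }
  d
}

#' Summarise RF delivery across ablation records
#'
#' @param records ablation tibble as from [load_table1()] (>= 2 rows).
#' @return One-row tibble: mean/sd power (W), mean/sd duration (s), mean/sd
#'   energy (kJ) and the energy range (kJ). Sample statistics use the n - 1
#'   denominator.
#' @export
energy_summary <- function(records) {
  if (nrow(records) < 2) stop("need at least 2 records", call. = FALSE)
  tibble::tibble(
    n = nrow(records),
    power_mean_w = mean(records$power_w),
    power_sd_w = stats::sd(records$power_w),
    duration_mean_s = mean(records$duration_s),
    duration_sd_s = stats::sd(records$duration_s),
    energy_mean_kj = mean(records$energy_j) / 1000,
    energy_sd_kj = stats::sd(records$energy_j) / 1000,
    energy_min_kj = min(records$energy_j) / 1000,
    energy_max_kj = max(records$energy_j) / 1000
  )
}

#' Paired lesion dimensions (thermal dose vs T1-weighted)
#'
#' Each lesion contributes two paired dimensions, matched positionally within
#' the record as printed (first with first, second with second); 12 records
#' give N = 24 pairs. Set `sort_desc = TRUE` to re-pair after sorting each
#' record's dimensions in decreasing order instead.
#'
#' @param records ablation tibble with both dimension pairs present.
#' @param sort_desc pair largest-with-largest instead of positionally.
#' @return Tibble with one row per paired dimension: `sheep_id`, `rfa_id`,
#'   `axis` (1 or 2), `td_mm`, `t1w_mm`.
#' @export
paired_dimensions <- function(records, sort_desc = FALSE) {
  if (nrow(records) == 0) {
    return(tibble::tibble(sheep_id = integer(), rfa_id = integer(),
                          axis = integer(), td_mm = numeric(),
                          t1w_mm = numeric()))
  }
  cols <- c("td_d1_mm", "td_d2_mm", "t1w_d1_mm", "t1w_d2_mm")
  if (any(is.na(records[cols]))) {
    stop("records with missing dimensions", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    td <- c(records$td_d1_mm[i], records$td_d2_mm[i])
    t1 <- c(records$t1w_d1_mm[i], records$t1w_d2_mm[i])
    if (sort_desc) {
      td <- sort(td, decreasing = TRUE)
      t1 <- sort(t1, decreasing = TRUE)
    }
    tibble::tibble(sheep_id = records$sheep_id[i], rfa_id = records$rfa_id[i],
                   axis = 1:2, td_mm = td, t1w_mm = t1)
  })
  do.call(rbind, rows)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient r.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Ordinary least-squares line
#'
#' Fits `response = intercept + slope * regressor`. In the lesion-concordance
#' analysis the thermal-dose dimensions are regressed on the T1-weighted
#' dimensions.
#'
#' @param x regressor (non-constant), `y` response; n >= 2.
#' @param y response vector.
#' @return Named numeric: `slope`, `intercept`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant regressor", call. = FALSE)
  cf <- stats::coef(stats::lm(y ~ x))
  c(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y`: bias = mean(d), sd of differences, and 95%
#' limits of agreement bias +/- 1.96 sd.
#'
#' @param x,y paired measurements (same length, n >= 2).
#' @return Named numeric: `bias`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  c(bias = bias, sd_diff = s,
    loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s)
}

#' Full lesion-dimension agreement analysis
#'
#' Computes Pearson correlation, the regression of thermal-dose dimensions on
#' T1-weighted dimensions, and Bland-Altman agreement over the paired lesion
#' dimensions of an ablation table.
#'
#' @param records ablation tibble (see [load_table1()]), or a pair tibble
#'   from [paired_dimensions()].
#' @param sort_desc see [paired_dimensions()].
#' @return An `agreement_stats` object with `n`, `r`, `slope`, `intercept`,
#'   `bias`, `sd_diff`, `loa_lower`, `loa_upper` and the pair data; has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
agreement_stats <- function(records, sort_desc = FALSE) {
  pairs <- if (all(c("td_mm", "t1w_mm") %in% names(records))) records
    else paired_dimensions(records, sort_desc = sort_desc)
  x <- pairs$td_mm
  y <- pairs$t1w_mm
  fit <- linear_fit(y, x) # TD (response) on T1-w (regressor)
  ba <- bland_altman(x, y)
  structure(list(
    n = length(x), r = pearson(x, y),
    slope = fit[["slope"]], intercept = fit[["intercept"]],
    bias = ba[["bias"]], sd_diff = ba[["sd_diff"]],
    loa_lower = ba[["loa_lower"]], loa_upper = ba[["loa_upper"]],
    pairs = pairs
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Lesion-dimension agreement (N = %d pairs)\n", x$n))
  cat(sprintf("  Pearson r        : %.3f\n", x$r))
  cat(sprintf("  TD ~ T1-w        : slope %.3f, intercept %.3f mm\n",
              x$slope, x$intercept))
  cat(sprintf("  Bias (TD - T1-w) : %.2f +/- %.2f mm\n", x$bias, x$sd_diff))
  cat(sprintf("  95%% limits       : [%.2f, %.2f] mm\n",
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @rdname agreement_stats
#' @param x an `agreement_stats` object.
#' @param ... unused.
#' @method tidy agreement_stats
#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(
    term = c("r", "slope", "intercept", "bias", "sd_diff",
             "loa_lower", "loa_upper"),
    estimate = c(x$r, x$slope, x$intercept, x$bias, x$sd_diff,
                 x$loa_lower, x$loa_upper)
  )
}

#' @rdname agreement_stats
#' @method glance agreement_stats
#' @export
glance.agreement_stats <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, slope = x$slope, intercept = x$intercept,
                 bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper)
}
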