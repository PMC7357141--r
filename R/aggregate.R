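#' Aggregate per-run series into group summaries
#'
#' The replication unit is the MD run, not the frame (frames within a run are
#' autocorrelated): run-level means are computed first, then each group's mean
#' and standard error are taken over its run means (SE = SD of run means /
#' sqrt(n_runs)).
#'
#' @param runs Tibble of per-frame values with columns `run`, `group`,
#'   `value`, and optionally `pair`/`metric` (kept as grouping keys).
#' @return Tibble of class `car_group_summary` with one row per group (and
#'   pair/metric if present): `n_runs`, `mean` (of run means), `se`, and
#'   `single_run` flag (SE reported as 0 when a group has one run).
#' @export
aggregate_runs <- function(runs) {
  runs <- tibble::as_tibble(runs)
  if (!all(c("run", "group", "value") %in% names(runs))) {
    rlang::abort("runs needs columns run, group, value", class = "car_grouping_error")
  }
  if (nrow(runs) == 0) {
    rlang::abort("no data to aggregate", class = "car_grouping_error")
  }
  keys <- intersect(c("pair", "metric"), names(runs))
  run_means <- runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "group", "run")))) |>
    dplyr::summarise(run_mean = mean(.data$value), n_frames = dplyr::n(), .groups = "drop")
  out <- run_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "group")))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean = mean(.data$run_mean),
      se = ifelse(dplyr::n() > 1, stats::sd(.data$run_mean) / sqrt(dplyr::n()), 0),
      single_run = dplyr::n() == 1,
      .groups = "drop"
    )
  class(out) <- unique(c("car_group_summary", class(out)))
  attr(out, "run_means") <- run_means
  out
}

#' Run-level means behind a group summary
#' @param summary A `car_group_summary`.
#' @return Tibble of run means.
#' @export
run_means <- function(summary) attr(summary, "run_means")

#' Compare two groups of run-level means with a Welch t-test
#'
#' Two-sided Welch (unequal-variance) t-test on run-level means. The test is
#' on runs, not frames; each side needs at least two runs. Significance stars:
#' `**` for p < 0.01, `*` for p < 0.05.
#'
#' @param a,b Numeric vectors of run-level means (or tibbles with a
#'   `run_mean` column as produced by [run_means()]).
#' @return A tibble of class `car_comparison`: `statistic`, `df`, `p_value`,
#'   `stars`, `method`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b) {
  a <- extract_run_means(a)
  b <- extract_run_means(b)
  if (length(a) < 2 || length(b) < 2) {
    rlang::abort(
      "each group needs at least two run-level means for a t-test",
      class = "car_insufficient_replication_error"
    )
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate: identical constant groups; t = 0, p = 1
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  p <- unname(tt$p.value)
  out <- tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = p,
    stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
    method = "welch_two_sided_on_run_means",
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b)
  )
  class(out) <- unique(c("car_comparison", class(out)))
  out
}

extract_run_means <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("run_mean", "value"), names(x))[1]
    if (is.na(col)) {
      rlang::abort("expected a run_mean or value column", class = "car_grouping_error")
    }
    x <- x[[col]]
  }
  as.double(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
tidy.car_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_a - x$mean_b,
    statistic = x$statistic, p.value = x$p_value,
    parameter = x$df, method = x$method
  )
}

#' @export
glance.car_group_summary <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    n_runs_total = sum(x$n_runs),
    any_single_run = any(x$single_run)
  )
}

#' Contact-frequency map over pooled runs
#'
#' For each residue pair, the contact frequency is the fraction of pooled
#' frames showing at least one hydrogen bond for that pair. Display
#' categories follow the conventions used for contact-map figures: `strong`
#' for frequency >= 0.10 (boundary inclusive), `weak` for 0.025 < f < 0.10
#' (lower boundary strict), `none` otherwise. Pooling is frame-weighted
#' across runs by default; `pooling = "runs"` averages per-run frequencies
#' instead.
#'
#' @param bond_frames Tibble with one row per (run, frame, pair) in which the
#'   pair shows at least one bond: columns `run`, `frame`, `pair`. Duplicate
#'   rows (several bonds in one frame) are collapsed.
#' @param frames_per_run Named numeric vector (or tibble `run`, `n_frames`)
#'   giving each run's total frame count.
#' @param pair_universe Optional character vector of pairs to report even when
#'   never bonded (frequency 0).
#' @param pooling `"frames"` (default) or `"runs"`.
#' @return Tibble of class `car_contact_map`: `pair`, `frequency`,
#'   `category`.
#' @export
contact_map <- function(bond_frames, frames_per_run, pair_universe = NULL,
                        pooling = c("frames", "runs")) {
  pooling <- rlang::arg_match(pooling)
  bond_frames <- tibble::as_tibble(bond_frames)
  if (is.data.frame(frames_per_run)) {
    fpr <- stats::setNames(frames_per_run$n_frames, frames_per_run$run)
  } else {
    fpr <- frames_per_run
  }
  total <- sum(fpr)
  if (total <= 0) {
    rlang::abort("pooled frame count must be positive", class = "car_grouping_error")
  }
  hits <- dplyr::distinct(bond_frames, .data$run, .data$frame, .data$pair)
  if (pooling == "frames") {
    freq <- hits |>
      dplyr::count(.data$pair, name = "n_hit") |>
      dplyr::mutate(frequency = .data$n_hit / total) |>
      dplyr::select("pair", "frequency")
  } else {
    freq <- hits |>
      dplyr::count(.data$run, .data$pair, name = "n_hit") |>
      dplyr::mutate(run_freq = .data$n_hit / fpr[as.character(.data$run)]) |>
      tidyr::complete(run = names(fpr), .data$pair, fill = list(run_freq = 0)) |>
      dplyr::group_by(.data$pair) |>
      dplyr::summarise(frequency = mean(.data$run_freq), .groups = "drop")
  }
  if (!is.null(pair_universe)) {
    freq <- freq |>
      tidyr::complete(pair = pair_universe, fill = list(frequency = 0))
  }
  out <- freq |>
    dplyr::mutate(category = contact_category(.data$frequency)) |>
    dplyr::arrange(.data$pair)
  class(out) <- unique(c("car_contact_map", class(out)))
  out
}

#' Display category for a contact frequency
#'
#' `strong` when f >= 0.10 (inclusive), `weak` when 0.025 < f < 0.10 (strict
#' lower bound), otherwise `none`.
#'
#' @param f Frequency in [0, 1].
#' @param strong Strong threshold (inclusive), default 0.10.
#' @param weak Weak threshold (exclusive), default 0.025.
#' @return Character vector of categories.
#' @export
contact_category <- function(f, strong = 0.10, weak = 0.025) {
  stopifnot(all(f >= 0 & f <= 1))
  dplyr::case_when(
    f >= strong ~ "strong",
    f > weak ~ "weak",
    TRUE ~ "none"
  )
}
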