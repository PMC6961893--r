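#' Tabulate a 2AFC response table into a psychometric grid
#'
#' Counts "faster" responses per (comparison velocity, noise level) cell,
#' marginalising over presentation order, separately for each subject.
#'
#' @param trials Tibble from [generate_2afc_dataset()] (or identically
#'   shaped real data): columns `subject`, `velocity`, `noise`, `response`.
#' @return Tibble with columns `subject`, `velocity`, `noise`, `n`,
#'   `n_faster`, `prop` (NA with `flag = "empty"` for empty cells).
#' @export
tabulate_2afc <- function(trials) {
  g <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject, .data$velocity, .data$noise),
    n = dplyr::n(),
    n_faster = sum(.data$response == "faster"),
    .groups = "drop")
  full <- tidyr::expand_grid(subject = unique(trials$subject),
                             velocity = sort(unique(trials$velocity)),
                             noise = sort(unique(trials$noise)))
  g <- dplyr::left_join(full, g, by = c("subject", "velocity", "noise"))
  g$n[is.na(g$n)] <- 0L
  g$prop <- ifelse(g$n > 0, g$n_faster / g$n, NA_real_)
  g$flag <- ifelse(g$n == 0, "empty", "")
  g
}

# 0.5 crossing of one proportion-vs-velocity profile
pse_one_profile <- function(velocity, prop) {
  ok <- !is.na(prop)
  v <- velocity[ok]; p <- prop[ok]
  if (length(v) < 2) {
    return(list(pse = NA_real_, flag = "insufficient"))
  }
  ord <- order(v)
  v <- v[ord]; p <- p[ord]
  exact <- which(p == 0.5)
  if (length(exact) > 0) {
    return(list(pse = mean(v[exact]),
                flag = if (length(exact) > 1) "multiple_exact" else ""))
  }
  up <- which(p[-length(p)] < 0.5 & p[-1] > 0.5)
  if (length(up) == 0) {
    return(list(pse = NA_real_, flag = "out_of_range"))
  }
  i <- up[1]  # first upward crossing, scanning low to high velocity
  pse <- v[i] + (0.5 - p[i]) / (p[i + 1] - p[i]) * (v[i + 1] - v[i])
  list(pse = pse, flag = if (length(up) > 1) "multiple_crossing" else "")
}

#' Points of subjective equality from a psychometric grid
#'
#' For each subject and noise level, finds the comparison velocity at which
#' the proportion of "faster" responses crosses 0.5, by piecewise-linear
#' interpolation in velocity. Cells at exactly 0.5 for more than one
#' velocity are averaged into a single estimate; non-monotone profiles use
#' the first upward crossing and are flagged; profiles with no crossing in
#' range yield `NA` with an `out_of_range` flag rather than a fabricated
#' value.
#'
#' @param grid Tibble from [tabulate_2afc()].
#' @return Tibble with columns `subject`, `noise`, `pse`, `flag`.
#' @export
pse_from_grid <- function(grid) {
  keys <- dplyr::distinct(grid, .data$subject, .data$noise)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- grid[grid$subject == keys$subject[i] &
                  grid$noise == keys$noise[i], ]
    est <- pse_one_profile(sub$velocity, sub$prop)
    tibble::tibble(subject = keys$subject[i], noise = keys$noise[i],
                   pse = est$pse, flag = est$flag)
  })
  dplyr::bind_rows(out)
}

#' Per-subject PSE table from raw 2AFC trials
#'
#' Convenience wrapper: [tabulate_2afc()] then [pse_from_grid()].
#'
#' @param trials 2AFC trial table.
#' @return Tibble with columns `subject`, `noise`, `pse`, `flag`, suitable
#'   for [fit_pse_slope()].
#' @export
pse_table <- function(trials) {
  pse_from_grid(tabulate_2afc(trials))
}
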