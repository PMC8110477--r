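#' Distance-decay expectation of a balanced map
#'
#' Computes, for every genomic distance (in bins), the mean balanced contact
#' value over all unmasked cis pairs, pooled across chromosomes, and fits the
#' power-law decay exponent alpha by least squares on log(value) vs
#' log(distance) over `fit_range`.
#'
#' @param map A balanced [contact_map()] (see [balance_map()]).
#' @param fit_range Length-2 integer vector of bin distances used for the
#'   alpha fit; default is 1 to a quarter of the longest chromosome.
#' @return A `decay_profile`: a tibble (`distance`, `expected`, `n_pairs`)
#'   with attributes `alpha` and `fit_range`.
#' @export
expected_by_distance <- function(map, fit_range = NULL) {
  if (map$kind != "balanced")
    stop_config("expected_by_distance needs a balanced map")
  max_d <- max(map$grid$nbins) - 1L
  if (max_d < 0 || all(purrr::map_lgl(map$grid$chroms,
                                      ~ all(map$mask[[.x]]))))
    stop_numeric("no unmasked pairs at any distance")
  sums <- numeric(max_d + 1L)
  npair <- numeric(max_d + 1L)
  for (ch in map$grid$chroms) {
    v <- map_values(map, ch)
    n <- nrow(v)
    for (d in 0:(n - 1L)) {
      diagv <- v[cbind(seq_len(n - d), seq_len(n - d) + d)]
      ok <- !is.na(diagv)
      sums[d + 1L] <- sums[d + 1L] + sum(diagv[ok])
      npair[d + 1L] <- npair[d + 1L] + sum(ok)
    }
  }
  if (all(npair == 0)) stop_numeric("no unmasked pairs at any distance")
  expected <- ifelse(npair > 0, sums / npair, NA_real_)
  prof <- tibble(distance = 0:max_d, expected = expected, n_pairs = npair)
  if (is.null(fit_range)) fit_range <- c(1L, max(1L, max_d %/% 4L))
  fit <- dplyr::filter(prof, .data$distance >= fit_range[1],
                       .data$distance <= fit_range[2],
                       !is.na(.data$expected), .data$expected > 0)
  alpha <- NA_real_
  if (nrow(fit) >= 2) {
    co <- stats::coef(stats::lm(log(expected) ~ log(distance), data = fit))
    alpha <- -unname(co[2])
  }
  structure(prof, alpha = alpha, fit_range = fit_range,
            class = c("decay_profile", class(prof)))
}

#' @describeIn expected_by_distance One-row summary (`alpha`, fit range,
#'   number of defined distances).
#' @param x A `decay_profile`.
#' @param ... Unused.
#' @export
glance.decay_profile <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"),
         fit_min = attr(x, "fit_range")[1], fit_max = attr(x, "fit_range")[2],
         n_distances = sum(!is.na(x$expected)))
}

#' Fitted decay exponent
#' @param profile A `decay_profile`.
#' @return The exponent alpha (positive for decaying contacts).
#' @export
decay_alpha <- function(profile) attr(profile, "alpha")

#' Observed/expected transform
#'
#' Divides each balanced cell by the expected value at its distance. Distances
#' with no defined expectation (or zero) borrow the nearest defined distance's
#' value, so map edges do not create division holes. Masked cells stay masked.
#'
#' @param map A balanced [contact_map()].
#' @param profile Optional [expected_by_distance()] profile; computed from
#'   `map` when absent.
#' @return A [contact_map()] of kind `"oe"`.
#' @export
observed_over_expected <- function(map, profile = NULL) {
  if (map$kind != "balanced")
    stop_config("observed_over_expected needs a balanced map")
  if (is.null(profile)) profile <- expected_by_distance(map)
  exp_v <- profile$expected
  ok <- which(!is.na(exp_v) & exp_v > 0)
  if (length(ok) == 0) stop_numeric("decay profile has no positive values")
  # nearest defined distance fills the gaps
  filled <- exp_v
  gaps <- which(is.na(exp_v) | exp_v <= 0)
  for (g in gaps) {
    lower <- ok[ok <= g]; upper <- ok[ok >= g]
    near <- if (length(lower) == 0) upper[1]
            else if (length(upper) == 0) tail(lower, 1)
            else if (g - tail(lower, 1) <= upper[1] - g) tail(lower, 1)
            else upper[1]
    filled[g] <- exp_v[near]
  }
  for (ch in map$grid$chroms) {
    v <- map_values(map, ch)
    n <- nrow(v)
    d <- abs(row(v) - col(v))
    map$counts[[ch]] <- v / matrix(filled[d + 1L], n, n)
  }
  map$kind <- "oe"
  map
}
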