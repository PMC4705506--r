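#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the model: for each draw,
#' every parameter with a [param_dist()] is sampled independently from
#' its distribution, the sampled values are written into a copy of the
#' parameter set, both arms are re-simulated, and the incremental pair
#' `(delta E, delta C)` plus the net monetary benefit at the configured
#' willingness to pay are recorded.
#'
#' Draws are consumed from a single seeded generator in declared
#' parameter order, so identical `(seed, n_draws, distributions)` yield
#' bitwise-identical results. A sampled set that violates model
#' invariants (for example competing exit probabilities exceeding 1, or
#' a normal draw outside the utility bounds) is rejected and redrawn;
#' rejections are counted and the run aborts if they exceed
#' `rejection_cap * n_draws`, naming the distribution targets so the
#' offending inputs can be re-specified rather than silently clamped.
#'
#' @param ps A `parameter_set`.
#' @param n_draws Number of accepted draws, `>= 1`.
#' @param seed Integer RNG seed.
#' @param distributions Optional list of [param_dist()]; defaults to the
#'   set's own `distributions` block.
#' @param settings Optional [outcome_settings()].
#' @param life_table Optional [life_table()].
#' @param rejection_cap Maximum tolerated rejected fraction (default
#'   0.05).
#' @return A `psa_result`; [tidy()] returns the per-draw table (sampled
#'   values, `delta_e`, `delta_c`, `inmb`), [glance()] a one-row summary,
#'   [autoplot()] the cost-effectiveness plane. Pass the result to
#'   [ceac()] for an acceptability curve.
#' @examples
#' fx <- synthetic_fixture(7)
#' psa <- run_psa(fx$parameter_set, n_draws = 50, seed = 1,
#'                life_table = fx$life_table)
#' glance(psa)
#' @export
run_psa <- function(ps, n_draws, seed, distributions = NULL,
                    settings = NULL, life_table = NULL,
                    rejection_cap = 0.05) {
  ps <- as_parameter_set(ps)
  settings <- resolve_settings(ps, settings)
  if (n_draws < 1) stop("`n_draws` must be >= 1.", call. = FALSE)
  if (is.null(distributions)) {
    distributions <- purrr::map(ps$distributions, dist_from_json)
  }
  if (!length(distributions)) {
    stop("no parameter distributions given and none stored in the set.",
         call. = FALSE)
  }
  for (d in distributions) {
    if (!has_path(ps, d$target)) {
      stop("distribution target '", d$target, "' does not resolve.",
           call. = FALSE)
    }
  }
  targets <- vapply(distributions, `[[`, "", "target")

  base <- run_comparison(ps, settings, life_table)
  max_reject <- max(1, ceiling(rejection_cap * n_draws))
  set.seed(seed)
  sampled <- matrix(NA_real_, n_draws, length(distributions),
                    dimnames = list(NULL, targets))
  delta_e <- delta_c <- numeric(n_draws)
  n_rejected <- 0L
  last_error <- NULL
  accepted <- 0L
  while (accepted < n_draws) {
    values <- vapply(distributions, sample_param, numeric(1))
    candidate <- ps
    for (j in seq_along(targets)) {
      candidate <- set_path(candidate, targets[j], values[j])
    }
    res <- tryCatch(run_comparison(candidate, settings, life_table),
                    error = function(e) e)
    if (inherits(res, "error")) {
      n_rejected <- n_rejected + 1L
      last_error <- conditionMessage(res)
      if (n_rejected > max_reject) {
        stop("PSA aborted: ", n_rejected, " invalid draws exceed the cap of ",
             max_reject, " (", rejection_cap * 100, "% of ", n_draws,
             " draws).\n  distributions: ",
             paste(targets, collapse = ", "),
             "\n  last rejection: ", last_error, call. = FALSE)
      }
      next
    }
    accepted <- accepted + 1L
    sampled[accepted, ] <- values
    delta_e[accepted] <- res$incremental$delta_e
    delta_c[accepted] <- res$incremental$delta_c
  }
  if (n_rejected > 0L) {
    message("run_psa: ", n_rejected, " invalid draw(s) rejected and redrawn.")
  }
  draws <- dplyr::bind_cols(
    tibble::tibble(draw = seq_len(n_draws)),
    tibble::as_tibble(sampled),
    tibble::tibble(delta_e = delta_e, delta_c = delta_c,
                   inmb = delta_e * settings$lambda - delta_c)
  )
  structure(
    list(draws = draws, n_draws = as.integer(n_draws), seed = seed,
         n_rejected = n_rejected, settings = settings, base = base,
         targets = targets),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_draws, " draws (seed ", x$seed, ", ",
      x$n_rejected, " rejected), ", length(x$targets),
      " uncertain parameters\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
#' @method tidy psa_result
tidy.psa_result <- function(x, ...) x$draws

#' @export
#' @method glance psa_result
glance.psa_result <- function(x, ...) {
  d <- x$draws
  tibble::tibble(
    n_draws = x$n_draws, n_rejected = x$n_rejected,
    mean_delta_e = mean(d$delta_e), mean_delta_c = mean(d$delta_c),
    mean_inmb = mean(d$inmb),
    prob_cost_effective = mean(d$inmb > 0),
    lambda = x$settings$lambda
  )
}

#' Cost-effectiveness plane
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot of the PSA cloud on the (delta E, delta C) plane with
#'   the willingness-to-pay line and the base-case point.
#' @export
#' @method autoplot psa_result
autoplot.psa_result <- function(object, ...) {
  base <- glance(object$base)
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(.data$delta_e, .data$delta_c)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_abline(slope = object$settings$lambda, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point(data = base, colour = "red", size = 2) +
    ggplot2::labs(x = expression(Delta * E ~ "(QALYs)"),
                  y = expression(Delta * C),
                  title = "Cost-effectiveness plane",
                  subtitle = "dashed: willingness-to-pay threshold") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the
#' intervention is cost-effective: the fraction of PSA draws with
#' `delta_e * lambda - delta_c > 0` (draws with INMB exactly 0 count as
#' not cost-effective).
#'
#' @param result A `psa_result`.
#' @param lambda_grid Non-empty numeric vector of willingness-to-pay
#'   values.
#' @return A `ceac_curve` tibble with columns `lambda`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(result, lambda_grid) {
  stopifnot(inherits(result, "psa_result"))
  if (length(lambda_grid) == 0L) {
    stop("`lambda_grid` must be non-empty.", call. = FALSE)
  }
  d <- result$draws
  out <- tibble::tibble(
    lambda = as.numeric(lambda_grid),
    prob_cost_effective = vapply(
      lambda_grid, function(l) mean(d$delta_e * l - d$delta_c > 0),
      numeric(1))
  )
  class(out) <- c("ceac_curve", class(out))
  out
}

#' @export
#' @method autoplot ceac_curve
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda,
                                       .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(lambda ~ "(willingness to pay per QALY)"),
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
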