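#' Declare a mapping algorithm from another HRQoL instrument to EQ-5D
#'
#' Many studies collect health-related quality of life with instruments
#' other than the EQ-5D (SF-36, SF-12, SF-6D, 15D, disease-specific
#' scales). A published mapping ("cross-walk") algorithm converts such
#' scores into predicted EQ-5D utilities, usually as a linear or
#' piecewise-linear regression with a residual standard error. This
#' constructor declares the coefficients of such an algorithm; estimating
#' one from raw data is out of scope.
#'
#' A single `(intercept, slope)` pair declares a linear map. For a
#' piecewise-linear map pass a `segments` tibble with columns `lower`,
#' `upper`, `intercept`, `slope`; segments must tile `score_range`.
#'
#' @param intercept,slope Coefficients of the linear transform.
#' @param se Residual standard error of the mapping on the utility scale;
#'   propagated into probabilistic sensitivity analysis.
#' @param score_range Length-2 admissible input score range.
#' @param segments Optional tibble for piecewise-linear algorithms.
#' @param name Label for reporting.
#' @return An object of class `mapping_algorithm`.
#' @examples
#' alg <- mapping_algorithm(intercept = 0.2, slope = 0.006, se = 0.08,
#'                          score_range = c(0, 100), name = "generic-0-100")
#' map_to_eq5d(50, alg)
#' @export
mapping_algorithm <- function(intercept = 0, slope = 1, se = 0,
                              score_range = c(-Inf, Inf), segments = NULL,
                              name = "linear") {
  if (se < 0) stop("`se` must be >= 0.", call. = FALSE)
  if (!is.null(segments)) {
    req <- c("lower", "upper", "intercept", "slope")
    if (!all(req %in% names(segments))) {
      stop("`segments` needs columns lower, upper, intercept, slope.",
           call. = FALSE)
    }
    segments <- dplyr::arrange(tibble::as_tibble(segments), .data$lower)
    if (any(segments$upper[-nrow(segments)] != segments$lower[-1])) {
      stop("piecewise segments must be contiguous.", call. = FALSE)
    }
    score_range <- c(segments$lower[1], segments$upper[nrow(segments)])
  }
  structure(
    list(intercept = intercept, slope = slope, se = se,
         score_range = as.numeric(score_range), segments = segments,
         name = name),
    class = "mapping_algorithm"
  )
}

#' Map a source-instrument score to an EQ-5D utility
#'
#' Applies a declared [mapping_algorithm()] to one or more scores. Scores
#' outside the algorithm's declared range are refused by default
#' (extrapolating a mapping beyond its estimation range is unreliable);
#' set `extrapolate = TRUE` to override. Predicted utilities falling
#' outside `utility_bounds` are clamped to the boundary and the clamp is
#' reported as a warning, so downstream analyses always receive a valid
#' utility. The returned standard error is the algorithm's residual error
#' and feeds the uncertainty analysis.
#'
#' @param score Numeric score(s) on the source instrument's scale.
#' @param algorithm A [mapping_algorithm()].
#' @param utility_bounds Admissible utility range for clamping.
#' @param extrapolate Allow scores outside the declared range.
#' @return A tibble with columns `score`, `utility`, `se`, `clamped`.
#' @export
map_to_eq5d <- function(score, algorithm, utility_bounds = c(0, 1),
                        extrapolate = FALSE) {
  rng <- algorithm$score_range
  out_of_range <- score < rng[1] | score > rng[2]
  if (any(out_of_range) && !extrapolate) {
    stop("score(s) ", paste(score[out_of_range], collapse = ", "),
         " outside the algorithm's declared range [", rng[1], ", ", rng[2],
         "]; set `extrapolate = TRUE` to override.", call. = FALSE)
  }
  raw <- if (is.null(algorithm$segments)) {
    algorithm$intercept + algorithm$slope * score
  } else {
    seg <- algorithm$segments
    vapply(score, function(s) {
      i <- max(1L, findInterval(s, seg$lower, rightmost.closed = TRUE))
      i <- min(i, nrow(seg))
      seg$intercept[i] + seg$slope[i] * s
    }, numeric(1))
  }
  clamped <- raw < utility_bounds[1] | raw > utility_bounds[2]
  utility <- pmin(pmax(raw, utility_bounds[1]), utility_bounds[2])
  if (any(clamped)) {
    warning(sum(clamped), " mapped utility value(s) clamped to [",
            utility_bounds[1], ", ", utility_bounds[2], "].", call. = FALSE)
  }
  tibble::tibble(score = score, utility = utility,
                 se = rep(algorithm$se, length(score)), clamped = clamped)
}
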