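#' Construct a life table
#'
#' A life table gives the annual probability of death at each integer age
#' for a target population; it supplies age-dependent baseline mortality
#' to the cohort model. Ages must be contiguous and ascending. The table
#' is closed either by a final row with probability 1, or by setting
#' `open_ended = TRUE`, in which case ages beyond the last row reuse the
#' final probability.
#'
#' @param age Integer ages in years, contiguous ascending.
#' @param mortality_prob Annual death probabilities in `[0, 1]`.
#' @param population Label for the population the table describes.
#' @param open_ended Logical; allow lookups beyond the last age.
#' @return A tibble of class `life_table` with columns `age`,
#'   `mortality_prob` and attributes `population`, `open_ended`.
#' @export
life_table <- function(age, mortality_prob, population = "unspecified",
                       open_ended = FALSE) {
  lt <- tibble::tibble(age = as.integer(age),
                       mortality_prob = as.numeric(mortality_prob))
  attr(lt, "population") <- population
  attr(lt, "open_ended") <- isTRUE(open_ended)
  class(lt) <- c("life_table", class(lt))
  validate_life_table(lt)
  lt
}

#' @rdname life_table
#' @param lt A `life_table` to validate.
#' @export
validate_life_table <- function(lt) {
  if (!all(c("age", "mortality_prob") %in% names(lt))) {
    stop("a life table needs columns `age` and `mortality_prob`.",
         call. = FALSE)
  }
  if (nrow(lt) == 0L) stop("life table is empty.", call. = FALSE)
  if (any(diff(lt$age) != 1L)) {
    stop("life-table ages must be contiguous ascending integers.",
         call. = FALSE)
  }
  p <- lt$mortality_prob
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("life-table mortality probabilities must lie in [0, 1].",
         call. = FALSE)
  }
  if (!isTRUE(attr(lt, "open_ended")) && p[length(p)] != 1) {
    stop("life table must end with mortality probability 1, or be flagged ",
         "open-ended.", call. = FALSE)
  }
  invisible(lt)
}

# Annual mortality probability at (non-integer) age; floor() lookup, no
# interpolation. Ages past the end fall through to the final row only for
# closed (final prob 1) or open-ended tables.
lookup_mortality <- function(lt, age) {
  a <- floor(age)
  last <- nrow(lt)
  if (a < lt$age[1]) {
    stop("life table for '", attr(lt, "population"),
         "' does not cover age ", a, " (starts at ", lt$age[1], ").",
         call. = FALSE)
  }
  if (a > lt$age[last]) {
    if (isTRUE(attr(lt, "open_ended")) || lt$mortality_prob[last] == 1) {
      return(lt$mortality_prob[last])
    }
    stop("life table for '", attr(lt, "population"),
         "' does not cover age ", a, " (ends at ", lt$age[last], ").",
         call. = FALSE)
  }
  lt$mortality_prob[a - lt$age[1] + 1L]
}

#' Read / write a life table as CSV
#'
#' The on-disk format is a plain CSV with header `age,mortality_prob`.
#'
#' @param path File path.
#' @param population Population label to attach on read.
#' @param open_ended Open-ended flag to attach on read.
#' @return `read_life_table()` returns a `life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path, population = "unspecified",
                            open_ended = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  life_table(df$age, df$mortality_prob, population = population,
             open_ended = open_ended)
}

#' @rdname read_life_table
#' @param lt A `life_table`.
#' @export
write_life_table <- function(lt, path) {
  readr::write_csv(tibble::as_tibble(lt)[c("age", "mortality_prob")], path)
  invisible(path)
}
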