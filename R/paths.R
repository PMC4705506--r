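# Dot-separated paths into nested parameter structures, e.g.
# "arms.intervention.transitions.incidence.value". Paths are the common
# addressing scheme for PSA distribution targets, scenario overrides and
# validation messages.

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

has_path <- function(x, path) {
  keys <- split_path(path)
  for (k in keys) {
    if (!is.list(x) || is.null(x[[k]])) return(FALSE)
    x <- x[[k]]
  }
  TRUE
}

get_path <- function(x, path) {
  keys <- split_path(path)
  purrr::reduce(keys, function(acc, k) {
    if (is.null(acc[[k]])) {
      stop("path '", path, "' does not resolve.", call. = FALSE)
    }
    acc[[k]]
  }, .init = x)
}

set_path <- function(x, path, value) {
  keys <- split_path(path)
  set_rec <- function(node, keys) {
    k <- keys[[1]]
    if (!is.list(node) || is.null(node[[k]])) {
      stop("path '", path, "' does not resolve.", call. = FALSE)
    }
    if (length(keys) == 1L) {
      node[[k]] <- value
    } else {
      node[[k]] <- set_rec(node[[k]], keys[-1])
    }
    node
  }
  set_rec(x, keys)
}

# Enumerate every leaf path of a nested list (used for provenance tagging
# and strict-merge checks).
leaf_paths <- function(x, prefix = character()) {
  if (!is.list(x) || length(x) == 0L) {
    return(paste(prefix, collapse = "."))
  }
  nms <- names(x)
  if (is.null(nms)) nms <- as.character(seq_along(x))
  unlist(purrr::imap(x, function(v, i) {
    nm <- if (is.character(i)) i else as.character(i)
    leaf_paths(v, c(prefix, nm))
  }), use.names = FALSE)
}
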