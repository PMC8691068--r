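#' Enumerate all root-to-terminal paths of a probability tree
#'
#' Full enumeration is the exact counterpart of the Monte Carlo sampler: each
#' complete path appears exactly once with probability equal to the product of
#' its transition probabilities, and the probabilities sum to one. It serves
#' both as the internal engine of the vectorized simulator (a cohort draw is a
#' multinomial over enumerated paths) and as the independent expectation
#' oracle against which sampled rates are tested.
#'
#' @param tree a valid `nas_tree`
#' @param max_paths capacity cap; enumeration stops with an error if the tree
#'   has more complete paths than this (default `1e6`).
#' @return A `path_distribution`: data.frame with columns `path_id`, `path`
#'   (state ids joined by `">"`), `terminal`, `prob`, and one logical column
#'   per flag defined on the tree.
#' @export
enumerate_paths <- function(tree, max_paths = 1e6) {
  v <- validate_tree(tree)
  if (length(v)) stop_nassim("invalid tree: %s", paste(v, collapse = "; "))

  tr <- tree$transitions
  kids <- split(seq_len(nrow(tr)), factor(tr$from, levels = tree$states$id))
  root <- tree_root(tree)

  paths <- vector("list", 64L)
  probs <- numeric(64L)
  n_found <- 0L
  # depth-first in file (canonical branch) order
  recurse <- function(node, acc, p) {
    idx <- kids[[node]]
    if (is.null(idx) || length(idx) == 0L) {
      n_found <<- n_found + 1L
      if (n_found > max_paths)
        stop_nassim("tree has more than max_paths = %g complete paths", max_paths)
      paths[[n_found]] <<- acc
      probs[n_found] <<- p
      return(invisible(NULL))
    }
    for (i in idx) recurse(tr$to[i], c(acc, tr$to[i]), p * tr$prob[i])
  }
  recurse(root, root, 1.0)

  paths <- paths[seq_len(n_found)]
  probs <- probs[seq_len(n_found)]
  out <- data.frame(
    path_id = seq_len(n_found),
    path = vapply(paths, paste, "", collapse = ">"),
    terminal = vapply(paths, function(p) p[length(p)], ""),
    prob = probs,
    stringsAsFactors = FALSE
  )
  for (f in names(tree$flags)) {
    set <- tree$flags[[f]]
    out[[f]] <- vapply(paths, function(p) any(p %in% set), logical(1))
  }
  class(out) <- c("path_distribution", "data.frame")
  out
}

#' Exact probability of an outcome flag under full enumeration
#'
#' Sums path probability over all enumerated paths carrying the flag. This is
#' the closed-form expectation the Monte Carlo flag rates converge to.
#'
#' @param dist a `path_distribution` from [enumerate_paths()]
#' @param flag flag name (a logical column of `dist`)
#' @return probability in \[0, 1\]
#' @export
expected_flag_rate <- function(dist, flag) {
  if (!flag %in% names(dist) || !is.logical(dist[[flag]]))
    stop_nassim("unknown flag '%s'", flag)
  sum(dist$prob[dist[[flag]]])
}

#' Sample complete paths through a probability tree
#'
#' `sample_paths()` draws `n` independent root-to-terminal paths, each by a
#' sequence of categorical draws at the visited non-terminal states, using the
#' transition-file branch order so that draws are reproducible for a given
#' random-number state. `sample_path()` is the single-woman form.
#'
#' @param tree a valid `nas_tree`
#' @param n number of women to sample
#' @return `sample_paths()`: data.frame with columns `path` and `terminal`
#'   plus one logical flag column per tree flag. `sample_path()`: a list with
#'   `path` (character vector of state ids), `terminal`, and `flags`.
#' @details The caller controls the random stream with `set.seed()`; the same
#'   stream state always yields the same path sequence.
#' @export
sample_paths <- function(tree, n) {
  v <- validate_tree(tree)
  if (length(v)) stop_nassim("invalid tree: %s", paste(v, collapse = "; "))
  if (!is_count(n)) stop_nassim("n must be a positive integer")

  tr <- tree$transitions
  kids <- split(seq_len(nrow(tr)), factor(tr$from, levels = tree$states$id))
  terminal <- setNames(tree$states$is_terminal, tree$states$id)
  root <- tree_root(tree)

  current <- rep(root, n)
  sweeps <- list(current)
  active <- !terminal[current]
  # advance every active woman one stage per sweep; tree depth bounds sweeps.
  # Draws happen state by state in file order, so the sequence is reproducible
  # for a fixed random-number state.
  while (any(active)) {
    for (s in unique(current[active])) {
      at <- which(active & current == s)
      idx <- kids[[s]]
      p <- tr$prob[idx]
      if (length(idx) == 1L) {
        draw <- rep(1L, length(at))
      } else {
        draw <- sample.int(length(idx), length(at), replace = TRUE, prob = p)
      }
      current[at] <- tr$to[idx][draw]
    }
    sweeps[[length(sweeps) + 1L]] <- current
    active <- !terminal[current]
  }

  # a woman parked at a terminal repeats that state in later sweeps; collapse
  # the trailing repeats when rendering the path (states never repeat otherwise)
  mat <- do.call(cbind, sweeps)
  path_str <- do.call(paste, c(asplit(mat, 2L), list(sep = ">")))
  path_str <- sub("(>[^>]+)(\\1)+$", "\\1", path_str, perl = TRUE)
  out <- data.frame(
    path = path_str,
    terminal = current,
    stringsAsFactors = FALSE
  )
  for (f in names(tree$flags)) {
    set <- tree$flags[[f]]
    hit <- matrix(mat %in% set, nrow = n)
    out[[f]] <- rowSums(hit) > 0L
  }
  out
}

#' @rdname sample_paths
#' @export
sample_path <- function(tree) {
  row <- sample_paths(tree, 1L)
  flags <- as.list(row[1, setdiff(names(row), c("path", "terminal")), drop = FALSE])
  list(path = strsplit(row$path[1], ">", fixed = TRUE)[[1]],
       terminal = row$terminal[1],
       flags = lapply(flags, isTRUE))
}

#' @export
print.path_distribution <- function(x, ...) {
  cat(sprintf("<path_distribution> %d complete paths, total probability %.12f\n",
              nrow(x), sum(x$prob)))
  NextMethod()
}
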