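#' Construct a probability tree
#'
#' A probability tree is the model's core object: a rooted, acyclic branching
#' structure in which every simulated woman follows one root-to-terminal path,
#' drawn by independent categorical draws at each non-terminal state. Topology
#' is data, not code: states, transitions and outcome-flag definitions all come
#' from the parameter file, so intervention variants are expressed as
#' transition modifiers over one shared baseline topology.
#'
#' @param states data.frame with columns `id`, `label`, `stage`,
#'   `is_terminal`. `stage` is one of `"pregnancy"`, `"treatment_entry"`,
#'   `"treatment_modality"`, `"treatment_outcome"`, `"birth_outcome"`,
#'   `"terminal"`.
#' @param transitions data.frame with columns `name`, `from`, `to`, `prob`.
#'   Row order is the canonical branch order used for categorical draws, so
#'   results are reproducible across runs.
#' @param flags named list mapping an outcome flag (e.g. `nas_case`) to the
#'   character vector of state ids whose visitation raises the flag.
#' @return An object of class `nas_tree`.
#' @seealso [validate_tree()], [enumerate_paths()], [sample_paths()]
#' @export
nas_tree <- function(states, transitions, flags = list()) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  need_s <- c("id", "label", "stage", "is_terminal")
  need_t <- c("name", "from", "to", "prob")
  if (!all(need_s %in% names(states)))
    stop_nassim("states must have columns: %s", paste(need_s, collapse = ", "))
  if (!all(need_t %in% names(transitions)))
    stop_nassim("transitions must have columns: %s", paste(need_t, collapse = ", "))
  structure(
    list(states = states[need_s], transitions = transitions[need_t],
         flags = flags),
    class = "nas_tree"
  )
}

TREE_STAGES <- c("pregnancy", "treatment_entry", "treatment_modality",
                 "treatment_outcome", "birth_outcome", "terminal")

#' Validate a probability tree
#'
#' Checks every structural invariant: unique state ids, exactly one root,
#' terminal states have no outgoing transitions and non-terminal states have
#' at least one, probabilities lie in \[0, 1\], sibling groups sum to one
#' within `tol`, the graph is acyclic, and every flag references existing
#' states. Violations are returned, never thrown, so validation is total.
#'
#' @param tree a `nas_tree`
#' @param tol sibling-probability sum tolerance (default `1e-9`)
#' @return character vector of violation messages; empty if valid.
#' @export
validate_tree <- function(tree, tol = PROB_TOL) {
  v <- character(0)
  st <- tree$states
  tr <- tree$transitions

  if (anyDuplicated(st$id))
    v <- c(v, sprintf("duplicate state id(s): %s",
                      paste(unique(st$id[duplicated(st$id)]), collapse = ", ")))
  if (anyDuplicated(tr$name))
    v <- c(v, sprintf("duplicate transition name(s): %s",
                      paste(unique(tr$name[duplicated(tr$name)]), collapse = ", ")))
  bad_stage <- setdiff(unique(st$stage), TREE_STAGES)
  if (length(bad_stage))
    v <- c(v, sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))

  unknown <- setdiff(c(tr$from, tr$to), st$id)
  if (length(unknown))
    v <- c(v, sprintf("transition references unknown state(s): %s",
                      paste(unknown, collapse = ", ")))

  roots <- setdiff(st$id, tr$to)
  if (length(roots) != 1L)
    v <- c(v, sprintf("tree must have exactly one root, found %d (%s)",
                      length(roots), paste(roots, collapse = ", ")))
  multi_parent <- unique(tr$to[duplicated(tr$to)])
  if (length(multi_parent))
    v <- c(v, sprintf("state(s) with more than one parent: %s",
                      paste(multi_parent, collapse = ", ")))

  for (i in seq_len(nrow(tr))) {
    p <- tr$prob[i]
    if (!is.finite(p) || p < 0 || p > 1)
      v <- c(v, sprintf("transition '%s' has probability %s outside [0, 1]",
                        tr$name[i], format(p)))
  }

  for (s in st$id) {
    out <- tr$prob[tr$from == s]
    terminal <- isTRUE(st$is_terminal[st$id == s][1])
    if (terminal && length(out) > 0)
      v <- c(v, sprintf("terminal state '%s' has outgoing transitions", s))
    if (!terminal && length(out) == 0)
      v <- c(v, sprintf("non-terminal state '%s' has no outgoing transitions", s))
    if (!terminal && length(out) > 0 && all(is.finite(out)) &&
        abs(sum(out) - 1) > tol)
      v <- c(v, sprintf(
        "outgoing probabilities of state '%s' sum to %.12g, not 1", s, sum(out)))
  }

  # acyclicity: iterative depth-first search over the directed edge set
  if (length(roots) >= 1L && !length(unknown)) {
    children <- split(tr$to, factor(tr$from, levels = st$id))
    color <- setNames(rep(0L, nrow(st)), st$id)  # 0 white, 1 grey, 2 black
    for (start in st$id) {
      if (color[start] != 0L) next
      stack <- list(list(node = start, next_child = 1L))
      color[start] <- 1L
      while (length(stack)) {
        top <- stack[[length(stack)]]
        kids <- children[[top$node]]
        if (is.null(kids) || top$next_child > length(kids)) {
          color[top$node] <- 2L
          stack[[length(stack)]] <- NULL
        } else {
          stack[[length(stack)]]$next_child <- top$next_child + 1L
          kid <- kids[top$next_child]
          if (color[kid] == 1L) {
            v <- c(v, sprintf("cycle detected through state '%s'", kid))
            stack <- list()
            break
          } else if (color[kid] == 0L) {
            color[kid] <- 1L
            stack[[length(stack) + 1L]] <- list(node = kid, next_child = 1L)
          }
        }
      }
      if (any(grepl("^cycle detected", v))) break
    }
  }

  for (f in names(tree$flags)) {
    missing <- setdiff(tree$flags[[f]], st$id)
    if (length(missing))
      v <- c(v, sprintf("flag '%s' references unknown state(s): %s",
                        f, paste(missing, collapse = ", ")))
  }
  v
}

tree_root <- function(tree) {
  setdiff(tree$states$id, tree$transitions$to)
}

#' @export
print.nas_tree <- function(x, ...) {
  cat(sprintf("<nas_tree> %d states, %d transitions, %d terminal states\n",
              nrow(x$states), nrow(x$transitions),
              sum(x$states$is_terminal)))
  cat(sprintf("  root: %s\n", tree_root(x)))
  if (length(x$flags))
    cat(sprintf("  flags: %s\n", paste(names(x$flags), collapse = ", ")))
  invisible(x)
}
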