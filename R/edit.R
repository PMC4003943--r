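# Programmatic skeleton editing. Every operation preserves the tree
# property (edits that would create a cycle or a second parent are
# rejected) and appends one replayable entry to the skeleton's journal.

journal_add <- function(skel, op, args) {
  skel$journal[[length(skel$journal) + 1L]] <- c(list(op = op), args)
  skel
}

descendants_of <- function(skel, id) {
  kids <- skeleton_children(skel)
  out <- integer(0)
  frontier <- id
  while (length(frontier)) {
    ch <- unlist(kids[as.character(frontier)], use.names = FALSE)
    out <- c(out, ch)
    frontier <- ch
  }
  out
}

#' Skeleton editing operations
#'
#' Semi-supervised repair of a reconstructed skeleton, as a programmatic
#' edit script: add a node (e.g. a missed tip), delete a node (its children
#' are reattached to its parent), move a node, set its radius, or connect
#' an orphan root under a parent (joining two trees). Each edit is
#' journaled on the skeleton and can be replayed with
#' [apply_edit_script()].
#'
#' @param skel a `skeleton`.
#' @param position length-3 numeric position in metres.
#' @param radius radius in metres (NA allowed for [add_node()]).
#' @param parent parent node id.
#' @param id node id to edit.
#' @param child an orphan-root node id to connect beneath `parent`.
#' @return the edited `skeleton`; [add_node()] attaches the new node id as
#'   `attr(, "new_id")`.
#' @name skeleton-edits
NULL

#' @rdname skeleton-edits
#' @export
add_node <- function(skel, position, radius = NA_real_, parent = NA) {
  stopifnot(inherits(skel, "skeleton"), length(position) == 3L)
  if (!is.na(parent)) node_row(skel, parent)  # must exist
  id <- max(skel$nodes$id) + 1L
  lvl <- if (is.na(parent)) 0L else
    skel$nodes$level[node_row(skel, parent)] + 1L
  skel$nodes <- rbind(skel$nodes,
                      data.frame(id = id, x = position[1], y = position[2],
                                 z = position[3], level = lvl,
                                 parent = as.integer(parent), radius = radius,
                                 comp = NA_integer_, n_members = 0L))
  skel$members <- c(skel$members, setNames(list(integer(0)), id))
  skel <- journal_add(skel, "add_node",
                      list(position = as.numeric(position), radius = radius,
                           parent = parent, id = id))
  check_skeleton(skel)
  attr(skel, "new_id") <- id
  skel
}

#' @rdname skeleton-edits
#' @export
delete_node <- function(skel, id) {
  stopifnot(inherits(skel, "skeleton"))
  ri <- node_row(skel, id)
  p <- skel$nodes$parent[ri]
  ch <- skel$nodes$id[!is.na(skel$nodes$parent) & skel$nodes$parent == id]
  skel$nodes$parent[match(ch, skel$nodes$id)] <- p  # NA => orphan roots
  skel$members <- skel$members[-ri]
  skel$nodes <- skel$nodes[-ri, , drop = FALSE]
  rownames(skel$nodes) <- NULL
  skel <- journal_add(skel, "delete_node", list(id = id))
  check_skeleton(skel)
}

#' @rdname skeleton-edits
#' @export
move_node <- function(skel, id, position) {
  stopifnot(inherits(skel, "skeleton"), length(position) == 3L)
  ri <- node_row(skel, id)
  skel$nodes[ri, c("x", "y", "z")] <- as.numeric(position)
  journal_add(skel, "move_node",
              list(id = id, position = as.numeric(position)))
}

#' @rdname skeleton-edits
#' @export
set_radius <- function(skel, id, radius) {
  stopifnot(inherits(skel, "skeleton"), is.numeric(radius), radius > 0)
  ri <- node_row(skel, id)
  skel$nodes$radius[ri] <- radius
  journal_add(skel, "set_radius", list(id = id, radius = radius))
}

#' @rdname skeleton-edits
#' @export
connect_node <- function(skel, child, parent) {
  stopifnot(inherits(skel, "skeleton"))
  ri <- node_row(skel, child)
  node_row(skel, parent)
  if (!is.na(skel$nodes$parent[ri]))
    stop("node ", child, " already has a parent; connecting it would give",
         " it a second one")
  if (parent %in% c(child, descendants_of(skel, child)))
    stop("connecting ", child, " under ", parent, " would create a cycle")
  skel$nodes$parent[ri] <- parent
  skel <- journal_add(skel, "connect_node",
                      list(child = child, parent = parent))
  check_skeleton(skel)
}

#' Replay an edit script
#'
#' Applies an ordered list of journaled edits (as produced on
#' `skeleton$journal`, or read from JSON with [read_edit_script()]) to a
#' skeleton.
#'
#' @param skel a `skeleton`.
#' @param script list of edit entries, each a list with an `op` field
#'   (`add_node`, `delete_node`, `move_node`, `set_radius`,
#'   `connect_node`) and that operation's arguments.
#' @return the edited `skeleton`.
#' @export
apply_edit_script <- function(skel, script) {
  for (e in script) {
    skel <- switch(e$op,
      add_node = add_node(skel, e$position, e$radius %||% NA_real_,
                          e$parent %||% NA),
      delete_node = delete_node(skel, e$id),
      move_node = move_node(skel, e$id, e$position),
      set_radius = set_radius(skel, e$id, e$radius),
      connect_node = connect_node(skel, e$child, e$parent),
      stop("unknown edit op: ", e$op))
  }
  skel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write an edit script as JSON
#' @param path JSON file holding an ordered array of edit objects.
#' @return for `read_edit_script`, the script list.
#' @export
read_edit_script <- function(path) {
  script <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  lapply(script, function(e) {
    e$position <- unlist(e$position)
    e
  })
}

#' @rdname read_edit_script
#' @param script an edit-script list (e.g. `skeleton$journal`).
#' @export
write_edit_script <- function(script, path) {
  jsonlite::write_json(script, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
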