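# Botanical axis ordering and reconstruction-quality metrics.
#
# Both a reconstructed skeleton and a ground-truth segment model reduce to
# the same edge-tree form: one row per edge (node/segment) with a parent
# link, an edge length and a radius used only for tie-breaking.

as_edge_tree <- function(x) UseMethod("as_edge_tree")

#' @export
as_edge_tree.segment_model <- function(x) {
  data.frame(id = x$id, parent = x$parent, length = x$length,
             radius = x$base_radius)
}

#' @export
as_edge_tree.skeleton <- function(x) {
  nd <- x$nodes
  pidx <- match(nd$parent, nd$id)
  len <- ifelse(is.na(pidx), 0,
                sqrt((nd$x - nd$x[pmax(pidx, 1L)])^2 +
                     (nd$y - nd$y[pmax(pidx, 1L)])^2 +
                     (nd$z - nd$z[pmax(pidx, 1L)])^2))
  # a skeleton node of a non-root level contributes the edge down to its
  # parent; roots carry zero length and only anchor their tree
  data.frame(id = nd$id, parent = nd$parent, length = len,
             radius = nd$radius)
}

#' Decompose a tree into botanically ordered axes
#'
#' Assigns every edge to exactly one axis following the botanical ordering
#' convention: the main stem (order 1) is traced from the root by choosing,
#' at each junction, the child bearing the largest total subtree length
#' (ties: larger radius, then smaller id); every other child starts a new
#' axis of order parent + 1, recursively to the tips. A forest is ordered
#' tree by tree (each root starting an order-1 axis) and flagged.
#'
#' @param x a `skeleton` or [segment_model()].
#' @return object of class `axis_decomposition`: data.frame with one row
#'   per axis (`axis`, `order`, `length`, `n_edges`, `parent_axis`), the
#'   per-edge axis assignment as `attr(, "edge_axis")`, and
#'   `attr(, "multi_root")`.
#' @export
assign_axis_orders <- function(x) {
  tr <- as_edge_tree(x)
  n <- nrow(tr)
  idx_parent <- match(tr$parent, tr$id)
  kids <- split(seq_len(n), factor(idx_parent, levels = seq_len(n)))

  # total subtree length per edge, children before parents
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(idx_parent[j])) { d <- d + 1L; j <- idx_parent[j] }
    depth[i] <- d
  }
  subtree <- tr$length
  for (i in order(depth, decreasing = TRUE)) {
    p <- idx_parent[i]
    if (!is.na(p)) subtree[p] <- subtree[p] + subtree[i]
  }

  roots <- which(is.na(idx_parent))
  axis_of <- integer(n)
  axes <- list()
  # iterative DFS: start an axis at `start` with the given order, follow
  # the main-continuation child until a leaf, spawning side axes
  queue <- lapply(roots, function(r) list(start = r, order = 1L,
                                          parent_axis = NA_integer_))
  while (length(queue)) {
    job <- queue[[1L]]; queue <- queue[-1L]
    ax <- length(axes) + 1L
    node <- job$start
    len <- 0; ne <- 0L
    repeat {
      axis_of[node] <- ax
      len <- len + tr$length[node]
      ne <- ne + 1L
      ch <- kids[[node]]
      if (length(ch) == 0L) break
      rad <- ifelse(is.na(tr$radius[ch]), -Inf, tr$radius[ch])
      main <- ch[order(-subtree[ch], -rad, tr$id[ch])][1L]
      for (s in setdiff(ch, main))
        queue[[length(queue) + 1L]] <- list(start = s,
                                            order = job$order + 1L,
                                            parent_axis = ax)
      node <- main
    }
    axes[[ax]] <- data.frame(axis = ax, order = job$order, length = len,
                             n_edges = ne, parent_axis = job$parent_axis)
  }
  out <- do.call(rbind, axes)
  class(out) <- c("axis_decomposition", "data.frame")
  attr(out, "edge_axis") <- setNames(axis_of, tr$id)
  attr(out, "multi_root") <- length(roots) > 1L
  if (length(roots) > 1L)
    warning("input is a forest with ", length(roots),
            " roots; each tree was ordered independently")
  out
}

#' Compare a reconstruction against reference structure, per axis order
#'
#' Aggregates both decompositions by order and reports, per order and in
#' total: measured axis count M and reconstructed count R, measured and
#' reconstructed cumulative length, the percentage detected
#' `R / M * 100`, and the error `|M - R| / M * 100` (analogously for
#' lengths). Matching is by aggregate counts and lengths per order, not by
#' one-to-one axis correspondence. Orders reconstructed but absent from
#' the reference (M = 0, R > 0) are flagged spurious with undefined
#' percentages.
#'
#' @param reference [assign_axis_orders()] of the ground truth.
#' @param reconstructed [assign_axis_orders()] of the reconstruction.
#' @return object of class `validation_report`: data.frame with one row
#'   per order plus a `"total"` row, columns `order`, `M`, `R`,
#'   `M_length`, `R_length`, `pct_detected`, `axis_error_pct`,
#'   `pct_length_detected`, `length_error_pct`, `spurious`.
#' @export
compare_decompositions <- function(reference, reconstructed) {
  stopifnot(inherits(reference, "axis_decomposition"),
            inherits(reconstructed, "axis_decomposition"))
  orders <- sort(unique(c(reference$order, reconstructed$order)))
  agg <- function(dec, o)
    c(n = sum(dec$order == o), len = sum(dec$length[dec$order == o]))
  rows <- lapply(orders, function(o) {
    m <- agg(reference, o); r <- agg(reconstructed, o)
    data.frame(order = as.character(o), M = m[["n"]], R = r[["n"]],
               M_length = m[["len"]], R_length = r[["len"]])
  })
  tot <- data.frame(order = "total",
                    M = nrow(reference), R = nrow(reconstructed),
                    M_length = sum(reference$length),
                    R_length = sum(reconstructed$length))
  out <- rbind(do.call(rbind, rows), tot)
  pct <- function(r, m) ifelse(m > 0, r / m * 100, NA_real_)
  err <- function(r, m) ifelse(m > 0, abs(m - r) / m * 100, NA_real_)
  out$pct_detected <- pct(out$R, out$M)
  out$axis_error_pct <- err(out$R, out$M)
  out$pct_length_detected <- pct(out$R_length, out$M_length)
  out$length_error_pct <- err(out$R_length, out$M_length)
  out$spurious <- out$M == 0 & out$R > 0
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> per-order axis and cumulative-length detection\n")
  df <- as.data.frame(x)
  df$MR <- sprintf("%d/%d", df$M, df$R)
  df$len_MR <- sprintf("%.2f/%.2f", df$M_length, df$R_length)
  print(df[, c("order", "MR", "axis_error_pct", "len_MR",
               "length_error_pct")], row.names = FALSE, digits = 3)
  if (any(x$spurious))
    cat("note: order(s) ", paste(x$order[x$spurious], collapse = ", "),
        " are spurious detections (absent from the reference)\n")
  invisible(x)
}

#' Write a validation report as TSV
#' @param report a [compare_decompositions()] result.
#' @param path output file.
#' @export
write_report_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
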