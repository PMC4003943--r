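# JSON persistence for skeletons and synthetic segment models. Every file
# embeds the provenance (configuration, seed, package version) needed to
# regenerate it.

provenance_block <- function(extra = list()) {
  c(list(package = "treeskel",
         version = as.character(packageVersion("treeskel"))),
    extra)
}

#' Write / read a skeleton as JSON
#'
#' The schema holds one object per node (`id`, `position`, `level`,
#' `parent`, `radius`, `n_members`), the journal of edits, and a
#' provenance block (reconstruction configuration, seed, package version).
#'
#' @param skeleton a `skeleton`.
#' @param path JSON file.
#' @param provenance optional named list stored under `provenance` (e.g.
#'   the [reconstruction_config()] used).
#' @return `read_skeleton_json` returns the `skeleton` (provenance in
#'   `attr(, "provenance")`).
#' @export
write_skeleton_json <- function(skeleton, path, provenance = list()) {
  stopifnot(inherits(skeleton, "skeleton"))
  nd <- skeleton$nodes
  doc <- list(
    type = "skeleton",
    provenance = provenance_block(provenance),
    nodes = lapply(seq_len(nrow(nd)), function(i) list(
      id = nd$id[i],
      position = c(nd$x[i], nd$y[i], nd$z[i]),
      level = nd$level[i],
      parent = nd$parent[i],
      radius = nd$radius[i],
      n_members = nd$n_members[i])),
    journal = skeleton$journal)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_skeleton_json
#' @export
read_skeleton_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$type, "skeleton"))
    stop(path, " is not a skeleton JSON file")
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  int_or_na <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  nd <- do.call(rbind, lapply(doc$nodes, function(n) data.frame(
    id = as.integer(n$id),
    x = as.numeric(n$position[[1]]), y = as.numeric(n$position[[2]]),
    z = as.numeric(n$position[[3]]),
    level = int_or_na(n$level), parent = int_or_na(n$parent),
    radius = num_or_na(n$radius), comp = NA_integer_,
    n_members = int_or_na(n$n_members))))
  skel <- new_skeleton(nd, setNames(rep(list(integer(0)), nrow(nd)), nd$id),
                       journal = doc$journal %||% list())
  check_skeleton(skel)
  attr(skel, "provenance") <- doc$provenance
  skel
}

#' Write / read a synthetic segment model as JSON
#'
#' Ground-truth schema: one object per truncated-cone segment (`id`,
#' `parent`, `base`, `tip`, `base_radius`, `top_radius`, `depth`) plus a
#' provenance block.
#'
#' @param model a [segment_model()].
#' @param path JSON file.
#' @param provenance optional named list (e.g. the grammar parameters).
#' @return `read_segment_model_json` returns the [segment_model()].
#' @export
write_segment_model_json <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "segment_model"))
  doc <- list(
    type = "segment_model",
    provenance = provenance_block(provenance),
    segments = lapply(seq_len(nrow(model)), function(i) list(
      id = model$id[i], parent = model$parent[i],
      base = c(model$x0[i], model$y0[i], model$z0[i]),
      tip = c(model$x1[i], model$y1[i], model$z1[i]),
      base_radius = model$base_radius[i],
      top_radius = model$top_radius[i],
      depth = model$depth[i])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_segment_model_json
#' @export
read_segment_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$type, "segment_model"))
    stop(path, " is not a segment-model JSON file")
  df <- do.call(rbind, lapply(doc$segments, function(s) data.frame(
    id = as.integer(s$id),
    parent = if (is.null(s$parent)) NA_integer_ else as.integer(s$parent),
    x0 = as.numeric(s$base[[1]]), y0 = as.numeric(s$base[[2]]),
    z0 = as.numeric(s$base[[3]]),
    x1 = as.numeric(s$tip[[1]]), y1 = as.numeric(s$tip[[2]]),
    z1 = as.numeric(s$tip[[3]]),
    base_radius = as.numeric(s$base_radius),
    top_radius = as.numeric(s$top_radius),
    depth = as.integer(s$depth))))
  model <- segment_model(df)
  attr(model, "provenance") <- doc$provenance
  model
}
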