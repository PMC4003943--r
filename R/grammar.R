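# Symbol alphabet for the bracketed turtle grammar.
#
# F          emit one truncated-cone segment along the current heading
# A..Z       nonterminals (no geometric effect unless a rule rewrites them;
#            F itself may carry a rule)
# ← →  yaw left / right about the turtle's up vector   (aliases < >)
# ↑ ↓  pitch up / down about the turtle's left vector  (aliases ^ &)
# + -        roll about the heading vector (- also accepted as −)
# [ ]        push / pop the full turtle state

TURN_LEFT  <- "\u2190"
TURN_RIGHT <- "\u2192"
PITCH_UP   <- "\u2191"
PITCH_DOWN <- "\u2193"

normalize_symbols <- function(s) {
  s <- gsub("\\s", "", s)
  s <- chartr("<>^&", paste0(TURN_LEFT, TURN_RIGHT, PITCH_UP, PITCH_DOWN), s)
  gsub("\u2212", "-", s)  # unicode minus -> ASCII
}

symbol_alphabet <- function() {
  c("F", LETTERS, TURN_LEFT, TURN_RIGHT, PITCH_UP, PITCH_DOWN,
    "+", "-", "[", "]")
}

check_symbols <- function(s, what) {
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), symbol_alphabet())
  if (length(bad))
    stop("unknown symbol(s) in ", what, ": ", paste(bad, collapse = " "))
  depth <- cumsum((chars == "[") - (chars == "]"))
  if (any(depth < 0) || (length(depth) && depth[length(depth)] != 0))
    stop("unbalanced brackets in ", what)
  invisible(chars)
}

#' Stochastic L-system grammar specification
#'
#' Defines a bracketed turtle grammar plus the stochastic geometry that
#' turns its expansion into a tree of truncated cones. Rewriting itself is
#' deterministic; only the geometric interpretation (angles, length and
#' radius scaling) draws from normal distributions, so tip and segment
#' counts depend on the grammar alone, never on the seed.
#'
#' Symbols: `F` emits a segment; uppercase letters are nonterminals;
#' `←`/`→` (aliases `<`/`>`) yaw the heading left/right,
#' `↑`/`↓` (aliases `^`/`&`) pitch it up/down, `+`/`-` roll about
#' the heading; `[`/`]` push/pop the turtle state. Each rotation symbol
#' draws its own angle from `N(angle_mean, angle_sd^2)` degrees.
#'
#' @param axiom start string.
#' @param rules named list/character vector mapping a nonterminal to its
#'   replacement string.
#' @param iterations non-negative integer number of parallel rewriting steps.
#' @param angle_mean,angle_sd branching-angle distribution, degrees.
#' @param initial_length root segment length, metres.
#' @param length_scaling_mean,length_scaling_sd per parent-to-child
#'   multiplicative length factor (dimensionless).
#' @param initial_radius root segment base radius, metres.
#' @param radius_scaling_mean,radius_scaling_sd per parent-to-child
#'   multiplicative radius factor (dimensionless).
#' @param seed integer seed for the single random stream used by
#'   [interpret_turtle()].
#' @return object of class `grammar_spec`.
#' @seealso [sapling_grammar()] for the packaged default parameter set.
#' @export
grammar_spec <- function(axiom, rules, iterations,
                         angle_mean = 30, angle_sd = 0,
                         initial_length = 1,
                         length_scaling_mean = 1, length_scaling_sd = 0,
                         initial_radius = 0.1,
                         radius_scaling_mean = 1, radius_scaling_sd = 0,
                         seed = 1L) {
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0L, initial_length > 0, initial_radius > 0,
            angle_sd >= 0, length_scaling_sd >= 0, radius_scaling_sd >= 0)
  axiom <- normalize_symbols(axiom)
  check_symbols(axiom, "axiom")
  rules <- as.list(rules)
  if (length(rules)) {
    if (is.null(names(rules)) || any(!names(rules) %in% c("F", LETTERS)))
      stop("rules must be named by a single nonterminal letter")
    rules <- lapply(rules, normalize_symbols)
    for (nm in names(rules)) check_symbols(rules[[nm]], paste("rule", nm))
  }
  structure(list(axiom = axiom, rules = rules, iterations = iterations,
                 angle_mean = angle_mean, angle_sd = angle_sd,
                 initial_length = initial_length,
                 length_scaling_mean = length_scaling_mean,
                 length_scaling_sd = length_scaling_sd,
                 initial_radius = initial_radius,
                 radius_scaling_mean = radius_scaling_mean,
                 radius_scaling_sd = radius_scaling_sd,
                 seed = as.integer(seed)),
            class = "grammar_spec")
}

#' @export
print.grammar_spec <- function(x, ...) {
  cat("<grammar_spec>\n")
  cat("  axiom:", x$axiom, "\n")
  for (nm in names(x$rules)) cat("  rule:", nm, "->", x$rules[[nm]], "\n")
  cat(sprintf("  iterations: %d; angle %g° ± %g°\n",
              x$iterations, x$angle_mean, x$angle_sd))
  cat(sprintf("  length %g m × %g ± %g; radius %g m × %g ± %g; seed %d\n",
              x$initial_length, x$length_scaling_mean, x$length_scaling_sd,
              x$initial_radius, x$radius_scaling_mean, x$radius_scaling_sd,
              x$seed))
  invisible(x)
}

#' Packaged default synthetic-tree grammar
#'
#' The packaged sapling model: axiom `FA` with the single rule
#' `A -> [↑FA]+++[→FA]` expanded 7 times, branching angle
#' 30° (SD 5°), initial segment length 1 m scaled by 0.75
#' (SD 0.1) per generation, initial radius 0.1 m scaled by 0.75 (SD 0.1).
#' The structure has 255 segments and 128 tips regardless of seed.
#'
#' @param seed integer seed for the geometric draws.
#' @return a [grammar_spec()].
#' @export
sapling_grammar <- function(seed = 42L) {
  grammar_spec(
    axiom = "FA",
    rules = list(A = paste0("[", PITCH_UP, "FA]+++[", TURN_RIGHT, "FA]")),
    iterations = 7L,
    angle_mean = 30, angle_sd = 5,
    initial_length = 1,
    length_scaling_mean = 0.75, length_scaling_sd = 0.1,
    initial_radius = 0.1,
    radius_scaling_mean = 0.75, radius_scaling_sd = 0.1,
    seed = seed)
}

#' Expand an L-system grammar
#'
#' Applies all rules simultaneously to every matching symbol, repeated
#' `spec$iterations` times. Expansion is purely deterministic.
#'
#' @param spec a [grammar_spec()].
#' @return the expanded symbol string.
#' @examples
#' expand_grammar(grammar_spec("F", list(F = "F[<F][>F]"), 1))
#' @export
expand_grammar <- function(spec) {
  stopifnot(inherits(spec, "grammar_spec"))
  chars <- strsplit(spec$axiom, "")[[1]]
  if (spec$iterations == 0L || length(spec$rules) == 0L)
    return(paste(chars, collapse = ""))
  repl <- lapply(spec$rules, function(r) strsplit(r, "")[[1]])
  for (i in seq_len(spec$iterations)) {
    out <- as.list(chars)
    hit <- chars %in% names(repl)
    out[hit] <- repl[chars[hit]]
    chars <- unlist(out, use.names = FALSE)
  }
  paste(chars, collapse = "")
}
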