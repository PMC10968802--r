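#' The symbolic-regression function set
#'
#' Fourteen operators over expression trees: binary `add, sub, mult, div,
#' max, min` and unary `sqrt, log, abs, neg, inv, sin, cos, tan`, each with
#' protected-evaluation semantics so that every evaluation of a valid tree
#' on finite inputs is finite:
#' `div(a, b) = 1` when `|b| < 1e-6`, else `a/b`;
#' `log(x) = 0` when `|x| < 1e-6`, else `log|x|`;
#' `sqrt(x) = sqrt(|x|)`; `inv(x) = 1` when `|x| < 1e-6`, else `1/x`;
#' `tan` is clamped to `[-1e6, 1e6]`. Every operator output is additionally
#' clamped to `[-1e10, 1e10]` (overflow guard) and any `NaN` is mapped to 0.
#'
#' @return A data frame with columns `name`, `id`, `arity`.
#' @export
function_set <- function() {
  data.frame(
    name = c("add", "sub", "mult", "div", "max", "min",
             "sqrt", "log", "abs", "neg", "inv", "sin", "cos", "tan"),
    id = 1:14,
    arity = c(rep(2L, 6), rep(1L, 8)),
    stringsAsFactors = FALSE
  )
}

.fs <- local({
  fs <- data.frame(
    name = c("add", "sub", "mult", "div", "max", "min",
             "sqrt", "log", "abs", "neg", "inv", "sin", "cos", "tan"),
    id = 1:14,
    arity = c(rep(2L, 6), rep(1L, 8)),
    stringsAsFactors = FALSE
  )
  list(table = fs,
       arity = c(rep(2L, 6), rep(1L, 8)),
       id_by_name = setNames(fs$id, fs$name))
})

.op_arity <- function(op) ifelse(op > 0L, .fs$arity[op], 0L)

.new_tree <- function(ops, consts) {
  structure(list(ops = as.integer(ops), consts = as.numeric(consts)),
            class = "expression_tree")
}

.check_tree <- function(tree) {
  if (!inherits(tree, "expression_tree"))
    stop("not an expression_tree")
  n <- length(tree$ops)
  if (n == 0L || length(tree$consts) != n)
    stop("malformed expression tree")
  # arity consistency: the subtree starting at node 1 must span exactly n
  if (subtree_end_cpp(tree$ops, 1L) != n)
    stop("malformed expression tree: arity-inconsistent encoding")
  invisible(tree)
}

#' Leaf and call constructors for expression trees
#'
#' @param x A constant value, or for `gp_call` an operator name.
#' @param ... Child trees (or bare numbers, promoted to constant leaves).
#' @return An `expression_tree`.
#' @examples
#' eval_tree(gp_call("add", gp_call("mult", 2, gp_var()), 1), 3)  # 7
#' @export
gp_var <- function() .new_tree(0L, NA_real_)

#' @rdname gp_var
#' @export
gp_const <- function(x) .new_tree(-1L, as.numeric(x))

#' @rdname gp_var
#' @export
gp_call <- function(x, ...) {
  id <- unname(.fs$id_by_name[x])
  if (is.na(id)) stop("unknown operator: ", x)
  kids <- lapply(list(...), function(k) {
    if (is.numeric(k)) gp_const(k) else .check_tree(k)
  })
  if (length(kids) != .fs$arity[id])
    stop("operator `", x, "` expects ", .fs$arity[id], " children")
  .new_tree(c(id, unlist(lapply(kids, `[[`, "ops"))),
            c(NA_real_, unlist(lapply(kids, `[[`, "consts"))))
}

#' Evaluate an expression tree at time values
#'
#' Element-wise protected evaluation (see [function_set()] for the exact
#' semantics); the output is finite for any finite input.
#'
#' @param tree An `expression_tree`.
#' @param t_values Numeric vector of time values.
#' @return Numeric vector of the same length as `t_values`.
#' @export
eval_tree <- function(tree, t_values) {
  .check_tree(tree)
  eval_program_cpp(tree$ops, tree$consts, as.numeric(t_values))
}

#' Number of nodes and depth of an expression tree
#'
#' A single leaf has `node_count` 1 and `tree_depth` 0.
#'
#' @param tree An `expression_tree`.
#' @export
node_count <- function(tree) length(tree$ops)

#' @rdname node_count
#' @export
tree_depth <- function(tree) program_depth_cpp(tree$ops)

# draw one terminal leaf: the variable with prob 1/2, otherwise a constant
# (uniform on const_range with prob 1/2, else an integer 0..int_const_max)
.random_terminal <- function(config) {
  if (runif(1) < 0.5) return(list(op = 0L, const = NA_real_))
  if (runif(1) < 0.5) {
    list(op = -1L, const = runif(1, config$const_range[1], config$const_range[2]))
  } else {
    list(op = -1L, const = as.numeric(sample.int(config$int_const_max + 1L, 1L) - 1L))
  }
}

#' Draw a random expression tree
#'
#' `full` builds trees whose leaves all sit at the drawn target depth;
#' `grow` may terminate branches early (each interior position is an
#' operator with probability 0.6, keeping early building blocks small) but
#' never exceeds the target depth. The
#' target depth is drawn uniformly from `depth_range`. Draws from the
#' current R RNG stream; seed beforehand for reproducibility.
#'
#' @param method `"full"` or `"grow"`.
#' @param depth_range Integer pair `(min, max)` of target depths.
#' @param config A [gp_config()] supplying the constant ranges.
#' @return An `expression_tree`.
#' @export
random_tree <- function(method = c("grow", "full"),
                        depth_range = c(2L, 6L),
                        config = gp_config()) {
  method <- match.arg(method)
  depth_range <- as.integer(depth_range)
  if (any(depth_range < 0L) || depth_range[1] > depth_range[2])
    stop("invalid depth_range")
  target <- if (depth_range[1] == depth_range[2]) depth_range[1] else
    sample(seq(depth_range[1], depth_range[2]), 1L)
  ops <- integer(0); consts <- numeric(0)
  build <- function(depth) {
    make_terminal <- depth >= target ||
      (method == "grow" && depth > 0 && runif(1) >= 0.6)
    if (make_terminal) {
      leaf <- .random_terminal(config)
      ops <<- c(ops, leaf$op); consts <<- c(consts, leaf$const)
    } else {
      id <- sample.int(14L, 1L)
      ops <<- c(ops, id); consts <<- c(consts, NA_real_)
      for (i in seq_len(.fs$arity[id])) build(depth + 1L)
    }
  }
  build(0L)
  .new_tree(ops, consts)
}

#' Serialize an expression tree to its canonical prefix string
#'
#' Prefix notation with explicit parentheses, e.g. `"add(t, 2.5)"`.
#' Constants are printed with `%.17g` so that `parse_tree(serialize_tree(x))`
#' is structurally identical to `x`.
#'
#' @param tree An `expression_tree`.
#' @return A character scalar.
#' @export
serialize_tree <- function(tree) {
  .check_tree(tree)
  ops <- tree$ops; consts <- tree$consts
  emit <- function(i) {
    op <- ops[i]
    if (op == 0L) return(list(str = "t", nxt = i + 1L))
    if (op == -1L) return(list(str = sprintf("%.17g", consts[i]), nxt = i + 1L))
    kids <- character(.fs$arity[op])
    j <- i + 1L
    for (k in seq_along(kids)) {
      res <- emit(j); kids[k] <- res$str; j <- res$nxt
    }
    list(str = paste0(.fs$table$name[op], "(", paste(kids, collapse = ", "), ")"),
         nxt = j)
  }
  emit(1L)$str
}

#' Parse a canonical prefix string into an expression tree
#'
#' Inverse of [serialize_tree()]. Malformed input raises an error naming the
#' character position of the problem.
#'
#' @param text A character scalar such as `"add(t, 2.5)"`.
#' @return An `expression_tree`.
#' @export
parse_tree <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single string")
  pat <- "[a-zA-Z_][a-zA-Z0-9_]*|[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?|[(),]"
  m <- gregexpr(pat, text)[[1]]
  tokens <- regmatches(text, gregexpr(pat, text))[[1]]
  starts <- as.integer(m)
  residue <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", residue))
    stop("parse error: unexpected characters in expression")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  where <- function() if (pos <= length(tokens)) starts[pos] else nchar(text) + 1L
  advance <- function() pos <<- pos + 1L
  expect <- function(tok) {
    if (!identical(peek(), tok))
      stop(sprintf("parse error at position %d: expected '%s', got '%s'",
                   where(), tok, ifelse(is.na(peek()), "<end>", peek())))
    advance()
  }
  parse_expr <- function() {
    tok <- peek()
    if (is.na(tok))
      stop(sprintf("parse error at position %d: unexpected end of input", where()))
    if (tok == "t") { advance(); return(gp_var()) }
    if (grepl("^[-+]?[0-9.]", tok)) { advance(); return(gp_const(as.numeric(tok))) }
    id <- unname(.fs$id_by_name[tok])
    if (is.na(id))
      stop(sprintf("parse error at position %d: unknown operator '%s'", where(), tok))
    advance(); expect("(")
    kids <- list(parse_expr())
    while (identical(peek(), ",")) { advance(); kids <- c(kids, list(parse_expr())) }
    expect(")")
    if (length(kids) != .fs$arity[id])
      stop(sprintf("parse error: operator '%s' expects %d arguments, got %d",
                   tok, .fs$arity[id], length(kids)))
    do.call(gp_call, c(list(tok), kids))
  }
  out <- parse_expr()
  if (!is.na(peek()))
    stop(sprintf("parse error at position %d: trailing input '%s'", where(), peek()))
  out
}

#' @export
print.expression_tree <- function(x, ...) {
  cat("<expression_tree> ", serialize_tree(x), "\n", sep = "")
  invisible(x)
}
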