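#' Expression trees for symbolic hazard models
#'
#' An expression tree encodes the log-odds \eqn{\varepsilon} of the
#' discrete-time hazard as a function of baseline covariates and the time
#' interval index `tj`. Internally a tree is an R language object built from
#' the protected primitive set (see [gp-primitives]); leaves are covariate
#' symbols, the time terminal `tj`, or numeric constants.
#'
#' `gp_tree()` wraps a parsed expression with the metadata needed to use it
#' as a hazard model: the terminal set it may reference, the interval width
#' it was trained with, and any preprocessing (winsorisation limits,
#' centring/scaling) that must be applied to new data before evaluation.
#'
#' @param expr an R language object over the primitive set.
#' @param terminals character vector of legal leaf symbols (covariate names;
#'   `"tj"` is always allowed and added if absent).
#' @param delta interval width in years used when the tree is interpreted as
#'   a discrete-time hazard model.
#' @param preprocess optional list with elements `winsor` and/or `scaling`
#'   as produced by [winsorize()] / [standardize()].
#' @param trained_intervals highest interval index seen in training; used to
#'   refuse extrapolation when predicting.
#' @return An object of class `gp_tree` implementing the hazard-model
#'   contract ([log_odds()]).
#' @seealso [parse_tree()], [serialize_tree()], [log_odds()]
#' @export
gp_tree <- function(expr, terminals, delta = 1, preprocess = NULL,
                    trained_intervals = NULL) {
  terminals <- union(terminals, "tj")
  structure(
    list(expr = expr, terminals = terminals, delta = delta,
         preprocess = preprocess, trained_intervals = trained_intervals),
    class = c("gp_tree", "hazard_model")
  )
}

#' @export
print.gp_tree <- function(x, ...) {
  cat("<gp_tree> depth", tree_depth(x$expr), "| size", tree_size(x$expr), "\n")
  cat(" ", serialize_tree(x), "\n")
  invisible(x)
}

# ---- structural helpers on language objects ------------------------------

#' Tree structure measures
#'
#' Depth counts levels (a single leaf has depth 1); size counts nodes.
#' Both accept a `gp_tree` or a bare language object.
#'
#' @param x a `gp_tree` or language object.
#' @return integer scalar.
#' @export
tree_depth <- function(x) {
  e <- tree_expr(x)
  if (!is.call(e)) return(1L)
  1L + max(vapply(as.list(e)[-1], tree_depth, integer(1)))
}

#' @rdname tree_depth
#' @export
tree_size <- function(x) {
  e <- tree_expr(x)
  if (!is.call(e)) return(1L)
  1L + sum(vapply(as.list(e)[-1], tree_size, integer(1)))
}

tree_expr <- function(x) if (inherits(x, "gp_tree")) x$expr else x

#' Covariates referenced by a tree
#'
#' @param x a `gp_tree` or language object.
#' @return character vector of distinct leaf symbols (including `"tj"` if
#'   the time terminal appears).
#' @export
predictors_used <- function(x) {
  e <- tree_expr(x)
  syms <- character(0)
  walk <- function(e) {
    if (is.symbol(e)) {
      syms[[length(syms) + 1L]] <<- as.character(e)
    } else if (is.call(e)) {
      for (a in as.list(e)[-1]) walk(a)
    }
  }
  walk(e)
  unique(syms)
}

# subtree_at / replace_at index nodes in preorder, root = 1
node_count <- tree_size

subtree_at <- function(e, k) {
  if (k == 1L) return(e)
  k <- k - 1L
  for (a in as.list(e)[-1]) {
    m <- tree_size(a)
    if (k <= m) return(subtree_at(a, k))
    k <- k - m
  }
  stop("node index out of range", call. = FALSE)
}

replace_at <- function(e, k, sub) {
  if (k == 1L) return(sub)
  k <- k - 1L
  args <- as.list(e)[-1]
  for (i in seq_along(args)) {
    m <- tree_size(args[[i]])
    if (k <= m) {
      e[[i + 1L]] <- replace_at(args[[i]], k, sub)
      return(e)
    }
    k <- k - m
  }
  stop("node index out of range", call. = FALSE)
}

# ---- evaluation ----------------------------------------------------------

# evaluate a bare expression on an environment of covariate columns;
# result is recycled to n rows
eval_expr <- function(expr, env, n) {
  out <- eval(expr, envir = env)
  if (length(out) != n) out <- rep_len(out, n)
  out
}

make_data_env <- function(data) {
  list2env(as.list(data), parent = asNamespace("survgp"))
}

#' Evaluate a tree's log-odds on data
#'
#' @param tree a `gp_tree`.
#' @param data data frame with one column per referenced covariate plus a
#'   `tj` column (the interval index terminal).
#' @return numeric vector of log-odds, one per row of `data`; guaranteed
#'   finite for finite inputs.
#' @export
evaluate_tree <- function(tree, data) {
  expr <- tree_expr(tree)
  need <- predictors_used(expr)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("unknown covariate reference: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  eval_expr(expr, make_data_env(data), nrow(data))
}

# ---- serialisation / parsing --------------------------------------------

#' Serialise and parse expression trees
#'
#' The interchange grammar is parenthesised infix: binary `+ - * /` with the
#' usual precedence, the unary functions `sin cos tan sqrt exp log`, numeric
#' constants, covariate names, and the time terminal `tj`. On parsing, the
#' surface operators are mapped to their protected internal counterparts, so
#' `parse_tree(serialize_tree(t))` evaluates identically to `t` everywhere.
#'
#' @param tree a `gp_tree` or language object.
#' @param text a single string in the grammar.
#' @param terminals legal leaf symbols for the parsed tree (`"tj"` always
#'   allowed).
#' @param ... passed on to [gp_tree()] (e.g. `delta`).
#' @return `serialize_tree()` returns a string; `parse_tree()` a `gp_tree`.
#' @examples
#' t <- parse_tree("x1 + sin(x2) / 2", terminals = c("x1", "x2"))
#' serialize_tree(t)
#' @export
serialize_tree <- function(tree) {
  fmt_expr(tree_expr(tree))$text
}

# shortest decimal representation that parses back to exactly x
fmt_const <- function(x) {
  for (d in c(15L, 16L, 17L)) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  s
}

# precedence-aware printer; binary ops are left-associative, so a right
# child of equal precedence is parenthesised
fmt_expr <- function(e) {
  if (is.numeric(e)) {
    s <- fmt_const(e)
    return(list(text = if (e < 0) paste0("(", s, ")") else s, prec = 4L))
  }
  if (is.symbol(e)) return(list(text = as.character(e), prec = 4L))
  op <- as.character(e[[1]])
  surf <- .gp_surface[[op]]
  if (is.null(surf)) stop("unknown operator in tree: ", op, call. = FALSE)
  if (op %in% .gp_binary_ops) {
    p <- if (surf %in% c("+", "-")) 1L else 2L
    l <- fmt_expr(e[[2]])
    r <- fmt_expr(e[[3]])
    lt <- if (l$prec < p) paste0("(", l$text, ")") else l$text
    rt <- if (r$prec <= p) paste0("(", r$text, ")") else r$text
    return(list(text = paste(lt, surf, rt), prec = p))
  }
  list(text = paste0(surf, "(", fmt_expr(e[[2]])$text, ")"), prec = 4L)
}

#' @rdname serialize_tree
#' @export
parse_tree <- function(text, terminals, ...) {
  stopifnot(is.character(text), length(text) == 1)
  e <- tryCatch(
    str2lang(text),
    error = function(err) {
      stop("syntax error in expression: ", conditionMessage(err),
           call. = FALSE)
    }
  )
  terminals <- union(terminals, "tj")
  expr <- from_surface(e, terminals)
  gp_tree(expr, terminals = terminals, ...)
}

from_surface <- function(e, terminals) {
  if (is.numeric(e)) return(e)
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% terminals) {
      stop("unknown symbol '", nm, "' (not in the declared terminal set)",
           call. = FALSE)
    }
    return(e)
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    # strip grouping parentheses
    if (op == "(") return(from_surface(e[[2]], terminals))
    # unary minus: fold constants, otherwise rewrite as (0 - x)
    if (op == "-" && length(e) == 2) {
      arg <- from_surface(e[[2]], terminals)
      if (is.numeric(arg)) return(-arg)
      return(as.call(list(as.name("-"), 0, arg)))
    }
    if (op == "+" && length(e) == 2) return(from_surface(e[[2]], terminals))
    internal <- unname(.gp_internal[op])
    if (is.null(internal) || is.na(internal)) {
      stop("unknown operator '", op, "' in expression", call. = FALSE)
    }
    arity <- if (internal %in% .gp_binary_ops) 2L else 1L
    if (length(e) - 1L != arity) {
      stop("operator '", op, "' expects ", arity, " argument(s)",
           call. = FALSE)
    }
    args <- lapply(as.list(e)[-1], from_surface, terminals = terminals)
    return(as.call(c(as.name(internal), args)))
  }
  stop("unsupported token in expression: ", deparse(e), call. = FALSE)
}

# ---- worked example model ------------------------------------------------

#' A previously evolved six-predictor cardiovascular risk model
#'
#' A fixed symbolic hazard model over standardised covariates (age, a
#' prior-atherosclerosis sum score, female sex, intima media thickness,
#' homocysteine, normal-albumin indicator) and the time terminal `tj`,
#' shipped as a parse/evaluation fixture and as a worked example of the
#' expression grammar. The covariate suffix `n` marks inputs standardised
#' to mean 0 / sd 1 on the derivation data.
#'
#' @return A `gp_tree` over the terminals
#'   `AGEn, HISTCAR2n, SEXfemale.n, IMTn, HOMOCn, ALBUMINNo.n, tj`.
#' @export
example_evolved_model <- function() {
  txt <- paste0(
    "(tj - (0.441 + tj)) * exp(sin(sin(ALBUMINNo.n))) * ",
    "exp((HOMOCn + AGEn) / tan(1.889)) * ",
    "cos((tan(SEXfemale.n) + HOMOCn + AGEn) / ",
    "exp(cos((tan(tan(exp(HISTCAR2n))) + sin(IMTn) + sin(IMTn)) / ",
    "tan(1.886)))) * 2.487 - ",
    "exp(cos(HISTCAR2n / tan(tan(-1.813)) / tan(tan(tan(0.739)))))"
  )
  parse_tree(
    txt,
    terminals = c("AGEn", "HISTCAR2n", "SEXfemale.n", "IMTn", "HOMOCn",
                  "ALBUMINNo.n")
  )
}
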