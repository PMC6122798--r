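# Postfix-program form of expression trees.
#
# The evolution loop compiles every individual to a flat postorder program
# (parallel opcode/value vectors) evaluated by the C++ stack machine in
# src/evaluator.cpp. Subtrees are contiguous slices of a postfix program, so
# subtree crossover and mutation reduce to vector splicing, which keeps the
# steady-state loop free of per-node R recursion. Programs and language
# objects encode exactly the same trees; tests assert the two evaluation
# paths agree.

.op_code <- c("+" = 1L, "-" = 2L, "gp_mul" = 3L, "gp_div" = 4L,
              "sin" = 5L, "cos" = 6L, "gp_tan" = 7L, "gp_sqrt" = 8L,
              "gp_exp" = 9L, "gp_log" = 10L)
.code_op <- names(.op_code)

compile_program <- function(expr, terminals) {
  code <- integer(0)
  val <- numeric(0)
  rec <- function(e) {
    if (is.numeric(e)) {
      code[[length(code) + 1L]] <<- 12L
      val[[length(val) + 1L]] <<- as.numeric(e)
    } else if (is.symbol(e)) {
      idx <- match(as.character(e), terminals)
      if (is.na(idx)) {
        stop("unknown terminal: ", as.character(e), call. = FALSE)
      }
      code[[length(code) + 1L]] <<- 11L
      val[[length(val) + 1L]] <<- idx
    } else {
      for (a in as.list(e)[-1]) rec(a)
      code[[length(code) + 1L]] <<- .op_code[[as.character(e[[1]])]]
      val[[length(val) + 1L]] <<- 0
    }
  }
  rec(expr)
  list(code = code, val = val)
}

program_to_expr <- function(prog, terminals) {
  stack <- vector("list", 64)
  top <- 0L
  for (i in seq_along(prog$code)) {
    op <- prog$code[i]
    if (op == 12L) {
      top <- top + 1L
      if (top > length(stack)) stack <- c(stack, vector("list", 64))
      stack[[top]] <- prog$val[i]
    } else if (op == 11L) {
      top <- top + 1L
      if (top > length(stack)) stack <- c(stack, vector("list", 64))
      stack[[top]] <- as.name(terminals[prog$val[i]])
    } else if (op <= 4L) {
      e <- as.call(list(as.name(.code_op[op]), stack[[top - 1L]],
                        stack[[top]]))
      top <- top - 1L
      stack[[top]] <- e
    } else {
      stack[[top]] <- as.call(list(as.name(.code_op[op]), stack[[top]]))
    }
  }
  stack[[1L]]
}

prog_size <- function(prog) length(prog$code)

# splice `sub` in place of the subtree ending at position pos
prog_splice <- function(prog, pos, sub) {
  s <- .prog_subtree_start(prog$code, pos)
  L <- length(prog$code)
  list(
    code = c(prog$code[seq_len(s - 1L)], sub$code,
             if (pos < L) prog$code[(pos + 1L):L] else integer(0)),
    val = c(prog$val[seq_len(s - 1L)], sub$val,
            if (pos < L) prog$val[(pos + 1L):L] else numeric(0))
  )
}

# extract the subtree (as a program) ending at position pos
prog_extract <- function(prog, pos) {
  s <- .prog_subtree_start(prog$code, pos)
  list(code = prog$code[s:pos], val = prog$val[s:pos])
}

# program-level subtree crossover with depth-cap rejection (child that
# would exceed the cap is replaced by its parent)
px_crossover <- function(p1, p2, max_depth) {
  pos1 <- sample.int(length(p1$code), 1L)
  pos2 <- sample.int(length(p2$code), 1L)
  s1 <- prog_extract(p1, pos1)
  s2 <- prog_extract(p2, pos2)
  c1 <- prog_splice(p1, pos1, s2)
  c2 <- prog_splice(p2, pos2, s1)
  if (.prog_depth(c1$code) > max_depth) c1 <- p1
  if (.prog_depth(c2$code) > max_depth) c2 <- p2
  list(c1, c2)
}

# program-level subtree mutation: replace a uniformly chosen node by a
# freshly grown subtree, retrying under the depth cap
px_mutate <- function(p, terminals, config, retries = 5L) {
  for (r in seq_len(retries)) {
    pos <- sample.int(length(p$code), 1L)
    d <- sample(seq(config$mutation_depth[1], config$mutation_depth[2]), 1L)
    sub <- compile_program(grow_tree(d, terminals, config$const_range),
                           terminals)
    out <- prog_splice(p, pos, sub)
    if (.prog_depth(out$code) <= config$max_depth) return(out)
  }
  p
}
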