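# Recursive-descent parser for Boolean expressions in the BoolNet dialect:
#   expr   := term ('|' term)*
#   term   := factor ('&' factor)*
#   factor := '!' factor | '(' expr ')' | identifier | 0 | 1
# Identifiers may contain letters, digits, '_', '.' and '-'.
# Returned AST nodes are lists: list(op = "var"|"const"|"not"|"and"|"or", ...).

bool_tokenize <- function(s) {
  pat <- "[A-Za-z0-9_.-]+|[&|!()]"
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  if (nchar(gsub(pat, "", gsub("[[:space:]]", "", s))) > 0)
    stop("malformed expression: ", s)
  toks
}

parse_bool_expr <- function(s) {
  toks <- bool_tokenize(s)
  if (length(toks) == 0L) stop("empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  p_expr <- function() {
    node <- p_term()
    while (!is.na(peek()) && peek() == "|") {
      advance()
      node <- list(op = "or", lhs = node, rhs = p_term())
    }
    node
  }
  p_term <- function() {
    node <- p_factor()
    while (!is.na(peek()) && peek() == "&") {
      advance()
      node <- list(op = "and", lhs = node, rhs = p_factor())
    }
    node
  }
  p_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression")
    if (t == "!") { advance(); return(list(op = "not", arg = p_factor())) }
    if (t == "(") {
      advance()
      node <- p_expr()
      if (is.na(peek()) || peek() != ")") stop("missing closing parenthesis")
      advance()
      return(node)
    }
    if (t %in% c("0", "1")) { advance(); return(list(op = "const", value = as.integer(t))) }
    if (grepl("^[A-Za-z0-9_.-]+$", t)) { advance(); return(list(op = "var", name = t)) }
    stop("unexpected token: ", t)
  }
  node <- p_expr()
  if (pos <= length(toks)) stop("trailing tokens in expression: ", toks[pos])
  node
}

bool_expr_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         not = bool_expr_vars(ast$arg),
         unique(c(bool_expr_vars(ast$lhs), bool_expr_vars(ast$rhs))))
}

# Variables in left-to-right first-appearance order (regulator order).
bool_expr_vars_ordered <- function(ast) {
  walk <- function(a) switch(a$op,
                             var = a$name,
                             const = character(0),
                             not = walk(a$arg),
                             c(walk(a$lhs), walk(a$rhs)))
  unique(walk(ast))
}

# env: named list of integer vectors of common length n (vectorized eval).
eval_bool_expr <- function(ast, env, n) {
  switch(ast$op,
         var = env[[ast$name]],
         const = rep(ast$value, n),
         not = 1L - eval_bool_expr(ast$arg, env, n),
         and = eval_bool_expr(ast$lhs, env, n) * eval_bool_expr(ast$rhs, env, n),
         or = {
           a <- eval_bool_expr(ast$lhs, env, n)
           b <- eval_bool_expr(ast$rhs, env, n)
           1L - (1L - a) * (1L - b)
         })
}
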