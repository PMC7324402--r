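#' Boolean update function for one module
#'
#' A function \eqn{f_i} over module states, stored as an ordered regulator
#' list plus an explicit truth table, together with an equivalent AND/OR/NOT
#' expression in the `targets, factors` rule dialect (`!`, `&`, `|`,
#' parentheses, identifiers `M1..Mm`, constants `0`/`1`).
#'
#' Truth-table row order: the row for a regulator pattern is
#' `1 + sum(bits * 2^(0:(k-1)))`, i.e. the first listed regulator is the
#' least significant bit.
#'
#' @param target index of the regulated module.
#' @param regulators integer vector of regulator module indices (ascending).
#' @param tt 0/1 integer vector of length `2^length(regulators)`.
#' @param expr optional expression text; synthesized from the truth table
#'   when omitted.
#' @return An object of class `boolean_function`.
#' @export
boolean_function <- function(target, regulators, tt, expr = NULL) {
  regulators <- as.integer(regulators)
  if (is.unsorted(regulators, strictly = TRUE) && length(regulators) > 1L)
    stopf("regulators must be strictly ascending module indices")
  tt <- check_bits(tt)
  if (length(tt) != 2^length(regulators))
    stopf("truth table must have 2^%d rows, got %d", length(regulators), length(tt))
  if (is.null(expr)) expr <- expr_from_tt(regulators, tt)
  structure(list(target = as.integer(target), regulators = regulators,
                 tt = tt, expr = expr),
            class = "boolean_function")
}

#' Synchronous Boolean network over gene modules
#'
#' @param functions list of `boolean_function` objects, one per module, in
#'   module order (element i regulates module i).
#' @return An object of class `boolean_network` with fields `m` and
#'   `functions`.
#' @export
boolean_network <- function(functions) {
  m <- length(functions)
  for (i in seq_len(m)) {
    fn <- functions[[i]]
    if (!inherits(fn, "boolean_function")) stopf("element %d is not a boolean_function", i)
    if (length(fn$regulators) && max(fn$regulators) > m)
      stopf("function for M%d references regulator M%d outside 1..%d",
            i, max(fn$regulators), m)
    functions[[i]]$target <- i
  }
  structure(list(m = m, functions = functions), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean gene-modular network, %d modules\n", x$m))
  for (fn in x$functions) cat(sprintf("  M%d, %s\n", fn$target, fn$expr))
  invisible(x)
}

#' Evaluate one update rule at a state
#'
#' @param fn a `boolean_function`.
#' @param state full module state (0/1 vector, M1 first) or a bit-string.
#' @return A single 0/1 integer.
#' @export
evaluate_rule <- function(fn, state) {
  stopifnot(inherits(fn, "boolean_function"))
  if (is.character(state)) state <- string_to_state(state)
  state <- check_bits(state)
  if (length(fn$regulators) && max(fn$regulators) > length(state))
    stopf("state has %d modules but the rule reads M%d",
          length(state), max(fn$regulators))
  k <- length(fn$regulators)
  idx <- if (k == 0L) 1L else 1L + sum(state[fn$regulators] * 2^(seq_len(k) - 1L))
  fn$tt[idx]
}

#' Synchronous update of all modules
#'
#' Applies \eqn{s_i(j+1) = f_i(s_1(j), \ldots, s_m(j))} simultaneously to
#' every module.
#'
#' @param net a `boolean_network`.
#' @param state 0/1 state vector or bit-string of length `net$m`.
#' @return Integer 0/1 vector of length `net$m`.
#' @export
bn_step <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.character(state)) state <- string_to_state(state)
  state <- check_bits(state)
  if (length(state) != net$m)
    stopf("state has %d modules, network has %d", length(state), net$m)
  vapply(net$functions, evaluate_rule, integer(1), state = state)
}

# successor state id (0-based) for every state id 0..2^m-1, vectorized
successor_map <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  m <- net$m
  S <- all_states_matrix(m)
  succ <- numeric(nrow(S))
  for (i in seq_len(m)) {
    fn <- net$functions[[i]]
    k <- length(fn$regulators)
    idx <- if (k == 0L) rep(1L, nrow(S))
           else 1L + as.integer(S[, fn$regulators, drop = FALSE] %*% 2^(seq_len(k) - 1L))
    succ <- succ + fn$tt[idx] * 2^(i - 1L)
  }
  as.integer(succ)
}

# ---- rule text ----------------------------------------------------------

# disjunctive-normal-form text for a truth table
expr_from_tt <- function(regulators, tt) {
  k <- length(regulators)
  if (all(tt == 0L)) return("0")
  if (all(tt == 1L)) return("1")
  pats <- all_states_matrix(k)
  ones <- which(tt == 1L)
  terms <- vapply(ones, function(r) {
    lits <- ifelse(pats[r, ] == 1L, paste0("M", regulators),
                   paste0("!M", regulators))
    t <- paste(lits, collapse = " & ")
    if (k > 1L && length(ones) > 1L) paste0("(", t, ")") else t
  }, character(1))
  paste(terms, collapse = " | ")
}

#' Parse Boolean rules in the `targets, factors` dialect
#'
#' One line per module: `Mi, <expr>` where `<expr>` uses identifiers
#' `M1..Mm`, `!`, `&`, `|`, parentheses and the constants `0`/`1`. A header
#' line `targets, factors` and `#` comment lines are ignored. Every module
#' `M1..Mm` (m = largest index mentioned) must get exactly one rule.
#'
#' @param text character scalar (file content) or vector of lines.
#' @return A `boolean_network` whose truth tables are derived by evaluating
#'   each expression over all regulator patterns.
#' @export
parse_rules <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^\\s*targets\\s*,\\s*factors\\s*$", lines, ignore.case = TRUE)
  idx <- which(keep)
  rules <- list()
  for (ln in idx) {
    line <- lines[ln]
    parts <- regmatches(line, regexpr(",", line), invert = TRUE)[[1]]
    if (length(parts) != 2L)
      stopf("line %d: expected 'Mi, <expression>': %s", ln, line)
    tgt <- trimws(parts[1]); rhs <- trimws(parts[2])
    if (!grepl("^M[0-9]+$", tgt))
      stopf("line %d: invalid target '%s' (expected M<index>)", ln, tgt)
    ti <- as.integer(sub("^M", "", tgt))
    leftover <- gsub("M[0-9]+|[!&|()01]|\\s", "", rhs)
    if (nzchar(leftover))
      stopf("line %d: unknown token(s) '%s' in expression '%s'", ln, leftover, rhs)
    if (!nzchar(gsub("\\s", "", rhs)))
      stopf("line %d: empty expression for %s", ln, tgt)
    if (!is.null(rules[[as.character(ti)]]))
      stopf("line %d: duplicate rule for %s", ln, tgt)
    regs <- sort(unique(as.integer(sub("^M", "", regmatches(rhs, gregexpr("M[0-9]+", rhs))[[1]]))))
    parsed <- tryCatch(parse(text = gsub("M([0-9]+)", "(s[\\1]==1)", rhs)),
                       error = function(e) stopf("line %d: syntax error in '%s'", ln, rhs))
    rules[[as.character(ti)]] <- list(line = ln, regs = regs, parsed = parsed, expr = rhs)
  }
  if (!length(rules)) stopf("no rules found")
  m <- max(as.integer(names(rules)), unlist(lapply(rules, `[[`, "regs")))
  missing <- setdiff(seq_len(m), as.integer(names(rules)))
  if (length(missing))
    stopf("no rule given for module(s): %s", paste0("M", missing, collapse = ", "))
  fns <- vector("list", m)
  for (ti in seq_len(m)) {
    r <- rules[[as.character(ti)]]
    k <- length(r$regs)
    pats <- all_states_matrix(max(k, 0L))
    tt <- integer(2^k)
    for (p in seq_len(2^k)) {
      s <- integer(m)
      if (k) s[r$regs] <- pats[p, seq_len(k)]
      val <- tryCatch(eval(r$parsed[[1]], list(s = s)),
                      error = function(e) stopf("line %d: cannot evaluate '%s'", r$line, r$expr))
      tt[p] <- as.integer(isTRUE(as.logical(val)))
    }
    fns[[ti]] <- boolean_function(ti, r$regs, tt, expr = r$expr)
  }
  boolean_network(fns)
}

#' Serialize a network in the `targets, factors` dialect
#'
#' @param net a `boolean_network`.
#' @return Character scalar; `parse_rules(serialize_rules(net))` is
#'   truth-table-equivalent to `net`.
#' @export
serialize_rules <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  paste(c("targets, factors",
          vapply(net$functions, function(fn) sprintf("M%d, %s", fn$target, fn$expr),
                 character(1))),
        collapse = "\n")
}

#' Read rules from a file
#' @param path rule file in the `targets, factors` dialect.
#' @return A `boolean_network`.
#' @export
read_rules <- function(path) parse_rules(readLines(path))

#' Write rules to a file
#' @param net a `boolean_network`.
#' @param path destination file.
#' @export
write_rules <- function(net, path) {
  writeLines(serialize_rules(net), path)
  invisible(path)
}
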