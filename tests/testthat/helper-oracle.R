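# independent brute-force simulator: evaluates the AND/OR/NOT expression
# text with R's own logical operators, never touching the package's truth
# tables or successor arithmetic

oracle_eval <- function(fn, state) {
  expr <- gsub("M([0-9]+)", "(s[\\1]==1)", fn$expr)
  as.integer(isTRUE(as.logical(eval(parse(text = expr)[[1]], list(s = state)))))
}

oracle_step <- function(net, state) {
  vapply(net$functions, oracle_eval, integer(1), state = state)
}

oracle_trajectory <- function(net, s0) {
  path <- list()
  keys <- character(0)
  s <- s0
  repeat {
    key <- paste(s, collapse = "")
    if (key %in% keys) break
    keys <- c(keys, key)
    path[[length(path) + 1L]] <- s
    s <- oracle_step(net, s)
  }
  keys
}

# exhaustive attractor/basin enumeration by walking every state to its cycle
oracle_attractors <- function(net) {
  m <- net$m
  basins <- list()
  for (id in 0:(2^m - 1L)) {
    s <- as.integer(id %/% 2^(seq_len(m) - 1L) %% 2)
    seen <- character(0)
    repeat {
      key <- paste(s, collapse = "")
      if (key %in% seen) break
      seen <- c(seen, key)
      s <- oracle_step(net, s)
    }
    # cycle = tail of `seen` from the first revisit
    entry <- match(paste(s, collapse = ""), seen)
    cyc <- sort(seen[entry:length(seen)])
    key <- paste(cyc, collapse = "|")
    basins[[key]] <- c(basins[[key]], paste(as.integer(id %/% 2^(seq_len(m) - 1L) %% 2), collapse = ""))
  }
  lapply(basins, sort)
}

# package report in the oracle's shape: sorted-cycle key -> sorted basin states
report_as_basins <- function(rep) {
  m <- rep$m
  ids <- 0:(rep$n_states - 1L)
  strs <- vapply(ids, function(id)
    paste(as.integer(id %/% 2^(seq_len(m) - 1L) %% 2), collapse = ""), character(1))
  out <- list()
  for (j in seq_along(rep$attractors)) {
    key <- paste(sort(rep$attractors[[j]]$states), collapse = "|")
    out[[key]] <- sort(strs[rep$attractor_of == j])
  }
  out
}

# parse each rule once, returning a fast independent step function
oracle_compile <- function(net) {
  parsed <- lapply(net$functions, function(fn)
    parse(text = gsub("M([0-9]+)", "(s[\\1]==1)", fn$expr))[[1]])
  function(state) {
    vapply(parsed, function(e)
      as.integer(isTRUE(as.logical(eval(e, list(s = state))))), integer(1))
  }
}
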