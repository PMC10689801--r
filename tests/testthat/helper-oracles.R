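# Independent brute-force oracles used across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# substitute bases at a fixed rate (always to a different base)
sub_mutate <- function(s, rate) {
  b <- strsplit(s, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in hit) b[i] <- sample(alt[[b[i]]], 1)
  paste(b, collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# naive O(nm) exact substring scan, one strand
naive_find <- function(pattern, subject) {
  m <- nchar(pattern)
  n <- nchar(subject)
  if (n < m) return(integer())
  windows <- substring(subject, 1:(n - m + 1), m:n)
  which(windows == pattern) - 1L
}

# longest prefix of s that also occurs as its suffix (length >= min_len)
oracle_prefix_suffix <- function(s, min_len) {
  n <- nchar(s)
  best <- 0L
  for (L in seq(min_len, n - 1L)) {
    if (substr(s, 1L, L) == substr(s, n - L + 1L, n)) best <- L
  }
  best
}

# union-find connected components over an edge list of node names
oracle_components <- function(nodes, edges_from, edges_to) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_from)) {
    a <- find(edges_from[i]); b <- find(edges_to[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, character(1))
  as.integer(factor(roots))
}

# textbook Benjamini-Hochberg step-up adjusted p-values
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
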