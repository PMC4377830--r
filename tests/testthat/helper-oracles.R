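# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# all 0-based start offsets of exact matches of `site` in `seq`,
# testing every offset; windows containing N never match
brute_scan <- function(seq, site) {
  L <- nchar(seq); k <- nchar(site)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  hits <- substring(seq, starts, starts + k - 1L) == site
  starts[hits] - 1L
}

# step-up BH from the definition: sort, p(i) * m / i, running minimum from
# the top, cap at 1, restore input order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact rank-sum p by full enumeration of all group assignments,
# straight from the definition
brute_ranksum_p <- function(x, y, alternative) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  e <- mean(ws)
  eps <- 1e-8
  switch(alternative,
    less      = mean(ws <= w + eps),
    greater   = mean(ws >= w - eps),
    two.sided = mean(abs(ws - e) >= abs(w - e) - eps))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small helper: build a gene_region_set from raw sequences
toy_region_set <- function(seqs, region = "UTR3") {
  ids <- sprintf("G%03d", seq_along(seqs))
  rec <- region_records(ids, sprintf("T%03d", seq_along(seqs)), region, seqs)
  select_longest_per_gene(rec)
}
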