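# Shared fixtures and independent oracles for the test suite.

# random rooted tree with uniform branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# brute-force patristic distance: weighted shortest path on the full graph
graph_distance_oracle <- function(tree, leaf_a, leaf_b) {
  g <- igraph::graph_from_edgelist(
    matrix(as.character(tree$edge), ncol = 2), directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  ia <- as.character(match(leaf_a, tree$tip.label))
  ib <- as.character(match(leaf_b, tree$tip.label))
  as.numeric(igraph::distances(g, v = ia, to = ib))
}

# closed-form normal-equations OLS, independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / sxx)
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  sst <- sum((y - mean(y))^2)
  list(slope = b, intercept = a, se_slope = se_b, se_intercept = se_a,
       r_squared = 1 - sum(res^2) / sst,
       p_slope = 2 * stats::pt(abs(b / se_b), df = n - 2, lower.tail = FALSE))
}

# exhaustive 9-mutant enumeration for one codon, via seqinr's translator
codon_enum_oracle <- function(codon) {
  bases <- c("a", "c", "g", "t")
  nt <- strsplit(tolower(codon), "")[[1]]
  aa0 <- seqinr::translate(nt)
  num <- 0L
  den <- 0L
  for (pos in 1:3) {
    for (alt in bases[bases != nt[pos]]) {
      mut <- nt
      mut[pos] <- alt
      aa1 <- seqinr::translate(mut)
      if (aa1 == "*") next
      den <- den + 1L
      if (aa1 != aa0) num <- num + 1L
    }
  }
  num / den
}

# random sense-codon sequence (no stops anywhere)
random_codon_seq <- function(n_codons, seed) {
  set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
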