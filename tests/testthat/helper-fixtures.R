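# Shared fixtures, built in code.

fixture_tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")

star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# comb (pectinate) tree with unit branches
comb_tree <- function(n) {
  txt <- paste0(paste(rep("(", n - 1), collapse = ""), "t1:1",
                paste(vapply(2:n, function(i) sprintf(",t%d:1):1", i),
                      character(1)), collapse = ""))
  txt <- sub(":1$", "", txt)
  parse_newick(paste0(txt, ";"))
}

named_rnorm <- function(tree, sd = 1) {
  stats::setNames(stats::rnorm(length(tree$tip.label), sd = sd), tree$tip.label)
}

# reduced study configuration for fast pipeline smoke tests
small_config <- function(...) {
  sim_config(n_tips = 60L, n_patterned = 30L, n_trees = 3L, ...)
}
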