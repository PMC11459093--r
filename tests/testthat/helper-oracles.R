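# Shared fixtures and independent brute-force oracles.

toy_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

star_tree <- function(k = 10, len = 1) {
  labs <- LETTERS[seq_len(k)]
  read_newick(text = paste0("(", paste0(labs, ":", len, collapse = ","), ");"))
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05   # strictly positive lengths
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# tip-to-tip distance by walking the node path and summing edge lengths --
# independent of cophenetic()
oracle_tip_dist <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  d <- 0
  for (i in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1]) |
               (tree$edge[, 2] == path[i] & tree$edge[, 1] == path[i + 1]))
    d <- d + tree$edge.length[e]
  }
  d
}

oracle_mpd <- function(tree, present) {
  pairs <- combn(present, 2)
  mean(apply(pairs, 2, function(p) oracle_tip_dist(tree, p[1], p[2])))
}

oracle_mntd <- function(tree, present) {
  mean(vapply(present, function(a) {
    min(vapply(setdiff(present, a),
               function(b) oracle_tip_dist(tree, a, b), numeric(1)))
  }, numeric(1)))
}

# community matrix in picante's samples-x-species layout (two identical
# rows: several picante metrics drop dimensions on single-sample input)
comm_matrix <- function(present, tips, abund = NULL) {
  m <- matrix(0, 2, length(tips), dimnames = list(c("p1", "p2"), tips))
  if (is.null(abund)) m[, present] <- 1
  else m[, names(abund)] <- rep(abund, each = 2)
  m
}
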