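#' @importFrom stats cov2cor setNames sd var
#' @importFrom utils combn read.csv write.csv
NULL

#' Normalize taxon labels
#'
#' Trims surrounding whitespace and replaces internal spaces with
#' underscores, the usual Newick dialect for multi-word species names.
#' Used everywhere labels from trees and survey tables are matched.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_labels <- function(x) {
  x <- trimws(as.character(x))
  gsub(" ", "_", x, fixed = TRUE)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream metrics
#' require: branch lengths present and nonnegative, unique tip labels,
#' a single root. Tip labels are normalized (whitespace trimmed, spaces
#' replaced by underscores).
#'
#' @param path path to a Newick file. A literal Newick string is also
#'   accepted via `text`.
#' @param text optional Newick string; overrides `path`.
#' @return an object of class `"phylo"`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure in '", path,
                                            "': ", conditionMessage(e)))
  } else {
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e)))
  }
  if (is.null(tr)) stop("Newick parse failure: no tree found")
  validate_phylogeny(tr)
}

#' Validate a phylogeny for diversity analysis
#'
#' @param tree a `"phylo"` object.
#' @return the tree, with normalized tip labels, invisibly unchanged otherwise.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; phylogenetic metrics are undefined")
  if (anyNA(tree$edge.length))
    stop("tree has missing (NA) branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  tree$tip.label <- normalize_labels(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the requested tips; unary internal nodes left by the
#' pruning are collapsed with their branch lengths summed, so patristic
#' distances between retained tips are unchanged.
#'
#' @param tree a `"phylo"` object.
#' @param taxa character vector of tip labels to keep.
#' @return the pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(normalize_labels(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree a `"phylo"` object.
#' @return symmetric numeric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristic_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

# Shared root-to-MRCA branch-length covariance of the present tips, scaled
# to a correlation matrix (C_ij = V_ij / sqrt(V_ii V_jj) on non-ultrametric
# trees). Depths are measured from the root of the FULL regional tree:
# subsetting, not pruning, so the root reference never moves.
phylo_correlation <- function(tree, present, V_full = NULL) {
  if (is.null(V_full)) V_full <- ape::vcv(tree)
  V <- V_full[present, present, drop = FALSE]
  cov2cor(V)
}

check_present <- function(tree, present, min_k = 1L) {
  present <- unique(normalize_labels(present))
  if (length(present) < min_k)
    stop("need at least ", min_k, " present species")
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("present species not in tree: ", paste(missing, collapse = ", "))
  present
}

#' Faith's phylogenetic diversity (PD)
#'
#' Cumulative branch length of the minimal subtree connecting the present
#' species. The convention here is root-inclusive: the spanning subtree
#' always includes the path up to the root, so a single-species assemblage
#' has PD equal to its root-to-tip distance. Set `include_root = FALSE`
#' for the MRCA-spanning variant.
#'
#' @param tree a `"phylo"` object.
#' @param present character vector of present species (tip labels).
#' @param include_root include the stem path to the root (default TRUE).
#' @return PD, in the tree's branch-length units.
#' @export
faith_pd <- function(tree, present, include_root = TRUE) {
  present <- check_present(tree, present, min_k = 1L)
  ntip <- length(tree$tip.label)
  tips <- match(present, tree$tip.label)
  # mark every edge on a root-to-present-tip path
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(max(tree$edge))       # edge index ending at node
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  used <- logical(nrow(tree$edge))
  for (tp in tips) {
    nd <- tp
    while (nd != root) {
      e <- edge_of[nd]
      if (used[e]) break
      used[e] <- TRUE
      nd <- parent[nd]
    }
  }
  pd <- sum(tree$edge.length[used])
  if (!include_root && length(present) >= 2) {
    mrca <- if (length(present) == ntip) root else
      ape::getMRCA(tree, present)
    # subtract the stem path root -> MRCA
    nd <- mrca
    while (nd != root) {
      pd <- pd - tree$edge.length[edge_of[nd]]
      nd <- parent[nd]
    }
  }
  pd
}

#' Phylogenetic species variability (PSV)
#'
#' PSV = (k tr(C) - sum(C)) / (k (k - 1)) where C is the phylogenetic
#' correlation matrix of the k present species. PSV is 1 on a star
#' phylogeny and decreases as species become more related.
#'
#' @inheritParams faith_pd
#' @param V_full optional precomputed full-tree covariance (from
#'   [ape::vcv()]), to avoid recomputation over many communities.
#' @return PSV in \[0, 1\]; `NA` (undefined) when fewer than 2 species.
#' @export
psv <- function(tree, present, V_full = NULL) {
  present <- unique(normalize_labels(present))
  if (length(present) < 2) return(NA_real_)
  present <- check_present(tree, present, min_k = 2L)
  C <- phylo_correlation(tree, present, V_full)
  k <- length(present)
  (k * sum(diag(C)) - sum(C)) / (k * (k - 1))
}

#' Phylogenetic species richness (PSR = k * PSV)
#'
#' @inheritParams faith_pd
#' @return PSR; `NA` when fewer than 2 species.
#' @inheritParams psv
#' @export
psr <- function(tree, present, V_full = NULL) {
  present <- unique(normalize_labels(present))
  v <- psv(tree, present, V_full)
  if (is.na(v)) return(NA_real_)
  length(present) * v
}

#' Phylogenetic species evenness (PSE)
#'
#' Abundance-weighted relative of PSV:
#' PSE = (N sum_i m_i C_ii - m' C m) / (N^2 - N mbar), with C the
#' phylogenetic correlation matrix, m the abundance vector, N = sum(m) and
#' mbar = N / k. Equals 1 exactly for a star phylogeny with equal
#' abundances and decreases with relatedness or abundance skew.
#'
#' @param tree a `"phylo"` object.
#' @param abundances named numeric vector of abundances (names are tip
#'   labels); species with zero abundance are dropped.
#' @return PSE in \[0, 1\]; `NA` when fewer than 2 species are present.
#' @inheritParams psv
#' @export
pse <- function(tree, abundances, V_full = NULL) {
  if (is.null(names(abundances))) stop("abundances must be named by species")
  names(abundances) <- normalize_labels(names(abundances))
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  m <- abundances[abundances > 0]
  if (length(m) < 2) return(NA_real_)
  present <- check_present(tree, names(m), min_k = 2L)
  m <- m[present]
  C <- phylo_correlation(tree, present, V_full)
  k <- length(m)
  N <- sum(m)
  num <- N * sum(m * diag(C)) - drop(t(m) %*% C %*% m)
  den <- N^2 - N * (N / k)
  num / den
}

#' Mean pairwise patristic distance (MPD)
#'
#' Presence-based by default (mean over all unordered distinct pairs of
#' present species). Supply `weights` for the abundance-weighted variant
#' (pair weight m_i m_j).
#'
#' @param dist patristic distance matrix (from [patristic_distances()]).
#' @param present character vector of present species.
#' @param weights optional named abundance vector for weighted MPD.
#' @return MPD; `NA` (undefined) when fewer than 2 species.
#' @export
mpd_obs <- function(dist, present, weights = NULL) {
  present <- unique(normalize_labels(present))
  if (length(present) < 2) return(NA_real_)
  missing <- setdiff(present, rownames(dist))
  if (length(missing))
    stop("species not in distance matrix: ", paste(missing, collapse = ", "))
  d <- dist[present, present, drop = FALSE]
  if (is.null(weights)) {
    k <- length(present)
    sum(d) / (k * (k - 1))
  } else {
    w <- weights[present]
    W <- outer(w, w)
    diag(W) <- 0
    sum(W * d) / sum(W)
  }
}

#' Mean nearest-taxon distance (MNTD)
#'
#' Mean, over present species, of the patristic distance to the closest
#' other present species. Supply `weights` for the abundance-weighted mean.
#'
#' @inheritParams mpd_obs
#' @return MNTD; `NA` when fewer than 2 species.
#' @export
mntd_obs <- function(dist, present, weights = NULL) {
  present <- unique(normalize_labels(present))
  if (length(present) < 2) return(NA_real_)
  missing <- setdiff(present, rownames(dist))
  if (length(missing))
    stop("species not in distance matrix: ", paste(missing, collapse = ", "))
  d <- dist[present, present, drop = FALSE]
  diag(d) <- Inf
  nt <- apply(d, 1, min)
  if (is.null(weights)) mean(nt) else {
    w <- weights[present]
    sum(w * nt) / sum(w)
  }
}

#' Per-plot, per-level phylogenetic diversity table
#'
#' Computes PD, PSV, PSR, PSE, MPD and MNTD for every plot in a survey
#' table, at the requested community levels. Species are matched to the
#' phylogeny by normalized label; plots whose metric is undefined (fewer
#' than 2 species) carry `NA` with a note.
#'
#' @param tree regional phylogeny (`"phylo"`).
#' @param survey data frame with columns `plot_id`, `stage_years`,
#'   `species`, `abundance`, `level` (`"herb"`/`"woody"`).
#' @param levels community levels to analyze, subset of
#'   `c("total", "herb", "woody")`.
#' @return data frame with one row per plot x level: `plot_id`,
#'   `stage_years`, `level`, `richness`, `abundance`, `PD`, `PSV`, `PSR`,
#'   `PSE`, `MPD`, `MNTD`.
#' @export
diversity_table <- function(tree, survey,
                            levels = c("total", "herb", "woody")) {
  survey <- validate_survey(survey, tree)
  dist <- patristic_distances(tree)
  V_full <- ape::vcv(tree)
  out <- list()
  for (lev in levels) {
    sv <- if (lev == "total") survey else survey[survey$level == lev, ]
    for (pid in unique(survey$plot_id)) {
      rows <- sv[sv$plot_id == pid & sv$abundance > 0, ]
      stage <- survey$stage_years[survey$plot_id == pid][1]
      if (nrow(rows) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          plot_id = pid, stage_years = stage, level = lev,
          richness = 0L, abundance = 0,
          PD = NA_real_, PSV = NA_real_, PSR = NA_real_,
          PSE = NA_real_, MPD = NA_real_, MNTD = NA_real_)
        next
      }
      ab <- tapply(rows$abundance, rows$species, sum)
      ab <- setNames(as.numeric(ab), names(ab))
      spp <- names(ab)
      out[[length(out) + 1L]] <- data.frame(
        plot_id = pid, stage_years = stage, level = lev,
        richness = length(spp), abundance = sum(ab),
        PD = faith_pd(tree, spp),
        PSV = psv(tree, spp, V_full),
        PSR = psr(tree, spp, V_full),
        PSE = pse(tree, ab, V_full),
        MPD = mpd_obs(dist, spp),
        MNTD = mntd_obs(dist, spp))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a survey table against a phylogeny
#'
#' @param survey data frame with columns `plot_id`, `stage_years`,
#'   `species`, `abundance`, `level`.
#' @param tree optional phylogeny; present species must be among its tips.
#' @return the survey with normalized species labels.
#' @export
validate_survey <- function(survey, tree = NULL) {
  need <- c("plot_id", "stage_years", "species", "abundance", "level")
  miss <- setdiff(need, names(survey))
  if (length(miss))
    stop("survey is missing columns: ", paste(miss, collapse = ", "))
  survey$species <- normalize_labels(survey$species)
  if (any(survey$abundance < 0)) stop("negative abundances in survey")
  bad <- !survey$level %in% c("herb", "woody")
  if (any(bad))
    stop("unknown level tags: ", paste(unique(survey$level[bad]), collapse = ", "))
  if (!is.null(tree)) {
    pres <- unique(survey$species[survey$abundance > 0])
    miss <- setdiff(pres, tree$tip.label)
    if (length(miss))
      stop("present species absent from phylogeny: ",
           paste(miss, collapse = ", "))
  }
  survey
}
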