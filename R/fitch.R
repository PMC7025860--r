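# Ancestral chromosome number by Fitch parsimony. Chromosome counts are
# treated as unordered character states (no stepwise 9 -> 8 -> 7 ordering is
# imposed): each karyotype change event is one state change, whichever
# numbers it connects.

#' Infer the ancestral chromosome number by Fitch parsimony
#'
#' Runs the Fitch bottom-up pass on a rooted binary tree whose tips carry
#' chromosome counts, returning the root's minimal-change state set and the
#' minimum number of changes.
#'
#' @param tree a rooted binary [ape::phylo] tree, or a path to / text of a
#'   newick tree.
#' @param counts named integer vector of chromosome counts, names matching
#'   `tree$tip.label`; all counts `>= 1`. If `NULL`, tip labels of the form
#'   `"name:count"` are not supported -- counts must be supplied.
#' @return list with `root_states` (sorted integer vector), `changes`
#'   (minimum number of state changes), and `node_states` (list of state
#'   sets, tips first then internal nodes in `tree` numbering).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' ancestral_chromosome_number(tr, c(a = 7, b = 9, c = 9, d = 9))
ancestral_chromosome_number <- function(tree, counts) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  tips <- tree$tip.label
  if (is.null(names(counts)) || !all(tips %in% names(counts))) {
    missing <- if (is.null(names(counts))) tips else setdiff(tips,
                                                             names(counts))
    stop("unlabeled leaf: no chromosome count for ",
         paste(missing, collapse = ", "))
  }
  counts <- counts[tips]
  if (anyNA(counts) || any(counts < 1)) {
    stop("chromosome counts must be integers >= 1")
  }
  n_tip <- length(tips)
  n_node <- tree$Nnode
  states <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) states[[i]] <- as.integer(counts[i])
  changes <- 0L
  post <- ape::reorder.phylo(tree, "postorder")$edge
  # children of each internal node, visited in postorder
  for (node in unique(post[, 1])) {
    kids <- post[post[, 1] == node, 2]
    s <- states[[kids[1]]]
    for (k in kids[-1]) {
      inter <- intersect(s, states[[k]])
      if (length(inter)) {
        s <- inter
      } else {
        s <- union(s, states[[k]])
        changes <- changes + 1L
      }
    }
    states[[node]] <- sort(s)
  }
  root <- n_tip + 1L
  list(root_states = states[[root]], changes = changes,
       node_states = states)
}

#' The Malassezia karyotype tree shipped with the package
#'
#' Loads the packaged species tree (newick) and per-species chromosome
#' counts for the nine Malassezia species with well-assembled genomes. The
#' topology transcribes the published clade structure (Clade C earliest
#' diverging; Clade A containing *M. furfur*, *M. japonica*,
#' *M. vespertilionis*; Clade B containing *M. globosa* / *M. restricta*
#' and *M. sympodialis* / *M. dermatis* / *M. nana*); branch lengths are
#' not meaningful.
#'
#' @return list with `tree` (an [ape::phylo]) and `counts` (named integer
#'   vector of chromosome numbers).
#' @export
malassezia_karyotype <- function() {
  nwk <- system.file("extdata", "malassezia_karyotype.nwk",
                     package = "censcape", mustWork = TRUE)
  tsv <- system.file("extdata", "malassezia_chromosome_counts.tsv",
                     package = "censcape", mustWork = TRUE)
  tree <- ape::read.tree(nwk)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  counts <- setNames(as.integer(tab$chromosomes), tab$species)
  list(tree = tree, counts = counts)
}
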