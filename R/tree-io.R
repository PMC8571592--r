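#' Parse a Newick tree with validation
#'
#' Thin, validating wrapper around [ape::read.tree()]. Beyond parsing, it
#' enforces the contracts the rest of the package relies on: balanced
#' parentheses (reporting the character offset of the first imbalance),
#' branch lengths present on every non-root edge, non-negative edge lengths
#' and unique tip labels.
#'
#' @param text a Newick string (single tree).
#' @return an object of class `"phylo"` (see \pkg{ape}).
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_parens(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: unparseable string", call. = FALSE)
  validate_tree(tr)
}

.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylo object for use in this package
#'
#' @param tree a `"phylo"` object.
#' @return the tree, invisibly unchanged, or an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths in Myr are required",
         call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)",
         call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) found", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Read one or many trees from a Newick or NEXUS file
#'
#' Dispatches on content: files starting with `#NEXUS` go through
#' [ape::read.nexus()], anything else through [ape::read.tree()].
#'
#' @param path file path.
#' @return a `"phylo"` or `"multiPhylo"` object.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  if (startsWith(first, "#NEXUS")) ape::read.nexus(path) else ape::read.tree(path)
}

#' Node ages (time before present, Myr)
#'
#' Ages are measured backward from the present: the youngest tip sits at 0
#' and the root at the tree height. For ultrametric chronograms every tip is
#' at age 0; non-ultrametric trees are permitted (ages are then heights above
#' the deepest tip) and flagged via [is_ultrametric_tree()].
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_ages <- function(tree) {
  validate_tree(tree)
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  names(ages) <- c(tree$tip.label,
                   if (!is.null(tree$node.label) &&
                       length(tree$node.label) == tree$Nnode) tree$node.label
                   else paste0("node", ape::Ntip(tree) + seq_len(tree$Nnode)))
  ages
}

#' Test ultrametricity under the package tolerance
#'
#' A tree is treated as ultrametric when every tip age is within
#' `tol_rel * root age` of zero (default relative tolerance 1e-6).
#'
#' @param tree a `"phylo"` object.
#' @param tol_rel relative tolerance on tip ages.
#' @return logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol_rel = 1e-6) {
  ages <- node_ages(tree)
  root_age <- max(ages)
  if (root_age == 0) return(TRUE)
  all(abs(ages[seq_len(ape::Ntip(tree))]) <= tol_rel * root_age)
}

#' Root age of a tree (Myr before present)
#'
#' @param tree a `"phylo"` object.
#' @return numeric scalar.
#' @export
root_age <- function(tree) max(node_ages(tree))

#' Read a taxon-to-state character table
#'
#' Expects a delimited file (comma or tab, auto-detected from the header)
#' with a header naming a taxon column and a state column; extra columns
#' (e.g. a free-text source note) are preserved. States are normalized via
#' [normalize_states()]; the vocabulary is closed, so any other string is an
#' error naming the offending rows. An optional two-column rename map
#' (`from,to`) is applied to taxon labels at read time, for harmonizing taxon
#' sets between alternative phylogenies.
#'
#' @param path file path, or a literal table passed via `text`.
#' @param text optional character scalar with the table contents.
#' @param rename_map optional data.frame with columns `from`, `to`, or a path
#'   to a two-column CSV.
#' @return data.frame with columns `taxon`, `state` (canonical) and any
#'   extra input columns.
#' @export
read_character_table <- function(path = NULL, text = NULL, rename_map = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("character table not found: ", path,
                                 call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  sep <- if (grepl("\t", strsplit(text, "\n")[[1]][1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = text, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("character table needs >= 2 columns", call. = FALSE)
  cn <- tolower(names(df))
  taxon_col <- which(cn %in% c("taxon", "taxa", "species", "tip", "label"))[1]
  state_col <- which(cn %in% c("state", "character", "habit", "ecology"))[1]
  if (is.na(taxon_col) || is.na(state_col))
    stop("header must name a taxon column and a state column", call. = FALSE)
  out <- data.frame(taxon = as.character(df[[taxon_col]]),
                    state = normalize_states(df[[state_col]]),
                    stringsAsFactors = FALSE)
  extra <- setdiff(seq_along(df), c(taxon_col, state_col))
  if (length(extra)) out <- cbind(out, df[extra])
  if (anyDuplicated(out$taxon))
    stop("duplicate taxon label(s): ",
         paste(unique(out$taxon[duplicated(out$taxon)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(rename_map)) {
    if (is.character(rename_map))
      rename_map <- utils::read.csv(rename_map, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to") %in% names(rename_map)))
    hit <- match(out$taxon, rename_map$from)
    out$taxon[!is.na(hit)] <- rename_map$to[hit[!is.na(hit)]]
  }
  out
}

#' Canonical clade keys for the internal nodes of a tree
#'
#' A clade key is the sorted set of descendant tip labels, collapsed to a
#' single string; two nodes in different trees are "phylogenetically
#' equivalent" iff their keys are equal.
#'
#' @param tree a `"phylo"` object.
#' @return named character vector, one key per node (tips included; a tip's
#'   key is its own label), names are ape node ids.
#' @export
clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # postorder over edges: children are complete before their parent
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
  names(keys) <- as.character(seq_along(keys))
  keys
}

#' Match phylogenetically equivalent nodes across a posterior tree set
#'
#' For every internal node of a reference tree, finds the node with an
#' identical descendant leaf set in each posterior tree (when one exists) and
#' reports the clade frequency: the fraction of posterior trees containing
#' that exact leaf set. All trees must share the reference tip set.
#'
#' @param ref reference `"phylo"` tree.
#' @param trees a `"multiPhylo"` object or list of `"phylo"` trees.
#' @return a list with `keys` (reference internal-node clade keys),
#'   `matches` (integer matrix, rows = reference internal nodes, cols =
#'   trees, entries = matched node id or NA) and `clade_freq` (numeric
#'   vector in \[0,1\]).
#' @export
match_nodes <- function(ref, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ref_tips <- sort(ref$tip.label)
  for (i in seq_along(trees)) {
    tt <- sort(trees[[i]]$tip.label)
    if (!identical(ref_tips, tt)) {
      d <- c(setdiff(ref_tips, tt), setdiff(tt, ref_tips))
      stop("tip set mismatch for tree ", i, ": ", paste(d, collapse = ", "),
           call. = FALSE)
    }
  }
  ntip <- ape::Ntip(ref)
  internal <- ntip + seq_len(ref$Nnode)
  rkeys <- clade_keys(ref)[internal]
  matches <- matrix(NA_integer_, nrow = length(internal), ncol = length(trees),
                    dimnames = list(internal, NULL))
  for (j in seq_along(trees)) {
    tkeys <- clade_keys(trees[[j]])
    idx <- match(rkeys, tkeys)
    matches[, j] <- idx
  }
  list(ref_nodes = internal,
       keys = rkeys,
       matches = matches,
       clade_freq = rowMeans(!is.na(matches)))
}

#' Total branch length of a tree
#'
#' @param tree a `"phylo"` object.
#' @return numeric scalar (Myr).
#' @export
total_tree_length <- function(tree) sum(tree$edge.length)
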