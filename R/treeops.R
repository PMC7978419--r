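# Tree I/O and topology surgery: Newick round-tripping, cropping to taxon
# subsets, clan maps, outgroup rooting, stem-branch measurement, branch
# collapse, and root-to-tip depths.

#' Parse / write Newick
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Absent branch lengths are set to 0 with a warning; unbalanced parentheses
#' and duplicate tips are errors.
#'
#' @param text A Newick string.
#' @return `parse_newick` returns a `phylo`; `write_newick` a string.
#' @export
parse_newick <- function(text) {
  op <- lengths(regmatches(text, gregexpr("\\(", text)))
  cl <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (op != cl)
    stop_invalid("unbalanced parentheses in Newick (", op, " '(' vs ", cl,
                 " ')')")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop_invalid("could not parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stop_invalid("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("Newick has no branch lengths; set to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' @rdname parse_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' Crop a tree to a taxon subset
#'
#' Drops all other tips and suppresses the resulting degree-2 nodes, summing
#' their edge lengths, so path lengths between kept tips are preserved.
#'
#' @param tree A `phylo` tree.
#' @param keep Character vector of tip labels to keep.
#' @export
crop_tree <- function(tree, keep) {
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 2L)
    stop_invalid("fewer than 2 of the requested taxa are in the tree")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Clan map: named taxon sets structuring all analyses
#'
#' Assigns taxa to the five clans (`Outgroup`, `Lophotrochozoa`,
#' `Ecdysozoa`, `Chordata`, `Xenambulacraria`). The derived unions
#' `Protostomia` (L+E), `Deuterostomia` (C+X) and `Bilateria` (P+D) are
#' available through [clan_taxa()]. Clans must be pairwise disjoint.
#'
#' @param outgroup,lophotrochozoa,ecdysozoa,chordata,xenambulacraria
#'   Character vectors of taxon names.
#' @return An object of class `clade_map` (a named list of taxon sets).
#' @export
clade_map <- function(outgroup, lophotrochozoa, ecdysozoa, chordata,
                      xenambulacraria) {
  cm <- list(Outgroup = outgroup, Lophotrochozoa = lophotrochozoa,
             Ecdysozoa = ecdysozoa, Chordata = chordata,
             Xenambulacraria = xenambulacraria)
  cm <- lapply(cm, as.character)
  all <- unlist(cm)
  if (anyDuplicated(all))
    stop_invalid("taxa assigned to more than one clan: ",
                 paste(unique(all[duplicated(all)]), collapse = ", "))
  structure(cm, class = "clade_map")
}

#' Taxa belonging to a clan or derived union
#'
#' @param cm A [clade_map()].
#' @param name A clan name, or one of `Protostomia`, `Deuterostomia`,
#'   `Bilateria`.
#' @param tree Optional tree; when given, the result is restricted to its
#'   tips.
#' @export
clan_taxa <- function(cm, name, tree = NULL) {
  x <- switch(name,
              Protostomia = c(cm$Lophotrochozoa, cm$Ecdysozoa),
              Deuterostomia = c(cm$Chordata, cm$Xenambulacraria),
              Bilateria = c(cm$Lophotrochozoa, cm$Ecdysozoa, cm$Chordata,
                            cm$Xenambulacraria),
              {
                if (!name %in% names(cm))
                  stop_invalid("unknown clan: ", name)
                cm[[name]]
              })
  if (!is.null(tree)) x <- intersect(x, tree$tip.label)
  x
}

#' Read / write a clan map as TSV
#'
#' Two columns, `taxon` and `clan`.
#' @param path File path.
#' @export
read_clade_map <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  get <- function(cl) d$taxon[d$clan == cl]
  clade_map(get("Outgroup"), get("Lophotrochozoa"), get("Ecdysozoa"),
            get("Chordata"), get("Xenambulacraria"))
}

#' @rdname read_clade_map
#' @param cm A [clade_map()].
#' @export
write_clade_map <- function(cm, path) {
  d <- data.frame(taxon = unlist(unclass(cm), use.names = FALSE),
                  clan = rep(names(cm), lengths(cm)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Root a tree on its outgroup clan
#'
#' Requires the outgroup taxa present in the tree to be separable from the
#' ingroup (monophyletic in the unrooted sense); roots on the branch between
#' them.
#'
#' @param tree A `phylo` tree.
#' @param cm A [clade_map()].
#' @export
root_on_outgroup <- function(tree, cm) {
  og <- intersect(tree$tip.label, cm$Outgroup)
  if (!length(og)) stop_invalid("no outgroup taxa in tree")
  if (length(og) == length(tree$tip.label))
    stop_invalid("tree contains only outgroup taxa")
  if (ape::is.rooted(tree) &&
      clade_is_monophyletic(tree, og) && clade_is_monophyletic(
        tree, setdiff(tree$tip.label, og)))
    return(tree)
  utree <- ape::unroot(tree)
  if (!split_in_tree(utree, og))
    stop_invalid("outgroup clan is not separable from the ingroup")
  ape::root(utree, outgroup = og, resolve.root = TRUE)
}

# Is `taxa` a monophyletic group in the rooted tree?
clade_is_monophyletic <- function(tree, taxa) {
  taxa <- intersect(tree$tip.label, taxa)
  if (length(taxa) < 1L) return(FALSE)
  if (length(taxa) == 1L) return(TRUE)
  node <- ape::getMRCA(tree, taxa)
  desc <- tree$tip.label[descendant_tips(tree)[[node]]]
  setequal(desc, taxa)
}

# Does `taxa` form one side of a branch of the (possibly unrooted) tree?
split_in_tree <- function(tree, taxa) {
  ok <- try(edge_for_split(tree, taxa), silent = TRUE)
  !inherits(ok, "try-error")
}

# MRCA node of the bilaterian taxa after rooting on the outgroup.
bilateria_mrca <- function(tree, cm) {
  bil <- clan_taxa(cm, "Bilateria", tree)
  if (length(bil) < 2L) stop_invalid("fewer than 2 bilaterian taxa in tree")
  ape::getMRCA(tree, bil)
}

#' Stem branch length of a clade
#'
#' The sum of branch lengths on the path from the Bilateria common ancestor
#' to the clade's common ancestor, after rooting the tree on the outgroup
#' clan; 0 when the two coincide (collapsed stem).
#'
#' @param tree A `phylo` tree containing outgroup taxa.
#' @param cm A [clade_map()].
#' @param clade Clan or union name resolvable by [clan_taxa()], typically
#'   `"Protostomia"` or `"Deuterostomia"`.
#' @return Nonnegative numeric.
#' @export
stem_branch_length <- function(tree, cm, clade) {
  tree <- root_on_outgroup(tree, cm)
  taxa <- clan_taxa(cm, clade, tree)
  if (length(taxa) < 2L)
    stop_invalid("clade '", clade, "' has fewer than 2 taxa in tree")
  a <- bilateria_mrca(tree, cm)
  b <- ape::getMRCA(tree, taxa)
  desc <- descendant_tips(tree)
  if (a == b) {
    # Either a collapsed stem (the clade's subtrees join the polytomy as
    # whole child subtrees: stem length 0) or genuine paraphyly (error).
    kids <- tree$edge[tree$edge[, 1L] == b, 2L]
    clean <- vapply(kids, function(v) {
      tx <- tree$tip.label[desc[[v]]]
      all(tx %in% taxa) || !any(tx %in% taxa)
    }, logical(1L))
    if (all(clean)) return(0)
  }
  if (!clade_is_monophyletic(tree, taxa)) {
    intr <- setdiff(tree$tip.label[desc[[b]]], taxa)
    stop_invalid("clade '", clade, "' is not monophyletic; intruding taxa: ",
                 paste(intr, collapse = ", "))
  }
  path_length(tree, a, b)
}

# Sum of edge lengths along the node path between two nodes.
path_length <- function(tree, a, b) {
  if (a == b) return(0)
  np <- ape::nodepath(tree, a, b)
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  tot <- 0
  for (i in seq_len(length(np) - 1L)) {
    e <- match(paste(np[i], np[i + 1L]), key)
    if (is.na(e)) e <- match(paste(np[i + 1L], np[i]), key)
    tot <- tot + tree$edge.length[e]
  }
  tot
}

#' Collapse a clade's stem branch into a polytomy
#'
#' Contracts the internal branch between the Bilateria common ancestor and
#' the clade's common ancestor, producing a multifurcation; every other
#' branch keeps its length. For example, collapsing the deuterostome stem of
#' a monophyletic-deuterostome tree yields
#' `((Lophotrochozoa, Ecdysozoa), Xenambulacraria, Chordata)` below the
#' bilaterian node.
#'
#' @inheritParams stem_branch_length
#' @return A `phylo` tree with the focal node dissolved.
#' @export
collapse_branch <- function(tree, cm, clade) {
  tree <- root_on_outgroup(tree, cm)
  taxa <- clan_taxa(cm, clade, tree)
  if (!clade_is_monophyletic(tree, taxa))
    stop_invalid("clade '", clade, "' is not monophyletic")
  a <- bilateria_mrca(tree, cm)
  b <- ape::getMRCA(tree, taxa)
  if (a == b)
    stop_invalid("clade MRCA coincides with the Bilateria MRCA; no stem")
  np <- ape::nodepath(tree, a, b)
  if (length(np) != 2L)
    stop_invalid("stem spans more than one branch; crop the tree first")
  contract_edge(tree, a, b)
}

# Contract the internal edge (u, v): children of v are reattached to u.
contract_edge <- function(tree, u, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) stop_invalid("cannot collapse a terminal branch")
  e <- which(tree$edge[, 1L] == u & tree$edge[, 2L] == v)
  if (!length(e)) stop_invalid("nodes are not joined by an edge")
  tree$edge.length[e] <- 0
  # di2multi collapses zero-length internal edges; restrict to this one by
  # temporarily bumping all other zero-length internal edges.
  internal <- tree$edge[, 2L] > ntip
  zero <- which(internal & tree$edge.length <= 0 &
                  seq_len(nrow(tree$edge)) != e)
  tree$edge.length[zero] <- 1e-12
  out <- ape::di2multi(tree, tol = 1e-13)
  out$edge.length[out$edge.length == 1e-12] <- 0
  out
}

#' Root-to-tip path lengths from a reference node
#'
#' Distances from the Bilateria common ancestor (default) or from the root
#' to every tip, ordered by taxon name.
#'
#' @inheritParams stem_branch_length
#' @param reference `"bilateria"` or `"root"`.
#' @return Named numeric vector of nonnegative distances.
#' @export
root_to_tip_lengths <- function(tree, cm, reference = c("bilateria",
                                                        "root")) {
  reference <- match.arg(reference)
  tree <- root_on_outgroup(tree, cm)
  node <- if (reference == "bilateria") bilateria_mrca(tree, cm)
          else length(tree$tip.label) + 1L
  d <- ape::dist.nodes(tree)[node, seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d[order(names(d))]
}

#' Export a depth table
#'
#' Per-taxon distances from the bilaterian common ancestor with clan
#' assignments, written as TSV.
#'
#' @inheritParams stem_branch_length
#' @param path Output file path.
#' @export
write_depth_table <- function(tree, cm, path) {
  d <- root_to_tip_lengths(tree, cm)
  clan <- vapply(names(d), function(tx) {
    hit <- names(cm)[vapply(cm, function(s) tx %in% s, logical(1L))]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1L))
  write.table(data.frame(taxon = names(d), clan = clan, distance = d),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
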