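# Amino-acid alignments: a character matrix (taxa x sites) over the 20
# standard residues plus gap '-' and missing 'X'.

#' Construct an amino-acid alignment
#'
#' An `aa_alignment` is a character matrix of single-letter residue codes with
#' unique taxon names as row names. Residues are stored uppercase; the gap
#' character `-` and the missing/ambiguity code `X` are permitted anywhere
#' (any other ambiguity code should be recoded to `X` before construction).
#'
#' @param residues Character matrix (taxa x sites), or a named character
#'   vector of equal-length sequence strings.
#' @param name Optional alignment (gene) name.
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(residues, name = NULL) {
  if (is.character(residues) && is.null(dim(residues))) {
    if (is.null(names(residues)))
      stop_invalid("sequence vector must be named by taxon")
    n <- nchar(residues)
    if (length(unique(n)) != 1L)
      stop_invalid("sequences have unequal lengths")
    residues <- do.call(rbind, strsplit(residues, ""))
  }
  if (!is.matrix(residues) || !is.character(residues))
    stop_invalid("residues must be a character matrix")
  if (is.null(rownames(residues)))
    stop_invalid("residue matrix must have taxon row names")
  if (anyDuplicated(rownames(residues)))
    stop_invalid("taxon names must be unique")
  if (ncol(residues) < 1L) stop_invalid("alignment must have >= 1 site")
  residues[] <- toupper(residues)
  bad <- !(residues %in% c(AA_ALPHABET, "-", "X"))
  if (any(bad))
    stop_invalid("invalid residue code(s): ",
                 paste(unique(residues[bad]), collapse = " "))
  structure(residues, class = "aa_alignment", name = name)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment '%s': %d taxa x %d sites\n",
              attr(x, "name") %||% "", nrow(x), ncol(x)))
  invisible(x)
}

#' Number of taxa / sites of an alignment
#' @param aln An `aa_alignment`.
#' @return Integer count.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname n_taxa
#' @export
n_sites <- function(aln) ncol(aln)

#' Taxon names of an alignment
#' @param aln An `aa_alignment`.
#' @export
taxa <- function(aln) rownames(aln)

#' Restrict an alignment to a taxon subset
#' @param aln An `aa_alignment`.
#' @param keep Character vector of taxa to keep.
#' @export
crop_alignment <- function(aln, keep) {
  keep <- intersect(rownames(aln), keep)
  if (length(keep) < 1L) stop_invalid("no requested taxa in alignment")
  aa_alignment(unclass(aln)[keep, , drop = FALSE], name = attr(aln, "name"))
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa missing from a gene are filled with `X` for that gene's columns.
#' @param genes List of `aa_alignment` objects.
#' @param name Name for the concatenated alignment.
#' @export
concat_alignments <- function(genes, name = "concat") {
  stopifnot(length(genes) >= 1L)
  all_taxa <- sort(unique(unlist(lapply(genes, rownames))))
  mats <- lapply(genes, function(g) {
    m <- matrix("X", length(all_taxa), ncol(g),
                dimnames = list(all_taxa, NULL))
    m[rownames(g), ] <- unclass(g)
    m
  })
  aa_alignment(do.call(cbind, mats), name = name)
}

# Integer state codes: 0 = gap/missing, 1..20 = AA_ALPHABET index.
aln_codes <- function(aln) {
  codes <- match(unclass(aln), AA_ALPHABET)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow(aln), ncol(aln),
         dimnames = list(rownames(aln), NULL))
}

# Site-pattern compression: unique columns + multiplicity weights.
compress_patterns <- function(codes) {
  key <- do.call(paste, c(lapply(seq_len(nrow(codes)), function(i) codes[i, ]),
                          sep = ","))
  idx <- match(key, unique(key))
  first <- which(!duplicated(key))
  list(codes = codes[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(first))),
       map = match(key, key[first]))
}

#' Read / write FASTA amino-acid alignments
#'
#' Reading is case-insensitive; any residue outside the 20-letter alphabet
#' and `-` is recoded to `X`.
#'
#' @param path File path.
#' @param name Alignment name (defaults to the file name).
#' @return `read_fasta_aa` returns an `aa_alignment`.
#' @export
read_fasta_aa <- function(path, name = basename(path)) {
  x <- ape::read.FASTA(path, type = "AA")
  m <- toupper(as.character(as.matrix(x)))
  m[!(m %in% c(AA_ALPHABET, "-"))] <- "X"
  aa_alignment(m, name = name)
}

#' @rdname read_fasta_aa
#' @param aln An `aa_alignment` to write.
#' @export
write_fasta_aa <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", rownames(aln)),
                           apply(unclass(aln), 1L, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write relaxed sequential PHYLIP amino-acid alignments
#'
#' The relaxed dialect: a header line `ntaxa nsites`, then one record per
#' taxon consisting of a whitespace-delimited name followed by the sequence,
#' which may be split across lines and contain internal whitespace.
#'
#' @param path File path.
#' @param name Alignment name (defaults to the file name).
#' @export
read_phylip_aa <- function(path, name = basename(path)) {
  toks <- scan(path, what = character(), quiet = TRUE)
  if (length(toks) < 2L) stop_invalid("not a PHYLIP file: ", path)
  nt <- suppressWarnings(as.integer(toks[1L]))
  ns <- suppressWarnings(as.integer(toks[2L]))
  if (is.na(nt) || is.na(ns))
    stop_invalid("malformed PHYLIP header in ", path)
  toks <- toks[-(1:2)]
  seqs <- character(nt)
  nms <- character(nt)
  i <- 1L
  for (t in seq_len(nt)) {
    if (i > length(toks)) stop_invalid("truncated PHYLIP file: ", path)
    nms[t] <- toks[i]
    i <- i + 1L
    s <- ""
    while (nchar(s) < ns) {
      if (i > length(toks)) stop_invalid("truncated PHYLIP file: ", path)
      s <- paste0(s, toks[i])
      i <- i + 1L
    }
    if (nchar(s) != ns)
      stop_invalid("sequence for '", nms[t], "' has ", nchar(s),
                   " residues, expected ", ns)
    seqs[t] <- s
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- nms
  m[!(m %in% c(AA_ALPHABET, "-"))] <- "X"
  aa_alignment(m, name = name)
}

#' @rdname read_phylip_aa
#' @param aln An `aa_alignment` to write.
#' @export
write_phylip_aa <- function(aln, path) {
  lines <- c(paste(nrow(aln), ncol(aln)),
             paste(rownames(aln),
                   apply(unclass(aln), 1L, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
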