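#' Map gene-sequence identifiers to taxa
#'
#' Gene identifiers in transcriptome assemblies conventionally carry the
#' taxon as a prefix, e.g. `"Pinus_00123"`. `taxonMap` builds an explicit
#' id -> taxon mapping from such labels; `taxonFromLabel` is the underlying
#' prefix rule.
#'
#' @param ids character vector of gene identifiers.
#' @param delimiter single character separating the taxon prefix from the
#'   rest of the id (default `"_"`).
#' @param taxa optional character vector of taxa parallel to `ids`; when
#'   given, the prefix rule is bypassed.
#' @return `taxonMap` returns a named character vector (names = gene ids,
#'   values = taxon ids). `taxonFromLabel` returns the taxon prefixes.
#' @examples
#' taxonFromLabel(c("A_1", "B_22"))          # "A" "B"
#' taxonMap(c("A_1", "A_2", "B_1"))
#' @export
taxonMap <- function(ids, delimiter = "_", taxa = NULL) {
  if (!length(ids)) stop("taxon map must cover at least one gene id")
  if (anyDuplicated(ids))
    stop("duplicated gene ids in taxon map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(taxa)) taxa <- taxonFromLabel(ids, delimiter)
  if (length(taxa) != length(ids))
    stop("'taxa' must be parallel to 'ids'")
  stats::setNames(as.character(taxa), ids)
}

#' @rdname taxonMap
#' @export
taxonFromLabel <- function(ids, delimiter = "_") {
  sub(paste0("\\Q", delimiter, "\\E.*$"), "", ids)
}

# minimal structural scan so parse failures report a byte offset
.checkNewickText <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at byte offset ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at byte offset ",
         length(chars))
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed newick: missing terminating ';' at byte offset ",
         nchar(txt))
  invisible(TRUE)
}

#' Read a rooted tree from a newick file
#'
#' Reads a gene tree or species tree in newick format. Polytomies are
#' resolved to binary nodes deterministically: at each multifurcation the
#' child subtrees are ordered by their smallest leaf label and combined
#' left-to-right into a caterpillar of zero-length internal branches, so a
#' given input always yields the same binary topology.
#'
#' @param path path to a newick file (first tree used), or a newick string
#'   containing `";"`.
#' @param rooted require a rooted tree (default TRUE). Unrooted input is
#'   rejected unless `outgroup` resolves a root.
#' @param outgroup optional taxon used to root an unrooted tree: the tree is
#'   rooted on the edge of the first outgroup leaf in sorted label order.
#' @param delimiter taxon prefix delimiter used when rooting by outgroup.
#' @return an object of class `phylo`, rooted and binary.
#' @examples
#' tr <- readNewick("((A_1,B_1),C_1);")
#' ape::Ntip(tr)
#' @export
readNewick <- function(path, rooted = TRUE, outgroup = NULL,
                       delimiter = "_") {
  txt <- if (grepl(";", path, fixed = TRUE)) path
         else {
           if (!file.exists(path)) stop("file not found: ", path)
           paste(readLines(path, warn = FALSE), collapse = "")
         }
  .checkNewickText(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr))
    stop("malformed newick: parser failure near byte offset ", nchar(txt),
         " in ", if (nchar(path) < 200) path else "input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (!ape::is.rooted(tr) && !is.null(outgroup)) {
    og <- sort(tr$tip.label[taxonFromLabel(tr$tip.label, delimiter) %in%
                              outgroup])
    if (!length(og))
      stop("rooting error: outgroup taxon not found among leaves")
    tr <- ape::root(tr, outgroup = og[1], resolve.root = TRUE)
  }
  # basal multifurcations are resolved by the deterministic binarization
  tr <- binarizeTree(tr)
  if (rooted && !ape::is.rooted(tr))
    stop("rooting error: tree could not be rooted and no outgroup given")
  tr
}

#' Deterministically resolve polytomies
#'
#' @param tree a `phylo` object.
#' @return a binary `phylo`; multifurcations are replaced by left
#'   caterpillars over children sorted by smallest leaf label, with
#'   zero-length inserted branches when the tree has branch lengths.
#' @export
binarizeTree <- function(tree) {
  if (ape::is.binary(tree) && ape::is.rooted(tree)) return(tree)
  nested <- .phyloToNested(tree)
  txt <- paste0(.nestedToNewick(nested, !is.null(tree$edge.length)), ";")
  ape::read.tree(text = txt)
}

# phylo -> nested list: leaf = list(label=, len=); internal = list(children=, len=)
.phyloToNested <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  blen <- tree$edge.length
  build <- function(node, eidx) {
    len <- if (!is.null(blen) && !is.na(eidx)) blen[eidx] else NULL
    if (node <= nt)
      return(list(label = tree$tip.label[node], len = len))
    es <- kids[[as.character(node)]]
    ch <- lapply(es, function(e) build(tree$edge[e, 2], e))
    list(children = ch, len = len)
  }
  build(root, NA_integer_)
}

.nestedMinLeaf <- function(x) {
  if (!is.null(x$label)) return(x$label)
  min(vapply(x$children, .nestedMinLeaf, character(1)))
}

.nestedToNewick <- function(x, hasLen) {
  suf <- function(len) {
    if (!hasLen) "" else paste0(":", format(if (is.null(len)) 0 else len,
                                            digits = 15))
  }
  if (!is.null(x$label)) return(paste0(x$label, suf(x$len)))
  ch <- x$children
  ord <- order(vapply(ch, .nestedMinLeaf, character(1)), method = "radix")
  ch <- ch[ord]
  # left caterpillar over sorted children
  cur <- paste0("(", .nestedToNewick(ch[[1]], hasLen), ",",
                .nestedToNewick(ch[[2]], hasLen), ")",
                if (hasLen) ":0" else "")
  if (length(ch) > 2) {
    for (i in 3:length(ch))
      cur <- paste0("(", cur, ",", .nestedToNewick(ch[[i]], hasLen), ")",
                    if (hasLen) ":0" else "")
  }
  # outermost node carries the original branch length
  if (hasLen) cur <- sub(":0$", suf(x$len), cur)
  cur
}

#' Write a tree to newick
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

.blastCols <- c("query", "subject", "identity", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")

#' Read BLAST tabular (12-column) hits
#'
#' Reads the standard 12-column tab-separated BLAST output (`-outfmt 6`).
#' Extra columns beyond the twelfth are ignored; self-hits are retained here
#' and filtered downstream.
#'
#' @param path path to a tab-separated hit table.
#' @return a data.frame with columns query, subject, identity, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore. An
#'   empty file yields a zero-row data.frame with those columns.
#' @export
readBlastTab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- stats::setNames(
    data.frame(character(0), character(0), numeric(0), integer(0),
               integer(0), integer(0), integer(0), integer(0), integer(0),
               integer(0), numeric(0), numeric(0),
               stringsAsFactors = FALSE),
    .blastCols)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 12L))
    stop("BLAST tabular row with fewer than 12 columns at line ",
         which(ncols < 12L)[1])
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  hits <- as.data.frame(m, stringsAsFactors = FALSE)
  names(hits) <- .blastCols
  for (col in c("identity", "length", "evalue", "bitscore",
                "mismatch", "gapopen", "qstart", "qend", "sstart", "send")) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(v))
      stop("non-numeric '", col, "' in BLAST tabular at line ",
           which(is.na(v))[1])
    hits[[col]] <- v
  }
  hits$length <- as.integer(hits$length)
  hits
}

#' Read a released MAPS analysis archive directory
#'
#' A released MAPS analysis is a directory with a `*-tre` folder of newick
#' gene trees, a `*-aln` folder of the matching alignments, and a readme
#' giving the taxon identifier -> species mapping. Trees and alignments are
#' paired by shared basename; a tree without a matching alignment is kept
#' with a warning. The readme is taken to be any two-column
#' whitespace-delimited id/species file whose name contains "readme"
#' (case-insensitive).
#'
#' @param dir path to the analysis directory.
#' @param delimiter taxon prefix delimiter used to binarize/parse trees.
#' @return a list with elements `trees` (named list of `phylo`),
#'   `alignments` (named character vector of paths, NA where missing) and
#'   `taxonMap` (named character vector, taxon id -> species name).
#' @export
readMapsRelease <- function(dir, delimiter = "_") {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  entries <- list.files(dir, full.names = TRUE)
  treDir <- entries[dir.exists(entries) & grepl("-tre$", entries)]
  alnDir <- entries[dir.exists(entries) & grepl("-aln$", entries)]
  if (length(treDir) != 1L)
    stop("expected exactly one '*-tre' folder in ", dir)
  if (length(alnDir) != 1L)
    stop("expected exactly one '*-aln' folder in ", dir)
  readme <- entries[!dir.exists(entries) &
                      grepl("readme", basename(entries), ignore.case = TRUE)]
  if (length(readme) < 1L)
    stop("no readme taxon map found in ", dir)
  rl <- readLines(readme[1], warn = FALSE)
  rl <- rl[nzchar(trimws(rl))]
  fields <- strsplit(trimws(rl), "[[:space:]]+")
  if (any(lengths(fields) < 2L))
    stop("readme is not a two-column id/species file: ", readme[1])
  tmap <- stats::setNames(vapply(fields, `[`, "", 2),
                          vapply(fields, `[`, "", 1))
  treeFiles <- sort(list.files(treDir, full.names = TRUE))
  alnFiles <- sort(list.files(alnDir, full.names = TRUE))
  base <- function(x) tools::file_path_sans_ext(basename(x))
  alnByBase <- stats::setNames(alnFiles, base(alnFiles))
  trees <- lapply(treeFiles, readNewick, delimiter = delimiter)
  names(trees) <- base(treeFiles)
  aln <- alnByBase[names(trees)]
  names(aln) <- names(trees)
  missing <- names(trees)[is.na(aln)]
  if (length(missing))
    warning(length(missing), " gene tree(s) without matching alignment: ",
            paste(missing, collapse = ", "))
  list(trees = trees, alignments = aln, taxonMap = tmap)
}

#' Write a MAPS-style analysis directory
#'
#' Counterpart of [readMapsRelease()]: writes trees to `<name>-tre/`,
#' optional alignment stubs to `<name>-aln/`, and a two-column readme.
#'
#' @param dir output directory (created).
#' @param trees named list of `phylo` gene trees.
#' @param taxonMap named character vector, taxon id -> species name.
#' @param name archive basename prefix (default "analysis").
#' @param alignments optional named character vector of alignment texts
#'   (FASTA) parallel to `trees`.
#' @return `dir`, invisibly.
#' @export
writeMapsRelease <- function(dir, trees, taxonMap, name = "analysis",
                             alignments = NULL) {
  treDir <- file.path(dir, paste0(name, "-tre"))
  alnDir <- file.path(dir, paste0(name, "-aln"))
  dir.create(treDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(alnDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(trees)))
    names(trees) <- sprintf("gene%04d", seq_along(trees))
  for (nm in names(trees))
    ape::write.tree(trees[[nm]], file = file.path(treDir,
                                                  paste0(nm, ".tre")))
  if (!is.null(alignments))
    for (nm in names(alignments))
      writeLines(alignments[[nm]], file.path(alnDir, paste0(nm, ".fasta")))
  writeLines(paste(names(taxonMap), unname(taxonMap), sep = "\t"),
             file.path(dir, "readme.txt"))
  invisible(dir)
}
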