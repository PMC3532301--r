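## Molecular graphs and linear-fragment enumeration.
##
## A molecule is held as a heavy-atom graph: hydrogens are implicit, stereo
## annotations are discarded, aromaticity is perceived by Open Babel during
## input normalisation.  Fragments are simple paths written as alternating
## atom and bond symbols ("C-C=O"); a fragment's length is its bond count.

BOND_SYMBOLS <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")

#' Construct a molecule graph
#'
#' Low-level constructor for the heavy-atom graph representation used
#' throughout the package.  Most users should call [parse_molecule()] instead,
#' which builds the graph from SMILES or MDL mol/SDF input with standard
#' aromaticity perception.
#'
#' @param atoms data frame with columns `element` (character symbol),
#'   `aromatic` (logical), `charge` (integer formal charge) and optionally
#'   `wildcard` (logical; `TRUE` for R-group/query atoms such as `*`).
#' @param bonds data frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (one of `"-"`, `"="`, `"#"`, `":"`).
#' @param id optional compound identifier.
#' @return An object of class `molecule_graph`.
#' @seealso [parse_molecule()], [enumerate_linear_fragments()]
#' @export
molecule_graph <- function(atoms, bonds = NULL, id = NULL) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "aromatic", "charge") %in% names(atoms)))
  if (is.null(atoms$wildcard)) atoms$wildcard <- atoms$element %in% WILDCARD_SYMBOLS
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(), order = character())
  }
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$from < 1L | bonds$from > n | bonds$to < 1L | bonds$to > n))
      stop("bond endpoint out of range", call. = FALSE)
    if (any(bonds$from == bonds$to))
      stop("bond endpoints must be distinct atoms", call. = FALSE)
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (anyDuplicated(key))
      stop("at most one bond per atom pair", call. = FALSE)
    if (!all(bonds$order %in% BOND_SYMBOLS))
      stop("unknown bond order symbol", call. = FALSE)
    arom <- bonds$order == ":"
    if (any(arom & !(atoms$aromatic[bonds$from] & atoms$aromatic[bonds$to])))
      stop("aromatic bonds must connect aromatic-flagged atoms", call. = FALSE)
  }
  if (any(atoms$element == "H"))
    stop("hydrogens must be implicit in a molecule_graph", call. = FALSE)
  structure(list(atoms = atoms, bonds = bonds, id = id),
            class = "molecule_graph")
}

WILDCARD_SYMBOLS <- c("*", "R", "R#", "A", "Q", "Du", "X")

## legacy V2000 atom-block charge codes (field 6): 1..7 except 4 (radical)
.V2000_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

## Minimal MDL V2000 reader for Open Babel-normalised SDF text.  Only the
## counts line, atom symbols, bond block and M CHG properties are needed;
## coordinates and stereo flags are deliberately ignored.
.read_v2000 <- function(lines) {
  if (length(lines) < 4L) stop("truncated molfile record", call. = FALSE)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds))
    stop("unreadable molfile counts line: ", counts, call. = FALSE)
  if (natoms == 0L)
    return(list(element = character(), charge = integer(),
                from = integer(), to = integer(), order = integer()))
  at <- lines[4L + seq_len(natoms)]
  element <- trimws(substr(at, 32L, 34L))
  charge <- unname(.V2000_CHARGE[substr(at, 37L, 39L) |> trimws()])
  charge[is.na(charge)] <- 0L
  from <- to <- order <- integer(0)
  if (nbonds > 0L) {
    bd <- lines[4L + natoms + seq_len(nbonds)]
    from  <- as.integer(substr(bd, 1L, 3L))
    to    <- as.integer(substr(bd, 4L, 6L))
    order <- as.integer(substr(bd, 7L, 9L))
  }
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    charge <- rep(0L, natoms)  # M CHG supersedes the atom-block codes
    for (ln in chg) {
      v <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
      n <- v[1L]
      idx <- v[1L + 2L * seq_len(n) - 1L]
      val <- v[1L + 2L * seq_len(n)]
      charge[idx] <- val
    }
  }
  list(element = element, charge = charge, from = from, to = to, order = order)
}

## session-scoped parse cache (keyed on format + record text)
.parse_cache <- new.env(parent = emptyenv())

.convert <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, text)),
    error = function(e) "")
  if (!nzchar(out))
    stop("structure conversion failed (", from, " -> ", to, ")", call. = FALSE)
  out
}

## Aromatic bonds according to Open Babel: bonds written as Sybyl type "ar"
## in MOL2 output *and* lying in a ring.  The ring condition separates true
## aromatic bonds from the Sybyl convention of writing carboxylate/amidinium
## groups with "ar" bonds.
.mol2_aromatic_bonds <- function(src, text, n_atoms) {
  mol2 <- .convert(src, "MOL2", text)
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf))
  writeLines(mol2, tf)
  m <- bio3d::read.mol2(tf)
  bonds <- m$bond
  if (is.null(bonds) || !nrow(bonds)) return(NULL)
  ar <- bonds$type == "ar"
  if (!any(ar)) return(NULL)
  g <- igraph::graph_from_edgelist(cbind(bonds$origin, bonds$target),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms) g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  in_ring <- vapply(which(ar), function(i) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(bonds$origin[i], bonds$target[i])))
    is.finite(igraph::distances(g2, v = bonds$origin[i],
                                to = bonds$target[i])[1L, 1L])
  }, logical(1))
  keep <- which(ar)[in_ring]
  if (!length(keep)) return(NULL)
  cbind(bonds$origin[keep], bonds$target[keep])
}

#' Parse a molecular structure into a heavy-atom graph
#'
#' Reads a single structure record and returns its heavy-atom
#' [molecule_graph()].  Input is normalised through Open Babel (via
#' \pkg{ChemmineOB}): hydrogens are suppressed, Kekulized rings are
#' re-aromatized by Open Babel's standard perception, and stereochemical
#' annotations are discarded, so two records differing only in stereo yield
#' identical graphs.  Records containing wildcard/R-group atoms (`*`, `R#`,
#' ...) parse successfully but carry `wildcard = TRUE` flags; the dataset
#' filter excludes such molecules (category 5).
#'
#' @param text the structure record: a SMILES string, or the text of an MDL
#'   mol/SDF (V2000) record.
#' @param format `"smiles"` or `"molfile"`.
#' @param id optional compound identifier attached to the graph (and used in
#'   error messages).
#' @return A `molecule_graph`.
#' @examples
#' \donttest{
#' eth <- parse_molecule("CCO", id = "ethanol")
#' eth$atoms$element            # "C" "C" "O"
#' enumerate_linear_fragments(eth, max_len = 2)
#' }
#' @export
parse_molecule <- function(text, format = c("smiles", "molfile"), id = NULL) {
  format <- match.arg(format)
  key <- paste0(format, "\r", text)
  hit <- .parse_cache[[key]]
  if (!is.null(hit)) {
    if (!is.null(id)) hit$id <- id
    return(hit)
  }
  label <- if (is.null(id)) substr(trimws(text), 1L, 60L) else id
  src <- switch(format, smiles = "SMI", molfile = "MOL")
  rec <- switch(format, smiles = paste0(text, "\tmol\n"), molfile = text)
  sdf <- tryCatch(.convert(src, "SDF", rec), error = function(e)
    stop("cannot parse ", format, " record '", label, "'", call. = FALSE))
  v <- .read_v2000(strsplit(sdf, "\n", fixed = TRUE)[[1L]])
  n <- length(v$element)
  aromatic <- rep(FALSE, n)
  order <- unname(BOND_SYMBOLS[as.character(v$order)])
  if (any(is.na(order)))
    stop("unsupported bond order in record '", label, "'", call. = FALSE)
  if (length(v$from)) {
    ar <- tryCatch(.mol2_aromatic_bonds(src, rec, n), error = function(e) NULL)
    if (!is.null(ar)) {
      key2 <- paste(pmin(v$from, v$to), pmax(v$from, v$to))
      ark <- paste(pmin(ar[, 1L], ar[, 2L]), pmax(ar[, 1L], ar[, 2L]))
      is_ar <- key2 %in% ark
      order[is_ar] <- ":"
      aromatic[unique(c(v$from[is_ar], v$to[is_ar]))] <- TRUE
    }
  }
  mol <- molecule_graph(
    atoms = data.frame(element = v$element, aromatic = aromatic,
                       charge = v$charge,
                       wildcard = v$element %in% WILDCARD_SYMBOLS),
    bonds = data.frame(from = v$from, to = v$to, order = order),
    id = id)
  .parse_cache[[key]] <- mol
  mol
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("<molecule_graph", if (!is.null(x$id)) paste0(" ", x$id), ">: ",
      nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  comp <- table(x$atoms$element)
  cat("  composition:", paste0(names(comp), comp, collapse = " "), "\n")
  if (any(x$atoms$aromatic))
    cat("  aromatic atoms:", sum(x$atoms$aromatic), "\n")
  if (any(x$atoms$wildcard))
    cat("  contains wildcard/R-group atoms\n")
  invisible(x)
}

## Atom symbol under the package's typing dialect: element symbol,
## lower-cased when aromatic, with the formal charge appended (e.g. "N+1")
## only when use_charge is set.
.atom_symbols <- function(mol, use_charge = FALSE) {
  s <- mol$atoms$element
  s[mol$atoms$aromatic] <- tolower(s[mol$atoms$aromatic])
  if (use_charge) {
    chg <- mol$atoms$charge
    nz <- chg != 0L
    s[nz] <- paste0(s[nz], sprintf("%+d", chg[nz]))
  }
  s
}

#' Enumerate counted linear fragments of a molecule
#'
#' Counts every simple path (no repeated atom) of 0 to `max_len` bonds in the
#' heavy-atom graph.  A fragment is spelled as alternating atom and bond
#' symbols and canonicalised as the lexicographic minimum of its forward and
#' reversed spelling; length-0 fragments are single heavy atoms.  Under the
#' default `count_mode = "path"` each undirected path is counted once; under
#' `"traversal"` each path of length >= 1 is counted once per traversal
#' direction (twice), the convention used by naive path enumerators and the
#' one reproducing the published worked reaction distances of this method
#' (see the package vignette).
#'
#' @param mol a [molecule_graph()].
#' @param max_len maximum fragment length in bonds, between 0 and 6.
#' @param count_mode `"path"` (undirected paths counted once, default) or
#'   `"traversal"` (counted once per direction).
#' @param use_charge logical; append formal charges to atom symbols
#'   (default `FALSE`).
#' @return Named integer vector: canonical fragment string -> count.
#' @examples
#' \donttest{
#' enumerate_linear_fragments(parse_molecule("CCO"), 2)
#' # C C-C C-C-O C-O O
#' # 2   1     1   1 1
#' }
#' @export
enumerate_linear_fragments <- function(mol, max_len,
                                       count_mode = c("path", "traversal"),
                                       use_charge = FALSE) {
  stopifnot(inherits(mol, "molecule_graph"))
  count_mode <- match.arg(count_mode)
  if (!is.numeric(max_len) || length(max_len) != 1L || is.na(max_len) ||
      max_len != as.integer(max_len) || max_len < 0L || max_len > 6L)
    stop("max_len must be an integer between 0 and 6", call. = FALSE)
  max_len <- as.integer(max_len)
  n <- nrow(mol$atoms)
  if (n == 0L) return(structure(integer(0), names = character(0)))
  sym <- .atom_symbols(mol, use_charge)

  counts <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(k, by) {
    cur <- counts[[k]]
    counts[[k]] <- if (is.null(cur)) by else cur + by
  }
  for (s in sym) bump(s, 1L)  # length-0 fragments, one per heavy atom

  if (max_len >= 1L && nrow(mol$bonds)) {
    nb <- vector("list", n)
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$from[i]; b <- mol$bonds$to[i]; o <- mol$bonds$order[i]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
    ## DFS over directed simple paths; every undirected path of length >= 1
    ## is reached exactly twice (once from each endpoint)
    visited <- logical(n)
    walk <- function(at, str, len) {
      adj <- nb[[at]]
      if (is.null(adj)) return()
      for (k in seq_len(nrow(adj))) {
        nxt <- as.integer(adj[k, 1L])
        if (visited[nxt]) next
        s2 <- paste0(str, adj[k, 2L], sym[nxt])
        bump(s2, 1L)
        if (len + 1L < max_len) {
          visited[nxt] <<- TRUE
          walk(nxt, s2, len + 1L)
          visited[nxt] <<- FALSE
        }
      }
    }
    for (a in seq_len(n)) {
      visited[a] <- TRUE
      walk(a, sym[a], 0L)
      visited[a] <- FALSE
    }
  }

  keys <- ls(counts)
  val <- vapply(keys, function(k) counts[[k]], integer(1))
  if (length(val)) {
    canon <- vapply(keys, .canonical_fragment, character(1))
    val <- vapply(split(val, canon), sum, integer(1))
    if (count_mode == "path") {
      ## each undirected path of length >= 1 was traversed from both ends,
      ## contributing 2 to its canonical spelling; halve to count it once
      len0 <- fragment_length(names(val)) == 0L
      val[!len0] <- val[!len0] %/% 2L
    }
  }
  val[order(names(val))]
}

## canonical spelling: lexicographic min of forward and reversed fragment
.canonical_fragment <- function(s) {
  toks <- .fragment_tokens(s)
  rev_s <- paste(rev(toks), collapse = "")
  if (rev_s < s) rev_s else s
}

.fragment_tokens <- function(s) {
  ## split "C-C=O" into c("C","-","C","=","O"); atom symbols may carry a
  ## charge suffix like "N+1" -- the +/- there is never a bond symbol since
  ## bond symbols are -=#: and charges always follow a letter+sign+digit form
  regmatches(s, gregexpr("[-=#:](?![0-9])|[^-=#:]+(?:[+-][0-9]+)?",
                         s, perl = TRUE))[[1L]]
}

#' Fragment length in bonds
#'
#' @param fragment canonical fragment string, e.g. `"C-C=O"`.
#' @return Integer bond count (0 for a single-atom fragment).
#' @export
fragment_length <- function(fragment) {
  vapply(fragment, function(s)
    sum(.fragment_tokens(s) %in% c("-", "=", "#", ":")), integer(1),
    USE.NAMES = FALSE)
}
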