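## Fingerprint algebra: molecular fingerprints (MFP), stoichiometry-weighted
## reaction difference fingerprints (RFP) and the Euclidean reaction distance.
## Fingerprints are sparse maps canonical fragment -> integer, held as named
## integer vectors with dialect metadata; zero entries are never stored.

.new_fp <- function(entries, max_len, type = c("mfp", "rfp"),
                    count_mode = "path", use_charge = FALSE) {
  type <- match.arg(type)
  entries <- entries[entries != 0L]
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, max_len = as.integer(max_len),
                 type = type, count_mode = count_mode,
                 use_charge = use_charge),
            class = "rdf_fingerprint")
}

#' @export
print.rdf_fingerprint <- function(x, ...) {
  cat("<", if (x$type == "mfp") "molecular" else "reaction difference",
      " fingerprint> max_len=", x$max_len, " count_mode=", x$count_mode,
      if (x$use_charge) " (charged atom types)", "\n", sep = "")
  if (!length(x$entries)) {
    cat("  (empty)\n")
  } else {
    print(x$entries)
  }
  invisible(x)
}

#' @export
as.data.frame.rdf_fingerprint <- function(x, ...) {
  data.frame(fragment = names(x$entries), count = unname(x$entries))
}

#' Molecular fingerprint of counted linear fragments
#'
#' Wraps [enumerate_linear_fragments()] with the metadata (maximum length,
#' counting mode, atom-typing flags) that make two fingerprints comparable.
#'
#' @inheritParams enumerate_linear_fragments
#' @return An `rdf_fingerprint` of type `"mfp"`; all stored counts are
#'   positive, zero entries are absent.
#' @examples
#' \donttest{
#' molecular_fingerprint(parse_molecule("CCO"), max_len = 2)
#' }
#' @export
molecular_fingerprint <- function(mol, max_len,
                                  count_mode = c("path", "traversal"),
                                  use_charge = FALSE) {
  count_mode <- match.arg(count_mode)
  .new_fp(enumerate_linear_fragments(mol, max_len, count_mode, use_charge),
          max_len, "mfp", count_mode, use_charge)
}

## coefficient-weighted sum of fragment maps for one reaction side
.side_fp <- function(side, graphs, max_len, count_mode, use_charge, rxn_id) {
  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(side))) {
    coef <- side$coef[i]
    cid <- side$compound[i]
    if (is.na(coef) || coef != as.integer(coef) || coef < 1)
      stop("reaction ", rxn_id, ": non-integer stoichiometric coefficient ",
           "for compound ", cid, call. = FALSE)
    g <- graphs[[cid]]
    if (is.null(g) || !inherits(g, "molecule_graph"))
      stop("reaction ", rxn_id, ": no structure for compound ", cid,
           call. = FALSE)
    fr <- enumerate_linear_fragments(g, max_len, count_mode, use_charge)
    for (k in names(fr)) {
      cur <- acc[[k]]
      acc[[k]] <- (if (is.null(cur)) 0L else cur) + as.integer(coef) * fr[[k]]
    }
  }
  keys <- ls(acc)
  structure(vapply(keys, function(k) acc[[k]], integer(1)), names = keys)
}

#' Reaction difference fingerprint
#'
#' Computes the signed fragment-count difference of a reaction:
#' the coefficient-weighted sum of the reactant molecular fingerprints minus
#' the coefficient-weighted sum of the product molecular fingerprints.
#' Exact-zero entries are dropped, so a transformation invisible to linear
#' fragments (e.g. a racemisation) yields an empty fingerprint.
#'
#' @param reaction an [reaction()] object, or an equation string such as
#'   `"C01010 + C00001 <=> 2 C00011 + 2 C00014"`.
#' @param compounds a compound table (data frame with columns `id`, `smiles`),
#'   a named list of [molecule_graph()] objects, or a named character vector
#'   of SMILES.
#' @inheritParams enumerate_linear_fragments
#' @return An `rdf_fingerprint` of type `"rfp"`; all stored values are
#'   non-zero signed integers.
#' @examples
#' \donttest{
#' cmp <- data.frame(id = c("C01010", "C00001", "C00011", "C00014"),
#'                   smiles = c("NC(=O)NC(O)=O", "O", "O=C=O", "N"))
#' reaction_difference_fingerprint(
#'   "C01010 + C00001 <=> 2 C00011 + 2 C00014", cmp, max_len = 1)
#' # C-N +3, C-O +1, C=O -2
#' }
#' @export
reaction_difference_fingerprint <- function(reaction, compounds, max_len,
                                            count_mode = c("path", "traversal"),
                                            use_charge = FALSE) {
  count_mode <- match.arg(count_mode)
  rxn <- as_reaction(reaction)
  if (isTRUE(rxn$symbolic))
    stop("reaction ", rxn$id %||% "", " has symbolic stoichiometric ",
         "coefficients (polymer notation); it cannot be fingerprinted",
         call. = FALSE)
  graphs <- compound_graphs(compounds)
  lhs <- .side_fp(rxn$reactants, graphs, max_len, count_mode, use_charge,
                  rxn$id %||% "<query>")
  rhs <- .side_fp(rxn$products, graphs, max_len, count_mode, use_charge,
                  rxn$id %||% "<query>")
  keys <- union(names(lhs), names(rhs))
  d <- structure(integer(length(keys)), names = keys)
  d[names(lhs)] <- lhs
  d[names(rhs)] <- d[names(rhs)] - rhs
  .new_fp(d, max_len, "rfp", count_mode, use_charge)
}

#' Euclidean distance between two reaction difference fingerprints
#'
#' The Euclidean norm of the entrywise difference over the union of fragment
#' keys (absent keys read as zero).  The squared distance is an exact integer;
#' comparisons inside the classifier are made on squared values and only the
#' reported distance takes the square root.
#'
#' @param a,b `rdf_fingerprint` objects sharing `max_len` and dialect.
#' @return Non-negative numeric distance.
#' @examples
#' \donttest{
#' cmp <- data.frame(id = c("A", "B"), smiles = c("CCO", "CC=O"))
#' r1 <- reaction_difference_fingerprint("A <=> B", cmp, 2)
#' euclidean_distance(r1, r1)  # 0
#' }
#' @export
euclidean_distance <- function(a, b) {
  sqrt(squared_distance(a, b))
}

#' @rdname euclidean_distance
#' @export
squared_distance <- function(a, b) {
  stopifnot(inherits(a, "rdf_fingerprint"), inherits(b, "rdf_fingerprint"))
  if (a$max_len != b$max_len)
    stop("fingerprints with different max_len are incomparable (",
         a$max_len, " vs ", b$max_len, ")", call. = FALSE)
  if (a$count_mode != b$count_mode || a$use_charge != b$use_charge)
    stop("fingerprints computed under different dialects are incomparable",
         call. = FALSE)
  keys <- union(names(a$entries), names(b$entries))
  if (!length(keys)) return(0)
  av <- structure(numeric(length(keys)), names = keys)
  bv <- av
  av[names(a$entries)] <- a$entries
  bv[names(b$entries)] <- b$entries
  sum((av - bv)^2)
}

#' Serialize a fingerprint to TSV
#'
#' Writes `fragment<TAB>count` rows preceded by header comment lines
#' recording the dialect (`max_len`, counting mode, charge typing), so that a
#' fingerprint read back with [read_fingerprint_tsv()] is comparable.
#'
#' @param fp an `rdf_fingerprint`.
#' @param path file path or connection.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  stopifnot(inherits(fp, "rdf_fingerprint"))
  hdr <- c(paste0("# type=", fp$type),
           paste0("# max_len=", fp$max_len),
           paste0("# count_mode=", fp$count_mode),
           paste0("# charge=", if (fp$use_charge) "on" else "off"),
           "# dialect=element+aromaticity linear fragments v1")
  rows <- if (length(fp$entries))
    paste(names(fp$entries), fp$entries, sep = "\t") else character(0)
  writeLines(c(hdr, rows), path)
  invisible(fp)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(k, default = NULL) {
    m <- grep(paste0("^# ", k, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", k, "="), "", m[1L]) else default
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  entries <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    entries <- structure(vapply(parts, function(p) as.integer(p[2L]), integer(1)),
                         names = vapply(parts, `[`, character(1), 1L))
  }
  .new_fp(entries, as.integer(get("max_len", "3")),
          get("type", "rfp"), get("count_mode", "path"),
          identical(get("charge", "off"), "on"))
}

#' Resolve a compound collection to molecule graphs
#'
#' Accepts a compound table (`id`, `smiles` columns), a named character
#' vector of SMILES, or a named list of [molecule_graph()] objects, and
#' returns a named list of graphs.  Compounds with a missing structure
#' (`NA`, empty, or `"-"`) map to `NA` entries, which the dataset filter
#' reports as category 4.
#'
#' @param compounds the collection to resolve.
#' @return Named list of `molecule_graph` objects (or `NA` for declared
#'   missing structures).
#' @export
compound_graphs <- function(compounds) {
  if (is.list(compounds) && !is.data.frame(compounds)) {
    ok <- vapply(compounds, function(x)
      inherits(x, "molecule_graph") || identical(x, NA), logical(1))
    if (all(ok)) {
      if (is.null(names(compounds)))
        stop("compound list must be named by id", call. = FALSE)
      return(compounds)
    }
    stop("compound list must contain molecule_graph objects", call. = FALSE)
  }
  if (is.character(compounds)) {
    compounds <- data.frame(id = names(compounds), smiles = unname(compounds))
  }
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in% names(compounds)))
  out <- vector("list", nrow(compounds))
  names(out) <- compounds$id
  for (i in seq_len(nrow(compounds))) {
    smi <- compounds$smiles[i]
    if (is.na(smi) || !nzchar(trimws(smi)) || identical(trimws(smi), "-")) {
      out[[i]] <- NA
    } else {
      out[[i]] <- parse_molecule(trimws(smi), "smiles", id = compounds$id[i])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
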