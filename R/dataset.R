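## Reaction data model: equation parsing, EC labels, compound/reaction
## readers and the six-case dataset exclusion filter.

#' Parse a reaction equation string
#'
#' Splits an equation of the form
#' `"C01010 + C00001 <=> 2 C00011 + 2 C00014"` into reactant and product
#' term lists.  Terms are separated by `+`; a leading integer is the
#' stoichiometric coefficient (default 1); compound identifiers are kept
#' verbatim.  Symbolic coefficients such as `n` or `(n+1)` (polymer
#' notation) are a parse error unless `partial = TRUE`, in which case the
#' affected terms get `NA` coefficients and the result carries
#' `symbolic = TRUE` so the dataset filter can report the reaction under
#' category 5.
#'
#' @param text equation string containing exactly one `<=>` arrow.
#' @param partial logical; tolerate symbolic coefficients (see above).
#' @return List with elements `reactants` and `products`, each a data frame
#'   with columns `coef` and `compound`, plus a logical `symbolic` flag.
#' @examples
#' parse_equation("C01010 + C00001 <=> 2 C00011 + 2 C00014")
#' @export
parse_equation <- function(text, partial = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  sides <- strsplit(text, "<=>", fixed = TRUE)[[1L]]
  if (length(sides) != 2L)
    stop("equation must contain exactly one '<=>' arrow: ", text,
         call. = FALSE)
  symbolic <- FALSE
  parse_side <- function(s, which) {
    if (grepl("^\\s*\\+", s) || grepl("\\+\\s*$", s))
      stop("empty ", which, " term in equation: ", text, call. = FALSE)
    ## terms are separated by "+" with whitespace on at least one side, so
    ## polymer multipliers like "(n+1)" stay within their term
    terms <- trimws(strsplit(s, "(\\s+\\+\\s*)|(\\s*\\+\\s+)",
                             perl = TRUE)[[1L]])
    if (!length(terms) || any(!nzchar(terms)))
      stop("empty ", which, " term in equation: ", text, call. = FALSE)
    coef <- integer(length(terms))
    cmp <- character(length(terms))
    for (i in seq_along(terms)) {
      m <- regmatches(terms[i], regexec("^([0-9]+)\\s+(\\S.*)$", terms[i]))[[1L]]
      if (length(m)) {
        coef[i] <- as.integer(m[2L])
        cmp[i] <- m[3L]
      } else if (grepl("^\\S+$", terms[i])) {
        coef[i] <- 1L
        cmp[i] <- terms[i]
      } else {
        ## a multiplier that is not a plain integer, e.g. "n H2O", "(n+1) X"
        if (!partial)
          stop("symbolic coefficient in ", which, " term '", terms[i],
               "' of equation: ", text, call. = FALSE)
        symbolic <<- TRUE
        coef[i] <- NA_integer_
        cmp[i] <- sub("^\\S+\\s+", "", terms[i])
      }
      if (!is.na(coef[i]) && coef[i] < 1L)
        stop("coefficient must be >= 1 in term '", terms[i], "'",
             call. = FALSE)
    }
    data.frame(coef = coef, compound = cmp)
  }
  list(reactants = parse_side(sides[1L], "reactant"),
       products = parse_side(sides[2L], "product"),
       symbolic = symbolic)
}

#' Serialize parsed equation sides back to an equation string
#'
#' Inverse of [parse_equation()]: coefficients of 1 are omitted, term order
#' is preserved, so parse-then-deparse round-trips.
#'
#' @param reactants,products data frames with `coef` and `compound` columns.
#' @return Equation string.
#' @export
deparse_equation <- function(reactants, products) {
  side <- function(s) paste(ifelse(!is.na(s$coef) & s$coef > 1L,
                                   paste(s$coef, s$compound), s$compound),
                            collapse = " + ")
  paste(side(reactants), "<=>", side(products))
}

#' Construct a reaction object
#'
#' @param id reaction identifier.
#' @param equation equation string (see [parse_equation()]), or `NULL` if
#'   `reactants`/`products` are given directly.
#' @param ec EC label string (possibly partial, e.g. `"2.1.1"`) or `NULL`.
#' @param reactants,products alternative to `equation`: data frames with
#'   `coef` and `compound` columns.
#' @param partial passed to [parse_equation()].
#' @return An object of class `rdf_reaction`.
#' @export
reaction <- function(id, equation = NULL, ec = NULL,
                     reactants = NULL, products = NULL, partial = FALSE) {
  if (!is.null(equation)) {
    p <- parse_equation(equation, partial = partial)
    reactants <- p$reactants
    products <- p$products
    symbolic <- p$symbolic
  } else {
    stopifnot(is.data.frame(reactants), is.data.frame(products))
    symbolic <- anyNA(reactants$coef) || anyNA(products$coef)
  }
  if (!nrow(reactants) || !nrow(products))
    stop("both reaction sides must be non-empty", call. = FALSE)
  ec_obj <- if (is.null(ec) || (length(ec) == 1L && (is.na(ec) || !nzchar(trimws(ec)))))
    NULL else as_ec_label(ec)
  structure(list(id = id, reactants = reactants, products = products,
                 ec = ec_obj, symbolic = symbolic,
                 equation = deparse_equation(reactants, products)),
            class = "rdf_reaction")
}

#' Coerce to a reaction object
#'
#' @param x an `rdf_reaction`, an equation string, or a one-row data frame
#'   with columns `id`, `equation` and optionally `ec`.
#' @param ... unused.
#' @return An `rdf_reaction`.
#' @export
as_reaction <- function(x, ...) {
  if (inherits(x, "rdf_reaction")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(reaction(id = NULL, equation = x))
  if (is.data.frame(x) && nrow(x) == 1L)
    return(reaction(id = x$id, equation = x$equation,
                    ec = if ("ec" %in% names(x)) x$ec else NULL,
                    partial = TRUE))
  stop("cannot coerce to reaction", call. = FALSE)
}

#' @export
print.rdf_reaction <- function(x, ...) {
  cat("<reaction ", x$id %||% "", "> ", x$equation, sep = "")
  if (!is.null(x$ec)) cat("  [EC ", format(x$ec), "]", sep = "")
  if (isTRUE(x$symbolic)) cat("  (symbolic coefficients)")
  cat("\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## EC labels

#' Enzyme Commission labels
#'
#' An EC label has 1 to 4 dotted components; trailing components may be the
#' placeholder `"-"` but no defined component may follow a placeholder.  The
#' main class must be 1..6 (oxidoreductases, transferases, hydrolases,
#' lyases, isomerases, ligases).
#'
#' @param x label string (`"2.7.1.90"`, `"2.1.1"`, `"3.6.1.-"`) or vector of
#'   components.
#' @return An object of class `ec_label` (character vector of defined
#'   components).
#' @examples
#' ec_truncate(as_ec_label("2.7.1.90"), 3)  # EC 2.7.1
#' @export
as_ec_label <- function(x) {
  if (inherits(x, "ec_label")) return(x)
  comp <- if (length(x) == 1L) strsplit(trimws(x), ".", fixed = TRUE)[[1L]]
          else as.character(x)
  if (!length(comp) || length(comp) > 4L)
    stop("EC label must have 1-4 components: ", paste(comp, collapse = "."),
         call. = FALSE)
  defined <- comp != "-"
  if (any(defined & cumsum(!defined) > 0L))
    stop("no defined EC field may follow a placeholder: ",
         paste(comp, collapse = "."), call. = FALSE)
  comp <- comp[defined]
  if (!length(comp))
    stop("EC label has no defined components", call. = FALSE)
  if (!all(grepl("^[0-9]+$", comp)))
    stop("EC components must be positive integers or '-': ",
         paste(comp, collapse = "."), call. = FALSE)
  if (!as.integer(comp[1L]) %in% 1:6)
    stop("EC main class must be 1..6: ", paste(comp, collapse = "."),
         call. = FALSE)
  structure(comp, class = "ec_label")
}

#' @export
format.ec_label <- function(x, ...) paste(unclass(x), collapse = ".")

#' @export
print.ec_label <- function(x, ...) {
  cat("EC", format(x), "\n")
  invisible(x)
}

#' Truncate an EC label to a hierarchy level
#'
#' @param ec an `ec_label` (or string coercible to one).
#' @param level integer in 1..4: 1 = main class, 2 = subclass,
#'   3 = sub-subclass, 4 = serial number.
#' @return The truncated `ec_label`.  Labels with fewer defined components
#'   than `level` are an error: such a reaction is unusable at that scoring
#'   level.
#' @export
ec_truncate <- function(ec, level) {
  ec <- as_ec_label(ec)
  stopifnot(length(level) == 1L, level %in% 1:4)
  if (length(ec) < level)
    stop("EC ", format(ec), " has fewer than ", level,
         " defined components", call. = FALSE)
  structure(unclass(ec)[seq_len(level)], class = "ec_label")
}

## ---------------------------------------------------------------------------
## Readers

#' Read a compound table
#'
#' Tab-separated file with columns `id` and `smiles` (a header line naming
#' them is recognised and skipped; `#` lines are comments).  An empty or
#' `"-"` structure field declares a compound without structure information.
#'
#' @param path file path.
#' @return Data frame with columns `id`, `smiles` (and `name` if present).
#' @export
read_compound_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && identical(tolower(parts[[1L]][1L]), "id"))
    parts <- parts[-1L]
  df <- data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    smiles = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1)))
  nm <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, character(1))
  if (any(!is.na(nm))) df$name <- nm
  df
}

#' Read compounds from an SDF file
#'
#' Multi-record MDL SDF (V2000); the record title line provides the
#' compound id unless a data field named in `id_field` is present.
#'
#' @param path file path.
#' @param id_field optional SDF data field holding the compound id.
#' @return Named list of [molecule_graph()] objects.
#' @export
read_compound_sdf <- function(path, id_field = NULL) {
  lines <- readLines(path)
  breaks <- c(0L, grep("^\\${4}", lines))
  out <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    rec <- lines[(breaks[i] + 1L):(breaks[i + 1L] - 1L)]
    if (!length(rec) || !any(nzchar(rec))) next
    id <- trimws(rec[1L])
    if (!is.null(id_field)) {
      fi <- grep(paste0("^>.*<", id_field, ">"), rec)
      if (length(fi) && fi[1L] < length(rec)) id <- trimws(rec[fi[1L] + 1L])
    }
    out[[id]] <- parse_molecule(paste(rec, collapse = "\n"), "molfile", id = id)
  }
  out
}

#' Read a reaction table
#'
#' Tab-separated file with columns `id`, `equation` and optionally `ec`
#' (multiple EC labels may be given separated by spaces, commas or
#' semicolons: the first is kept and the rest reported via a message).
#' Equations with symbolic coefficients are tolerated here and flagged so
#' that [filter_dataset()] can report them under category 5.
#'
#' @param path file path.
#' @return List of [reaction()] objects.
#' @export
read_reaction_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && identical(tolower(parts[[1L]][1L]), "id"))
    parts <- parts[-1L]
  lapply(parts, function(p) {
    ec <- if (length(p) >= 3L && nzchar(trimws(p[3L]))) {
      ecs <- strsplit(trimws(p[3L]), "[,; ]+")[[1L]]
      if (length(ecs) > 1L)
        message("reaction ", p[1L], ": keeping first of ",
                length(ecs), " EC labels (", paste(ecs, collapse = ", "), ")")
      ecs[1L]
    } else NULL
    reaction(id = p[1L], equation = p[2L], ec = ec, partial = TRUE)
  })
}

## ---------------------------------------------------------------------------
## Dataset filter

FILTER_CATEGORIES <- c(
  "1" = "elementally unbalanced equation",
  "2" = "glycan participant",
  "3" = "missing or incomplete EC label",
  "4" = "compound without structure information",
  "5" = "wildcard/R-group atoms or symbolic coefficients",
  "6" = "zero reaction difference fingerprint")

## heavy-atom element counts of one side, coefficient-weighted;
## NULL when a missing structure or wildcard makes the count undefined
.side_elements <- function(side, graphs) {
  tot <- integer(0)
  for (i in seq_len(nrow(side))) {
    g <- graphs[[side$compound[i]]]
    if (is.null(g) || !inherits(g, "molecule_graph") || any(g$atoms$wildcard))
      return(NULL)
    coef <- side$coef[i]
    if (is.na(coef)) return(NULL)
    tab <- table(g$atoms$element)
    for (el in names(tab)) {
      tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0L) +
        as.integer(coef) * as.integer(tab[[el]])
    }
  }
  tot[order(names(tot))]
}

#' Apply the six-case dataset exclusion filter
#'
#' Reactions are excluded, in this fixed order of precedence, when they are
#' (1) elementally unbalanced (heavy-atom element counts weighted by
#' coefficients differ between sides), (2) involve glycan compounds
#' (identifier prefix `"G"`), (3) lack an EC label defined to at least the
#' sub-subclass, (4) cite a compound declared without a structure record,
#' (5) contain wildcard/R-group atoms or symbolic (polymer) coefficients, or
#' (6) have a zero reaction difference fingerprint at `max_len`.  Categories
#' overlap; each reaction is reported once under the first matching one.
#' The balance check uses heavy atoms only (structures are
#' hydrogen-suppressed) and is skipped -- never fired -- when a missing
#' structure or wildcard atom makes element counts undefined.
#'
#' @param reactions list of [reaction()] objects (or a data frame with
#'   columns `id`, `equation`, `ec`).
#' @param compounds compound collection resolvable by id (see
#'   [compound_graphs()]).  A compound id cited by a reaction but absent
#'   from the table is a data-integrity error, distinct from category 4.
#' @param max_len fragment length used for the category-6 test.
#' @param require_ec_level EC depth (defined components) required by
#'   category 3; default 3 (sub-subclass), the level the classifier
#'   predicts.
#' @param glycan_prefix id prefix marking glycan compounds.
#' @param glycan_override ids exempt from glycan detection.
#' @inheritParams enumerate_linear_fragments
#' @return An object of class `rdf_filter_report`: a data frame with one row
#'   per input reaction (`id`, `status`, `category`, `message`), with the
#'   category counts, configuration and kept ids as attributes.
#' @examples
#' \donttest{
#' cmp <- data.frame(id = c("A", "B"), smiles = c("CCO", "CC=O"))
#' rxn <- list(reaction("R1", "A <=> B", ec = "1.1.1.1"))
#' filter_dataset(rxn, cmp, max_len = 3)
#' }
#' @export
filter_dataset <- function(reactions, compounds, max_len = 3L,
                           count_mode = c("path", "traversal"),
                           use_charge = FALSE,
                           require_ec_level = 3L,
                           glycan_prefix = "G",
                           glycan_override = character()) {
  count_mode <- match.arg(count_mode)
  reactions <- .as_reaction_list(reactions)
  graphs <- compound_graphs(compounds)
  cited <- unique(unlist(lapply(reactions, function(r)
    c(r$reactants$compound, r$products$compound))))
  unknown <- setdiff(cited, names(graphs))
  if (length(unknown))
    stop("unknown compound id(s) cited by reactions: ",
         paste(unknown, collapse = ", "),
         " (not present in the compound table)", call. = FALSE)

  n <- length(reactions)
  status <- rep("kept", n)
  category <- rep(NA_integer_, n)
  msg <- rep("", n)
  for (i in seq_len(n)) {
    r <- reactions[[i]]
    ids <- c(r$reactants$compound, r$products$compound)
    ex <- function(cat, m) {
      status[i] <<- "excluded"; category[i] <<- cat; msg[i] <<- m
    }
    lhs <- .side_elements(r$reactants, graphs)
    rhs <- .side_elements(r$products, graphs)
    glyc <- ids[startsWith(ids, glycan_prefix) & !(ids %in% glycan_override)]
    no_struct <- ids[vapply(ids, function(id)
      !inherits(graphs[[id]], "molecule_graph"), logical(1))]
    wild <- ids[vapply(ids, function(id) {
      g <- graphs[[id]]
      inherits(g, "molecule_graph") && any(g$atoms$wildcard)
    }, logical(1))]

    if (!is.null(lhs) && !is.null(rhs) && !identical(lhs, rhs)) {
      ex(1L, paste0("element counts differ: [",
                    paste0(names(lhs), lhs, collapse = " "), "] vs [",
                    paste0(names(rhs), rhs, collapse = " "), "]"))
    } else if (length(glyc)) {
      ex(2L, paste("glycan compound(s):", paste(unique(glyc), collapse = ", ")))
    } else if (is.null(r$ec) || length(r$ec) < require_ec_level) {
      ex(3L, if (is.null(r$ec)) "no EC label"
             else paste0("EC ", format(r$ec), " not defined to level ",
                         require_ec_level))
    } else if (length(no_struct)) {
      ex(4L, paste("no structure for:", paste(unique(no_struct), collapse = ", ")))
    } else if (isTRUE(r$symbolic) || length(wild)) {
      ex(5L, if (isTRUE(r$symbolic)) "symbolic (polymer) coefficients"
             else paste("wildcard atoms in:", paste(unique(wild), collapse = ", ")))
    } else {
      rfp <- reaction_difference_fingerprint(r, graphs, max_len,
                                             count_mode, use_charge)
      if (!length(rfp$entries))
        ex(6L, paste0("zero difference fingerprint at max_len ", max_len))
    }
  }
  out <- data.frame(id = vapply(reactions, function(r) r$id %||% NA_character_,
                                character(1)),
                    status = status, category = category, message = msg)
  structure(out,
            class = c("rdf_filter_report", "data.frame"),
            counts = table(factor(category, levels = 1:6)),
            config = list(max_len = as.integer(max_len),
                          count_mode = count_mode, use_charge = use_charge,
                          require_ec_level = require_ec_level,
                          glycan_prefix = glycan_prefix,
                          category_order = "1<2<3<4<5<6 (first match reported)"),
            kept = out$id[status == "kept"])
}

#' @export
print.rdf_filter_report <- function(x, ...) {
  cfg <- attr(x, "config")
  counts <- attr(x, "counts")
  cat("Dataset filter report (max_len=", cfg$max_len,
      ", count_mode=", cfg$count_mode,
      ", categories applied in order 1..6, first match reported)\n", sep = "")
  cat("  reactions: ", nrow(x), "  kept: ", sum(x$status == "kept"),
      "  excluded: ", sum(x$status == "excluded"), "\n", sep = "")
  for (k in as.character(1:6)) {
    if (counts[[k]] > 0L)
      cat(sprintf("  category %s (%s): %d\n", k, FILTER_CATEGORIES[[k]],
                  counts[[k]]))
  }
  invisible(x)
}

#' Identifiers of reactions kept by a filter report
#'
#' @param report an `rdf_filter_report`.
#' @return Character vector of kept reaction ids.
#' @export
kept_ids <- function(report) {
  stopifnot(inherits(report, "rdf_filter_report"))
  attr(report, "kept")
}

#' Write a filter report to TSV
#'
#' @param report an `rdf_filter_report`.
#' @param path file path.
#' @export
write_filter_report <- function(report, path) {
  cfg <- attr(report, "config")
  hdr <- c(paste0("# max_len=", cfg$max_len),
           paste0("# count_mode=", cfg$count_mode),
           paste0("# require_ec_level=", cfg$require_ec_level),
           paste0("# category_order=", cfg$category_order),
           "# balance check: heavy-atom element counts (proxy for missing molecules)",
           paste("id", "status", "category", "message", sep = "\t"))
  rows <- paste(report$id, report$status,
                ifelse(is.na(report$category), "", report$category),
                report$message, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(report)
}

.as_reaction_list <- function(reactions) {
  if (inherits(reactions, "rdf_reaction")) return(list(reactions))
  if (is.data.frame(reactions)) {
    return(lapply(seq_len(nrow(reactions)), function(i)
      as_reaction(reactions[i, , drop = FALSE])))
  }
  stopifnot(is.list(reactions))
  lapply(reactions, as_reaction)
}
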