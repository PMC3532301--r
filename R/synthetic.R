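## Synthetic labelled reaction sets built from transformation templates.
##
## A template is a structural edit applied to a scaffold: the substrate and
## product are written by appending a functional-group suffix to the
## scaffold SMILES, optionally together with a cosubstrate/coproduct pair
## (e.g. a methyl donor), chosen so that every generated equation is
## heavy-atom balanced by construction.  Sets generated with disjoint edit
## signatures give class structure the classifier can recover perfectly,
## which makes every other module testable without any database download.

#' Define a transformation template
#'
#' @param name template name (used in error messages and metadata).
#' @param ec three-level EC label the template emulates.
#' @param substrate_suffix,product_suffix SMILES suffixes appended to a
#'   scaffold SMILES to build the substrate and product (e.g. `"N"` ->
#'   `"NC"` for N-methylation of a primary amine).
#' @param cosubstrate,coproduct optional SMILES of an unchanged-scaffold
#'   cosubstrate/coproduct pair (e.g. a methyl donor and its demethylated
#'   form) keeping the equation balanced.
#' @param zero_rfp logical; `TRUE` marks a template (e.g. a racemisation)
#'   whose reactions have zero difference fingerprints -- emitted only when
#'   [generate_reaction_set()] is asked for them.
#' @return An object of class `rdf_template`.
#' @export
reaction_template <- function(name, ec, substrate_suffix, product_suffix,
                              cosubstrate = NULL, coproduct = NULL,
                              zero_rfp = FALSE) {
  structure(list(name = name, ec = format(as_ec_label(ec)),
                 substrate_suffix = substrate_suffix,
                 product_suffix = product_suffix,
                 cosubstrate = cosubstrate, coproduct = coproduct,
                 zero_rfp = zero_rfp),
            class = "rdf_template")
}

#' @export
print.rdf_template <- function(x, ...) {
  cat("<template ", x$name, "> EC ", x$ec, ": R+", x$substrate_suffix,
      if (!is.null(x$cosubstrate)) paste0(" + ", x$cosubstrate),
      " <=> R+", x$product_suffix,
      if (!is.null(x$coproduct)) paste0(" + ", x$coproduct),
      if (x$zero_rfp) "  (zero-RFP)", "\n", sep = "")
  invisible(x)
}

#' Built-in transformation templates
#'
#' Six templates spanning five EC main classes, with edit signatures chosen
#' to be mutually disjoint at fragment length 3:
#' \describe{
#'   \item{amine_methylation (EC 2.1.1)}{`R-NH2` + dimethyl sulfide donor ->
#'     `R-NHCH3` + methanethiol; discriminating fragments from length 1.}
#'   \item{ester_hydrolysis (EC 3.1.1)}{methyl ester + water -> acid +
#'     methanol; difference fingerprint zero at length <= 1, collides with
#'     ether hydrolysis at length 2, separates at length 3.}
#'   \item{ether_hydrolysis (EC 3.3.1)}{methyl ether + water -> alcohol +
#'     methanol; see above.}
#'   \item{alcohol_oxidation (EC 1.1.1)}{primary alcohol + acetone ->
#'     aldehyde + 2-propanol; zero at length <= 1, separated from length 2.}
#'   \item{decarboxylation (EC 4.1.1)}{2-amino acid -> amine + CO2;
#'     discriminating from length 1.}
#'   \item{racemisation (EC 5.1.1, zero-RFP)}{L- to D-2-amino acid: the
#'     stereo-only edit is invisible to linear fragments.}
#' }
#' The staggered discriminating lengths are what makes cross-validation
#' accuracy degrade as the fingerprint length is reduced below 3.
#'
#' @return Named list of [reaction_template()] objects.
#' @export
reaction_templates <- function() {
  list(
    amine_methylation = reaction_template(
      "amine_methylation", "2.1.1", "N", "NC",
      cosubstrate = "CSC", coproduct = "CS"),
    ester_hydrolysis = reaction_template(
      "ester_hydrolysis", "3.1.1", "C(=O)OC", "C(=O)O",
      cosubstrate = "O", coproduct = "CO"),
    ether_hydrolysis = reaction_template(
      "ether_hydrolysis", "3.3.1", "COC", "CO",
      cosubstrate = "O", coproduct = "CO"),
    alcohol_oxidation = reaction_template(
      "alcohol_oxidation", "1.1.1", "CO", "C=O",
      cosubstrate = "CC(C)=O", coproduct = "CC(C)O"),
    decarboxylation = reaction_template(
      "decarboxylation", "4.1.1", "C(N)C(=O)O", "CN",
      coproduct = "O=C=O"),
    racemisation = reaction_template(
      "racemisation", "5.1.1", "[C@@H](N)C(=O)O", "[C@H](N)C(=O)O",
      zero_rfp = TRUE))
}

#' Default scaffold set
#'
#' Small linear alkyl scaffolds (3-7 chain carbons, `<= 12` heavy atoms
#' after decoration) whose local neighbourhood at the attachment point is
#' identical, so reactions generated from the same template have identical
#' difference fingerprints and templates separate cleanly.
#'
#' @return Character vector of scaffold SMILES (attachment at the string
#'   end).
#' @export
default_scaffolds <- function() {
  c("CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC")
}

#' Generate a labelled synthetic reaction set
#'
#' Applies each template to scaffolds sampled under a fixed seed and emits a
#' compound table and a labelled reaction table in the package's dataset
#' formats.  Every emitted reaction is heavy-atom balanced and passes filter
#' categories 1-5; zero-difference-fingerprint templates (racemisations) are
#' only emitted when `include_zero_rfp = TRUE`, to exercise filter
#' category 6.
#'
#' @param templates list of [reaction_template()] objects.
#' @param scaffolds character vector of scaffold SMILES.
#' @param n_per_template reactions generated per template (>= 1); scaffolds
#'   are sampled without replacement while possible.
#' @param seed integer fixing all randomness (scaffold sampling).  The same
#'   call with the same seed is byte-identical.  The global RNG state is
#'   left untouched.
#' @param include_zero_rfp emit zero-RFP templates too (default `FALSE`).
#' @return An object of class `rdf_reaction_set`: list with `compounds`
#'   (data frame `id`, `smiles`), `reactions` (data frame `id`, `equation`,
#'   `ec`, `template`) and the generating configuration.
#' @examples
#' \donttest{
#' set <- generate_reaction_set(n_per_template = 3, seed = 7)
#' head(set$reactions)
#' }
#' @export
generate_reaction_set <- function(templates = reaction_templates(),
                                  scaffolds = default_scaffolds(),
                                  n_per_template = 5L, seed = 1L,
                                  include_zero_rfp = FALSE) {
  stopifnot(n_per_template >= 1L, length(scaffolds) >= 1L)
  templates <- Filter(function(t) include_zero_rfp || !t$zero_rfp, templates)
  if (!length(templates)) stop("no templates to apply", call. = FALSE)

  ## seeded sampling without touching the caller's RNG state
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  smiles_id <- character(0)  # structure -> compound id
  compounds <- data.frame(id = character(), smiles = character())
  next_cmp <- 1L
  intern <- function(smi) {
    if (!is.null(smiles_id[smi]) && !is.na(smiles_id[smi]))
      return(unname(smiles_id[smi]))
    id <- sprintf("M%04d", next_cmp)
    next_cmp <<- next_cmp + 1L
    smiles_id[smi] <<- id
    compounds <<- rbind(compounds, data.frame(id = id, smiles = smi))
    id
  }

  rows <- list()
  next_rxn <- 1L
  for (tpl in templates) {
    picks <- if (n_per_template <= length(scaffolds))
      sample(scaffolds, n_per_template)
    else sample(scaffolds, n_per_template, replace = TRUE)
    applied <- 0L
    for (s in picks) {
      sub_smi <- paste0(s, tpl$substrate_suffix)
      prod_smi <- paste0(s, tpl$product_suffix)
      ok <- tryCatch({
        parse_molecule(sub_smi, "smiles")
        parse_molecule(prod_smi, "smiles")
        TRUE
      }, error = function(e) FALSE)
      if (!ok) next
      applied <- applied + 1L
      lhs <- intern(sub_smi)
      rhs <- intern(prod_smi)
      lhs_terms <- c(lhs, if (!is.null(tpl$cosubstrate)) intern(tpl$cosubstrate))
      rhs_terms <- c(rhs, if (!is.null(tpl$coproduct)) intern(tpl$coproduct))
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("R%04d", next_rxn),
        equation = paste(paste(lhs_terms, collapse = " + "), "<=>",
                         paste(rhs_terms, collapse = " + ")),
        ec = tpl$ec, template = tpl$name)
      next_rxn <- next_rxn + 1L
    }
    if (applied == 0L)
      stop("template '", tpl$name, "' is not applicable to any scaffold",
           call. = FALSE)
  }
  structure(list(compounds = compounds, reactions = do.call(rbind, rows),
                 seed = as.integer(seed), scaffolds = scaffolds,
                 n_per_template = as.integer(n_per_template)),
            class = "rdf_reaction_set")
}

#' @export
print.rdf_reaction_set <- function(x, ...) {
  cat("<synthetic reaction set> ", nrow(x$reactions), " reactions, ",
      nrow(x$compounds), " compounds (seed ", x$seed, ")\n", sep = "")
  tab <- table(x$reactions$template)
  for (t in names(tab)) cat("  ", t, ": ", tab[[t]], "\n", sep = "")
  invisible(x)
}

#' Write a synthetic reaction set to TSV files
#'
#' Emits `compounds.tsv` (`id`, `smiles`) and `reactions.tsv`
#' (`id`, `equation`, `ec`) in the dataset module's formats, with a header
#' comment recording the generating seed.  Identical calls produce
#' byte-identical files.
#'
#' @param set an `rdf_reaction_set`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reaction_set <- function(set, dir) {
  stopifnot(inherits(set, "rdf_reaction_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "compounds.tsv")
  rpath <- file.path(dir, "reactions.tsv")
  writeLines(c(paste0("# seed=", set$seed), "id\tsmiles",
               paste(set$compounds$id, set$compounds$smiles, sep = "\t")),
             cpath)
  writeLines(c(paste0("# seed=", set$seed), "id\tequation\tec",
               paste(set$reactions$id, set$reactions$equation,
                     set$reactions$ec, sep = "\t")),
             rpath)
  invisible(c(cpath, rpath))
}
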