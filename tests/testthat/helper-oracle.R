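# Independent brute-force oracles and random-structure generators used by
# the property tests.  The fragment oracle enumerates simple paths through
# igraph::all_simple_paths and builds fragment strings on its own, so it
# shares no code with the package's depth-first enumerator.

# Brute-force counted linear fragments of a molecule_graph.
oracle_fragments <- function(mol, max_len, count_mode = "path") {
  n <- nrow(mol$atoms)
  sym <- mol$atoms$element
  sym[mol$atoms$aromatic] <- tolower(sym[mol$atoms$aromatic])
  counts <- list()
  bump <- function(k, by = 1L) {
    counts[[k]] <<- (counts[[k]] %||% 0L) + by
  }
  for (s in sym) bump(s)
  if (max_len >= 1L && nrow(mol$bonds) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = mol$bonds$from, to = mol$bonds$to,
                 sym = mol$bonds$order),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    bond_sym <- function(a, b) {
      hit <- (mol$bonds$from == a & mol$bonds$to == b) |
             (mol$bonds$from == b & mol$bonds$to == a)
      mol$bonds$order[hit]
    }
    for (u in seq_len(n)) {
      for (v in seq_len(n)) {
        if (u == v) next
        if (count_mode == "path" && u > v) next
        paths <- suppressWarnings(igraph::all_simple_paths(
          g, from = u, to = v, cutoff = max_len))
        for (p in paths) {
          idx <- as.integer(names(p))
          str <- sym[idx[1L]]
          for (k in seq_len(length(idx) - 1L))
            str <- paste0(str, bond_sym(idx[k], idx[k + 1L]), sym[idx[k + 1L]])
          toks <- regmatches(str, gregexpr("[-=#:]|[^-=#:]+", str))[[1L]]
          rev_str <- paste(rev(toks), collapse = "")
          bump(min(str, rev_str))
        }
      }
    }
  }
  out <- unlist(counts)
  out <- out[order(names(out))]
  storage.mode(out) <- "integer"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random connected molecule_graph with <= n_max heavy atoms: a random
# spanning tree plus a few extra edges, random elements and bond orders,
# occasionally an aromatic 6-ring.  Chemical valence is irrelevant for the
# path-counting oracle.
random_molecule <- function(n_max = 10L) {
  if (stats::runif(1) < 0.25 && n_max >= 6L) {
    n_extra <- sample.int(n_max - 6L + 1L, 1L) - 1L
    atoms <- data.frame(
      element = c(rep("C", 6L),
                  sample(c("C", "N", "O", "S"), n_extra, replace = TRUE)),
      aromatic = c(rep(TRUE, 6L), rep(FALSE, n_extra)),
      charge = 0L, wildcard = FALSE)
    bonds <- data.frame(from = 1:6, to = c(2:6, 1L),
                        order = ":")
    for (i in seq_len(n_extra)) {
      at <- 6L + i
      bonds <- rbind(bonds, data.frame(
        from = sample.int(at - 1L, 1L), to = at,
        order = sample(c("-", "=", "#"), 1L, prob = c(.7, .2, .1))))
    }
    return(molecule_graph(atoms, bonds))
  }
  n <- sample(1:n_max, 1L)
  atoms <- data.frame(
    element = sample(c("C", "C", "C", "N", "O", "S", "P"), n, replace = TRUE),
    aromatic = FALSE, charge = 0L, wildcard = FALSE)
  bonds <- NULL
  if (n > 1L) {
    bonds <- data.frame(
      from = vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)),
      to = 2:n,
      order = sample(c("-", "=", "#"), n - 1L, replace = TRUE,
                     prob = c(.7, .2, .1)))
    for (k in seq_len(2L)) {  # a couple of ring-closing edges when possible
      if (n >= 4L && stats::runif(1) < 0.5) {
        cand <- utils::combn(n, 2L)
        key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
        free <- cand[, !(paste(cand[1L, ], cand[2L, ]) %in% key), drop = FALSE]
        if (ncol(free)) {
          pick <- free[, sample.int(ncol(free), 1L)]
          bonds <- rbind(bonds, data.frame(from = pick[1L], to = pick[2L],
                                           order = sample(c("-", "="), 1L)))
        }
      }
    }
  }
  molecule_graph(atoms, bonds)
}

# Entrywise difference of two fingerprints over the key union.
fp_diff <- function(a, b) {
  keys <- union(names(a$entries), names(b$entries))
  av <- structure(numeric(length(keys)), names = keys)
  bv <- av
  av[names(a$entries)] <- a$entries
  bv[names(b$entries)] <- b$entries
  d <- av - bv
  d[d != 0]
}

# Naive nearest-neighbour assignment, written independently of the
# package's vote: full sort on rounded distances, majority by table(),
# ties to the numerically smallest EC.
naive_assign <- function(q_rfp, rfps, ecs) {
  d2 <- vapply(rfps, function(f) squared_distance(f, q_rfp), numeric(1))
  at_min <- which(d2 == min(d2))
  tab <- sort(table(ecs[at_min]), decreasing = TRUE)
  best <- names(tab)[tab == tab[1L]]
  nums <- lapply(strsplit(best, ".", fixed = TRUE), as.integer)
  ord <- order(vapply(nums, `[`, integer(1), 1L),
               vapply(nums, `[`, integer(1), 2L),
               vapply(nums, `[`, integer(1), 3L))
  list(ec = best[ord[1L]], dist = sqrt(min(d2)))
}

worked_compounds <- function()
  read_compound_table(system.file("extdata", "worked_compounds.tsv",
                                  package = "rdfec"))

worked_reactions <- function() {
  rxn <- read_reaction_table(system.file("extdata", "worked_reactions.tsv",
                                         package = "rdfec"))
  names(rxn) <- vapply(rxn, function(r) r$id, character(1))
  rxn
}
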