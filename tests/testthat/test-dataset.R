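# Equation parsing, EC labels, readers and the six-case dataset filter.

test_that("equations parse coefficients and compound ids verbatim", {
  p <- parse_equation("C01010 + C00001 <=> 2 C00011 + 2 C00014")
  expect_equal(p$reactants,
               data.frame(coef = c(1L, 1L), compound = c("C01010", "C00001")))
  expect_equal(p$products,
               data.frame(coef = c(2L, 2L), compound = c("C00011", "C00014")))
  expect_false(p$symbolic)
  q <- parse_equation("A <=> B")
  expect_equal(q$reactants$coef, 1L)
  expect_equal(q$products$compound, "B")
})

test_that("malformed and symbolic equations are parse errors with context", {
  expect_error(parse_equation("A + B"), "<=>")
  expect_error(parse_equation("A <=> B <=> C"), "<=>")
  expect_error(parse_equation(" <=> B"), "empty reactant")
  expect_error(parse_equation("A + <=> B"), "empty reactant")
  # polymer notation (KEGG R00001 style)
  expect_error(parse_equation("Polyphosphate + n H2O <=> (n+1) Oligophosphate"),
               "symbolic coefficient")
  tol <- parse_equation("Polyphosphate + n H2O <=> (n+1) Oligophosphate",
                        partial = TRUE)
  expect_true(tol$symbolic)
  expect_true(anyNA(tol$reactants$coef))
})

test_that("parse/deparse round-trips equations", {
  for (eq in c("C01010 + C00001 <=> 2 C00011 + 2 C00014",
               "A <=> B",
               "3 X + Y <=> Z")) {
    p <- parse_equation(eq)
    expect_identical(deparse_equation(p$reactants, p$products), eq)
  }
})

test_that("EC labels validate structure and truncate by level", {
  expect_equal(format(ec_truncate("2.7.1.90", 3)), "2.7.1")
  expect_equal(format(ec_truncate("2.1.1", 1)), "2")
  expect_equal(format(as_ec_label("3.6.1.-")), "3.6.1")  # placeholder dropped
  expect_error(ec_truncate("3.6.1", 4), "fewer than 4")
  expect_error(as_ec_label("7.1.1"), "main class")
  expect_error(as_ec_label("2.-.1"), "placeholder")
  expect_error(as_ec_label("2.1.1.1.1"), "1-4")
  expect_error(as_ec_label("-"), "no defined")
})

test_that("compound and reaction tables read headers, comments and gaps", {
  ct <- tempfile(); rt <- tempfile()
  writeLines(c("# comment", "id\tsmiles", "A\tCCO", "B\t-", "C\t"), ct)
  cmp <- read_compound_table(ct)
  expect_equal(cmp$id, c("A", "B", "C"))
  graphs <- compound_graphs(cmp)
  expect_s3_class(graphs$A, "molecule_graph")
  expect_true(identical(graphs$B, NA) && identical(graphs$C, NA))

  writeLines(c("id\tequation\tec", "R1\tA <=> A\t1.1.1.1", "R2\tA <=> A\t"),
             rt)
  rxn <- read_reaction_table(rt)
  expect_length(rxn, 2L)
  expect_equal(format(rxn[[1]]$ec), "1.1.1.1")
  expect_null(rxn[[2]]$ec)
  # multiple EC labels: first kept, rest reported
  writeLines(c("R3\tA <=> A\t1.1.1.1; 2.3.4.5"), rt)
  expect_message(rxn3 <- read_reaction_table(rt), "keeping first")
  expect_equal(format(rxn3[[1]]$ec), "1.1.1.1")
})

test_that("SDF compound files parse to the same graphs as SMILES", {
  sdf <- paste0(ChemmineOB::convertFormat("SMI", "SDF", "CCO\tEtOH\n"),
                ChemmineOB::convertFormat("SMI", "SDF", "CC(=O)O\tAcOH\n"))
  tf <- tempfile(fileext = ".sdf")
  writeLines(sdf, tf)
  mols <- read_compound_sdf(tf)
  expect_named(mols, c("EtOH", "AcOH"))
  expect_identical(enumerate_linear_fragments(mols$EtOH, 2),
                   enumerate_linear_fragments(parse_molecule("CCO"), 2))
})

# A small corpus hitting each exclusion category exactly once.
filter_fixture <- function() {
  compounds <- data.frame(
    id = c("ETH", "ALD", "MET", "NOS", "G00001", "WAT", "WLD", "LAA", "DAA",
           "POL"),
    smiles = c("CCO", "CC=O", "C", "", "O", "O", "*CC(O)=O",
               "CC[C@@H](N)C(O)=O", "CC[C@H](N)C(O)=O", "OP(=O)(O)O"))
  reactions <- list(
    reaction("Rbal", "ETH <=> MET", ec = "1.1.1.1"),           # cat 1
    reaction("Rgly", "G00001 <=> WAT", ec = "1.1.1.1"),        # cat 2
    reaction("Rnoec", "ETH <=> ALD"),                          # cat 3
    reaction("Rpart", "ETH <=> ALD", ec = "1.1"),              # cat 3 (shallow)
    reaction("Rmiss", "NOS <=> ALD", ec = "1.1.1.1"),          # cat 4
    reaction("Rwild", "WLD <=> WLD", ec = "1.1.1.1"),          # cat 5
    reaction("Rpoly", "POL + n WAT <=> (n+1) POL", ec = "2.7.4.1",
             partial = TRUE),                                  # cat 5
    reaction("Rrace", "LAA <=> DAA", ec = "5.1.1.1"),          # cat 6
    reaction("Rkeep", "ETH <=> ALD", ec = "1.1.1.1"))          # kept
  list(compounds = compounds, reactions = reactions)
}

test_that("the six exclusion cases are detected in their declared order", {
  fx <- filter_fixture()
  rep <- filter_dataset(fx$reactions, fx$compounds, max_len = 3)
  got <- setNames(rep$category, rep$id)
  expect_equal(got[["Rbal"]], 1L)
  expect_equal(got[["Rgly"]], 2L)
  expect_equal(got[["Rnoec"]], 3L)
  expect_equal(got[["Rpart"]], 3L)
  expect_equal(got[["Rmiss"]], 4L)
  expect_equal(got[["Rwild"]], 5L)
  expect_equal(got[["Rpoly"]], 5L)
  expect_equal(got[["Rrace"]], 6L)
  expect_true(is.na(got[["Rkeep"]]))
  expect_equal(kept_ids(rep), "Rkeep")
  expect_equal(sum(rep$status == "kept") + sum(rep$status == "excluded"),
               nrow(rep))
})

test_that("an uncatalogued compound id is a data-integrity error, not category 4", {
  cmp <- data.frame(id = "A", smiles = "CCO")
  expect_error(filter_dataset(list(reaction("R1", "A <=> ZZZ", ec = "1.1.1.1")),
                              cmp, 3),
               "unknown compound id.*ZZZ")
})

test_that("balance checking never fires on element-identical sides", {
  cmp <- data.frame(id = c("A", "B"), smiles = c("CCO", "CC=O"))
  # ethanol vs acetaldehyde differ only in hydrogens: heavy-atom balanced
  rep <- filter_dataset(list(reaction("R", "A <=> B", ec = "1.1.1.1")), cmp, 3)
  expect_equal(rep$status, "kept")
})

test_that("the filter is deterministic and stable on its own kept set", {
  fx <- filter_fixture()
  rep1 <- filter_dataset(fx$reactions, fx$compounds, max_len = 3)
  rep2 <- filter_dataset(fx$reactions, fx$compounds, max_len = 3)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  keep <- fx$reactions[vapply(fx$reactions, function(r)
    r$id %in% kept_ids(rep1), logical(1))]
  rep3 <- filter_dataset(keep, fx$compounds, max_len = 3)
  expect_true(all(rep3$status == "kept"))
  # at a smaller max_len only category 6 may newly fire
  rep0 <- filter_dataset(keep, fx$compounds, max_len = 0)
  expect_true(all(is.na(rep0$category) | rep0$category == 6L))
})

test_that("glycan override exempts listed ids", {
  cmp <- data.frame(id = c("G1", "W"), smiles = c("OCC(O)C(O)O", "OCC(O)C(O)O"))
  r <- list(reaction("R", "G1 <=> W", ec = "5.3.1.1"))
  rep <- filter_dataset(r, cmp, 3)
  expect_equal(rep$category, 2L)
  rep2 <- filter_dataset(r, cmp, 3, glycan_override = "G1")
  # past the glycan gate it is caught as an identity reaction (zero RFP)
  expect_equal(rep2$category, 6L)
})

test_that("filter reports serialise with their configuration", {
  fx <- filter_fixture()
  rep <- filter_dataset(fx$reactions, fx$compounds, max_len = 3)
  tf <- tempfile()
  write_filter_report(rep, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^# max_len=3", lines)))
  expect_true(any(grepl("^Rrace\texcluded\t6", lines)))
})
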