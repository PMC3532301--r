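# Nearest-neighbour assignment, LOOCV, length sweep, distance binning.

# Tiny labelled corpus: two methylation-template and two hydrolysis-template
# reactions on different scaffolds, plus compound structures.
two_template_corpus <- function() {
  compounds <- data.frame(
    id = c("AM1", "AM1P", "AM2", "AM2P", "ES1", "ES1P", "ES2", "ES2P",
           "DMS", "MSH", "WAT", "MEOH"),
    smiles = c("CCCN", "CCCNC", "CCCCN", "CCCCNC",
               "CCCC(=O)OC", "CCCC(=O)O", "CCCCC(=O)OC", "CCCCC(=O)O",
               "CSC", "CS", "O", "CO"))
  reactions <- data.frame(
    id = c("M1", "M2", "H1", "H2"),
    equation = c("AM1 + DMS <=> AM1P + MSH",
                 "AM2 + DMS <=> AM2P + MSH",
                 "ES1 + WAT <=> ES1P + MEOH",
                 "ES2 + WAT <=> ES2P + MEOH"),
    ec = c("2.1.1.1", "2.1.1.2", "3.1.1.1", "3.1.1.3"))
  list(compounds = compounds, reactions = reactions)
}

test_that("a query identical to a training reaction gets its EC at distance 0", {
  cx <- two_template_corpus()
  fit <- rdf_knn(cx$reactions, cx$compounds, max_len = 3)
  a <- assign_ec("AM1 + DMS <=> AM1P + MSH", fit, cx$compounds)
  expect_equal(a$ec, "2.1.1")
  expect_equal(a$distance, 0)
  expect_true("M1" %in% a$supporting_ids)
})

test_that("the majority EC wins among training reactions tied at the minimum", {
  cmp <- data.frame(id = c("A", "B", "C", "D"),
                    smiles = c("CCCN", "CCCNC", "CSC", "CS"))
  eq <- "A + C <=> B + D"
  train <- data.frame(id = c("T1", "T2", "T3"),
                      equation = eq,
                      ec = c("2.1.1.1", "2.1.1.2", "3.1.1.1"))
  fit <- rdf_knn(train, cmp, max_len = 3)
  a <- assign_ec(eq, fit, cmp)
  expect_equal(a$ec, "2.1.1")          # 2 votes vs 1 at the same distance
  expect_setequal(a$supporting_ids, c("T1", "T2", "T3"))
  expect_false(a$tie_broken)
})

test_that("residual frequency ties break to the numerically smallest EC", {
  cmp <- data.frame(id = c("A", "B", "C", "D"),
                    smiles = c("CCCN", "CCCNC", "CSC", "CS"))
  eq <- "A + C <=> B + D"
  train <- data.frame(id = c("T1", "T2"), equation = eq,
                      ec = c("3.1.1.1", "2.1.1.1"))
  fit <- rdf_knn(train, cmp, max_len = 3)
  a <- assign_ec(eq, fit, cmp)
  expect_equal(a$ec, "2.1.1")
  expect_true(a$tie_broken)
  # numeric, not string, component order: 2.1.9 before 2.1.10
  train2 <- data.frame(id = c("T1", "T2"), equation = eq,
                       ec = c("2.1.10.1", "2.1.9.1"))
  fit2 <- rdf_knn(train2, cmp, max_len = 3)
  expect_equal(assign_ec(eq, fit2, cmp)$ec, "2.1.9")
})

test_that("assignment is invariant to training-set order and to distant additions", {
  set <- generate_reaction_set(n_per_template = 4, seed = 21)
  fit <- rdf_knn(set$reactions, set$compounds, max_len = 3)
  q <- set$reactions$equation[7]
  base <- assign_ec(q, fit, set$compounds)

  perm <- sample(nrow(set$reactions))
  fitp <- rdf_knn(set$reactions[perm, ], set$compounds, max_len = 3)
  ap <- assign_ec(q, fitp, set$compounds)
  expect_equal(ap$ec, base$ec)
  expect_equal(ap$distance, base$distance)
  expect_setequal(ap$supporting_ids, base$supporting_ids)

  # adding a training reaction at strictly larger distance changes nothing
  far <- data.frame(id = "FAR",
                    equation = "FA + FB <=> FC + FD", ec = "6.3.1.2")
  cmp2 <- rbind(set$compounds,
                data.frame(id = c("FA", "FB", "FC", "FD"),
                           smiles = c("OC(=O)CCC(N)C(O)=O", "N",
                                      "NC(=O)CCC(N)C(O)=O", "O")))
  fit2 <- rdf_knn(rbind(set$reactions[, c("id", "equation", "ec")], far),
                  cmp2, max_len = 3)
  a2 <- assign_ec(q, fit2, cmp2)
  expect_gt(assign_ec(far$equation, fit, cmp2)$distance, base$distance)
  expect_equal(a2$ec, base$ec)
  expect_setequal(a2$supporting_ids, base$supporting_ids)
})

test_that("assignment agrees with an independent brute-force scan", {
  set <- generate_reaction_set(n_per_template = 5, seed = 31)
  fit <- rdf_knn(set$reactions, set$compounds, max_len = 3)
  expect_lte(length(fit$ids), 50L)
  for (i in seq_along(fit$ids)) {
    a <- assign_ec(fit$rfps[[i]], fit)
    nv <- naive_assign(fit$rfps[[i]], fit$rfps, fit$ec)
    expect_equal(a$ec, nv$ec)
    expect_equal(a$distance, nv$dist)
  }
})

test_that("zero-fingerprint queries are refused and empty training is an error", {
  cx <- two_template_corpus()
  fit <- rdf_knn(cx$reactions, cx$compounds, max_len = 3)
  cmp <- rbind(cx$compounds,
               data.frame(id = c("L", "D"),
                          smiles = c("CC[C@@H](N)C(O)=O", "CC[C@H](N)C(O)=O")))
  expect_error(assign_ec("L <=> D", fit, cmp), "cannot be classified")
  expect_error(rdf_knn(data.frame(id = "R", equation = "L <=> D",
                                  ec = "5.1.1.1"),
                       cmp, max_len = 3),
               "no training reactions")
  expect_error(rdf_knn(data.frame(id = "R", equation = "L <=> D",
                                  ec = "5.1.1.1"),
                       cmp, max_len = 3, filter = FALSE),
               "filter_dataset")
})

test_that("training ECs deeper than the sub-subclass are truncated on ingest", {
  cx <- two_template_corpus()
  expect_message(fit <- rdf_knn(cx$reactions, cx$compounds, max_len = 3),
                 "truncated")
  expect_true(all(fit$ec %in% c("2.1.1", "3.1.1")))
})

test_that("LOOCV is perfect on well-separated templates and on duplicates", {
  cx <- two_template_corpus()
  fit <- rdf_knn(cx$reactions, cx$compounds, max_len = 3)
  cv <- loocv(fit)
  expect_equal(unname(cv$accuracy), c(1, 1, 1))
  expect_equal(sum(cv$by_class$n), 4L)

  # duplicated dataset (distinct ids, same RFP and EC) stays perfect
  dup <- rbind(cx$reactions,
               transform(cx$reactions, id = paste0(id, "dup")))
  cvd <- loocv(rdf_knn(dup, cx$compounds, max_len = 3))
  expect_equal(unname(cvd$accuracy), c(1, 1, 1))
  expect_true(all(cvd$predictions$distance == 0))
})

test_that("a constructed confusable corpus is misassigned as predicted", {
  # at max_len 2 an ester and an ether hydrolysis have identical difference
  # fingerprints {C-O-C:+1}; with 2 esters and 1 ether every reaction's
  # neighbours are all at distance 0 and the vote sends everything to 3.1.1,
  # so exactly the ether is wrong: sub-subclass accuracy 2/3
  cmp <- data.frame(
    id = c("E1", "E1P", "E2", "E2P", "T1", "T1P", "WAT", "MEOH"),
    smiles = c("CCCC(=O)OC", "CCCC(=O)O", "CCCCC(=O)OC", "CCCCC(=O)O",
               "CCCCOC", "CCCCO", "O", "CO"))
  rxn <- data.frame(
    id = c("RE1", "RE2", "RT1"),
    equation = c("E1 + WAT <=> E1P + MEOH", "E2 + WAT <=> E2P + MEOH",
                 "T1 + WAT <=> T1P + MEOH"),
    ec = c("3.1.1.1", "3.1.1.3", "3.3.1.1"))
  fit <- rdf_knn(rxn, cmp, max_len = 2)
  # construction check: all three difference fingerprints coincide
  expect_equal(fit$rfps[[1]]$entries, c("C-O-C" = 1L))
  expect_true(all(vapply(fit$rfps, function(f)
    identical(f$entries, fit$rfps[[1]]$entries), logical(1))))
  cv <- loocv(fit)
  expect_equal(cv$accuracy[["subsubclass"]], 2 / 3)
  expect_equal(cv$predictions$correct_subsubclass,
               c(TRUE, TRUE, FALSE))
  # at max_len 3 the ester's O=C-O-C fragment separates the templates: the
  # esters become each other's neighbours at distance 0, while the lone
  # ether (no same-class partner) still resolves to an ester
  cv3 <- loocv(rdf_knn(rxn, cmp, max_len = 3))
  expect_equal(cv3$predictions$correct_subsubclass, c(TRUE, TRUE, FALSE))
  expect_equal(cv3$predictions$distance[1:2], c(0, 0))
  expect_equal(cv3$predictions$distance[3], 1)
})

test_that("the length sweep reports one row per length and re-filters", {
  set <- generate_reaction_set(n_per_template = 3, seed = 13)
  sw <- length_sweep(set$reactions, set$compounds, c(0, 1, 2))
  expect_s3_class(sw, "rdf_sweep")
  expect_equal(sw$max_len, c(0L, 1L, 2L))
  expect_equal(nrow(sw), 3L)
  expect_true(all(sw$n_kept <= sw$n_input))
  # every balanced reaction is invisible at length 0
  expect_equal(sw$n_kept[1], 0L)
  expect_length(nrow(length_sweep(set$reactions, set$compounds, integer(0))),
                1L)
  expect_equal(nrow(length_sweep(set$reactions, set$compounds, integer(0))), 0L)
  expect_error(length_sweep(set$reactions, set$compounds, c(2, 9)), "0..6")
})

test_that("predict() vectorises assignments over query tables", {
  cx <- two_template_corpus()
  fit <- rdf_knn(cx$reactions, cx$compounds, max_len = 3)
  pred <- predict(fit, cx$reactions[, c("id", "equation")], cx$compounds)
  expect_equal(nrow(pred), 4L)
  expect_equal(pred$ec, c("2.1.1", "2.1.1", "3.1.1", "3.1.1"))
  expect_true(all(pred$distance == 0))
})

test_that("distance binning uses half-open bins with an open-ended last bin", {
  fake_cv <- structure(
    list(predictions = data.frame(distance = c(2, 15, 40),
                                  correct_subsubclass = c(TRUE, FALSE, TRUE))),
    class = "rdf_cv")
  b <- distance_binned_accuracy(fake_cv, edges = c(0, 10, 20, 50))
  expect_equal(b$n_correct + b$n_incorrect, c(1L, 1L, 1L))
  expect_equal(b$upper[3], Inf)
  # beyond-last-edge distances still land in the final bin (conservation)
  fake2 <- structure(
    list(predictions = data.frame(distance = c(0, 0, 120),
                                  correct_subsubclass = TRUE)),
    class = "rdf_cv")
  b2 <- distance_binned_accuracy(fake2, edges = c(0, 10))
  expect_equal(sum(b2$n_correct + b2$n_incorrect), 3L)
  expect_error(distance_binned_accuracy(fake_cv, edges = c(0, 0, 10)),
               "strictly increasing")
})
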