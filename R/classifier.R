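## Nearest-neighbour EC assignment over reaction difference fingerprints:
## model fitting, prediction, leave-one-out cross-validation, fingerprint
## length sweep and distance-binned accuracy reporting.
##
## Distances are compared on exact squared-integer values; only reported
## distances take the square root, so there is never a floating-point
## ambiguity about which training reactions attain the minimum.

#' Fit a nearest-neighbour EC assignment model
#'
#' Builds the training side of the classifier: every labelled reaction is
#' converted to its reaction difference fingerprint and stored together with
#' its EC label truncated to the sub-subclass (three components).  Queries
#' are classified with [predict.rdf_knn()] by Euclidean nearest neighbour;
#' among training reactions tied at the minimum distance the most frequent
#' three-level EC wins, residual frequency ties breaking to the smallest EC
#' in component-wise numeric order (deterministic, so training-set order
#' never matters).
#'
#' @param reactions labelled reactions: a list of [reaction()] objects or a
#'   data frame with columns `id`, `equation`, `ec`.
#' @param compounds compound collection resolvable by id (see
#'   [compound_graphs()]).
#' @param max_len maximum fragment length in bonds (0..6); the published
#'   configuration of this method selects 3.
#' @param filter apply [filter_dataset()] first and train on the kept set
#'   (default).  With `filter = FALSE` the reactions must already satisfy
#'   the filter invariants; a zero-fingerprint training reaction is an
#'   error directing to [filter_dataset()].
#' @inheritParams enumerate_linear_fragments
#' @param require_ec_level,glycan_prefix,glycan_override passed to
#'   [filter_dataset()].
#' @return An object of class `rdf_knn` with components `rfps` (list of
#'   fingerprints), `ec` (character vector of 3-level labels), `ids`,
#'   `max_len`, `dialect`, and `filter_report` (when filtering was applied).
#' @examples
#' \donttest{
#' set <- generate_reaction_set(n_per_template = 3, seed = 1)
#' fit <- rdf_knn(set$reactions, set$compounds, max_len = 3)
#' fit
#' }
#' @export
rdf_knn <- function(reactions, compounds, max_len = 3L,
                    count_mode = c("path", "traversal"), use_charge = FALSE,
                    filter = TRUE, require_ec_level = 3L,
                    glycan_prefix = "G", glycan_override = character()) {
  count_mode <- match.arg(count_mode)
  reactions <- .as_reaction_list(reactions)
  graphs <- compound_graphs(compounds)
  report <- NULL
  if (filter) {
    report <- filter_dataset(reactions, graphs, max_len, count_mode,
                             use_charge, require_ec_level,
                             glycan_prefix, glycan_override)
    keep <- report$status == "kept"
    reactions <- reactions[keep]
  }
  if (!length(reactions))
    stop("no training reactions remain after filtering", call. = FALSE)
  ids <- vapply(reactions, function(r) r$id %||% NA_character_, character(1))
  n_trunc <- 0L
  ec <- vapply(reactions, function(r) {
    if (is.null(r$ec))
      stop("training reaction ", r$id, " has no EC label; run filter_dataset()",
           call. = FALSE)
    if (length(r$ec) > 3L) n_trunc <<- n_trunc + 1L
    format(ec_truncate(r$ec, 3L))
  }, character(1))
  if (n_trunc > 0L)
    message(n_trunc, " training EC label(s) truncated to the sub-subclass")
  rfps <- lapply(reactions, reaction_difference_fingerprint,
                 compounds = graphs, max_len = max_len,
                 count_mode = count_mode, use_charge = use_charge)
  empty <- !vapply(rfps, function(f) length(f$entries) > 0L, logical(1))
  if (any(empty))
    stop("training reaction(s) with zero difference fingerprint: ",
         paste(ids[empty], collapse = ", "),
         "; run filter_dataset() first (category 6)", call. = FALSE)
  structure(list(rfps = rfps, ec = ec, ids = ids,
                 max_len = as.integer(max_len),
                 dialect = list(count_mode = count_mode,
                                use_charge = use_charge),
                 filter_report = report,
                 call = match.call()),
            class = "rdf_knn")
}

#' @export
print.rdf_knn <- function(x, ...) {
  cat("Nearest-neighbour EC assignment model (reaction difference fingerprints)\n")
  cat("  training reactions:", length(x$ids),
      " max_len:", x$max_len,
      " count_mode:", x$dialect$count_mode, "\n")
  main <- table(vapply(strsplit(x$ec, ".", fixed = TRUE), `[`, character(1), 1L))
  cat("  main classes: ",
      paste0("EC", names(main), ":", as.integer(main), collapse = "  "), "\n")
  if (!is.null(x$filter_report))
    cat("  (fitted on the kept set of a ", nrow(x$filter_report),
        "-reaction filter run)\n", sep = "")
  invisible(x)
}

#' @export
summary.rdf_knn <- function(object, ...) {
  print(object)
  cat("  distinct sub-subclasses:", length(unique(object$ec)), "\n")
  if (!is.null(object$filter_report)) print(object$filter_report)
  invisible(object)
}

## core nearest-neighbour vote; qsq = squared distances to all training rfps
.nn_vote <- function(sqd, ec) {
  msq <- min(sqd)
  support <- which(sqd == msq)
  tab <- table(ec[support])
  winners <- names(tab)[tab == max(tab)]
  tie_broken <- length(winners) > 1L
  if (tie_broken) {
    ## smallest EC in component-wise numeric (tuple lexicographic) order
    key <- vapply(strsplit(winners, ".", fixed = TRUE), function(p)
      paste(sprintf("%06d", as.integer(p)), collapse = "."), character(1))
    winners <- winners[order(key)][1L]
  }
  list(ec = winners[1L], sqdist = msq, support = support,
       tie_broken = tie_broken)
}

#' Assign an EC number to a query reaction
#'
#' Computes the query's reaction difference fingerprint, finds the training
#' reactions at minimum Euclidean distance and votes among their three-level
#' EC labels (see [rdf_knn()] for the tie-break rules).  A query whose
#' difference fingerprint is zero cannot be classified -- such reactions are
#' excluded from training data for the same reason -- and is a refusal
#' error.
#'
#' @param query a [reaction()] object, equation string, or an
#'   `rdf_fingerprint` of type `"rfp"`.
#' @param model an [rdf_knn()] model.
#' @param compounds compound collection needed when `query` is not already a
#'   fingerprint.
#' @return An object of class `rdf_assignment`: list with `ec` (3-level
#'   label string), `distance`, `supporting_ids` (training reactions at the
#'   minimum) and `tie_broken`.
#' @examples
#' \donttest{
#' set <- generate_reaction_set(n_per_template = 3, seed = 1)
#' fit <- rdf_knn(set$reactions, set$compounds)
#' assign_ec(set$reactions$equation[1], fit, set$compounds)
#' }
#' @export
assign_ec <- function(query, model, compounds = NULL) {
  stopifnot(inherits(model, "rdf_knn"))
  if (!length(model$ids)) stop("empty training set", call. = FALSE)
  qr <- if (inherits(query, "rdf_fingerprint")) {
    if (query$type != "rfp")
      stop("query fingerprint must be a reaction difference fingerprint",
           call. = FALSE)
    query
  } else {
    if (is.null(compounds))
      stop("compounds needed to fingerprint the query reaction", call. = FALSE)
    reaction_difference_fingerprint(as_reaction(query), compounds,
                                    model$max_len,
                                    model$dialect$count_mode,
                                    model$dialect$use_charge)
  }
  if (!length(qr$entries))
    stop("query reaction has a zero difference fingerprint at max_len ",
         model$max_len, "; it cannot be classified (the transformation is ",
         "invisible to linear fragments)", call. = FALSE)
  sqd <- vapply(model$rfps, squared_distance, numeric(1), b = qr)
  v <- .nn_vote(sqd, model$ec)
  structure(list(ec = v$ec, distance = sqrt(v$sqdist),
                 squared_distance = v$sqdist,
                 supporting_ids = model$ids[v$support],
                 tie_broken = v$tie_broken),
            class = "rdf_assignment")
}

#' @export
print.rdf_assignment <- function(x, ...) {
  cat("EC ", x$ec, "  (distance ", format(x$distance), ", ",
      length(x$supporting_ids), " supporting training reaction",
      if (length(x$supporting_ids) > 1L) "s", ": ",
      paste(utils::head(x$supporting_ids, 5L), collapse = ", "),
      if (length(x$supporting_ids) > 5L) ", ...",
      if (x$tie_broken) "; frequency tie broken", ")\n", sep = "")
  invisible(x)
}

#' Predict EC numbers for a set of query reactions
#'
#' @param object an [rdf_knn()] model.
#' @param newdata query reactions (list of [reaction()] objects or a data
#'   frame with `id`, `equation` columns).
#' @param compounds compound collection covering the query compounds.
#' @param ... unused.
#' @return Data frame with one row per query: `id`, `ec`, `distance`,
#'   `n_support`, `supporting_ids` (comma-separated), `tie_broken`.
#' @export
predict.rdf_knn <- function(object, newdata, compounds, ...) {
  newdata <- .as_reaction_list(newdata)
  graphs <- compound_graphs(compounds)
  rows <- lapply(newdata, function(r) {
    a <- assign_ec(r, object, graphs)
    data.frame(id = r$id %||% NA_character_, ec = a$ec,
               distance = a$distance, n_support = length(a$supporting_ids),
               supporting_ids = paste(a$supporting_ids, collapse = ","),
               tie_broken = a$tie_broken)
  })
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Leave-one-out cross-validation

#' Leave-one-out cross-validation of an EC assignment model
#'
#' Each training reaction is classified against all remaining ones;
#' accuracy at level L is the fraction of reactions whose predicted
#' three-level EC, truncated to L, equals the truncation of the true label.
#'
#' @param model an [rdf_knn()] model with at least two training reactions.
#' @return An object of class `rdf_cv`: list with `predictions` (data frame
#'   with per-reaction predicted EC, minimum distance and per-level
#'   correctness), `accuracy` (named vector: main, subclass, subsubclass)
#'   and `by_class` (per-main-class counts and sub-subclass accuracies).
#' @examples
#' \donttest{
#' set <- generate_reaction_set(n_per_template = 3, seed = 1)
#' cv <- loocv(rdf_knn(set$reactions, set$compounds))
#' cv$accuracy
#' }
#' @export
loocv <- function(model) {
  stopifnot(inherits(model, "rdf_knn"))
  n <- length(model$ids)
  if (n < 2L)
    stop("leave-one-out cross-validation needs at least 2 reactions",
         call. = FALSE)
  ## pairwise squared distances (symmetric, exact integers)
  sq <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sq[i, j] <- sq[j, i] <- squared_distance(model$rfps[[i]],
                                               model$rfps[[j]])
    }
  }
  pred <- character(n); dist <- numeric(n); ties <- logical(n)
  for (i in seq_len(n)) {
    v <- .nn_vote(sq[i, -i], model$ec[-i])
    pred[i] <- v$ec
    dist[i] <- sqrt(v$sqdist)
    ties[i] <- v$tie_broken
  }
  truth <- model$ec
  lvl <- function(e, L) vapply(strsplit(e, ".", fixed = TRUE), function(p)
    paste(p[seq_len(L)], collapse = "."), character(1))
  correct <- sapply(1:3, function(L) lvl(pred, L) == lvl(truth, L))
  predictions <- data.frame(id = model$ids, ec_true = truth, ec_pred = pred,
                            distance = dist, tie_broken = ties,
                            correct_main = correct[, 1L],
                            correct_subclass = correct[, 2L],
                            correct_subsubclass = correct[, 3L])
  accuracy <- c(main = mean(correct[, 1L]),
                subclass = mean(correct[, 2L]),
                subsubclass = mean(correct[, 3L]))
  main_class <- lvl(truth, 1L)
  by_class <- do.call(rbind, lapply(sort(unique(main_class)), function(m) {
    sel <- main_class == m
    data.frame(main_class = paste0("EC", m), n = sum(sel),
               accuracy_subsubclass = mean(correct[sel, 3L]))
  }))
  structure(list(predictions = predictions, accuracy = accuracy,
                 by_class = by_class, max_len = model$max_len,
                 dialect = model$dialect, n = n),
            class = "rdf_cv")
}

#' @export
print.rdf_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation (", x$n, " reactions, max_len=",
      x$max_len, ")\n", sep = "")
  cat(sprintf("  accuracy: main %.3f  subclass %.3f  sub-subclass %.3f\n",
              x$accuracy[["main"]], x$accuracy[["subclass"]],
              x$accuracy[["subsubclass"]]))
  invisible(x)
}

#' @export
summary.rdf_cv <- function(object, ...) {
  print(object)
  cat("  per main class (sub-subclass accuracy):\n")
  for (i in seq_len(nrow(object$by_class)))
    cat(sprintf("    %s: n=%d acc=%.3f\n", object$by_class$main_class[i],
                object$by_class$n[i], object$by_class$accuracy_subsubclass[i]))
  invisible(object)
}

#' @export
plot.rdf_cv <- function(x, edges = c(0, 10, 20, 50), ...) {
  b <- distance_binned_accuracy(x, edges)
  m <- rbind(correct = b$n_correct, incorrect = b$n_incorrect)
  graphics::barplot(m, names.arg = b$bin, legend.text = rownames(m),
                    xlab = "distance to closest training reaction",
                    ylab = "predictions", ...)
  invisible(b)
}

## ---------------------------------------------------------------------------
## Fingerprint length sweep

#' Cross-validation sweep over fingerprint lengths
#'
#' Re-runs the dataset filter (category 6 depends on the length) and
#' leave-one-out cross-validation at each fragment length.  Alongside the
#' kept-set accuracies the table reports `n_kept` and a coverage-adjusted
#' sub-subclass accuracy (`acc_overall`): correct predictions divided by the
#' total number of input reactions, counting reactions unassignable at that
#' length (zero fingerprints) as failures.
#'
#' @param reactions,compounds as in [rdf_knn()].
#' @param lengths integer vector of fragment lengths, each in 0..6.
#' @inheritParams rdf_knn
#' @return A data frame of class `rdf_sweep` with one row per length:
#'   `max_len`, `n_input`, `n_kept`, `acc_main`, `acc_subclass`,
#'   `acc_subsubclass`, `acc_overall`.
#' @export
length_sweep <- function(reactions, compounds, lengths = 0:6,
                         count_mode = c("path", "traversal"),
                         use_charge = FALSE, ...) {
  count_mode <- match.arg(count_mode)
  if (length(lengths) &&
      (!is.numeric(lengths) || any(is.na(lengths)) ||
       any(lengths != as.integer(lengths)) || any(lengths < 0 | lengths > 6)))
    stop("lengths must be integers in 0..6", call. = FALSE)
  reactions <- .as_reaction_list(reactions)
  graphs <- compound_graphs(compounds)
  rows <- lapply(as.integer(lengths), function(L) {
    fit <- tryCatch(rdf_knn(reactions, graphs, max_len = L,
                            count_mode = count_mode, use_charge = use_charge,
                            filter = TRUE, ...),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ids) < 2L) {
      return(data.frame(max_len = L, n_input = length(reactions),
                        n_kept = if (is.null(fit)) 0L else length(fit$ids),
                        acc_main = NA_real_, acc_subclass = NA_real_,
                        acc_subsubclass = NA_real_, acc_overall = 0))
    }
    cv <- loocv(fit)
    data.frame(max_len = L, n_input = length(reactions),
               n_kept = cv$n,
               acc_main = cv$accuracy[["main"]],
               acc_subclass = cv$accuracy[["subclass"]],
               acc_subsubclass = cv$accuracy[["subsubclass"]],
               acc_overall = sum(cv$predictions$correct_subsubclass) /
                 length(reactions))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(max_len = integer(), n_input = integer(),
                      n_kept = integer(), acc_main = numeric(),
                      acc_subclass = numeric(), acc_subsubclass = numeric(),
                      acc_overall = numeric())
  class(out) <- c("rdf_sweep", "data.frame")
  out
}

#' @export
plot.rdf_sweep <- function(x, ...) {
  graphics::matplot(x$max_len, cbind(x$acc_main, x$acc_subclass,
                                     x$acc_subsubclass),
                    type = "b", pch = 1:3, lty = 1,
                    xlab = "fingerprint length (bonds)", ylab = "accuracy",
                    ...)
  graphics::legend("bottomright", c("main", "subclass", "sub-subclass"),
                   pch = 1:3, lty = 1, col = 1:3)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Distance-binned accuracy

#' Bin cross-validated predictions by nearest-neighbour distance
#'
#' Predictions are assigned to half-open bins `[e_i, e_{i+1})` of their
#' minimum distance; the final bin is closed above at `+Inf`.  The default
#' edges emphasise the distance regions below 20 and below 50, where
#' nearest-neighbour assignments are most trustworthy.
#'
#' @param cv an [loocv()] result.
#' @param edges strictly increasing numeric bin edges (at least two).
#' @return Data frame with `bin`, `lower`, `upper`, `n_correct`
#'   (sub-subclass), `n_incorrect`.
#' @export
distance_binned_accuracy <- function(cv, edges = c(0, 10, 20, 50)) {
  stopifnot(inherits(cv, "rdf_cv"))
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing (>= 2 edges)", call. = FALSE)
  d <- cv$predictions$distance
  ok <- cv$predictions$correct_subsubclass
  k <- length(edges) - 1L
  lower <- edges[-length(edges)]
  upper <- edges[-1L]
  upper[k] <- Inf  # final bin closed above at +Inf
  idx <- findInterval(d, lower)  # 0 = below the first edge (not counted)
  data.frame(bin = sprintf("[%g,%g)", lower, upper),
             lower = lower, upper = upper,
             n_correct = vapply(seq_len(k), function(b)
               sum(ok[which(idx == b)]), integer(1)),
             n_incorrect = vapply(seq_len(k), function(b)
               sum(!ok[which(idx == b)]), integer(1)))
}
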