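#' Train the three-class decision-tree stress model
#'
#' Fits a CART classifier mapping the 34 HRV features to stress states
#' 0 (none), 1 (moderate), 2 (severe) under the reference hyperparameters
#' (max depth 10, min samples to split 10, min samples per leaf 5, Gini
#' impurity). Splits are found with \pkg{rpart} (no surrogate or competitor
#' splits), then extracted into a plain node table so the fitted model is
#' self-describing: prediction is a deterministic root-to-leaf descent over
#' that table, and the model serializes to JSON without loss.
#'
#' @param table Labeled feature table (34 canonical columns + `label` in
#'   {0, 1, 2}).
#' @param hp A [tree_hyperparams()] object.
#' @return An object of class `stress_model`: `nodes` (data frame with node
#'   id, split variable, threshold, leaf class and class counts),
#'   `feature_order`, `hyperparams`, and training metadata (class counts,
#'   training accuracy).
#' @export
train_stress_model <- function(table, hp = tree_hyperparams()) {
  validate_feature_table(table)
  if (!"label" %in% names(table)) {
    stop("training requires a labeled feature table", call. = FALSE)
  }
  feats <- table[, hrv_feature_names(), drop = FALSE]
  bad <- which(!stats::complete.cases(feats) |
                 apply(feats, 1L, function(r) any(!is.finite(r))))
  if (length(bad)) {
    stop(sprintf("non-finite feature value(s) in row(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  if (nrow(table) < hp$min_samples_split) {
    warning("fewer rows than min_samples_split: fitting a single-leaf model",
            call. = FALSE)
  }
  if (length(unique(table$label)) < 3L) {
    warning("not all three stress classes present in training data",
            call. = FALSE)
  }
  df <- feats
  df$.label <- factor(table$label, levels = c(0L, 1L, 2L))
  set.seed(hp$seed)
  fit <- rpart::rpart(
    .label ~ ., data = df, method = "class",
    parms = list(split = hp$split_criterion),
    control = rpart::rpart.control(
      maxdepth = hp$max_depth, minsplit = hp$min_samples_split,
      minbucket = hp$min_samples_leaf, cp = 0, xval = 0,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  nodes <- extract_tree_nodes(fit)
  model <- structure(list(nodes = nodes,
                          feature_order = hrv_feature_names(),
                          hyperparams = hp,
                          metadata = list(
                            n_train = nrow(table),
                            class_counts = as.integer(table(df$.label)))),
                     class = "stress_model")
  preds <- predict_stress(model, table)
  model$metadata$train_accuracy <- mean(preds == table$label)
  model
}

# flatten an rpart fit (no surrogates/competitors) into a node table;
# children of node id k are 2k and 2k+1
extract_tree_nodes <- function(fit) {
  fr <- fit$frame
  ids <- as.integer(rownames(fr))
  is_leaf <- fr$var == "<leaf>"
  thr <- rep(NA_real_, nrow(fr))
  dir <- rep(NA_integer_, nrow(fr))
  if (any(!is_leaf)) {
    sp <- fit$splits
    thr[!is_leaf] <- sp[, "index"]
    dir[!is_leaf] <- as.integer(sign(sp[, "ncat"]))  # -1: left if x < thr
  }
  counts <- fr$yval2[, 2:4, drop = FALSE]
  data.frame(node = ids,
             var = ifelse(is_leaf, NA_character_, as.character(fr$var)),
             threshold = thr,
             dir = dir,
             is_leaf = is_leaf,
             class = as.integer(fr$yval) - 1L,
             n = fr$n,
             n0 = counts[, 1L], n1 = counts[, 2L], n2 = counts[, 3L],
             stringsAsFactors = FALSE)
}

#' @export
print.stress_model <- function(x, ...) {
  n_leaves <- sum(x$nodes$is_leaf)
  depth <- max(floor(log2(x$nodes$node)))
  cat(sprintf("<stress_model> CART: %d nodes (%d leaves), depth %d; trained on %d rows",
              nrow(x$nodes), n_leaves, depth, x$metadata$n_train))
  if (!is.null(x$metadata$train_accuracy)) {
    cat(sprintf(" (train accuracy %.3f)", x$metadata$train_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' Predict stress states for HRV feature vectors
#'
#' Deterministic root-to-leaf descent over the model's node table. At each
#' internal node the split variable is compared with the threshold (`< thr`
#' goes left when the split direction is -1, `>= thr` when +1, as recorded at
#' training time). Leaf class ties were broken toward the lower class index
#' at training time.
#'
#' @param model A `stress_model`.
#' @param x A feature table (data frame) or a single named 34-element vector.
#' @return Integer vector of predicted labels in {0, 1, 2}.
#' @export
predict_stress <- function(model, x) {
  stopifnot(inherits(model, "stress_model"))
  if (!is.data.frame(x)) {
    x <- as.data.frame(as.list(unclass(x)))
  }
  validate_feature_table(x)
  feats <- x[, model$feature_order, drop = FALSE]
  if (any(!is.finite(as.matrix(feats)))) {
    bad <- which(!apply(is.finite(as.matrix(feats)), 1L, all))
    stop(sprintf("non-finite feature value(s) in row(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  nodes <- model$nodes
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$node)
  vapply(seq_len(nrow(feats)), function(i) {
    id <- 1L
    repeat {
      row <- nodes[idx[[as.character(id)]], ]
      if (row$is_leaf) return(row$class)
      v <- feats[[row$var]][i]
      goes_left <- if (row$dir < 0) v < row$threshold else v >= row$threshold
      id <- if (goes_left) 2L * id else 2L * id + 1L
    }
  }, integer(1))
}

#' Evaluate a stress model on a labeled test table
#'
#' @param model A `stress_model`.
#' @param test Labeled feature table.
#' @return An `eval_report`: `accuracy`, per-class `precision`, `recall`,
#'   `f1` (classes with zero support or zero predictions report 0 and are
#'   listed in `flags`), and the 3x3 `confusion` matrix (rows = truth,
#'   columns = prediction).
#' @export
evaluate_stress_model <- function(model, test) {
  validate_feature_table(test)
  if (!nrow(test)) stop("test table is empty", call. = FALSE)
  if (!"label" %in% names(test)) stop("test table must be labeled", call. = FALSE)
  pred <- predict_stress(model, test)
  truth <- as.integer(test$label)
  cm <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  cm <- matrix(as.integer(cm), 3L, 3L,
               dimnames = list(truth = 0:2, pred = 0:2))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  flags <- character(0)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  if (any(predicted == 0)) flags <- c(flags, "zero_predictions_for_some_class")
  if (any(support == 0)) flags <- c(flags, "zero_support_for_some_class")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(accuracy = sum(tp) / sum(cm),
                 precision = stats::setNames(precision, 0:2),
                 recall = stats::setNames(recall, 0:2),
                 f1 = stats::setNames(f1, 0:2),
                 confusion = cm, flags = flags),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f\n", x$accuracy))
  m <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(m, 4))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Stratified train/test split of a labeled feature table
#'
#' Rows are partitioned per class, so class proportions are preserved;
#' reproducible for a given seed.
#'
#' @param table Labeled feature table.
#' @param test_fraction Fraction of each class assigned to the test set,
#'   in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with disjoint `train` and `test` data frames.
#' @export
split_train_test <- function(table, test_fraction = 0.3, seed = 1L) {
  validate_feature_table(table)
  if (!"label" %in% names(table)) stop("table must be labeled", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  tab <- table(table$label)
  if (any(tab < 2L)) {
    stop("every class needs >= 2 rows to stratify", call. = FALSE)
  }
  set.seed(seed)
  test_idx <- unlist(lapply(sort(unique(table$label)), function(cl) {
    rows <- which(table$label == cl)
    sample(rows, round(length(rows) * test_fraction))
  }))
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

#' Save / load a stress model as a JSON archive
#'
#' The archive is self-describing: node table, canonical feature order,
#' hyperparameters, training metadata and a format version, so feature-order
#' mismatches at predict time are impossible.
#'
#' @param model A `stress_model`.
#' @param path File path.
#' @return `save_stress_model`: `path` invisibly; `load_stress_model`: the
#'   reconstructed `stress_model`.
#' @export
save_stress_model <- function(model, path) {
  stopifnot(inherits(model, "stress_model"))
  obj <- list(format = "hrvstress-model", version = 1L,
              feature_order = model$feature_order,
              hyperparams = unclass(model$hyperparams),
              metadata = model$metadata,
              nodes = model$nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_stress_model
#' @export
load_stress_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "hrvstress-model") {
    stop("not a stress-model archive", call. = FALSE)
  }
  if (!identical(as.character(obj$feature_order), hrv_feature_names())) {
    stop("model feature order does not match the canonical 34 features",
         call. = FALSE)
  }
  nodes <- as.data.frame(obj$nodes)
  nodes$var <- as.character(nodes$var)
  structure(list(nodes = nodes,
                 feature_order = as.character(obj$feature_order),
                 hyperparams = do.call(tree_hyperparams, obj$hyperparams),
                 metadata = obj$metadata),
            class = "stress_model")
}
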