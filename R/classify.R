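#' Render one nucleus and measure its features
#'
#' Convenience generator used to build labelled training material: draws a
#' nucleus specification for the class, renders it at its sharpest
#' available optical plane, segments the patch and computes the 18-feature
#' vector plus IOD from the measured optical densities (falling back to the
#' truth mask if the patch segmentation finds nothing).
#'
#' @param class_label diagnostic class.
#' @param config see [karyo_config()].
#' @param measurement_cv percent IOD rendering noise.
#' @return One-row data.frame: class + 18 features.
#' @export
simulate_nucleus_example <- function(class_label, config = karyo_config(),
                                     measurement_cv = 3) {
  sp <- sample_nucleus_spec(class_label)
  bp <- min(max(sp$z_position, 0L), 6L) # sharpest plane the scanner can reach
  rn <- render_nucleus(sp, config = config, measurement_cv = measurement_cv,
                       planes = bp)
  od <- to_optical_density(rn$stack[, , 1], config$background_level)
  thr <- max(otsu_threshold(as.numeric(od)), config$od_floor)
  bw <- EBImage::fillHull(EBImage::opening(od > thr,
                                           EBImage::makeBrush(3, "disc")))
  lab <- matrix(as.integer(EBImage::bwlabel(bw)), nrow(od))
  mask <- if (max(lab) > 0) {
    biggest <- which.max(tabulate(lab[lab > 0]))
    lab == biggest
  } else rn$mask
  if (sum(mask) < 3) mask <- rn$mask
  fv <- compute_features(mask, od, config)
  cbind(data.frame(class = class_label, stringsAsFactors = FALSE),
        as.data.frame(t(fv)))
}

#' Generate a labelled synthetic training set
#'
#' @param n_per_class objects rendered per class.
#' @param classes label schema (default the eight-class oral schema).
#' @param seed RNG seed.
#' @param config see [karyo_config()].
#' @param measurement_cv percent IOD rendering noise.
#' @return data.frame: class (factor) + 18 feature columns.
#' @export
simulate_training_set <- function(n_per_class = 2000,
                                  classes = oral_classes(), seed = 0,
                                  config = karyo_config(),
                                  measurement_cv = 3) {
  set.seed(seed)
  rows <- vector("list", n_per_class * length(classes))
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      rows[[k]] <- simulate_nucleus_example(cl, config, measurement_cv)
    }
  }
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = classes)
  out
}

#' Train the random-forest nuclear classifier
#'
#' Stratified 70/30 split, 500 trees, sqrt(p) candidate features per split,
#' probability forest (class confidences). The held-out confusion matrix
#' and per-class accuracies are attached; training is deterministic for a
#' fixed seed.
#'
#' @param records data.frame with a `class` column and the 18 feature
#'   columns of [feature_names()].
#' @param num_trees,holdout_fraction,seed forest hyperparameters.
#' @return `karyo_classifier` list: `forest`, `classes`, `features`,
#'   `confusion` (held-out, rows = truth), `per_class_accuracy`,
#'   `overall_accuracy`, `metadata`.
#' @export
train_classifier <- function(records, num_trees = 500,
                             holdout_fraction = 0.3, seed = 0) {
  feats <- feature_names()
  missing <- setdiff(feats, names(records))
  if (length(missing))
    stop("missing features: ", paste(missing, collapse = ", "))
  records$class <- droplevels(factor(records$class))
  tab <- table(records$class)
  if (length(tab) < 2) stop("need at least 2 classes to train")
  small <- names(tab)[tab < 20]
  if (length(small))
    stop("fewer than 20 records for class: ", paste(small, collapse = ", "))
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_len(nrow(records)), records$class),
                            function(ix) sample(ix, round(length(ix) * holdout_fraction))))
  train <- records[-test_idx, c("class", feats)]
  test <- records[test_idx, c("class", feats)]
  forest <- ranger::ranger(class ~ ., data = train, num.trees = num_trees,
                           mtry = floor(sqrt(length(feats))),
                           probability = TRUE, seed = seed, num.threads = 1)
  prob <- predict(forest, test, num.threads = 1)$predictions
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = levels(records$class))
  confusion <- table(truth = test$class, predicted = pred)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(
    forest = forest, classes = levels(records$class), features = feats,
    confusion = confusion, per_class_accuracy = per_class,
    overall_accuracy = sum(diag(confusion)) / sum(confusion),
    metadata = list(n_per_class = as.list(tab), seed = seed, round = 0L,
                    num_trees = num_trees)
  ), class = "karyo_classifier")
}

#' @export
print.karyo_classifier <- function(x, ...) {
  cat("karyoscan random-forest nuclear classifier\n")
  cat(" classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf(" held-out overall accuracy: %.1f%% (round %d)\n",
              100 * x$overall_accuracy, x$metadata$round))
  print(round(100 * x$per_class_accuracy, 1))
  invisible(x)
}

#' Classify nucleus records
#'
#' @param model a `karyo_classifier`.
#' @param records data.frame containing the model's feature columns.
#' @return `records` with `predicted_class` and `class_confidence` added.
#' @export
classify_nuclei <- function(model, records) {
  missing <- setdiff(model$features, names(records))
  if (length(missing))
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  prob <- predict(model$forest, records[, model$features, drop = FALSE],
                  num.threads = 1)$predictions
  records$predicted_class <- colnames(prob)[max.col(prob, ties.method = "first")]
  records$class_confidence <- apply(prob, 1, max)
  records
}

#' Apply gallery corrections to classified records
#'
#' Emulates the interactive image-gallery review: a corrections table
#' (object_id, new_class, optionally operator/timestamp) overrides the
#' automatic class downstream. When the same object is corrected more than
#' once, the last correction wins; every applied correction is logged.
#'
#' @param records data.frame with `object_id` and `predicted_class`.
#' @param corrections data.frame with `object_id`, `new_class`, or a path
#'   to such a CSV file.
#' @return `records` with a `corrected_class` column (NA where
#'   uncorrected) and an `effective_class` column; the correction log is
#'   attached as attribute `correction_log`.
#' @export
apply_corrections <- function(records, corrections) {
  if (is.character(corrections) && length(corrections) == 1)
    corrections <- read.csv(corrections, stringsAsFactors = FALSE)
  if (!"corrected_class" %in% names(records))
    records$corrected_class <- NA_character_
  log <- data.frame(object_id = character(), from = character(),
                    to = character(), stringsAsFactors = FALSE)
  if (nrow(corrections)) {
    unknown <- setdiff(corrections$object_id, records$object_id)
    if (length(unknown))
      stop("corrections reference unknown object_id: ",
           paste(head(unknown, 5), collapse = ", "))
    for (i in seq_len(nrow(corrections))) {
      j <- match(corrections$object_id[i], records$object_id)
      log <- rbind(log, data.frame(
        object_id = corrections$object_id[i],
        from = records$corrected_class[j] %|na|% records$predicted_class[j],
        to = corrections$new_class[i], stringsAsFactors = FALSE))
      records$corrected_class[j] <- corrections$new_class[i] # last wins
    }
  }
  records$effective_class <- ifelse(is.na(records$corrected_class),
                                    records$predicted_class,
                                    records$corrected_class)
  attr(records, "correction_log") <- log
  records
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Uncorrected and corrected class counts
#'
#' @param records output of [apply_corrections()] (or any data.frame with
#'   `predicted_class` and optionally `corrected_class`).
#' @return data.frame: class, n_uncorrected, n_corrected.
#' @export
class_counts <- function(records) {
  eff <- if ("effective_class" %in% names(records)) records$effective_class
  else records$predicted_class
  classes <- sort(unique(c(records$predicted_class, eff)))
  data.frame(
    class = classes,
    n_uncorrected = as.integer(table(factor(records$predicted_class,
                                            levels = classes))),
    n_corrected = as.integer(table(factor(eff, levels = classes))),
    stringsAsFactors = FALSE
  )
}

#' Retrain the classifier with gallery corrections
#'
#' Each round enriches the previous training set with the corrected
#' records (at their corrected labels) and refits the forest; per-round
#' held-out accuracy is logged. With `rounds = 0` the model is returned
#' unchanged.
#'
#' @param model a `karyo_classifier`.
#' @param training_records the labelled training set the model was built
#'   from (class + features).
#' @param corrected_records records carrying `corrected_class` (from
#'   [apply_corrections()]) and the feature columns.
#' @param rounds number of retraining rounds.
#' @param seed RNG seed (round index is folded in).
#' @return List: `model` (final), `history` (one `karyo_classifier` per
#'   round), `accuracy_log` (data.frame round/overall_accuracy).
#' @export
retrain_with_corrections <- function(model, training_records,
                                     corrected_records, rounds = 1,
                                     seed = 0) {
  if (rounds == 0)
    return(list(model = model, history = list(),
                accuracy_log = data.frame(round = integer(),
                                          overall_accuracy = numeric())))
  corr <- corrected_records[!is.na(corrected_records$corrected_class), ]
  if (!nrow(corr)) stop("no corrections available for retraining")
  add <- corr[, c("corrected_class", model$features)]
  names(add)[1] <- "class"
  history <- vector("list", rounds)
  log <- data.frame(round = seq_len(rounds), overall_accuracy = NA_real_)
  current <- training_records[, c("class", model$features)]
  for (r in seq_len(rounds)) {
    current <- rbind(current, add)
    m <- train_classifier(current, num_trees = model$metadata$num_trees,
                          seed = seed + r)
    m$metadata$round <- r
    history[[r]] <- m
    log$overall_accuracy[r] <- m$overall_accuracy
  }
  list(model = history[[rounds]], history = history, accuracy_log = log)
}
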