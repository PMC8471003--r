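#' CNN configuration
#'
#' Hyper-parameters of the 1D convolutional classifier. The defaults are
#' the study protocol: three convolution blocks with 8, 10 and 12 filters
#' (kernel 5, stride 1, no padding), each followed by ReLU and
#' non-overlapping max pooling of size 2; a single affine projection to
#' class scores with softmax (multiclass) or sigmoid (binary) output;
#' full-batch ADAM at learning rate 1e-4 and cross-entropy loss; training
#' stops when the training loss has not decreased for 400 epochs or after
#' 1000 epochs; 30% of the training samples are split off (stratified by
#' class) to monitor validation loss; 10 replicate networks are trained.
#'
#' @param input_length Feature length: 3587 for single spectra or 7174 for
#'   two-fiber combined spectra on the full grid (shorter grids scale
#'   accordingly).
#' @param head `"auto"` (sigmoid for 2-class designs, softmax otherwise),
#'   `"multiclass"`, or `"binary"`.
#' @param conv_filters Filters of the three convolution layers.
#' @param kernel_size,conv_stride,pool_size Convolution/pooling geometry.
#' @param learning_rate ADAM learning rate.
#' @param max_epochs,patience_epochs Stopping rule on the training loss.
#' @param validation_fraction Fraction of training samples for validation
#'   monitoring.
#' @param n_replicates Number of replicate networks per assessment.
#' @return An object of class `lss_cnn_config`.
#' @export
cnn_config <- function(input_length = 3587L,
                       head = c("auto", "multiclass", "binary"),
                       conv_filters = c(8L, 10L, 12L),
                       kernel_size = 5L, conv_stride = 1L, pool_size = 2L,
                       learning_rate = 1e-4, max_epochs = 1000L,
                       patience_epochs = 400L, validation_fraction = 0.30,
                       n_replicates = 10L) {
  head <- match.arg(head)
  stopifnot(learning_rate > 0, max_epochs >= 1, patience_epochs >= 1,
            validation_fraction > 0, validation_fraction < 1,
            n_replicates >= 1, length(conv_filters) == 3,
            conv_stride == 1L, pool_size == 2L)
  cfg <- structure(
    list(input_length = as.integer(input_length), head = head,
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         conv_stride = as.integer(conv_stride),
         pool_size = as.integer(pool_size),
         learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs),
         patience_epochs = as.integer(patience_epochs),
         validation_fraction = validation_fraction,
         n_replicates = as.integer(n_replicates)),
    class = "lss_cnn_config"
  )
  cnn_layer_dims(cfg)  # validates that three poolings are feasible
  cfg
}

# positions surviving each conv (valid) and pool (floor) stage
cnn_layer_dims <- function(config) {
  L <- config$input_length
  dims <- list()
  for (i in 1:3) {
    conv_out <- L - config$kernel_size + 1L
    if (conv_out < config$pool_size) {
      stop(sprintf(
        "input_length %d too short for three conv/pool blocks (block %d)",
        config$input_length, i), call. = FALSE)
    }
    pool_out <- conv_out %/% config$pool_size
    dims[[i]] <- c(conv = conv_out, pool = pool_out)
    L <- pool_out
  }
  dims$flatten <- L * config$conv_filters[3]
  dims
}

glorot_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build an untrained CNN
#'
#' Instantiates the network weights (Glorot-uniform, drawn from the
#' caller's RNG state; seed before calling for reproducibility) for a
#' given configuration and class count.
#'
#' @param config A [cnn_config()].
#' @param n_classes Number of classes (>= 2).
#' @return An object of class `lss_cnn` with untrained weights.
#' @export
build_model <- function(config, n_classes) {
  stopifnot(inherits(config, "lss_cnn_config"), n_classes >= 2)
  dims <- cnn_layer_dims(config)
  K <- config$kernel_size
  f <- config$conv_filters
  binary <- config$head == "binary" ||
    (config$head == "auto" && n_classes == 2)
  n_out <- if (binary) 1L else as.integer(n_classes)
  weights <- list(
    W1 = glorot_uniform(K, f[1]), b1 = rep(0, f[1]),
    W2 = glorot_uniform(K * f[1], f[2]), b2 = rep(0, f[2]),
    W3 = glorot_uniform(K * f[2], f[3]), b3 = rep(0, f[3]),
    Wd = glorot_uniform(dims$flatten, n_out), bd = rep(0, n_out)
  )
  structure(
    list(config = config, n_classes = as.integer(n_classes),
         binary = binary, weights = weights, dims = dims,
         classes = NULL, trained = FALSE, history = NULL, epochs = 0L),
    class = "lss_cnn"
  )
}

#' @export
print.lss_cnn <- function(x, ...) {
  cat(sprintf(
    "<lss_cnn> input %d | conv %s (kernel %d) | flatten %d | %s head (%d classes) | %s\n",
    x$config$input_length,
    paste(x$config$conv_filters, collapse = "/"),
    x$config$kernel_size, x$dims$flatten,
    if (x$binary) "sigmoid" else "softmax", x$n_classes,
    if (x$trained) sprintf("trained %d epochs", x$epochs) else "untrained"
  ))
  invisible(x)
}

#' Assemble a feature matrix for a fiber specification
#'
#' Extracts the mean-normalized spectra of one collection fiber, or the
#' concatenation of two (lower fiber index first), from a simulated or
#' loaded dataset. Two-fiber features pair the spectra acquired at the
#' same construct, rebuild, and probe placement (replicate index).
#'
#' @param dataset An `lss_dataset`.
#' @param fibers One or two fiber ids, e.g. `"R5"` or `c("R1", "R5")`.
#' @return An object of class `lss_feature_set`: list with `X` (samples x
#'   features), `labels`, `rebuild_id`, `fibers`.
#' @export
make_features <- function(dataset, fibers) {
  stopifnot(inherits(dataset, "lss_dataset"),
            length(fibers) %in% c(1L, 2L),
            all(fibers %in% paste0("R", 1:5)))
  if (anyDuplicated(fibers)) {
    stop("fiber pair must use two distinct fibers", call. = FALSE)
  }
  fibers <- fibers[order(fiber_index(fibers))]
  man <- dataset$manifest
  if (!all(fibers %in% man$fiber_id)) {
    stop("requested fiber absent from the dataset manifest: ",
         paste(setdiff(fibers, man$fiber_id), collapse = ","), call. = FALSE)
  }
  tissue <- man$role == "tissue"
  norm_col <- function(j) {
    v <- dataset$spectra[, j]
    m <- mean(v)
    if (m <= 0) stop("degenerate spectrum in dataset column ", j, call. = FALSE)
    v / m
  }
  if (length(fibers) == 1L) {
    idx <- which(tissue & man$fiber_id == fibers)
    X <- t(vapply(idx, norm_col, numeric(nrow(dataset$spectra))))
    labels <- man$construct_label[idx]
    rebuilds <- man$rebuild_id[idx]
  } else {
    i1 <- which(tissue & man$fiber_id == fibers[1])
    key <- function(i) paste(man$construct_label[i], man$rebuild_id[i],
                             man$rep_index[i], sep = "|")
    i2_all <- which(tissue & man$fiber_id == fibers[2])
    lookup <- stats::setNames(i2_all, vapply(i2_all, key, character(1)))
    i2 <- lookup[vapply(i1, key, character(1))]
    if (anyNA(i2)) {
      stop("unmatched probe placements between the two fibers", call. = FALSE)
    }
    X <- t(vapply(seq_along(i1), function(r) {
      c(norm_col(i1[r]), norm_col(i2[r]))
    }, numeric(2L * nrow(dataset$spectra))))
    labels <- man$construct_label[i1]
    rebuilds <- man$rebuild_id[i1]
  }
  structure(
    list(X = X, labels = labels, rebuild_id = rebuilds, fibers = fibers),
    class = "lss_feature_set"
  )
}

#' Subject-wise hold-out split
#'
#' For every class, the spectra of one randomly chosen rebuild are wholly
#' withheld as the test set; of the remaining samples, a stratified
#' `validation_fraction` goes to validation monitoring and the rest is the
#' training set. No rebuild contributes to both training and test, which
#' prevents subject-level leakage.
#'
#' @param features An `lss_feature_set` (or any object with `labels` and
#'   `rebuild_id` vectors).
#' @param design A [study_design()] whose classes cover the labels.
#' @param validation_fraction Stratified validation share (default 0.30).
#' @return List of integer index vectors `train`, `validation`, `test` and
#'   the per-class `test_rebuilds`.
#' @export
subject_wise_split <- function(features, design, validation_fraction = 0.30) {
  labels <- features$labels
  rebuilds <- features$rebuild_id
  stopifnot(length(labels) == length(rebuilds),
            inherits(design, "lss_study_design"))
  if (!all(labels %in% design$classes)) {
    stop("dataset contains labels outside the study's class set", call. = FALSE)
  }
  test_idx <- integer(0)
  test_rebuilds <- integer(0)
  for (cls in design$classes) {
    in_cls <- which(labels == cls)
    rb <- unique(rebuilds[in_cls])
    if (length(rb) < 2L) {
      stop("class ", cls, " has fewer than 2 rebuilds; cannot hold one out",
           call. = FALSE)
    }
    held <- rb[sample.int(length(rb), 1L)]
    test_rebuilds <- c(test_rebuilds, held)
    test_idx <- c(test_idx, in_cls[rebuilds[in_cls] == held])
  }
  remaining <- setdiff(seq_along(labels), test_idx)
  val_idx <- integer(0)
  for (cls in design$classes) {
    pool <- remaining[labels[remaining] == cls]
    n_val <- round(validation_fraction * length(pool))
    if (n_val > 0) val_idx <- c(val_idx, sample(pool, n_val))
  }
  train_idx <- setdiff(remaining, val_idx)
  list(train = sort(train_idx), validation = sort(val_idx),
       test = sort(test_idx),
       test_rebuilds = stats::setNames(test_rebuilds, design$classes))
}

# per-sample mean subtraction at the network input (Table-style
# "mean normalization" of the first layer)
center_rows <- function(X) X - rowMeans(X)

encode_labels <- function(labels, classes, binary) {
  y <- match(labels, classes) - 1L
  if (anyNA(y)) stop("label outside the class set", call. = FALSE)
  if (binary) y <- as.integer(y == 1L)
  y
}

#' Train replicate CNNs under the subject-wise hold-out protocol
#'
#' Trains `config$n_replicates` networks. Each replicate draws its own
#' subject-wise hold-out split, validation split, and weight
#' initialization from a seed derived from `base_seed`, is trained
#' full-batch with ADAM and cross-entropy under the stopping rule, and
#' records its held-out test predictions.
#'
#' @param dataset An `lss_dataset`.
#' @param design The [study_design()] that generated it.
#' @param config A [cnn_config()]; `input_length` must equal the grid
#'   length times the number of fibers in `fibers`.
#' @param fibers One or two fiber ids forming the feature vector.
#' @param base_seed Integer; replicate `r` uses `base_seed + r - 1`.
#' @return List of `lss_trained_replicate` objects, each with the trained
#'   model, training history, early-stop epoch, seed, and held-out
#'   predictions/truths.
#' @export
train_replicates <- function(dataset, design, config, fibers, base_seed = 1L) {
  stopifnot(inherits(config, "lss_cnn_config"))
  features <- make_features(dataset, fibers)
  if (ncol(features$X) != config$input_length) {
    stop(sprintf("config input_length %d does not match feature length %d",
                 config$input_length, ncol(features$X)), call. = FALSE)
  }
  classes <- design$classes
  binary <- config$head == "binary" ||
    (config$head == "auto" && length(classes) == 2)
  Xc <- center_rows(features$X)
  replicate_list <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    seed_r <- as.integer(base_seed) + r - 1L
    set.seed(seed_r)
    split <- subject_wise_split(features, design, config$validation_fraction)
    model <- build_model(config, length(classes))
    y_all <- encode_labels(features$labels, classes, binary)
    fit <- cnn_train_cpp(
      Xc[split$train, , drop = FALSE], y_all[split$train],
      Xc[split$validation, , drop = FALSE], y_all[split$validation],
      model$weights, config$kernel_size, config$learning_rate,
      config$max_epochs, config$patience_epochs, binary
    )
    model$weights <- fit$weights
    model$trained <- TRUE
    model$history <- fit$history
    model$epochs <- fit$epochs
    model$classes <- classes
    pred <- predict(model, Xc[split$test, , drop = FALSE])
    replicate_list[[r]] <- structure(
      list(model = model, seed = seed_r, split = split,
           history = fit$history, epochs = fit$epochs,
           stopped_early = fit$stopped_early,
           test_predictions = pred$labels,
           test_probabilities = pred$probabilities,
           test_truth = features$labels[split$test],
           fibers = features$fibers),
      class = "lss_trained_replicate"
    )
  }
  replicate_list
}

#' Predict construct classes from feature vectors
#'
#' @param object A trained `lss_cnn`.
#' @param newdata Numeric matrix (samples x features, already
#'   row-mean-centered as in training), a single numeric vector, or an
#'   `lss_features` object from [concatenate_fiber_spectra()].
#' @param ... Unused.
#' @return List with `probabilities` (samples x classes, rows sum to 1)
#'   and `labels` (argmax class; ties resolve to the lowest class index;
#'   binary threshold 0.5).
#' @export
predict.lss_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "lss_features")) newdata <- newdata$values
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$config$input_length) {
    stop(sprintf("feature length %d does not match model input length %d",
                 ncol(newdata), object$config$input_length), call. = FALSE)
  }
  raw <- cnn_forward_cpp(newdata, object$weights, object$config$kernel_size,
                         object$binary)
  if (object$binary) {
    probs <- cbind(1 - raw[, 1], raw[, 1])
    pred_idx <- ifelse(raw[, 1] > 0.5, 2L, 1L)
  } else {
    probs <- raw
    pred_idx <- max.col(probs, ties.method = "first")
  }
  classes <- object$classes
  if (is.null(classes)) classes <- as.character(seq_len(ncol(probs)))
  colnames(probs) <- classes
  list(probabilities = probs, labels = classes[pred_idx])
}
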