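#' Architecture of the shallow multi-output regression network
#'
#' A fully connected feed-forward network with four sigmoid hidden layers
#' (widths configurable) and a linear output layer, trained with
#' mean-squared-error loss.  In `rmsd_regression` mode the 16 outputs are the
#' fragment's structural coordinates (RMSDs to the block prototypes) and the
#' predicted class is the argmin output; in `one_hot` mode the outputs are
#' one-hot class indicators (e.g. DSSP-8 or DSSP-3) trained with the same MSE
#' loss, and the predicted class is the argmax output.
#'
#' @param input_dim number of input features.
#' @param output_dim number of outputs (16 blocks, or 8/3 DSSP classes).
#' @param hidden integer widths of the hidden layers.
#' @param activation hidden activation; only `"sigmoid"` is supported.
#' @param task `"rmsd_regression"` or `"one_hot"`.
#' @return a `pb_mlp_spec` list.
#' @export
mlp_spec <- function(input_dim, output_dim,
                     hidden = c(512, 256, 128, 64),
                     activation = "sigmoid",
                     task = c("rmsd_regression", "one_hot")) {
  task <- match.arg(task)
  if (activation != "sigmoid") abort("only the sigmoid activation is supported")
  if (input_dim < 0 || output_dim < 1 || any(hidden < 1)) abort("invalid layer sizes")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 activation = activation, task = task),
            class = "pb_mlp_spec")
}

#' Optimizer schedule for network training
#'
#' Adam with an initial learning rate of 1e-2; whenever the monitored loss
#' stops improving by at least `min_delta` for `patience` epochs, the rate is
#' divided by `decay_factor`, down to `floor_lr` (1e-5), after which a final
#' plateau stops training.
#'
#' @param initial_lr,decay_factor,floor_lr learning-rate schedule.
#' @param patience epochs without improvement before decay.
#' @param min_delta minimum loss improvement that resets the plateau counter.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param shuffle reshuffle rows every epoch (deterministic given `seed`).
#' @param seed RNG seed for initialization and shuffling.
#' @return a `pb_schedule` list.
#' @export
training_schedule <- function(initial_lr = 1e-2, decay_factor = 5,
                              floor_lr = 1e-5, patience = 5, min_delta = 1e-4,
                              batch_size = 1024, max_epochs = 200,
                              shuffle = TRUE, seed = 1) {
  if (floor_lr > initial_lr) abort("floor_lr must not exceed initial_lr")
  if (decay_factor <= 1) abort("decay_factor must exceed 1")
  structure(list(initial_lr = initial_lr, decay_factor = decay_factor,
                 floor_lr = floor_lr, patience = patience,
                 min_delta = min_delta, batch_size = batch_size,
                 max_epochs = max_epochs, shuffle = shuffle, seed = seed),
            class = "pb_schedule")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; returns list of activations (A[[1]] = input)
mlp_forward <- function(W, b, X) {
  A <- vector("list", length(W) + 1)
  A[[1]] <- X
  for (l in seq_along(W)) {
    Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
    A[[l + 1]] <- if (l < length(W)) sigmoid(Z) else Z
  }
  A
}

# strip key columns and coerce a feature table to a named numeric matrix
feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  keys <- intersect(c("chain_id", "start", "center", "seq5"), names(x))
  as.matrix(x[, setdiff(names(x), keys)])
}

#' Train the shallow multi-output regression network
#'
#' Minimizes the mean squared error between predicted and observed targets
#' (structural coordinates, or one-hot class indicators) with Adam,
#' He-uniform ("kaiming") weight initialization and the plateau-driven
#' learning-rate schedule of [training_schedule()].  Inputs are standardized
#' with training-set statistics, which are frozen into the model together
#' with the feature-name fingerprint.  Training is deterministic for a fixed
#' seed under single-threaded BLAS.
#'
#' @param x feature matrix or tibble (key columns `chain_id`, `start`,
#'   `center`, `seq5` are dropped automatically).
#' @param y numeric target matrix (n x output_dim) with column names.
#' @param spec a [mlp_spec()]; defaults to the dimensions of `x`/`y`.
#' @param schedule a [training_schedule()].
#' @param validation optional list(x, y) monitored for the plateau rule;
#'   when absent the training loss is monitored.
#' @param standardize_targets optimize the MSE of per-target z-scored
#'   outputs instead of raw outputs (predictions are always returned on the
#'   original scale).  Balances the gradient across targets whose dynamic
#'   ranges differ; useful in regression mode where RMSDs to compact blocks
#'   vary much less than RMSDs to extended ones.
#' @return a `pb_mlp` model: weights, standardization statistics, feature
#'   fingerprint and a per-epoch training log ([tidy()]), with [glance()]
#'   summarizing final losses.
#' @export
train_mlp <- function(x, y, spec = NULL, schedule = training_schedule(),
                      validation = NULL, standardize_targets = FALSE) {
  X <- feature_matrix(x)
  Y <- as.matrix(y)
  if (nrow(X) != nrow(Y)) abort("x and y must have the same number of rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  spec <- spec %||% mlp_spec(ncol(X), ncol(Y))
  if (spec$input_dim != ncol(X) || spec$output_dim != ncol(Y)) {
    abort("spec dimensions do not match the data")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (standardize_targets) {
    y_ctr <- colMeans(Y)
    y_scl <- apply(Y, 2, sd)
    y_scl[y_scl < 1e-12] <- 1
    Y <- sweep(sweep(Y, 2, y_ctr), 2, y_scl, "/")
  } else {
    y_ctr <- rep(0, ncol(Y))
    y_scl <- rep(1, ncol(Y))
  }
  if (!is.null(validation)) {
    Xv <- feature_matrix(validation$x)
    Xv <- sweep(sweep(Xv[, colnames(X), drop = FALSE], 2, ctr), 2, scl, "/")
    Yv <- sweep(sweep(as.matrix(validation$y), 2, y_ctr), 2, y_scl, "/")
  }
  sizes <- c(spec$input_dim, spec$hidden, spec$output_dim)
  nl <- length(sizes) - 1
  n <- nrow(Xs)

  withr::with_seed(schedule$seed, {
    W <- vector("list", nl); b <- vector("list", nl)
    for (l in seq_len(nl)) {
      bound <- sqrt(6 / sizes[l])
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -bound, bound),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    tstep <- 0
    lr <- schedule$initial_lr
    best <- Inf
    stall <- 0L
    log <- vector("list", schedule$max_epochs)
    final_epoch <- 0L

    for (epoch in seq_len(schedule$max_epochs)) {
      ord <- if (schedule$shuffle) sample.int(n) else seq_len(n)
      batch_starts <- seq(1, n, by = schedule$batch_size)
      tot_loss <- 0
      for (s in batch_starts) {
        idx <- ord[s:min(s + schedule$batch_size - 1, n)]
        Xb <- Xs[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        m <- nrow(Xb)
        A <- mlp_forward(W, b, Xb)
        out <- A[[nl + 1]]
        loss <- mean((out - Yb)^2)
        if (!is.finite(loss)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", epoch,
                       "; reduce the learning rate or inspect the inputs"))
        }
        tot_loss <- tot_loss + loss * m
        G <- 2 * (out - Yb) / (m * ncol(Yb))
        tstep <- tstep + 1
        for (l in nl:1) {
          dW <- crossprod(A[[l]], G)
          db <- colSums(G)
          if (l > 1) {
            G <- (G %*% t(W[[l]])) * A[[l]] * (1 - A[[l]])
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * dW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * dW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * db
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * db^2
          mhW <- mW[[l]] / (1 - beta1^tstep); vhW <- vW[[l]] / (1 - beta2^tstep)
          mhb <- mb[[l]] / (1 - beta1^tstep); vhb <- vb[[l]] / (1 - beta2^tstep)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      train_loss <- tot_loss / n
      val_loss <- if (!is.null(validation)) {
        mean((mlp_forward(W, b, Xv)[[nl + 1]] - Yv)^2)
      } else NA_real_
      monitored <- if (!is.null(validation)) val_loss else train_loss
      log[[epoch]] <- tibble(epoch = epoch, lr = lr,
                             train_loss = train_loss, val_loss = val_loss)
      final_epoch <- epoch
      if (monitored < best - schedule$min_delta) {
        best <- monitored
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= schedule$patience) {
          new_lr <- lr / schedule$decay_factor
          if (new_lr >= schedule$floor_lr * (1 - 1e-9)) {
            lr <- new_lr
            stall <- 0L
          } else {
            break  # floor reached and patience exhausted
          }
        }
      }
    }
  })

  structure(list(
    spec = spec, schedule = schedule, W = W, b = b,
    center = ctr, scale = scl, y_center = y_ctr, y_scale = y_scl,
    features = colnames(X), targets = colnames(Y),
    log = bind_rows(log[seq_len(final_epoch)])
  ), class = "pb_mlp")
}

#' Predict network outputs for new fragments
#'
#' The feature fingerprint (column names) of `newdata` must match the one
#' the model was trained with; mismatches are refused with a message naming
#' the missing and extra features.
#'
#' @param object a `pb_mlp` model.
#' @param newdata feature matrix or tibble.
#' @param ... unused.
#' @return numeric matrix (rows in input order) with one column per target.
#' @export
predict.pb_mlp <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  if (nrow(X) == 0) {
    return(matrix(numeric(0), 0, length(object$targets),
                  dimnames = list(NULL, object$targets)))
  }
  missing <- setdiff(object$features, colnames(X))
  extra <- setdiff(colnames(X), object$features)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "feature fingerprint mismatch.",
      if (length(missing) > 0) paste0(" missing: ", paste(head(missing, 5), collapse = ", "),
                                      if (length(missing) > 5) " ..." else "", "."),
      if (length(extra) > 0) paste0(" extra: ", paste(head(extra, 5), collapse = ", "),
                                    if (length(extra) > 5) " ..." else "", ".")
    ))
  }
  Xs <- sweep(sweep(X[, object$features, drop = FALSE], 2, object$center),
              2, object$scale, "/")
  out <- mlp_forward(object$W, object$b, Xs)[[length(object$W) + 1]]
  if (!is.null(object$y_scale)) {
    out <- sweep(sweep(out, 2, object$y_scale, "*"), 2, object$y_center, "+")
  }
  colnames(out) <- object$targets
  out
}

#' Predict structural coordinates for a fragment feature table
#'
#' Convenience wrapper around [predict.pb_mlp()] returning a tibble of the
#' predicted 16 RMSDs alongside any key columns present in the input.
#'
#' @param model a trained `pb_mlp` (or constant fallback) model.
#' @param x feature tibble/matrix.
#' @return tibble of key columns plus one column per predicted target.
#' @export
predict_structural_coordinates <- function(model, x) {
  pred <- predict(model, x)
  keys <- if (is.data.frame(x)) {
    x[, intersect(c("chain_id", "start", "center", "seq5"), names(x))]
  } else {
    tibble(.rows = nrow(pred))
  }
  bind_cols(keys, as_tibble(pred))
}

#' Turn predicted output vectors into class labels
#'
#' In `rmsd` mode the class is the block whose predicted RMSD is smallest;
#' in `one_hot` mode it is the class with the largest output.  Ties within
#' 1e-6 go to the first class in alphabet order and are flagged.
#'
#' @param pred numeric matrix of predicted outputs (columns = classes, in
#'   alphabet order).
#' @param mode `"rmsd"` (argmin) or `"one_hot"` (argmax).
#' @param alphabet class labels; default derived from column names.
#' @return tibble with columns `label` and `tie`.
#' @export
classify_predictions <- function(pred, mode = c("rmsd", "one_hot"),
                                 alphabet = NULL) {
  mode <- match.arg(mode)
  pred <- as.matrix(pred)
  alphabet <- alphabet %||% sub("^(rmsd_|sc_)", "", colnames(pred))
  S <- if (mode == "rmsd") pred else -pred
  idx <- max.col(-S, ties.method = "first")
  mins <- S[cbind(seq_len(nrow(S)), idx)]
  tibble(label = alphabet[idx],
         tie = rowSums(S <= mins + 1e-6) > 1)
}

#' One-hot encode class labels
#'
#' @param labels character vector.
#' @param alphabet class alphabet defining column order.
#' @return numeric matrix (n x length(alphabet)).
#' @export
one_hot <- function(labels, alphabet) {
  if (!all(labels %in% alphabet)) abort("labels outside the alphabet")
  M <- matrix(0, length(labels), length(alphabet),
              dimnames = list(NULL, alphabet))
  M[cbind(seq_along(labels), match(labels, alphabet))] <- 1
  M
}

# intercept-only fallback used when feature selection keeps nothing:
# predicts the training-mean target vector for every fragment
constant_model <- function(y) {
  Y <- as.matrix(y)
  structure(list(means = colMeans(Y), targets = colnames(Y)),
            class = "pb_constant_model")
}

#' @export
predict.pb_constant_model <- function(object, newdata, ...) {
  n <- if (is.null(dim(newdata))) length(newdata) else nrow(newdata)
  matrix(object$means, n, length(object$means), byrow = TRUE,
         dimnames = list(NULL, object$targets))
}

#' @export
tidy.pb_mlp <- function(x, ...) x$log

#' @export
glance.pb_mlp <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble(epochs = last$epoch, final_lr = last$lr,
         final_train_loss = last$train_loss, final_val_loss = last$val_loss,
         n_parameters = sum(vapply(x$W, length, integer(1))) +
           sum(vapply(x$b, length, integer(1))))
}

#' @export
print.pb_mlp <- function(x, ...) {
  cat("Shallow multi-output regression network (", x$spec$task, ")\n",
      "  layers: ", paste(c(x$spec$input_dim, x$spec$hidden, x$spec$output_dim),
                          collapse = " -> "), "\n",
      "  trained ", nrow(x$log), " epochs, final train loss ",
      signif(x$log$train_loss[nrow(x$log)], 4), "\n", sep = "")
  invisible(x)
}
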