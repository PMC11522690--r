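# Model fitting: seeded molecule-level splits, a composite local+global
# loss, an Adam training loop over precomputed minibatches, and MAE/RMSE
# evaluation with per-particle-type breakdowns.
#
# The loss is
#   w_local * mean_particles (yhat - y)^2 +
#   w_global * mean_molecules (reconstructed molecular quantity - target)^2
# where the molecular term is (sum Q_hat - 0)^2 for charges and
# (sum N_hat - sum Z)^2 for populations; with w_global = 0 it reduces
# exactly to the plain local loss. Weighting the reconstruction error
# ("global-to-local tradeoff") rewards predictions whose sum respects the
# known molecular value, which improves generalization of the local
# values without extra labels.

# Properties with a label-free molecular target; value function of Z.
.GLOBAL_TARGETS <- list(
  Q = function(Z) 0,
  N_A = function(Z) sum(Z)
)

#' Training configuration
#'
#' @param property property name present in the records (`"Q"`, `"delta"`,
#'   ...).
#' @param mode readout mode (see [readout_config()]).
#' @param w_local,w_global loss weights in `[0, 1]`, not both zero. The
#'   global (molecular-reconstruction) term is only defined for
#'   properties with a known molecular target (`Q`, `N_A`); for other
#'   properties set `w_global = 0` explicitly.
#' @param batch_size molecules per minibatch.
#' @param lr Adam learning rate.
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param splits train/validation/test fractions, positive, summing to 1.
#' @param hidden_sizes head hidden-layer widths.
#' @param seed integer seed controlling the split and minibatch partition.
#' @return object of class `train_config`.
#' @export
train_config <- function(property, mode, w_local = 1, w_global = 0.1,
                         batch_size = 64L, lr = 1e-3, epochs = 60L,
                         patience = 30L, splits = c(0.8, 0.1, 0.1),
                         hidden_sizes = c(32L, 16L), seed = 1L) {
  if (w_local < 0 || w_global < 0 || w_local + w_global <= 0) {
    stop("loss weights must be >= 0 with w_local + w_global > 0")
  }
  if (length(splits) != 3L || any(splits <= 0) ||
      abs(sum(splits) - 1) > 1e-8) {
    stop("splits must be three positive fractions summing to 1")
  }
  if (w_global > 0 && !(property %in% names(.GLOBAL_TARGETS))) {
    stop("no molecular target is defined for property '", property,
         "'; set w_global = 0 explicitly to train with the local loss only")
  }
  structure(list(property = property, mode = mode, w_local = w_local,
                 w_global = w_global, batch_size = as.integer(batch_size),
                 lr = lr, epochs = as.integer(epochs),
                 patience = as.integer(patience), splits = splits,
                 hidden_sizes = as.integer(hidden_sizes),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split records into train/validation/test partitions
#'
#' Molecule-level, seeded, deterministic: the three partitions are
#' disjoint and exhaustive.
#'
#' @param records list of `local_record`s (>= 3).
#' @param fractions positive fractions summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(records)
  if (n < 3L) stop("need at least 3 records to split")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive values summing to 1")
  }
  set.seed(seed)
  perm <- sample.int(n)
  n_val <- max(1L, floor(fractions[2] * n))
  n_test <- max(1L, floor(fractions[3] * n))
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("split leaves no training records")
  list(train = records[perm[seq_len(n_train)]],
       val = records[perm[n_train + seq_len(n_val)]],
       test = records[perm[n_train + n_val + seq_len(n_test)]])
}

#' Composite local + global loss
#'
#' `w_local * mean((yhat - y)^2) + w_global * mean_molecules(g_m^2)` where
#' `g_m` is the molecular-reconstruction residual of molecule m: `sum of
#' predicted Q` (target 0) or `sum of predicted N_A - sum Z`. With
#' `w_global = 0` the molecular term is skipped entirely and the value
#' equals the plain mean squared local error.
#'
#' @param predictions,labels aligned numeric vectors over particles.
#' @param Z list of atomic-number vectors, one per molecule (used for the
#'   molecular target).
#' @param w_local,w_global loss weights.
#' @param property property name (decides the molecular target).
#' @param mol_id molecule index of each particle (defaults to a single
#'   molecule).
#' @return scalar loss.
#' @export
composite_loss <- function(predictions, labels, Z, w_local, w_global,
                           property = "Q", mol_id = NULL) {
  if (length(predictions) != length(labels)) stop("prediction/label shape mismatch")
  if (is.null(mol_id)) mol_id <- rep(1L, length(predictions))
  if (!is.list(Z)) Z <- list(Z)
  loss <- w_local * mean((predictions - labels)^2)
  if (w_global > 0) {
    tgt_fun <- .GLOBAL_TARGETS[[property]]
    if (is.null(tgt_fun)) {
      stop("no molecular target is defined for property '", property, "'")
    }
    n_mol <- length(Z)
    g <- vapply(seq_len(n_mol), function(m) {
      sum(predictions[mol_id == m]) - tgt_fun(Z[[m]])
    }, numeric(1))
    loss <- loss + w_global * mean(g^2)
  }
  loss
}

# ---------------------------------------------------------------------------
# Internal batched prediction/loss machinery

# Precompute batch structures + label vectors for a record list.
.prepare_batches <- function(records, model, property, batch_size, is2p) {
  idx_chunks <- split(seq_along(records),
                      ceiling(seq_along(records) / batch_size))
  lapply(idx_chunks, function(idx) {
    mols <- lapply(records[idx], `[[`, "molecule")
    batch <- .make_batch(mols, model$rep, pairs = is2p)
    labels <- if (is2p) {
      unlist(lapply(records[idx], function(r) r$props_2p[[property]]),
             use.names = FALSE)
    } else {
      unlist(lapply(records[idx], function(r) r$props_1p[[property]]),
             use.names = FALSE)
    }
    if (is.null(labels) || anyNA(labels)) {
      stop("records are not labeled with property '", property, "'")
    }
    n_expected <- if (is2p) length(batch$pi) else batch$n_atoms
    stopifnot(length(labels) == n_expected)
    batch$labels <- labels
    batch$particle_mol <- if (is2p) batch$pmol else batch$mol_id
    batch$Zlist <- lapply(mols, `[[`, "Z")
    batch
  })
}

# Forward + loss (+ gradients) on one prepared batch.
.batch_loss <- function(model, batch, cfg, with_grad = FALSE) {
  is2p <- is_2p_mode(model$readout$mode)
  fw <- .rep_forward(model$rep, batch, keep_cache = with_grad)
  hv <- if (is2p) {
    .heads_forward_2p(model, fw$x, batch, keep_cache = with_grad)
  } else {
    .heads_forward_1p(model, fw$x, batch$Z, keep_cache = with_grad)
  }
  pred <- hv$y
  n_part <- length(pred)
  n_mol <- batch$n_mols
  resid <- pred - batch$labels
  loss <- cfg$w_local * mean(resid^2)
  g <- NULL
  if (cfg$w_global > 0) {
    tgt_fun <- .GLOBAL_TARGETS[[cfg$property]]
    tgt <- vapply(batch$Zlist, tgt_fun, numeric(1))
    g <- as.numeric(.rowsum_full(matrix(pred, ncol = 1),
                                 batch$particle_mol, n_mol)) - tgt
    loss <- loss + cfg$w_global * mean(g^2)
  }
  if (!with_grad) return(list(loss = loss, pred = pred))
  dy <- 2 * cfg$w_local * resid / n_part
  if (!is.null(g)) {
    dy <- dy + 2 * cfg$w_global * g[batch$particle_mol] / n_mol
  }
  n <- model$rep$config$n
  if (is2p) {
    hb <- .heads_backward_2p(model, hv$caches, dy, batch, batch$n_atoms, n)
  } else {
    hb <- .heads_backward_1p(model, hv$caches, dy, batch$n_atoms, n)
  }
  rep_grads <- .rep_backward(model$rep, batch, fw$cache, hb$dx)
  head_grads <- lapply(stats::setNames(names(model$heads), names(model$heads)),
                       function(k) {
                         if (!is.null(hb$hgrads[[k]])) hb$hgrads[[k]]
                         else .zeros_like(model$heads[[k]])
                       })
  list(loss = loss, pred = pred,
       grads = list(rep = rep_grads, heads = head_grads))
}

# Predictions for a list of records, batched. Returns list of numeric
# vectors aligned with each record's atoms/pairs.
.predict_records <- function(model, records, batch_size = 256L) {
  is2p <- is_2p_mode(model$readout$mode)
  out <- vector("list", length(records))
  idx_chunks <- split(seq_along(records),
                      ceiling(seq_along(records) / batch_size))
  for (idx in idx_chunks) {
    mols <- lapply(records[idx], `[[`, "molecule")
    batch <- .make_batch(mols, model$rep, pairs = is2p)
    x <- .rep_forward(model$rep, batch)$x
    pred <- if (is2p) .heads_forward_2p(model, x, batch)$y
            else .heads_forward_1p(model, x, batch$Z)$y
    pm <- if (is2p) batch$pmol else batch$mol_id
    for (m in seq_along(idx)) out[[idx[m]]] <- pred[pm == m]
  }
  out
}

#' Train a local model on labeled records
#'
#' Adam minimization of the composite loss over seeded, fixed minibatches
#' of molecules; the parameters with the best validation loss are
#' returned. Fully reproducible given the seeds in the configurations.
#'
#' @param records list of labeled `local_record`s.
#' @param cfg a [train_config()].
#' @param rep_cfg a [rep_config()] (its seed initializes all weights).
#' @param verbose print a progress line every 10 epochs.
#' @return a `local_model` with attributes `log` (per-epoch data.frame:
#'   epoch, train_loss, val_loss, val_mae) and `split` (the record
#'   partition used).
#' @export
train_local_model <- function(records, cfg, rep_cfg = rep_config(),
                              verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(rep_cfg, "rep_config"))
  split <- split_dataset(records, cfg$splits, cfg$seed)
  elements <- sort(unique(unlist(lapply(split$train,
                                        function(r) r$molecule$Z))))
  other <- sort(unique(unlist(lapply(c(split$val, split$test),
                                     function(r) r$molecule$Z))))
  if (!all(other %in% elements)) {
    stop("validation/test records contain element(s) unseen in training: ",
         paste(element_symbol(setdiff(other, elements)), collapse = ", "))
  }
  unit <- {
    u <- unname(split$train[[1]]$units[cfg$property])
    if (length(u) == 0L || is.na(u)) "e" else u
  }
  ro_cfg <- readout_config(cfg$mode, cfg$hidden_sizes, elements)
  model <- local_model(cfg$property, unit, rep_cfg, ro_cfg)
  is2p <- is_2p_mode(cfg$mode)

  set.seed(cfg$seed + 1L)
  train_order <- sample(seq_along(split$train))
  train_batches <- .prepare_batches(split$train[train_order], model,
                                    cfg$property, cfg$batch_size, is2p)
  val_batches <- .prepare_batches(split$val, model, cfg$property,
                                  max(cfg$batch_size, 256L), is2p)

  params <- list(rep = model$rep$params, heads = model$heads)
  adam <- .adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  log <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    tr_loss <- 0
    for (b in train_batches) {
      model$rep$params <- params$rep
      model$heads <- params$heads
      bl <- .batch_loss(model, b, cfg, with_grad = TRUE)
      if (!is.finite(bl$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; lower the learning rate or check the labels")
      }
      step <- .adam_step(params, bl$grads, adam, lr = cfg$lr)
      params <- step$params
      adam <- step$state
      tr_loss <- tr_loss + bl$loss
    }
    tr_loss <- tr_loss / length(train_batches)
    model$rep$params <- params$rep
    model$heads <- params$heads
    val_loss <- 0; val_ae <- 0; val_n <- 0L
    for (b in val_batches) {
      bl <- .batch_loss(model, b, cfg, with_grad = FALSE)
      val_loss <- val_loss + bl$loss * 1
      val_ae <- val_ae + sum(abs(bl$pred - b$labels))
      val_n <- val_n + length(b$labels)
    }
    val_loss <- val_loss / length(val_batches)
    val_mae <- val_ae / val_n
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                               val_loss = val_loss, val_mae = val_mae)
    if (verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  train %.3e  val %.3e  val MAE %.4f",
                      epoch, tr_loss, val_loss, val_mae))
    }
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      log <- log[seq_len(epoch)]
      break
    }
  }
  model$rep$params <- best$params$rep
  model$heads <- best$params$heads
  attr(model, "log") <- do.call(rbind, log)
  attr(model, "split") <- split
  attr(model, "train_config") <- cfg
  model
}

#' Evaluate a trained model on labeled records
#'
#' @param model a `local_model`.
#' @param records non-empty list of labeled `local_record`s.
#' @return object of class `eval_report`: overall `mae` and `rmse` (model
#'   units; also `mae_kcalmol`/`rmse_kcalmol` for "au" properties), a
#'   `by_type` data.frame (per element or per element pair), and
#'   `per_molecule` (id, n-particle count, MAE, molecular reconstruction
#'   residual where defined).
#' @export
evaluate <- function(model, records) {
  stopifnot(inherits(model, "local_model"))
  if (length(records) == 0L) stop("cannot evaluate on an empty record set")
  property <- model$property
  is2p <- is_2p_mode(model$readout$mode)
  preds <- .predict_records(model, records)
  labels <- lapply(records, function(r) {
    v <- if (is2p) r$props_2p[[property]] else r$props_1p[[property]]
    if (is.null(v)) stop("records lack labels for property '", property, "'")
    v
  })
  err <- unlist(preds) - unlist(labels)
  mae <- mean(abs(err)); rmse <- sqrt(mean(err^2))
  type <- unlist(lapply(records, function(r) {
    Z <- r$molecule$Z
    if (is2p) {
      pr <- enumerate_pairs(length(Z))
      paste(element_symbol(pmin(Z[pr$i], Z[pr$j])),
            element_symbol(pmax(Z[pr$i], Z[pr$j])), sep = "-")
    } else element_symbol(Z)
  }))
  by_type <- do.call(rbind, lapply(split(seq_along(err), type), function(ix) {
    data.frame(type = type[ix[1]], n = length(ix),
               mae = mean(abs(err[ix])), rmse = sqrt(mean(err[ix]^2)))
  }))
  rownames(by_type) <- NULL
  tgt_fun <- .GLOBAL_TARGETS[[property]]
  per_mol <- do.call(rbind, lapply(seq_along(records), function(m) {
    e <- preds[[m]] - labels[[m]]
    resid <- if (!is.null(tgt_fun) && !is2p) {
      abs(sum(preds[[m]]) - tgt_fun(records[[m]]$molecule$Z))
    } else NA_real_
    data.frame(id = records[[m]]$molecule$id, n = length(e),
               mae = mean(abs(e)), resid = resid)
  }))
  out <- list(property = property, unit = model$unit, mae = mae, rmse = rmse,
              by_type = by_type, per_molecule = per_mol)
  if (identical(model$unit, "au")) {
    out$mae_kcalmol <- mae * AU_TO_KCALMOL
    out$rmse_kcalmol <- rmse * AU_TO_KCALMOL
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report '", x$property, "'>\n", sep = "")
  cat(sprintf("  MAE  = %.6g %s\n  RMSE = %.6g %s\n",
              x$mae, x$unit, x$rmse, x$unit))
  if (!is.null(x$mae_kcalmol)) {
    cat(sprintf("       (%.4g / %.4g kcal/mol)\n", x$mae_kcalmol, x$rmse_kcalmol))
  }
  cat("  by type:\n")
  print(x$by_type, row.names = FALSE)
  invisible(x)
}
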