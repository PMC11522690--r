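test_that("dataset splits are disjoint, exhaustive, seeded and seed-sensitive", {
  recs <- fix_records(10, seed = 3)
  sp <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  ids <- function(part) vapply(part, function(r) r$molecule$id, character(1))
  all_ids <- c(ids(sp$train), ids(sp$val), ids(sp$test))
  expect_setequal(all_ids, ids(recs))
  expect_equal(anyDuplicated(all_ids), 0L)
  sp2 <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(ids(sp2$train), ids(sp$train))
  sp3 <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = 8)
  expect_false(identical(ids(sp3$train), ids(sp$train)))
  expect_error(split_dataset(recs, c(0.8, 0.3, 0.1)), "summing to 1")
  expect_error(split_dataset(recs[1:2], c(0.8, 0.1, 0.1)), "at least 3")
})

test_that("the composite loss reduces to the local MSE and adds (Mc)^2 per molecule", {
  y <- c(0.1, -0.2, 0.1)
  Z <- list(c(1, 1, 8))
  expect_equal(composite_loss(y, y, Z, 1, 0.5), 0)
  yhat <- y + c(0.05, -0.03, 0.2)
  expect_equal(composite_loss(yhat, y, Z, 1, 0), mean((yhat - y)^2))
  # uniform +c on each of M charges: global term is w_global (M c)^2
  c_ <- 0.07; M <- 3
  expect_equal(composite_loss(y + c_, y, Z, 0, 0.4, property = "Q"),
               0.4 * (M * c_)^2, tolerance = 1e-12)
  expect_error(composite_loss(y, y, Z, 1, 0.5, property = "delta"),
               "no molecular target")
  expect_error(train_config("delta", "AIMwise-2P", w_global = 0.5),
               "w_global = 0")
  # multi-molecule form averages the per-molecule residuals
  mol_id <- c(1L, 1L, 2L)
  Z2 <- list(c(1, 1), 8)
  got <- composite_loss(c(0.1, 0.2, -0.05), c(0, 0, 0), Z2, 0, 1,
                        property = "Q", mol_id = mol_id)
  expect_equal(got, mean(c(0.3^2, 0.05^2)))
})

test_that("analytic gradients of the full model agree with finite differences", {
  recs <- fix_records(4, seed = 11)
  for (case in list(list(mode = "ElementalAIMwise", property = "Q", wg = 0.2),
                    list(mode = "ElementalPairAIMwise", property = "delta", wg = 0))) {
    cfg <- train_config(case$property, case$mode, w_global = case$wg,
                        batch_size = 4, seed = 3, hidden_sizes = c(5, 4))
    rc <- rep_config(n = 6, n_interactions = 2, n_rbf = 5, seed = 7)
    ro <- readout_config(case$mode, cfg$hidden_sizes, elements = c(1, 6, 7, 8))
    model <- local_model(case$property, "e", rc, ro)
    is2p <- is_2p_mode(case$mode)
    b <- localaim:::.prepare_batches(recs, model, case$property, 4, is2p)[[1]]
    bl <- localaim:::.batch_loss(model, b, cfg, with_grad = TRUE)
    params <- list(rep = model$rep$params, heads = model$heads)
    pflat <- unlist(params, use.names = FALSE)
    gflat <- unlist(bl$grads, use.names = FALSE)
    set.seed(99)
    idx <- sample(length(pflat), 25)
    for (k in idx) {
      eps <- 1e-6
      perturbed <- function(sign) {
        v <- pflat; v[k] <- v[k] + sign * eps
        pr <- utils::relist(v, params)
        m <- model; m$rep$params <- pr$rep; m$heads <- pr$heads
        localaim:::.batch_loss(m, b, cfg)$loss
      }
      num <- (perturbed(1) - perturbed(-1)) / (2 * eps)
      expect_lt(abs(num - gflat[k]) / max(1e-6, abs(num)), 1e-3)
    }
  }
})

test_that("evaluation metrics follow their definitions and RMSE >= MAE", {
  recs <- fix_records(8, seed = 13)
  cfg <- train_config("Q", "ElementalAIMwise", epochs = 2, batch_size = 8,
                      splits = c(0.5, 0.25, 0.25), seed = 2)
  model <- train_local_model(recs, cfg, tiny_rep_cfg(seed = 2))
  ev <- evaluate(model, attr(model, "split")$test)
  expect_gte(ev$rmse, ev$mae)
  expect_gte(ev$mae, 0)
  expect_true(all(c("type", "n", "mae", "rmse") %in% names(ev$by_type)))
  expect_true(all(ev$per_molecule$resid >= 0))
  expect_error(evaluate(model, list()), "empty")

  # hand-checkable values through a stub record: errors {0, 0.2}
  err <- c(0, 0.2)
  expect_equal(mean(abs(err)), 0.1)
  expect_equal(sqrt(mean(err^2)), 0.1414214, tolerance = 1e-6)
})

test_that("training reduces the loss, is seed-deterministic, and absorbs constants", {
  recs <- fix_records(60, seed = 17)
  cfg <- train_config("Q", "ElementalAIMwise", epochs = 15, batch_size = 30,
                      patience = 50, seed = 5)
  rc <- tiny_rep_cfg(seed = 5)
  m1 <- train_local_model(recs, cfg, rc)
  log <- attr(m1, "log")
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  m2 <- train_local_model(recs, cfg, rc)
  expect_identical(m1$heads, m2$heads)
  expect_identical(m1$rep$params, m2$rep$params)

  # constant labels: the head bias absorbs the constant almost exactly
  const <- lapply(recs, function(r) {
    r$props_1p$Q <- rep(0.25, n_atoms(r$molecule)); r
  })
  cfgc <- train_config("Q", "AIMwise-1P", w_global = 0, epochs = 60,
                       batch_size = 30, lr = 1e-2, patience = 100, seed = 5)
  mc <- train_local_model(const, cfgc, tiny_rep_cfg(seed = 5, n_interactions = 0L))
  evc <- evaluate(mc, attr(mc, "split")$test)
  expect_lt(evc$mae, 0.01)
})

test_that("unseen elements in validation or test are refused", {
  recs <- fix_records(12, seed = 19)
  # replace one molecule with a fluorine-free impossibility: give val a new element
  odd <- molecule(c(16, 1), rbind(c(0, 0, 0), c(1.4, 0, 0)), id = "odd")
  recs[[1]] <- local_record(odd, props_1p = list(Q = c(0.1, -0.1)),
                            props_2p = list(delta = 0.5))
  cfg <- train_config("Q", "ElementalAIMwise", epochs = 1, seed = 42)
  # with seed 42 the sulfur record may fall anywhere; force it into val
  # by using a split seed that places record 1 outside training
  placed_out <- FALSE
  for (s in 1:20) {
    sp <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = s)
    in_train <- any(vapply(sp$train, function(r) r$molecule$id == "odd",
                           logical(1)))
    if (!in_train) {
      cfg$seed <- s
      placed_out <- TRUE
      break
    }
  }
  expect_true(placed_out)
  expect_error(train_local_model(recs, cfg, tiny_rep_cfg()), "S")
})

test_that("raising w_global does not worsen the validation reconstruction residual", {
  recs <- fix_records(250, seed = 23)
  median_resid <- function(wg) {
    cfg <- train_config("Q", "ElementalAIMwise", w_global = wg, epochs = 12,
                        batch_size = 50, patience = 50, seed = 4)
    m <- train_local_model(recs, cfg, tiny_rep_cfg(seed = 4, n = 16))
    ev <- evaluate(m, attr(m, "split")$val)
    median(ev$per_molecule$resid)
  }
  r0 <- median_resid(0)
  r5 <- median_resid(0.5)
  expect_lte(r5, r0 * 1.05)   # "does not worsen", with 5% numerical slack
})
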