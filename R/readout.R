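# Readout ("prediction") block: turns per-atom environment vectors into
# per-atom (1P) or per-pair (2P) property values. The cumulative pooling
# layer used for molecular targets is removed: the output is the vector
# of local values itself. Four modes are supported:
#   AIMwise-1P / AIMwise-2P  - one universal head for all particles,
#   ElementalAIMwise         - one head per element (1P),
#   ElementalPairAIMwise     - one head per unordered element pair (2P).
# 2P heads act on the concatenation [AE_i, AE_j, r_ij] (length 2n + 1) and
# are always evaluated in both concatenation orders and averaged, making
# the prediction exactly symmetric under i <-> j regardless of weights.

.READOUT_MODES <- c("AIMwise-1P", "AIMwise-2P",
                    "ElementalAIMwise", "ElementalPairAIMwise")

#' Readout configuration
#'
#' @param mode one of `"AIMwise-1P"`, `"AIMwise-2P"`, `"ElementalAIMwise"`
#'   (1P, one head per element), `"ElementalPairAIMwise"` (2P, one head
#'   per unordered element pair).
#' @param hidden_sizes integer vector of hidden-layer widths of each head
#'   (default `c(32, 16)`), shifted-softplus activations, scalar linear
#'   output.
#' @param elements atomic numbers covered; required non-empty for the
#'   particle-specific modes.
#' @return object of class `readout_config`.
#' @export
readout_config <- function(mode, hidden_sizes = c(32L, 16L), elements = integer()) {
  mode <- match.arg(mode, .READOUT_MODES)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L)) {
    stop("hidden_sizes must be positive integers")
  }
  elements <- sort(unique(as.integer(elements)))
  if (mode %in% c("ElementalAIMwise", "ElementalPairAIMwise") &&
      length(elements) == 0L) {
    stop("particle-specific mode '", mode, "' requires a non-empty element set")
  }
  structure(list(mode = mode, hidden_sizes = hidden_sizes, elements = elements),
            class = "readout_config")
}

#' Is a readout mode two-body?
#' @param mode readout mode string.
#' @return logical.
#' @export
is_2p_mode <- function(mode) mode %in% c("AIMwise-2P", "ElementalPairAIMwise")

#' Symmetric integer identifier of an unordered element pair (pairmat)
#'
#' With `a = min(Z_i, Z_j)` and `b = max(Z_i, Z_j)` the identifier is
#' `b(b-1)/2 + a`: symmetric in its arguments and injective on unordered
#' pairs, so every chemically distinct pair is routed to exactly one head.
#'
#' @param Z_i,Z_j atomic numbers (>= 1); vectorized.
#' @return non-negative integer id(s).
#' @examples
#' pair_type_id(1, 1)  # 1
#' pair_type_id(1, 8)  # 29
#' pair_type_id(8, 8)  # 36
#' @export
pair_type_id <- function(Z_i, Z_j) {
  if (any(Z_i < 1L) || any(Z_j < 1L)) stop("atomic numbers must be >= 1")
  a <- pmin(Z_i, Z_j); b <- pmax(Z_i, Z_j)
  as.integer(b * (b - 1) / 2 + a)
}

#' Number of readout heads implied by a mode and element set
#'
#' Universal (AIMwise) modes use a single head; ElementalAIMwise uses one
#' head per element (T); ElementalPairAIMwise one per unordered element
#' pair (T(T+1)/2).
#'
#' @param mode readout mode string.
#' @param elements atomic numbers covered.
#' @return integer K.
#' @examples
#' count_heads("ElementalPairAIMwise", c(1, 6, 7, 8))  # 10
#' @export
count_heads <- function(mode, elements = integer()) {
  mode <- match.arg(mode, .READOUT_MODES)
  T_ <- length(unique(elements))
  switch(mode,
         "AIMwise-1P" = 1L,
         "AIMwise-2P" = 1L,
         "ElementalAIMwise" = {
           if (T_ == 0L) stop("ElementalAIMwise requires a non-empty element set")
           T_
         },
         "ElementalPairAIMwise" = {
           if (T_ == 0L) stop("ElementalPairAIMwise requires a non-empty element set")
           as.integer(T_ * (T_ + 1) / 2)
         })
}

#' Build the two-body descriptor for one atom pair
#'
#' Concatenates the two environment vectors with the interatomic distance:
#' `[AE_i, AE_j, r_ij]`, of length 2n + 1. Consumers evaluate heads on
#' both concatenation orders and average, so predictions are
#' order-independent.
#'
#' @param AE_i,AE_j environment vectors of equal length n.
#' @param r_ij interatomic distance (> 0), Angstrom.
#' @return numeric vector of length 2n + 1.
#' @export
build_pair_descriptor <- function(AE_i, AE_j, r_ij) {
  if (length(AE_i) != length(AE_j)) {
    stop("environment vectors differ in length (", length(AE_i), " vs ",
         length(AE_j), ")")
  }
  if (!is.finite(r_ij) || r_ij <= 0) stop("r_ij must be a positive distance")
  c(as.numeric(AE_i), as.numeric(AE_j), r_ij)
}

# ---------------------------------------------------------------------------
# Head MLPs

.mlp_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  lapply(seq_len(length(dims) - 1L), function(l) .init_dense(dims[l], dims[l + 1L]))
}

# X: rows = particles. Returns list(y = numeric, cache).
.mlp_forward <- function(layers, X, keep_cache = FALSE) {
  L <- length(layers)
  H <- X
  cache <- if (keep_cache) list(H = list(X), z = list()) else NULL
  for (l in seq_len(L)) {
    Z <- H %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(H))
    if (l < L) {
      H <- ssp(Z)
      if (keep_cache) { cache$z[[l]] <- Z; cache$H[[l + 1L]] <- H }
    } else {
      if (keep_cache) cache$z[[l]] <- Z
      H <- Z
    }
  }
  list(y = as.numeric(H), cache = cache)
}

# dy: numeric vector. Returns list(grads, dX).
.mlp_backward <- function(layers, cache, dy) {
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- matrix(dy, ncol = 1L)
  for (l in rev(seq_len(L))) {
    if (l < L) dZ <- dZ * ssp_grad(cache$z[[l]])
    grads[[l]] <- list(W = crossprod(cache$H[[l]], dZ), b = colSums(dZ))
    dZ <- dZ %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = dZ)
}

# ---------------------------------------------------------------------------
# Local model = representation + readout head registry

#' Construct an (untrained) local model
#'
#' Bundles a representation block with a registry of readout heads for a
#' named property. In particle-specific modes every covered element
#' (resp. unordered element pair) owns exactly one head; universal modes
#' own a single shared head.
#'
#' @param property property name (e.g. `"Q"`, `"delta"`).
#' @param unit unit tag, `"e"` or `"au"`.
#' @param rep_cfg a [rep_config()]; its `seed` also seeds the heads.
#' @param readout_cfg a [readout_config()].
#' @return object of class `local_model`.
#' @export
local_model <- function(property, unit, rep_cfg, readout_cfg) {
  stopifnot(inherits(rep_cfg, "rep_config"), inherits(readout_cfg, "readout_config"))
  elements <- readout_cfg$elements
  if (length(elements) == 0L) {
    stop("local_model requires the readout element coverage to be stated")
  }
  rep <- rep_init(rep_cfg, elements)     # seeds the RNG stream
  mode <- readout_cfg$mode
  n <- rep_cfg$n
  d_in <- if (is_2p_mode(mode)) 2L * n + 1L else n
  keys <- switch(mode,
                 "AIMwise-1P" = "all",
                 "AIMwise-2P" = "all",
                 "ElementalAIMwise" = as.character(elements),
                 "ElementalPairAIMwise" = {
                   grid <- expand.grid(a = elements, b = elements)
                   grid <- grid[grid$a <= grid$b, ]
                   as.character(pair_type_id(grid$a, grid$b))
                 })
  heads <- stats::setNames(
    lapply(keys, function(k) .mlp_init(d_in, readout_cfg$hidden_sizes)), keys)
  structure(list(property = property, unit = unit, rep = rep,
                 readout = readout_cfg, heads = heads),
            class = "local_model")
}

#' @export
print.local_model <- function(x, ...) {
  cat("<local_model '", x$property, "' [", x$unit, "], mode ",
      x$readout$mode, ", ", length(x$heads), " head(s), elements {",
      paste(element_symbol(x$rep$elements), collapse = " "), "}>\n", sep = "")
  invisible(x)
}

# Route atoms to 1P heads: returns named list key -> atom row indices.
.route_1p <- function(model, Z) {
  if (model$readout$mode == "AIMwise-1P") return(list(all = seq_along(Z)))
  split(seq_along(Z), as.character(Z))
}

# Route pairs to 2P heads: key per pair.
.route_2p <- function(model, Zi, Zj) {
  if (model$readout$mode == "AIMwise-2P") {
    return(list(all = seq_along(Zi)))
  }
  split(seq_along(Zi), as.character(pair_type_id(Zi, Zj)))
}

# Lexicographic row order of a numeric matrix (ties keep input order).
.lex_order <- function(...) {
  keys <- list(...)
  cols <- unlist(lapply(keys, function(K) {
    if (is.matrix(K)) lapply(seq_len(ncol(K)), function(c) K[, c]) else list(K)
  }), recursive = FALSE)
  do.call(order, cols)
}

# Batched 1P head evaluation. x: A x n AE matrix. Returns y (length A) and,
# if requested, per-head caches for backprop. With canonical = TRUE the
# rows fed to each head are sorted by their (label-invariant) content, so
# results are bitwise independent of the atom labeling; BLAS kernels are
# otherwise sensitive to row position at the last-ulp level.
.heads_forward_1p <- function(model, x, Z, keep_cache = FALSE,
                              canonical = FALSE) {
  routes <- .route_1p(model, Z)
  missing <- setdiff(names(routes), names(model$heads))
  if (length(missing)) {
    stop("element(s) not covered by the model: ",
         paste(element_symbol(as.integer(missing)), collapse = ", "))
  }
  y <- numeric(nrow(x))
  caches <- if (keep_cache) list() else NULL
  for (k in names(routes)) {
    idx <- routes[[k]]
    Xk <- x[idx, , drop = FALSE]
    if (canonical) {
      ord <- .lex_order(Xk)
      idx <- idx[ord]
      Xk <- Xk[ord, , drop = FALSE]
    }
    fw <- .mlp_forward(model$heads[[k]], Xk, keep_cache)
    y[idx] <- fw$y
    if (keep_cache) caches[[k]] <- list(idx = idx, cache = fw$cache)
  }
  list(y = y, caches = caches)
}

.heads_backward_1p <- function(model, caches, dy, A, n) {
  dx <- matrix(0, A, n)
  hgrads <- list()
  for (k in names(caches)) {
    idx <- caches[[k]]$idx
    bw <- .mlp_backward(model$heads[[k]], caches[[k]]$cache, dy[idx])
    hgrads[[k]] <- bw$grads
    dx[idx, ] <- dx[idx, ] + bw$dX
  }
  list(hgrads = hgrads, dx = dx)
}

# Batched, symmetrized 2P head evaluation over the batch pair arrays.
# With canonical = TRUE the two concatenation orders of every pair are
# assigned canonically (lexicographic comparison of the two AE vectors)
# and the rows of each head are sorted by content, making the result
# bitwise independent of the atom labeling. The symmetrized average
# itself is unchanged: both orders are always evaluated.
.heads_forward_2p <- function(model, x, batch, keep_cache = FALSE,
                              canonical = FALSE) {
  Zi <- batch$Z[batch$pi]; Zj <- batch$Z[batch$pj]
  routes <- .route_2p(model, Zi, Zj)
  missing <- setdiff(names(routes), names(model$heads))
  if (length(missing)) {
    first <- routes[[missing[1]]][1]
    stop("pair type not covered by the model: (",
         element_symbol(Zi[first]), ", ", element_symbol(Zj[first]), ")")
  }
  Xi <- x[batch$pi, , drop = FALSE]
  Xj <- x[batch$pj, , drop = FALSE]
  if (canonical) {
    # orient each pair so the lexicographically smaller AE vector is first
    P <- nrow(Xi)
    first_ok <- rep(TRUE, P)
    undecided <- rep(TRUE, P)
    for (c in seq_len(ncol(Xi))) {
      if (!any(undecided)) break
      diffc <- undecided & (Xi[, c] != Xj[, c])
      first_ok[diffc] <- Xi[diffc, c] < Xj[diffc, c]
      undecided <- undecided & !diffc
    }
    swap <- which(!first_ok)
    if (length(swap)) {
      tmp <- Xi[swap, , drop = FALSE]
      Xi[swap, ] <- Xj[swap, , drop = FALSE]
      Xj[swap, ] <- tmp
    }
  }
  D1 <- cbind(Xi, Xj, batch$pr)
  D2 <- cbind(Xj, Xi, batch$pr)
  y <- numeric(length(batch$pi))
  caches <- if (keep_cache) list() else NULL
  for (k in names(routes)) {
    idx <- routes[[k]]
    if (canonical) {
      ord <- .lex_order(batch$pr[idx], D1[idx, , drop = FALSE])
      idx <- idx[ord]
    }
    fw1 <- .mlp_forward(model$heads[[k]], D1[idx, , drop = FALSE], keep_cache)
    fw2 <- .mlp_forward(model$heads[[k]], D2[idx, , drop = FALSE], keep_cache)
    y[idx] <- 0.5 * (fw1$y + fw2$y)
    if (keep_cache) caches[[k]] <- list(idx = idx, c1 = fw1$cache, c2 = fw2$cache)
  }
  list(y = y, caches = caches)
}

.heads_backward_2p <- function(model, caches, dy, batch, A, n) {
  dx <- matrix(0, A, n)
  hgrads <- list()
  for (k in names(caches)) {
    idx <- caches[[k]]$idx
    half <- 0.5 * dy[idx]
    bw1 <- .mlp_backward(model$heads[[k]], caches[[k]]$c1, half)
    bw2 <- .mlp_backward(model$heads[[k]], caches[[k]]$c2, half)
    hgrads[[k]] <- .map2_params(bw1$grads, bw2$grads, `+`)
    pi_k <- batch$pi[idx]; pj_k <- batch$pj[idx]
    # D1 = [x_i, x_j, r], D2 = [x_j, x_i, r]
    dx_i <- bw1$dX[, 1:n, drop = FALSE] + bw2$dX[, (n + 1):(2 * n), drop = FALSE]
    dx_j <- bw1$dX[, (n + 1):(2 * n), drop = FALSE] + bw2$dX[, 1:n, drop = FALSE]
    dx <- dx + .rowsum_full(dx_i, pi_k, A) + .rowsum_full(dx_j, pj_k, A)
  }
  list(hgrads = hgrads, dx = dx)
}

# Label-invariant canonical atom order: by element, then by the sorted
# profile of distances to all other atoms. Makes every downstream array
# (edges, pair rows, head inputs) bitwise independent of the labeling the
# caller happened to use; BLAS results are sensitive to row order at the
# last ulp, so predictions would otherwise not be exactly
# permutation-consistent.
.canonical_atom_order <- function(mol) {
  M <- n_atoms(mol)
  if (M == 1L) return(1L)
  D <- as.matrix(stats::dist(mol$R))
  prof <- t(apply(D, 1, sort))
  .lex_order(as.numeric(mol$Z), prof)
}

#' Predict a one-body property for every atom of a molecule
#'
#' Each atom's environment vector is routed to exactly one head; no
#' pooling is applied, so the output is the per-atom value vector.
#' Predictions are evaluated in a canonical atom order internally, so
#' relabeling the atoms permutes the output exactly.
#'
#' @param mol a `molecule`.
#' @param model a 1P `local_model`.
#' @return numeric vector of length M, in the model's unit.
#' @export
predict_1p <- function(mol, model) {
  stopifnot(inherits(model, "local_model"))
  if (is_2p_mode(model$readout$mode)) {
    stop("predict_1p called with a 2P model (mode ", model$readout$mode, ")")
  }
  ord <- .canonical_atom_order(mol)
  mol_c <- molecule(mol$Z[ord], mol$R[ord, , drop = FALSE], id = mol$id)
  batch <- .make_batch(list(mol_c), model$rep)
  x <- .rep_forward(model$rep, batch)$x
  y_c <- .heads_forward_1p(model, x, batch$Z, canonical = TRUE)$y
  y <- numeric(length(y_c))
  y[ord] <- y_c
  y
}

#' Predict a two-body property for every unordered atom pair
#'
#' Pair descriptors `[AE_i, AE_j, r_ij]` are evaluated in both
#' concatenation orders and averaged, so the value for (i, j) equals the
#' value for (j, i) exactly. All M(M-1)/2 pairs are predicted regardless
#' of the representation cutoff: the explicit distance feature carries
#' the long-range information.
#'
#' @param mol a `molecule`.
#' @param model a 2P `local_model`.
#' @return numeric vector of length M(M-1)/2 in canonical pair order.
#' @export
predict_2p <- function(mol, model) {
  stopifnot(inherits(model, "local_model"))
  if (!is_2p_mode(model$readout$mode)) {
    stop("predict_2p called with a 1P model (mode ", model$readout$mode, ")")
  }
  ord <- .canonical_atom_order(mol)
  mol_c <- molecule(mol$Z[ord], mol$R[ord, , drop = FALSE], id = mol$id)
  batch <- .make_batch(list(mol_c), model$rep, pairs = TRUE)
  x <- .rep_forward(model$rep, batch)$x
  y_c <- .heads_forward_2p(model, x, batch, canonical = TRUE)$y
  M <- n_atoms(mol)
  y <- numeric(length(y_c))
  pr <- enumerate_pairs(M)
  y[pair_flat_index(ord[pr$i], ord[pr$j], M)] <- y_c
  y
}

# ---------------------------------------------------------------------------
# Checkpoints (versioned JSON)

.CKPT_VERSION <- "localaim-ckpt-1"

#' Save a local model to a JSON checkpoint
#'
#' @param model a `local_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "local_model"))
  obj <- list(
    version = .CKPT_VERSION,
    property = model$property,
    unit = model$unit,
    rep_config = unclass(model$rep$config),
    elements = model$rep$elements,
    readout = unclass(model$readout),
    rep_params = model$rep$params,
    heads = model$heads
  )
  writeLines(as.character(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)),
             path)
  invisible(path)
}

.as_matrix <- function(x) { x <- as.matrix(x); storage.mode(x) <- "double"; x }

.restore_dense <- function(l) list(W = .as_matrix(l$W), b = as.numeric(l$b))

#' Load a local model from a JSON checkpoint
#'
#' Refuses checkpoints written under a different schema version.
#'
#' @param path checkpoint path.
#' @return a `local_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$version) || !identical(obj$version, .CKPT_VERSION)) {
    stop("checkpoint version mismatch: found '", obj$version,
         "', expected '", .CKPT_VERSION, "'")
  }
  rc <- obj$rep_config
  rep_cfg <- rep_config(rc$n, rc$n_interactions, rc$r_cut, rc$n_rbf, rc$seed)
  ro <- obj$readout
  readout_cfg <- readout_config(ro$mode, ro$hidden_sizes, ro$elements)
  model <- local_model(obj$property, obj$unit, rep_cfg, readout_cfg)
  model$rep$params$emb <- .as_matrix(obj$rep_params$emb)
  model$rep$params$blocks <- lapply(obj$rep_params$blocks, function(bl) {
    lapply(bl, .restore_dense)
  })
  model$heads <- lapply(obj$heads, function(h) lapply(h, .restore_dense))
  model$heads <- model$heads[names(model$heads)]
  model
}
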