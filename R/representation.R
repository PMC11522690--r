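# Representation block: maps (Z, R) to a fixed-width per-atom environment
# matrix (the AE tensor) through a learned element embedding followed by
# continuous-filter interaction blocks. The output depends on geometry
# only through interatomic distances, so it inherits invariance under
# rigid rotations/translations and equivariance under atom relabeling.
#
# Each interaction block performs the residual update
#   x_i <- x_i + W_out( sum_{j != i} W_in(x_j) * F(r_ij) )
# where the filter F is a two-layer shifted-softplus network on a
# Gaussian radial expansion of r_ij, multiplied by a smooth cosine cutoff
# so that atoms beyond r_cut contribute exactly zero. W_out is a
# dense -> ssp -> dense atom-wise stack.

#' Representation configuration
#'
#' @param n feature width of the per-atom environment vectors (>= 1).
#' @param n_interactions number of interaction blocks (>= 0).
#' @param r_cut radial cutoff in Angstrom (> 0).
#' @param n_rbf number of Gaussian radial basis functions (>= 2).
#' @param seed integer seed for weight initialization.
#' @return object of class `rep_config`.
#' @details Defaults (n = 64, 3 interactions, r_cut = 5 Angstrom, 20
#'   radial basis functions) are sized for CPU-scale training; moderate
#'   feature widths also keep the 2P descriptor (length 2n + 1) small.
#' @export
rep_config <- function(n = 64L, n_interactions = 3L, r_cut = 5.0,
                       n_rbf = 20L, seed = 1L) {
  n <- as.integer(n); n_interactions <- as.integer(n_interactions)
  n_rbf <- as.integer(n_rbf)
  if (n < 1L) stop("feature width n must be >= 1")
  if (n_interactions < 0L) stop("n_interactions must be >= 0")
  if (!is.finite(r_cut) || r_cut <= 0) stop("r_cut must be > 0")
  if (n_rbf < 2L) stop("n_rbf must be >= 2")
  structure(list(n = n, n_interactions = n_interactions, r_cut = r_cut,
                 n_rbf = n_rbf, seed = as.integer(seed)),
            class = "rep_config")
}

#' Read a representation configuration from a JSON key-value file
#'
#' Unknown keys are rejected so that typos in a config file cannot pass
#' silently; missing keys fall back to the defaults of [rep_config()].
#'
#' @param path JSON file with any of the keys `n`, `n_interactions`,
#'   `r_cut`, `n_rbf`, `seed`.
#' @return a [rep_config()].
#' @export
rep_config_from_file <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  known <- c("n", "n_interactions", "r_cut", "n_rbf", "seed")
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop("unknown representation config key(s): ", paste(extra, collapse = ", "))
  }
  defaults <- rep_config()
  args <- utils::modifyList(unclass(defaults), obj)
  rep_config(args$n, args$n_interactions, args$r_cut, args$n_rbf, args$seed)
}

#' Gaussian radial expansion of a distance
#'
#' Component k equals `exp(-gamma (d - mu_k)^2)` with centers mu_k equally
#' spaced on [0, r_cut] and `gamma = 1 / (2 dmu^2)` where dmu is the
#' center spacing. Distances beyond r_cut are allowed; components simply
#' decay.
#'
#' @param d numeric vector of distances (>= 0), Angstrom.
#' @param config a [rep_config()].
#' @return length(d) x n_rbf matrix of values in (0, 1].
#' @export
gaussian_expansion <- function(d, config) {
  if (any(d < 0)) stop("distances must be >= 0")
  mu <- seq(0, config$r_cut, length.out = config$n_rbf)
  dmu <- mu[2] - mu[1]
  gamma <- 1 / (2 * dmu^2)
  exp(-gamma * outer(d, mu, `-`)^2)
}

#' Smooth cosine cutoff
#'
#' `0.5 (cos(pi d / r_cut) + 1)` for d < r_cut and exactly 0 beyond;
#' continuous and monotonically non-increasing on [0, r_cut].
#'
#' @param d numeric vector of distances (>= 0), Angstrom.
#' @param r_cut cutoff radius (> 0), Angstrom.
#' @return numeric vector in [0, 1].
#' @export
cosine_cutoff <- function(d, r_cut) {
  if (!is.finite(r_cut) || r_cut <= 0) stop("r_cut must be > 0")
  if (any(d < 0)) stop("distances must be >= 0")
  ifelse(d < r_cut, 0.5 * (cos(pi * d / r_cut) + 1), 0)
}

#' Initialize a representation block
#'
#' @param config a [rep_config()].
#' @param elements integer vector of atomic numbers the model covers; the
#'   embedding table has one row per element and unseen elements are
#'   rejected at prediction time.
#' @return object of class `aim_representation` with fields `config`,
#'   `elements`, `params`.
#' @export
rep_init <- function(config, elements) {
  stopifnot(inherits(config, "rep_config"))
  elements <- sort(unique(as.integer(elements)))
  if (length(elements) < 1L || any(elements < 1L)) {
    stop("elements must be a non-empty set of atomic numbers >= 1")
  }
  set.seed(config$seed)
  n <- config$n
  lim <- 1 / sqrt(n)
  params <- list(
    emb = matrix(stats::runif(length(elements) * n, -lim, lim),
                 length(elements), n),
    blocks = lapply(seq_len(config$n_interactions), function(t) {
      list(inl = .init_dense(n, n),
           f1 = .init_dense(config$n_rbf, n),
           f2 = .init_dense(n, n),
           o1 = .init_dense(n, n),
           o2 = .init_dense(n, n))
    })
  )
  structure(list(config = config, elements = elements, params = params),
            class = "aim_representation")
}

# ---------------------------------------------------------------------------
# Batch assembly: concatenate molecules into flat atom/edge/pair arrays so
# that a whole minibatch is processed with a handful of matrix products.

# Directed edges (both orientations) within each molecule, pruned at
# r_cut where the cutoff is exactly zero anyway.
.make_batch <- function(mols, rep, pairs = FALSE) {
  config <- rep$config
  Z <- unlist(lapply(mols, `[[`, "Z"), use.names = FALSE)
  zidx <- match(Z, rep$elements)
  if (anyNA(zidx)) {
    bad <- sort(unique(Z[is.na(zidx)]))
    stop("element(s) not covered by the model: ",
         paste(element_symbol(bad), collapse = ", "))
  }
  sizes <- vapply(mols, n_atoms, integer(1))
  offset <- cumsum(c(0L, sizes[-length(sizes)]))
  mol_id <- rep(seq_along(mols), sizes)

  ei <- vector("list", length(mols)); ej <- ei; ed <- ei
  pi_ <- vector("list", length(mols)); pj_ <- pi_; pr <- pi_; pm <- pi_
  for (m in seq_along(mols)) {
    M <- sizes[m]
    if (M >= 2L) {
      pr_df <- enumerate_pairs(M)
      d <- pair_distances(mols[[m]])
      keep <- d < config$r_cut
      a <- pr_df$i[keep]; b <- pr_df$j[keep]; dk <- d[keep]
      ei[[m]] <- offset[m] + c(a, b)
      ej[[m]] <- offset[m] + c(b, a)
      ed[[m]] <- c(dk, dk)
      if (pairs) {
        pi_[[m]] <- offset[m] + pr_df$i
        pj_[[m]] <- offset[m] + pr_df$j
        pr[[m]] <- d
        pm[[m]] <- rep.int(m, nrow(pr_df))
      }
    }
  }
  ed <- unlist(ed, use.names = FALSE)
  if (is.null(ed)) ed <- numeric(0)
  ei <- unlist(ei, use.names = FALSE); ej <- unlist(ej, use.names = FALSE)
  if (length(ed) > 0L) {
    # canonical, label-invariant edge order (target atom, distance,
    # neighbor element): makes the neighbor summation order - hence the
    # result, bit for bit - invariant under atom relabeling
    ord <- order(ei, ed, Z[ej])
    ei <- ei[ord]; ej <- ej[ord]; ed <- ed[ord]
  }
  batch <- list(
    Z = Z, zidx = zidx, mol_id = mol_id, n_atoms = length(Z),
    n_mols = length(mols), sizes = sizes, offset = offset,
    ei = ei, ej = ej,
    G = gaussian_expansion(ed, config),
    fc = cosine_cutoff(ed, config$r_cut)
  )
  if (pairs) {
    batch$pi <- unlist(pi_, use.names = FALSE)
    batch$pj <- unlist(pj_, use.names = FALSE)
    batch$pr <- unlist(pr, use.names = FALSE)
    batch$pmol <- unlist(pm, use.names = FALSE)
  }
  batch
}

# Forward pass over a batch. Returns list(x = A x n matrix, cache).
.rep_forward <- function(rep, batch, keep_cache = FALSE) {
  p <- rep$params
  x <- p$emb[batch$zidx, , drop = FALSE]
  A <- batch$n_atoms
  has_edges <- length(batch$ei) > 0L
  cache <- if (keep_cache) list(x0 = x, blocks = list()) else NULL
  for (t in seq_along(p$blocks)) {
    bl <- p$blocks[[t]]
    a <- x %*% bl$inl$W + rep(bl$inl$b, each = A)
    if (has_edges) {
      z1 <- batch$G %*% bl$f1$W + rep(bl$f1$b, each = nrow(batch$G))
      f1 <- ssp(z1)
      z2 <- f1 %*% bl$f2$W + rep(bl$f2$b, each = nrow(f1))
      f2 <- ssp(z2)
      Wfil <- f2 * batch$fc
      msg <- a[batch$ej, , drop = FALSE] * Wfil
      s <- .rowsum_full(msg, batch$ei, A)
    } else {
      z1 <- f1 <- z2 <- f2 <- Wfil <- NULL
      s <- matrix(0, A, ncol(a))
    }
    zo <- s %*% bl$o1$W + rep(bl$o1$b, each = A)
    u <- ssp(zo)
    v <- u %*% bl$o2$W + rep(bl$o2$b, each = A)
    if (keep_cache) {
      cache$blocks[[t]] <- list(x_in = x, a = a, z1 = z1, f1 = f1, z2 = z2,
                                Wfil = Wfil, s = s, zo = zo, u = u)
    }
    x <- x + v
  }
  list(x = x, cache = cache)
}

# Backward pass: dL/dx (A x n) -> gradient structure mirroring params.
.rep_backward <- function(rep, batch, cache, dx) {
  p <- rep$params
  A <- batch$n_atoms
  has_edges <- length(batch$ei) > 0L
  grads <- .zeros_like(p)
  for (t in rev(seq_along(p$blocks))) {
    bl <- p$blocks[[t]]
    cb <- cache$blocks[[t]]
    dv <- dx                                   # residual: dx flows to both terms
    grads$blocks[[t]]$o2$W <- crossprod(cb$u, dv)
    grads$blocks[[t]]$o2$b <- colSums(dv)
    du <- dv %*% t(bl$o2$W)
    dzo <- du * ssp_grad(cb$zo)
    grads$blocks[[t]]$o1$W <- crossprod(cb$s, dzo)
    grads$blocks[[t]]$o1$b <- colSums(dzo)
    ds <- dzo %*% t(bl$o1$W)
    if (has_edges) {
      dmsg <- ds[batch$ei, , drop = FALSE]
      aj <- cb$a[batch$ej, , drop = FALSE]
      da_edge <- dmsg * cb$Wfil
      dWfil <- dmsg * aj
      da <- .rowsum_full(da_edge, batch$ej, A)
      df2 <- dWfil * batch$fc
      dz2 <- df2 * ssp_grad(cb$z2)
      grads$blocks[[t]]$f2$W <- crossprod(cb$f1, dz2)
      grads$blocks[[t]]$f2$b <- colSums(dz2)
      df1 <- dz2 %*% t(bl$f2$W)
      dz1 <- df1 * ssp_grad(cb$z1)
      grads$blocks[[t]]$f1$W <- crossprod(batch$G, dz1)
      grads$blocks[[t]]$f1$b <- colSums(dz1)
    } else {
      da <- matrix(0, A, ncol(ds))
    }
    grads$blocks[[t]]$inl$W <- crossprod(cb$x_in, da)
    grads$blocks[[t]]$inl$b <- colSums(da)
    dx <- dx + da %*% t(bl$inl$W)
  }
  grads$emb <- .rowsum_full(dx, batch$zidx, nrow(p$emb))
  grads
}

#' Compute per-atom environment vectors (the AE tensor)
#'
#' @param mol a `molecule`; every element must be covered by `rep`.
#' @param rep an `aim_representation` from [rep_init()].
#' @return object of class `atom_environments`: field `values` is the
#'   M x n matrix of environment vectors, `config` the configuration used.
#' @examples
#' rep <- rep_init(rep_config(n = 8, n_interactions = 1, seed = 1), c(1, 8))
#' water <- molecule(c(8, 1, 1),
#'                   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' ae <- compute_environments(water, rep)
#' dim(ae$values)  # 3 x 8
#' @export
compute_environments <- function(mol, rep) {
  stopifnot(inherits(mol, "molecule"), inherits(rep, "aim_representation"))
  batch <- .make_batch(list(mol), rep)
  out <- .rep_forward(rep, batch)
  structure(list(values = out$x, config = rep$config),
            class = "atom_environments")
}
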