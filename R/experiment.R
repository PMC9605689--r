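# Inter-eye-design comparison: small-point localisation in a white world.
# Views of a black sphere are rendered through an eye design while the eye is
# moved around a sampling cube; an MLP is trained to recover the sphere's
# relative position from the view, and its error volume measures the
# task-specific utility of the design.

#' Generate view/position training pairs
#'
#' Places the eye (fixed, forward-facing orientation) at `n` positions drawn
#' uniformly inside a cube of side `cube_side` centred on a black sphere,
#' renders the compound view at each position, and pairs the single-channel
#' view vector with the sphere's position relative to the eye. Views are
#' single channel (mean of RGB) because the world is purely black and white.
#'
#' @param eye an [eye_description()].
#' @param n number of pairs.
#' @param cube_side side of the sampling cube, mm.
#' @param sphere_diameter target sphere diameter, mm.
#' @param cfg a [sampler_config()] used for every view.
#' @param seed seed for the pose draw (view sampling streams are keyed by
#'   `cfg$rng_seed` and the pair index).
#' @return a list of class `view_position_pairs` with `views` (n x
#'   n_ommatidia matrix in `[0, 1]`) and `rel_pos` (n x 3 matrix, mm,
#'   sphere centre relative to the eye).
#' @export
generate_dataset <- function(eye, n, cube_side = 50, sphere_diameter = 2,
                             cfg = sampler_config(32L), seed = 1L) {
  stopifnot(inherits(eye, "eye_description"), inherits(cfg, "sampler_config"))
  if (!is_number(n) || n < 1) stopf("n must be >= 1")
  if (!is_number(cube_side) || cube_side <= 0) stopf("cube_side must be positive")
  n <- as.integer(n)
  a <- build_accel(fixture_white_world_sphere(sphere_diameter))
  set.seed(seed)
  pos <- matrix(stats::runif(3L * n, -cube_side / 2, cube_side / 2), n, 3L)
  views <- matrix(0, n, n_ommatidia(eye))
  for (i in seq_len(n)) {
    v <- render_eye(a, eye, eye_pose(pos[i, ]), cfg, frame = i - 1L)
    views[i, ] <- rowMeans(v)
  }
  structure(list(views = views, rel_pos = -pos, eye_ref = eye$name,
                 cube_side = cube_side, sphere_diameter = sphere_diameter),
            class = "view_position_pairs")
}

#' Fit a z-score normaliser
#'
#' Per-dimension mean/SD standardisation for network inputs and outputs.
#' Dimensions with (near-)zero spread are flagged and passed through
#' unchanged.
#'
#' @param x input matrix (one row per sample).
#' @param y output matrix.
#' @return an object of class `normaliser`.
#' @export
fit_normaliser <- function(x, y) {
  stat <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    const <- !is.finite(sd) | sd < 1e-12
    sd[const] <- 1
    mu[const] <- 0
    list(mu = mu, sd = sd, const = const)
  }
  structure(list(x = stat(x), y = stat(y)), class = "normaliser")
}

#' Apply a fitted normaliser
#'
#' @param nz a [fit_normaliser()] result.
#' @param x,y matrices to standardise (either may be `NULL`).
#' @return a list with standardised `x` and `y`.
#' @export
apply_normaliser <- function(nz, x = NULL, y = NULL) {
  tr <- function(m, s) sweep(sweep(m, 2, s$mu), 2, s$sd, "/")
  list(x = if (!is.null(x)) tr(x, nz$x), y = if (!is.null(y)) tr(y, nz$y))
}

#' Invert the output side of a normaliser
#'
#' @param nz a [fit_normaliser()] result.
#' @param y_z standardised outputs (e.g. network predictions).
#' @return outputs on the original scale.
#' @export
invert_normaliser <- function(nz, y_z) {
  sweep(sweep(y_z, 2, nz$y$sd, "*"), 2, nz$y$mu, "+")
}

#' Initialise the localisation MLP
#'
#' Two ReLU hidden layers (1000 and 256 units by default) and a linear
#' 3-unit output; He-uniform weight initialisation.
#'
#' @param n_in input dimension (the eye's ommatidial count).
#' @param hidden hidden-layer widths.
#' @param n_out output dimension.
#' @param seed RNG seed for the weight draw.
#' @return an object of class `mlp_model`.
#' @export
mlp_init <- function(n_in, hidden = c(1000L, 256L), n_out = 3L, seed = 1L) {
  set.seed(seed)
  dims <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    r <- sqrt(6 / dims[l])
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -r, r),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  structure(list(W = W, b = b, dims = dims), class = "mlp_model")
}

mlp_forward <- function(model, X) {
  L <- length(model$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% model$W[[l]], 2, model$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  acts
}

#' Predict with the localisation MLP
#'
#' @param model an `mlp_model`.
#' @param X input matrix (one standardised view per row).
#' @return prediction matrix (standardised scale).
#' @export
mlp_predict <- function(model, X) {
  acts <- mlp_forward(model, X)
  acts[[length(acts)]]
}

#' Mean per-sample L1 loss
#'
#' The localisation objective: the sum over the three axes of the absolute
#' prediction error, averaged over samples.
#'
#' @param pred,target matrices of equal shape.
#' @return a scalar.
#' @export
mlp_l1 <- function(pred, target) mean(rowSums(abs(pred - target)))

#' Gradients of the L1 objective
#'
#' Backpropagated gradients of [mlp_l1()] with respect to every weight and
#' bias (subgradient `sign(error)` at the output).
#'
#' @param model an `mlp_model`.
#' @param X,Y a batch of inputs and targets.
#' @return a list with gradient lists `W` and `b` matching the model shapes.
#' @export
mlp_gradients <- function(model, X, Y) {
  L <- length(model$W)
  acts <- mlp_forward(model, X)
  delta <- sign(acts[[L + 1L]] - Y) / nrow(X)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(model$W[[l]])) * (acts[[l]] > 0)
  }
  list(W = gW, b = gb)
}

#' Train the localisation MLP
#'
#' Batched stochastic gradient descent on the mean per-sample L1 loss, with
#' a constant learning rate (the classical plain-SGD recipe; batch size 64
#' by default). Deterministic for a fixed seed.
#'
#' @param x,y standardised training inputs/targets (matrices, row = sample).
#' @param x_val,y_val optional validation set for the per-epoch error trace;
#'   when absent the trace is the training loss.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr learning rate.
#' @param seed RNG seed (weight initialisation and shuffling).
#' @param model optionally continue training an existing `mlp_model`.
#' @param hidden hidden widths used when `model` is `NULL`.
#' @return a list with the trained `model` and the per-epoch validation
#'   `trace` (mean per-sample L1, standardised scale).
#' @export
train_mlp <- function(x, y, x_val = NULL, y_val = NULL, epochs = 100L,
                      batch_size = 64L, lr = 1e-2, seed = 1L, model = NULL,
                      hidden = c(1000L, 256L)) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!nrow(x)) stopf("training set is empty")
  if (nrow(x) != nrow(y)) stopf("x and y must have matching rows")
  if (is.null(model)) model <- mlp_init(ncol(x), hidden, ncol(y), seed = seed)
  set.seed(seed + 1L)
  n <- nrow(x)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      g <- mlp_gradients(model, x[idx, , drop = FALSE], y[idx, , drop = FALSE])
      for (l in seq_along(model$W)) {
        model$W[[l]] <- model$W[[l]] - lr * g$W[[l]]
        model$b[[l]] <- model$b[[l]] - lr * g$b[[l]]
      }
    }
    trace[e] <- if (!is.null(x_val))
      mlp_l1(mlp_predict(model, x_val), y_val)
    else mlp_l1(mlp_predict(model, x), y)
  }
  list(model = model, trace = trace)
}

#' Directions within the eye's field of view
#'
#' A direction counts as inside the field of view when it lies within
#' `margin` of some ommatidial axis (default: the largest acceptance angle,
#' i.e. within roughly one acceptance cone of the sampled surface).
#'
#' @param eye an [eye_description()].
#' @param dirs m x 3 matrix of unit directions (eye-local frame).
#' @param margin angular margin, radians.
#' @return logical vector of length m.
#' @export
in_field_of_view <- function(eye, dirs, margin = NULL) {
  if (is.null(margin)) margin <- max(eye$ommatidia$acceptance)
  cp <- dirs %*% t(eye_axes(eye))
  apply(cp, 1, max) >= cos(margin)
}

#' Error volume of a trained localiser
#'
#' Evaluates the trained model on a regular `grid_n`^3 lattice of eye
#' positions spanning the sampling cube (corners and centre included),
#' rendering views live, and records the per-cell L1 error of the
#' denormalised prediction against the true relative position.
#'
#' @param model a trained `mlp_model`; alternatively, for validating the
#'   evaluation itself, a function `(views, positions) -> predictions` in
#'   millimetres that bypasses the network and normaliser (a perfect oracle
#'   returning the truth yields an all-zero volume).
#' @param nz the [fit_normaliser()] fitted on the model's training set
#'   (ignored for a function `model`).
#' @param eye the [eye_description()] the model was trained for.
#' @param grid_n lattice points per axis (odd values include the centre).
#' @param cube_side,sphere_diameter,cfg as in [generate_dataset()].
#' @param frame0 base frame index for the evaluation render streams.
#' @return an object of class `error_volume`: data frame `cells` with the
#'   cell positions, `l1` error (mm) and an `in_fov` flag, plus the lattice
#'   axes.
#' @export
error_volume <- function(model, nz, eye, grid_n = 11L, cube_side = 50,
                         sphere_diameter = 2, cfg = sampler_config(32L),
                         frame0 = 1e6) {
  ax <- seq(-cube_side / 2, cube_side / 2, length.out = grid_n)
  cells <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  a <- build_accel(fixture_white_world_sphere(sphere_diameter))
  n <- nrow(cells)
  views <- matrix(0, n, n_ommatidia(eye))
  for (i in seq_len(n)) {
    v <- render_eye(a, eye, eye_pose(cells[i, ]), cfg, frame = frame0 + i - 1L)
    views[i, ] <- rowMeans(v)
  }
  truth <- -cells
  pred <- if (is.function(model)) {
    model(views, cells)
  } else {
    invert_normaliser(nz, mlp_predict(model, apply_normaliser(nz, x = views)$x))
  }
  l1 <- rowSums(abs(pred - truth))
  d <- row_norms(truth)
  dirs <- truth / ifelse(d > 0, d, 1)
  fov <- in_field_of_view(eye, dirs) | d <= sphere_diameter / 2
  structure(list(cells = data.frame(cells, l1 = l1, in_fov = fov),
                 axes = ax, grid_n = grid_n, cube_side = cube_side,
                 eye_ref = eye$name),
            class = "error_volume")
}

#' Absolute difference of two error volumes
#'
#' Cell-wise `|a - b|` over identical lattices; the standard way to compare
#' where one eye design out-localises another.
#'
#' @param a,b [error_volume()]s on the same lattice.
#' @return an `error_volume`-shaped object whose `l1` holds the absolute
#'   difference.
#' @export
difference_volume <- function(a, b) {
  stopifnot(inherits(a, "error_volume"), inherits(b, "error_volume"))
  if (!isTRUE(all.equal(a$axes, b$axes)))
    stopf("error volumes are on different lattices")
  out <- a
  out$cells$l1 <- abs(a$cells$l1 - b$cells$l1)
  out$eye_ref <- paste(a$eye_ref, "vs", b$eye_ref)
  out
}

#' Top-down map of an error volume
#'
#' Reduces the volume over the z axis (mean by default), yielding the
#' x-y map used to display difference volumes from above.
#'
#' @param vol an [error_volume()].
#' @param reduce reduction function over z.
#' @return a matrix indexed `[x, y]`.
#' @export
top_down_map <- function(vol, reduce = mean) {
  stopifnot(inherits(vol, "error_volume"))
  with(vol$cells, tapply(l1, list(x = x, y = y), reduce))
}

#' Compare eye designs on the localisation task
#'
#' Builds the requested design variants of a labelled base eye ("real" keeps
#' the full 3D surface, "split" collapses each eye to its centre point,
#' "single" collapses everything to one point), generates a shared-pose
#' dataset per design, trains one localiser per design and evaluates error
#' volumes plus design-difference volumes against the "real" arm.
#'
#' @param base_eye a labelled [eye_description()] (see [make_paired_eye()]).
#' @param designs subset of `c("real", "split", "single")`.
#' @param n_train total pairs per design (split 80/20 into train/validation).
#' @param epochs training epochs.
#' @param cfg a [sampler_config()] for all renders.
#' @param cube_side,sphere_diameter experiment geometry, mm.
#' @param grid_n error-volume lattice points per axis.
#' @param lr,batch_size,hidden MLP hyperparameters.
#' @param seed master seed (poses, weights, shuffling).
#' @return a list of class `design_comparison`: per-design results (`model`,
#'   `trace`, `volume`, `normaliser`), difference volumes vs the "real" arm,
#'   and a `summary` data frame with final validation L1 (mm), in- and
#'   out-of-field error means and the no-information baseline.
#' @export
run_design_comparison <- function(base_eye,
                                  designs = c("real", "split", "single"),
                                  n_train = 2000L, epochs = 10L,
                                  cfg = sampler_config(32L),
                                  cube_side = 50, sphere_diameter = 2,
                                  grid_n = 7L, lr = 1e-2, batch_size = 64L,
                                  hidden = c(1000L, 256L), seed = 1L) {
  designs <- match.arg(designs, several.ok = TRUE)
  eyes <- list()
  for (d in designs)
    eyes[[d]] <- switch(d, real = base_eye,
                        split = collapse_to_split(base_eye),
                        single = collapse_to_single(base_eye))
  results <- list()
  summary <- NULL
  for (d in designs) {
    ds <- generate_dataset(eyes[[d]], n_train, cube_side, sphere_diameter,
                           cfg, seed = seed)        # shared poses across designs
    n_tr <- floor(0.8 * n_train)
    tr <- seq_len(n_tr)
    va <- setdiff(seq_len(n_train), tr)
    nz <- fit_normaliser(ds$views[tr, , drop = FALSE],
                         ds$rel_pos[tr, , drop = FALSE])
    z_tr <- apply_normaliser(nz, ds$views[tr, , drop = FALSE],
                             ds$rel_pos[tr, , drop = FALSE])
    z_va <- apply_normaliser(nz, ds$views[va, , drop = FALSE],
                             ds$rel_pos[va, , drop = FALSE])
    fit <- train_mlp(z_tr$x, z_tr$y, z_va$x, z_va$y, epochs = epochs,
                     batch_size = batch_size, lr = lr, seed = seed,
                     hidden = hidden)
    vol <- error_volume(fit$model, nz, eyes[[d]], grid_n, cube_side,
                        sphere_diameter, cfg)
    pred_mm <- invert_normaliser(nz, mlp_predict(fit$model, z_va$x))
    val_mm <- mlp_l1(pred_mm, ds$rel_pos[va, , drop = FALSE])
    cells <- vol$cells
    baseline <- mean(rowSums(abs(cells[cells$in_fov, c("x", "y", "z")])))
    summary <- rbind(summary, data.frame(
      design = d, n_ommatidia = n_ommatidia(eyes[[d]]),
      val_l1_mm = val_mm,
      in_fov_l1 = mean(cells$l1[cells$in_fov]),
      out_fov_l1 = if (any(!cells$in_fov)) mean(cells$l1[!cells$in_fov]) else NA_real_,
      baseline_l1 = baseline))
    results[[d]] <- list(eye = eyes[[d]], model = fit$model, trace = fit$trace,
                         normaliser = nz, volume = vol)
  }
  diffs <- list()
  if ("real" %in% designs)
    for (d in setdiff(designs, "real"))
      diffs[[d]] <- difference_volume(results$real$volume, results[[d]]$volume)
  structure(list(results = results, differences = diffs, summary = summary,
                 settings = list(n_train = n_train, epochs = epochs, lr = lr,
                                 batch_size = batch_size, seed = seed,
                                 cube_side = cube_side,
                                 sphere_diameter = sphere_diameter)),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("<design_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
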