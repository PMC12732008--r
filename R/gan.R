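#' Directed acyclic graph of clinical dependencies
#'
#' The DAG constrains generation: each variable's generator head only sees
#' its DAG parents, outcomes are terminal nodes (never used as conditioning
#' variables), and generation proceeds in topological order.
#'
#' @param nodes variable identifiers.
#' @param edges two-column character matrix (or list of `c(parent, child)`
#'   pairs).
#' @param terminal_outcomes subset of nodes with no outgoing edges.
#' @return an object of class `dag_spec`.
#' @export
dag_spec <- function(nodes, edges, terminal_outcomes = character(0)) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  stopifnot(all(edges %in% nodes), all(terminal_outcomes %in% nodes))
  if (any(edges[, "parent"] %in% terminal_outcomes)) {
    stop("terminal outcomes must have no outgoing edges", call. = FALSE)
  }
  dag <- structure(list(nodes = nodes, edges = edges,
                        terminal_outcomes = terminal_outcomes),
                   class = "dag_spec")
  topo_sort(dag)  # errors on cycles
  dag
}

dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, "child"] == node, "parent"])
}

topo_sort <- function(dag) {
  remaining <- dag$nodes
  order <- character(0)
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(v) {
      !any(dag_parents(dag, v) %in% remaining)
    }, logical(1))]
    if (!length(free)) stop("DAG contains a cycle", call. = FALSE)
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

#' Default clinical DAG for the USVT cohort
#'
#' Nodes are the five key covariates (site, treatment, age, sex, active
#' cancer) and the three modeled outcomes (recanalization, recurrence,
#' major bleeding) as terminal nodes. Age, sex, cancer and site feed
#' treatment choice; all five covariates feed each outcome.
#'
#' @return a `dag_spec`.
#' @export
default_dag <- function() {
  covs <- c("age", "sex", "active_cancer", "usvt_site")
  outcomes <- c("recanalization", "recurrence", "major_bleed")
  edges <- rbind(
    cbind(covs, "treatment"),
    do.call(rbind, lapply(outcomes, function(o) cbind(c(covs, "treatment"), o)))
  )
  dag_spec(nodes = c(covs, "treatment", outcomes), edges = edges,
           terminal_outcomes = outcomes)
}

#' Conditional GAN training configuration
#'
#' @param latent_dim dimension of the shared latent noise vector.
#' @param generator_widths,discriminator_widths hidden-layer sizes.
#' @param epochs training epochs.
#' @param batch_size discriminator minibatch size.
#' @param learning_rates named pair `c(generator=, discriminator=)` (Adam).
#' @param conditioning_vars covariates the generator is conditioned on;
#'   must exclude terminal outcomes.
#' @param convergence_window,convergence_tol window (epochs) and relative
#'   tolerance of the loss-stabilization criterion.
#' @param temperature softmax sampling temperature at generation time
#'   (< 1 sharpens categorical draws).
#' @param moment_weight weight of the conditional moment-matching penalty
#'   added to the adversarial generator loss (stabilizes marginals on
#'   small training tables).
#' @param domain_slack fractional widening of the training min/max range
#'   allowed for generated continuous values.
#' @param smoothing label smoothing applied to real discrete encodings on
#'   the discriminator side.
#' @param seed integer seed.
#' @return a list of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 8, generator_widths = 32,
                       discriminator_widths = 32, epochs = 2000,
                       batch_size = 32,
                       learning_rates = c(generator = 1e-3, discriminator = 1e-3),
                       conditioning_vars = c("usvt_site", "treatment", "age",
                                             "sex", "active_cancer"),
                       convergence_window = 100, convergence_tol = 0.05,
                       temperature = 1, moment_weight = 10,
                       domain_slack = 0.05, smoothing = 0.05, seed = NULL) {
  structure(list(latent_dim = latent_dim, generator_widths = generator_widths,
                 discriminator_widths = discriminator_widths, epochs = epochs,
                 batch_size = batch_size, learning_rates = learning_rates,
                 conditioning_vars = conditioning_vars,
                 convergence_window = convergence_window,
                 convergence_tol = convergence_tol, temperature = temperature,
                 moment_weight = moment_weight, domain_slack = domain_slack,
                 smoothing = smoothing, seed = seed),
            class = "gan_config")
}

## ---- encoding -------------------------------------------------------------

build_maps <- function(cohort, schema) {
  maps <- lapply(schema, function(s) {
    x <- cohort[[s$name]]
    if (s$kind == "continuous") {
      xx <- x[!is.na(x)]
      if (!length(xx)) xx <- 0
      sdv <- stats::sd(xx); if (!is.finite(sdv) || sdv == 0) sdv <- 1
      list(kind = "continuous", mean = mean(xx), sd = sdv,
           min = min(xx), max = max(xx), dim = 1L)
    } else if (s$kind == "binary") {
      list(kind = "binary", dim = 1L)
    } else {
      list(kind = "categorical", levels = s$levels, dim = length(s$levels))
    }
  })
  names(maps) <- names(schema)
  maps
}

encode_block <- function(x, map) {
  n <- length(x)
  switch(map$kind,
    continuous = {
      z <- (x - map$mean) / map$sd
      z[is.na(z)] <- 0
      matrix(z, ncol = 1)
    },
    binary = {
      z <- as.numeric(x); z[is.na(z)] <- 0
      matrix(z, ncol = 1)
    },
    categorical = {
      m <- matrix(0, n, length(map$levels))
      idx <- match(x, map$levels)
      ok <- which(!is.na(idx))
      m[cbind(ok, idx[ok])] <- 1
      m
    })
}

encode_vars <- function(data, maps, vars) {
  do.call(cbind, lapply(vars, function(v) encode_block(data[[v]], maps[[v]])))
}

var_col_index <- function(maps, vars) {
  dims <- vapply(vars, function(v) maps[[v]]$dim, integer(1))
  ends <- cumsum(dims)
  starts <- ends - dims + 1L
  stats::setNames(lapply(seq_along(vars), function(i) starts[i]:ends[i]), vars)
}

## ---- tiny MLP with manual gradients and Adam ------------------------------

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sc <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sc),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass; hidden layers are tanh, the output is returned pre-activation.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    H[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  list(out = H[[L + 1]], H = H)
}

# dOut is dL/d(pre-activation output); returns parameter grads and dL/dX.
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- dOut
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$H[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dH <- dZ %*% t(net$W[[l]])
    if (l > 1) dZ <- dH * (1 - fw$H[[l]]^2)
  }
  list(dW = dW, db = db, dX = dH)
}

adam_init <- function(net) {
  zeros <- function(x) lapply(x, function(m) m * 0)
  list(mW = zeros(net$W), vW = zeros(net$W),
       mb = zeros(net$b), vb = zeros(net$b), t = 0L)
}

adam_step <- function(net, state, grads, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

## ---- generator assembly ---------------------------------------------------

head_activation <- function(kind) {
  switch(kind, continuous = "linear", binary = "sigmoid", categorical = "softmax")
}

apply_activation <- function(Z, act) {
  switch(act,
    linear = Z,
    sigmoid = 1 / (1 + exp(-Z)),
    softmax = {
      E <- exp(Z - apply(Z, 1, max))
      E / rowSums(E)
    })
}

# dL/dA -> dL/dZ through the output activation (A = activated output).
activation_backward <- function(dA, A, act) {
  switch(act,
    linear = dA,
    sigmoid = dA * A * (1 - A),
    softmax = A * (dA - rowSums(dA * A)))
}

# Forward all generator heads in topological order for conditioning block C
# (encoded) and latent Z; returns the activated gen-part matrix and caches.
heads_forward <- function(heads, maps, gen_order, contexts, C_enc, cond_index,
                          Z, gen_index, cache = FALSE) {
  n <- nrow(Z)
  gen_dim <- sum(vapply(gen_order, function(v) maps[[v]]$dim, integer(1)))
  G <- matrix(0, n, gen_dim)
  caches <- if (cache) vector("list", length(gen_order)) else NULL
  if (cache) names(caches) <- gen_order
  lookup <- function(v) {
    if (v %in% names(cond_index)) C_enc[, cond_index[[v]], drop = FALSE]
    else G[, gen_index[[v]], drop = FALSE]
  }
  for (v in gen_order) {
    ctx <- contexts[[v]]
    Xin <- cbind(Z, if (length(ctx)) do.call(cbind, lapply(ctx, lookup)))
    fw <- mlp_forward(heads[[v]]$net, Xin)
    A <- apply_activation(fw$out, heads[[v]]$act)
    G[, gen_index[[v]]] <- A
    if (cache) caches[[v]] <- list(fw = fw, A = A)
  }
  list(G = G, caches = caches)
}

# Zero the structurally-missing encodings: TTR for non-VKA rows, DOAC agent
# for non-DOAC rows. `treatment` is a conditioning variable, so the mask is
# known at generation time.
structural_mask <- function(G, gen_index, treatment) {
  if ("ttr" %in% names(gen_index)) {
    G[treatment != "VKA", gen_index[["ttr"]]] <- 0
  }
  if ("doac_agent" %in% names(gen_index)) {
    G[treatment != "DOAC", gen_index[["doac_agent"]]] <- 0
  }
  G
}

bce_disc_grad <- function(p, y) (p - y) / length(p)  # d(BCE)/d(pre-activation)

## ---- training -------------------------------------------------------------

#' Train a DAG-informed conditional GAN on a cohort
#'
#' Trains one generator head per non-conditioning variable (multilayer
#' perceptrons over a shared latent vector plus the variable's DAG parents,
#' or the full conditioning set for variables outside the DAG) against a
#' shared discriminator, with alternating single-step Adam updates and a
#' binary cross-entropy objective. The generator loss additionally carries a
#' conditional moment-matching penalty (means of generated encodings and
#' their interactions with the conditioning one-hots, matched to the
#' training cohort), which anchors the arm-conditional marginals on
#' 90-row-scale tables. Outcomes are terminal DAG nodes and are generated,
#' never conditioned on. Deterministic given `config$seed`.
#'
#' @param cohort training `usvt_cohort` (non-empty).
#' @param dag a [dag_spec()]; nodes must be schema variables.
#' @param config a [gan_config()].
#' @return an object of class `cgan_model` with the trained heads,
#'   preprocessing maps, loss history and convergence flag.
#' @export
train_cgan <- function(cohort, dag = default_dag(), config = gan_config()) {
  schema <- schema_of(cohort)
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  stopifnot(all(dag$nodes %in% names(schema)))
  cond_vars <- config$conditioning_vars
  if (any(cond_vars %in% dag$terminal_outcomes)) {
    stop("conditioning variables must exclude terminal outcomes", call. = FALSE)
  }
  stopifnot(all(cond_vars %in% names(schema)))
  gen_vars <- setdiff(names(schema), cond_vars)

  # generation order: DAG topological order for DAG members, then the rest
  topo <- topo_sort(dag)
  gen_order <- c(intersect(topo, gen_vars), setdiff(gen_vars, topo))
  contexts <- lapply(gen_order, function(v) {
    if (v %in% dag$nodes) dag_parents(dag, v) else cond_vars
  })
  names(contexts) <- gen_order
  for (v in gen_order) {
    ok <- contexts[[v]] %in% c(cond_vars, gen_order[seq_len(match(v, gen_order) - 1)])
    if (!all(ok)) {
      stop("DAG parents of '", v, "' are not available before it is generated",
           call. = FALSE)
    }
  }

  maps <- build_maps(cohort, schema)
  cond_index <- var_col_index(maps, cond_vars)
  gen_index <- var_col_index(maps, gen_order)
  C_enc <- encode_vars(cohort, maps, cond_vars)
  G_real <- encode_vars(cohort, maps, gen_order)
  G_real <- structural_mask(G_real, gen_index, cohort$treatment)
  n <- nrow(cohort)

  # conditioning one-hot / binary columns used for interaction moments
  cond_cat_cols <- unlist(lapply(cond_vars, function(v) {
    if (maps[[v]]$kind %in% c("binary", "categorical")) cond_index[[v]] else integer(0)
  }))
  C_cat <- C_enc[, cond_cat_cols, drop = FALSE]
  cont_cols <- unlist(lapply(gen_order, function(v) {
    if (maps[[v]]$kind == "continuous") gen_index[[v]] else integer(0)
  }))
  # matched moments: marginal means, conditional means (interactions with
  # the conditioning one-hots), and second moments of continuous encodings
  mom_real <- c(colMeans(G_real),
                as.vector(crossprod(C_cat, G_real) / n),  # [C x g] flattened
                colMeans(G_real[, cont_cols, drop = FALSE]^2))

  discrete_cols <- unlist(lapply(gen_order, function(v) {
    if (maps[[v]]$kind != "continuous") gen_index[[v]] else integer(0)
  }))
  eps <- config$smoothing
  G_real_sm <- G_real
  G_real_sm[, discrete_cols] <- G_real_sm[, discrete_cols] * (1 - 2 * eps) + eps

  with_seed(config$seed, {
    heads <- lapply(gen_order, function(v) {
      in_dim <- config$latent_dim +
        sum(vapply(contexts[[v]], function(p) maps[[p]]$dim, integer(1)))
      list(net = mlp_init(c(in_dim, config$generator_widths, maps[[v]]$dim)),
           act = head_activation(maps[[v]]$kind))
    })
    names(heads) <- gen_order
    D_dim <- ncol(C_enc) + ncol(G_real)
    disc <- mlp_init(c(D_dim, config$discriminator_widths, 1))
    g_state <- lapply(heads, function(h) adam_init(h$net))
    d_state <- adam_init(disc)
    lr_g <- config$learning_rates[["generator"]]
    lr_d <- config$learning_rates[["discriminator"]]

    loss_g <- loss_d <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      # alternating single-step updates: one discriminator minibatch step,
      # then one full-table generator step
      {
        idx <- sample.int(n, min(config$batch_size, n))
        bn <- length(idx)
        Z <- matrix(stats::rnorm(bn * config$latent_dim), bn)
        fake <- heads_forward(heads, maps, gen_order, contexts,
                              C_enc[idx, , drop = FALSE], cond_index, Z, gen_index)$G
        fake <- structural_mask(fake, gen_index, cohort$treatment[idx])
        Xr <- cbind(C_enc[idx, , drop = FALSE], G_real_sm[idx, , drop = FALSE])
        Xf <- cbind(C_enc[idx, , drop = FALSE], fake)
        fw <- mlp_forward(disc, rbind(Xr, Xf))
        p <- 1 / (1 + exp(-fw$out))
        y <- c(rep(1, bn), rep(0, bn))
        d_loss <- -mean(y * log(pmax(p, 1e-12)) +
                        (1 - y) * log(pmax(1 - p, 1e-12)))
        grads <- mlp_backward(disc, fw, bce_disc_grad(p, y))
        upd <- adam_step(disc, d_state, grads, lr_d)
        disc <- upd$net; d_state <- upd$state
      }

      # generator step on the full table (adversarial + moment matching)
      Z <- matrix(stats::rnorm(n * config$latent_dim), n)
      hf <- heads_forward(heads, maps, gen_order, contexts, C_enc, cond_index,
                          Z, gen_index, cache = TRUE)
      G_fake <- structural_mask(hf$G, gen_index, cohort$treatment)
      Xf <- cbind(C_enc, G_fake)
      fw <- mlp_forward(disc, Xf)
      p <- 1 / (1 + exp(-fw$out))
      adv_loss <- -mean(log(pmax(p, 1e-12)))
      dZ_disc <- (p - 1) / n                       # d(-mean log p)/d preact
      dX <- mlp_backward(disc, fw, dZ_disc)$dX
      dG <- dX[, ncol(C_enc) + seq_len(ncol(G_fake)), drop = FALSE]

      mom_fake <- c(colMeans(G_fake), as.vector(crossprod(C_cat, G_fake) / n),
                    colMeans(G_fake[, cont_cols, drop = FALSE]^2))
      diff <- mom_fake - mom_real
      g <- ncol(G_fake)
      n_int <- ncol(C_cat) * g
      d_base <- matrix(diff[seq_len(g)], n, g, byrow = TRUE)
      Dint <- matrix(diff[g + seq_len(n_int)], nrow = ncol(C_cat))  # [C x g]
      dG_mom <- (2 / n) * (d_base + C_cat %*% Dint)
      if (length(cont_cols)) {
        d_sq <- diff[g + n_int + seq_along(cont_cols)]
        dG_mom[, cont_cols] <- dG_mom[, cont_cols] +
          (2 / n) * sweep(2 * G_fake[, cont_cols, drop = FALSE], 2, d_sq, "*")
      }
      dG <- dG + config$moment_weight * dG_mom
      dG <- structural_mask(dG, gen_index, cohort$treatment)

      for (v in gen_order) {
        hd <- heads[[v]]
        cache <- hf$caches[[v]]
        dA <- dG[, gen_index[[v]], drop = FALSE]
        dZh <- activation_backward(dA, cache$A, hd$act)
        grads <- mlp_backward(hd$net, cache$fw, dZh)
        upd <- adam_step(hd$net, g_state[[v]], grads, lr_g)
        heads[[v]]$net <- upd$net
        g_state[[v]] <- upd$state
      }
      loss_g[epoch] <- adv_loss
      loss_d[epoch] <- d_loss
    }

    loss_history <- data.frame(epoch = seq_len(config$epochs),
                               generator = loss_g, discriminator = loss_d)
    converged <- tryCatch(
      check_convergence(loss_history, config$convergence_window,
                        config$convergence_tol),
      error = function(e) FALSE)
    if (!converged) {
      warning("CGAN loss did not stabilize within ", config$epochs,
              " epochs (flagged, see $converged)", call. = FALSE)
    }

    structure(list(
      heads = heads, disc = disc, maps = maps, schema = schema,
      cond_vars = cond_vars, gen_order = gen_order, contexts = contexts,
      cond_index = cond_index, gen_index = gen_index,
      dag = dag, config = config, loss_history = loss_history,
      converged = converged, seed = config$seed,
      train_cond = as.data.frame(cohort)[cond_vars],
      train_data = as.data.frame(cohort), n_train = n
    ), class = "cgan_model")
  })
}

#' @export
print.cgan_model <- function(x, ...) {
  cat("<cgan_model> trained on ", x$n_train, " records\n", sep = "")
  cat("  conditioning: ", paste(x$cond_vars, collapse = ", "), "\n", sep = "")
  cat("  generated:    ", length(x$gen_order), " variables, ",
      x$config$epochs, " epochs, ",
      if (x$converged) "loss stabilized" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Conditioning context of a generator head
#'
#' Exposes the input wiring of the generator: which variables a given head
#' is allowed to see. For DAG members this is exactly the set of DAG
#' parents.
#'
#' @param model a `cgan_model`.
#' @param variable a generated variable name.
#' @return character vector of context variable names.
#' @export
head_context <- function(model, variable) {
  if (!variable %in% model$gen_order) {
    stop("'", variable, "' is not a generated variable", call. = FALSE)
  }
  model$contexts[[variable]]
}

#' Loss-stabilization convergence check
#'
#' Applies a trailing moving average of length `window` to each loss series
#' and declares convergence when the relative oscillation (range over the
#' final `window` smoothed values divided by their mean magnitude) is at
#' most `tol` for both generator and discriminator.
#'
#' @param loss_history data.frame with `generator` and `discriminator`
#'   columns (as stored in a `cgan_model`), or a single numeric series.
#' @param window smoothing / assessment window in epochs.
#' @param tol relative tolerance.
#' @return `TRUE` iff both losses have stabilized.
#' @export
check_convergence <- function(loss_history, window = 100, tol = 0.05) {
  series <- if (is.data.frame(loss_history)) {
    list(loss_history$generator, loss_history$discriminator)
  } else list(as.numeric(loss_history))
  stable <- vapply(series, function(x) {
    if (length(x) < window) {
      stop("insufficient history: ", length(x), " < window ", window, call. = FALSE)
    }
    ma <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
    ma <- ma[!is.na(ma)]
    last <- utils::tail(ma, window)
    m <- mean(abs(last))
    if (m == 0) return(TRUE)
    (max(last) - min(last)) / m <= tol
  }, logical(1))
  all(stable)
}

## ---- generation -----------------------------------------------------------

sample_categorical <- function(P, levels, temperature) {
  Q <- P^(1 / temperature)
  Q <- Q / rowSums(Q)
  vapply(seq_len(nrow(Q)), function(i) {
    sample(levels, 1L, prob = Q[i, ])
  }, character(1))
}

sharpen_binary <- function(p, temperature) {
  a <- p^(1 / temperature); b <- (1 - p)^(1 / temperature)
  a / (a + b)
}

#' Generate digital twins from a trained model
#'
#' Draws `n` synthetic records. By default (the 1:1 twin setting) the
#' conditioning covariates are reused from the training rows, which
#' guarantees the conditioned marginals match the source exactly; for other
#' `n` the conditioning rows are resampled from the training set. Supplied
#' `conditions` are hard constraints: every generated record carries the
#' requested level. Generated continuous values are clipped to the training
#' range widened by the configured slack; categorical draws use
#' softmax-with-temperature sampling. Terminal outcomes are generated
#' jointly with the covariates and can never be conditioned on.
#'
#' @param model a `cgan_model`.
#' @param n number of twins (default: training size).
#' @param conditions optional named list/level map over conditioning
#'   variables.
#' @param seed integer seed.
#' @return a `usvt_cohort` of `n` records.
#' @export
generate_twins <- function(model, n = model$n_train, conditions = NULL,
                           seed = NULL) {
  schema <- model$schema
  if (!is.null(conditions)) {
    bad <- setdiff(names(conditions), model$cond_vars)
    if (length(bad)) {
      stop("contract error: cannot condition on non-conditioning variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (n == 0) {
    empty <- as.data.frame(model$train_data)[0, , drop = FALSE]
    return(as_cohort(empty, schema, label = "digital twins (empty)"))
  }
  with_seed(seed, {
    cond <- if (n == model$n_train) model$train_cond
            else model$train_cond[sample.int(model$n_train, n, replace = TRUE), ,
                                  drop = FALSE]
    rownames(cond) <- NULL
    for (v in names(conditions)) cond[[v]] <- conditions[[v]]

    C_enc <- encode_vars(cond, model$maps, model$cond_vars)
    Z <- matrix(stats::rnorm(n * model$config$latent_dim), n)
    G <- heads_forward(model$heads, model$maps, model$gen_order, model$contexts,
                       C_enc, model$cond_index, Z, model$gen_index)$G

    out <- cond
    temp <- model$config$temperature
    for (v in model$gen_order) {
      map <- model$maps[[v]]
      A <- G[, model$gen_index[[v]], drop = FALSE]
      out[[v]] <- switch(map$kind,
        continuous = {
          x <- round(A[, 1] * map$sd + map$mean, 1)
          slack <- model$config$domain_slack * (map$max - map$min)
          pmin(pmax(x, map$min - slack), map$max + slack)
        },
        binary = as.integer(stats::runif(n) < sharpen_binary(A[, 1], temp)),
        categorical = sample_categorical(A, map$levels, temp))
    }
    out$ttr[out$treatment != "VKA"] <- NA_real_
    out$doac_agent[out$treatment != "DOAC"] <- NA_character_
    if (!is.null(out$age)) out$age <- pmax(out$age, 18)
    if (!is.null(out$follow_up)) out$follow_up <- pmax(out$follow_up, 0)
    as_cohort(out[names(schema)], schema, label = "digital twins")
  })
}

#' Train replicated digital-twin cohorts under controlled seeds
#'
#' Repeats the train-and-generate cycle `n_replicas` times, each with the
#' deterministic seed `seed_base + replica index`, producing independent 1:1
#' twin cohorts for reproducibility assessment.
#'
#' @param cohort training cohort.
#' @param dag a [dag_spec()].
#' @param config a [gan_config()]; its seed field is overridden per replica.
#' @param n_replicas number of replicas (>= 1).
#' @param seed_base base seed.
#' @return an object of class `twin_replicas`: list with `twins` (list of
#'   cohorts), `models`, and `seeds`.
#' @export
replicate_twins <- function(cohort, dag = default_dag(), config = gan_config(),
                            n_replicas = 10, seed_base = 1L) {
  stopifnot(n_replicas >= 1)
  seeds <- seed_base + seq_len(n_replicas)
  models <- vector("list", n_replicas)
  twins <- vector("list", n_replicas)
  for (i in seq_len(n_replicas)) {
    cfg <- config
    cfg$seed <- seeds[i]
    models[[i]] <- train_cgan(cohort, dag, cfg)
    twins[[i]] <- generate_twins(models[[i]], seed = derive_seed(seeds[i], 1L))
  }
  structure(list(twins = twins, models = models, seeds = seeds),
            class = "twin_replicas")
}

#' Summarize fidelity across twin replicas
#'
#' @param object a `twin_replicas`.
#' @param reference the training cohort the replicas emulate.
#' @param variables variables entering the MASMD (default as in
#'   [fidelity_report()]).
#' @param ... unused.
#' @return data.frame with one row per replica (MASMD and its SD) plus the
#'   across-replica mean and SD as attributes `masmd_mean` / `masmd_sd`.
#' @export
summary.twin_replicas <- function(object, reference, variables = NULL, ...) {
  schema <- schema_of(reference)
  variables <- variables %||% setdiff(names(schema), c("doac_agent", "ttr"))
  rows <- lapply(seq_along(object$twins), function(i) {
    m <- masmd(reference, object$twins[[i]], variables, schema)
    data.frame(replica = i, seed = object$seeds[i],
               masmd = m$masmd, masmd_sd = m$sd)
  })
  out <- do.call(rbind, rows)
  attr(out, "masmd_mean") <- mean(out$masmd)
  attr(out, "masmd_sd") <- stats::sd(out$masmd)
  out
}
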