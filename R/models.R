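# Model specifications, parameter initialization, the named-layer
# registry, and the forward/backward passes of the three architectures:
#
#  * bigraph      — GCN drug branch + embedding/BiLSTM protein branch,
#                   fused by a fully connected head (the hybrid model);
#  * graphdta_gcn — same drug branch, single 1D-convolution protein branch;
#  * deepdta      — two parallel embedding + 3-convolution token branches
#                   (drug SMILES characters, protein residues).

#' Model specification
#'
#' Declarative description of an architecture.  Dimensions default to the
#' published configuration: 78-dim atom features, three GCN layers with
#' widths `(C, 2C, 4C)`, 128-dim embeddings, BiLSTM hidden size 128 per
#' direction, branch outputs of 128, and a 1024/512 fully connected head.
#'
#' @param family `"bigraph"`, `"graphdta_gcn"`, or `"deepdta"`.
#' @param atom_dim Atom feature length `C` (graph families).
#' @param n_gcn_layers Number of graph-convolution layers (2, 3 or 4).
#' @param gcn_widths Output widths of the GCN layers; default
#'   `atom_dim * c(1, 2, 4, 4)[1:n_gcn_layers]`.
#' @param fc_g1_dim,fc_g2_dim Drug-branch fully connected widths.
#' @param embed_dim Token embedding dimension.
#' @param bilstm_hidden BiLSTM hidden size per direction (bigraph).
#' @param bilstm_mode `"flatten"` passes all position-wise BiLSTM outputs
#'   (length `2 * hidden * L`) to `fc1_xt`; `"last_hidden"` concatenates
#'   the two directions' final states over each sequence's non-pad prefix.
#' @param conv_filters,conv_kernel Protein 1D-convolution shape
#'   (graphdta_gcn) and base filter count / kernel of both token branches
#'   (deepdta, where the three layers use `f`, `2f`, `3f` filters).
#' @param fc1_xt_dim Protein-branch output width.
#' @param head_dims Widths of head layers `fc1`, `fc2` (graph families) or
#'   `fc1`, `fc2`, `fc3` (deepdta; default `c(1024, 1024, 512)`).
#' @param dropout_rate Dropout rate (0.2 for graph families, 0.1 for
#'   deepdta).
#' @param extra_head_layers 0 or 2 additional fully connected layers
#'   (`extra_head_1`, `extra_head_2`) before the output layer.
#' @param extra_head_dim Width of those layers.
#' @param fc3_dim If > 0, an additional `fc3` layer of this width after
#'   `fc2` (graph families; used by the deeper-architecture ablation).
#' @param extra_protein_conv Add a second protein convolution
#'   (graphdta_gcn ablation).
#' @param drop_fc2 Remove `fc2` from the head (shallower ablation).
#' @param seq_len Protein token length `L`.
#' @param vocab_size Protein vocabulary size `V`.
#' @param smiles_len,smiles_vocab_size SMILES token length and vocabulary
#'   size (deepdta).
#' @return Object of class `dta_model_spec`.
#' @export
model_spec <- function(family = c("bigraph", "graphdta_gcn", "deepdta"),
                       atom_dim = 78L,
                       n_gcn_layers = 3L,
                       gcn_widths = NULL,
                       fc_g1_dim = 1024L,
                       fc_g2_dim = 128L,
                       embed_dim = 128L,
                       bilstm_hidden = 128L,
                       bilstm_mode = c("flatten", "last_hidden"),
                       conv_filters = 32L,
                       conv_kernel = 8L,
                       fc1_xt_dim = 128L,
                       head_dims = NULL,
                       dropout_rate = NULL,
                       extra_head_layers = 0L,
                       extra_head_dim = 512L,
                       fc3_dim = 0L,
                       extra_protein_conv = FALSE,
                       drop_fc2 = FALSE,
                       seq_len = 1000L,
                       vocab_size = 25L,
                       smiles_len = 100L,
                       smiles_vocab_size = NULL) {
  family <- match.arg(family)
  bilstm_mode <- match.arg(bilstm_mode)
  if (is.null(head_dims)) {
    head_dims <- if (family == "deepdta") c(1024L, 1024L, 512L) else c(1024L, 512L)
  }
  if (is.null(dropout_rate)) {
    dropout_rate <- if (family == "deepdta") 0.1 else 0.2
  }
  if (!(n_gcn_layers %in% 2:4)) stop_config("n_gcn_layers must be 2, 3 or 4")
  if (!(extra_head_layers %in% c(0L, 2L))) {
    stop_config("extra_head_layers must be 0 or 2")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate must be in [0, 1)")
  }
  if (is.null(gcn_widths)) {
    gcn_widths <- as.integer(atom_dim) * c(1L, 2L, 4L, 4L)[seq_len(n_gcn_layers)]
  }
  if (length(gcn_widths) != n_gcn_layers) {
    stop_config("gcn_widths length must equal n_gcn_layers")
  }
  structure(
    list(
      family = family, atom_dim = as.integer(atom_dim),
      n_gcn_layers = as.integer(n_gcn_layers),
      gcn_widths = as.integer(gcn_widths),
      fc_g1_dim = as.integer(fc_g1_dim), fc_g2_dim = as.integer(fc_g2_dim),
      embed_dim = as.integer(embed_dim),
      bilstm_hidden = as.integer(bilstm_hidden), bilstm_mode = bilstm_mode,
      conv_filters = as.integer(conv_filters),
      conv_kernel = as.integer(conv_kernel),
      fc1_xt_dim = as.integer(fc1_xt_dim),
      head_dims = as.integer(head_dims), dropout_rate = dropout_rate,
      extra_head_layers = as.integer(extra_head_layers),
      extra_head_dim = as.integer(extra_head_dim),
      fc3_dim = as.integer(fc3_dim),
      extra_protein_conv = isTRUE(extra_protein_conv),
      drop_fc2 = isTRUE(drop_fc2),
      seq_len = as.integer(seq_len), vocab_size = as.integer(vocab_size),
      smiles_len = as.integer(smiles_len),
      smiles_vocab_size = if (is.null(smiles_vocab_size)) NULL else as.integer(smiles_vocab_size)
    ),
    class = "dta_model_spec"
  )
}

#' Desk-scale model specification
#'
#' A small configuration (protein length 100, hidden size 32, 128/64
#' head) used for fast experiments and the package's own test suite.
#'
#' @param family Model family, as in [model_spec()].
#' @param seq_len Protein token length.
#' @param dropout_rate Dropout rate (default 0.1).
#' @param ... Further overrides passed to [model_spec()].
#' @return A `dta_model_spec`.
#' @export
model_spec_small <- function(family = "bigraph", seq_len = 100L,
                             dropout_rate = 0.1, ...) {
  model_spec(
    family = family,
    gcn_widths = c(32L, 32L, 64L)[seq_len(3L)],
    fc_g1_dim = 64L, fc_g2_dim = 32L,
    embed_dim = 16L, bilstm_hidden = 32L,
    conv_filters = 8L, conv_kernel = 8L,
    fc1_xt_dim = 32L,
    head_dims = if (family == "deepdta") c(128L, 128L, 64L) else c(128L, 64L),
    dropout_rate = dropout_rate,
    seq_len = as.integer(seq_len),
    ...
  )
}

# Flattened protein-branch width entering fc1_xt.
.protein_flat_dim <- function(spec) {
  if (spec$family == "bigraph") {
    if (spec$bilstm_mode == "flatten") {
      2L * spec$bilstm_hidden * spec$seq_len
    } else {
      2L * spec$bilstm_hidden
    }
  } else {
    L1 <- spec$seq_len - spec$conv_kernel + 1L
    if (spec$extra_protein_conv) {
      L2 <- L1 - spec$conv_kernel + 1L
      spec$conv_filters * L2
    } else {
      spec$conv_filters * L1
    }
  }
}

# Ordered head plan: layer group name, output width, whether dropout
# follows the ReLU.  The output layer is always linear.
.head_plan <- function(spec) {
  plan <- list()
  add <- function(plan, name, dim, dropout) {
    c(plan, list(list(name = name, dim = dim, dropout = dropout)))
  }
  plan <- add(plan, "fc1", spec$head_dims[1], TRUE)
  if (spec$family == "deepdta") {
    plan <- add(plan, "fc2", spec$head_dims[2], TRUE)
    plan <- add(plan, "fc3", spec$head_dims[3], FALSE)
  } else {
    if (!spec$drop_fc2) plan <- add(plan, "fc2", spec$head_dims[2], TRUE)
    if (spec$fc3_dim > 0) plan <- add(plan, "fc3", spec$fc3_dim, FALSE)
    if (spec$extra_head_layers == 2L) {
      plan <- add(plan, "extra_head_1", spec$extra_head_dim, TRUE)
      plan <- add(plan, "extra_head_2", spec$extra_head_dim, TRUE)
    }
  }
  plan
}

#' Build a model from a specification
#'
#' Initializes all parameters deterministically under `seed` (Glorot
#' uniform weights, zero biases, forget-gate biases 1) and assembles the
#' named-layer registry used by regularization selectors and freeze
#' policies.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give bitwise
#'   identical parameters.
#' @param meta Optional featurization metadata (atom scheme, vocabularies,
#'   token lengths) persisted with checkpoints.
#' @return Object of class `dta_model`: `spec`, `params` (named list of
#'   matrices/vectors, names `<group>.<tensor>`), `registry` (group ->
#'   parameter names), `head_plan`, `seed`, `meta`.
#' @export
build_model <- function(spec, seed = 1L, meta = NULL) {
  params <- list()
  dense_init <- function(name, in_dim, out_dim) {
    params[[paste0(name, ".W")]] <<- glorot_uniform(in_dim, out_dim)
    params[[paste0(name, ".b")]] <<- numeric(out_dim)
  }
  with_seed(seed, {
    if (spec$family %in% c("bigraph", "graphdta_gcn")) {
      in_dim <- spec$atom_dim
      for (l in seq_len(spec$n_gcn_layers)) {
        dense_init(paste0("gcn", l), in_dim, spec$gcn_widths[l])
        in_dim <- spec$gcn_widths[l]
      }
      dense_init("fc_g1", in_dim, spec$fc_g1_dim)
      dense_init("fc_g2", spec$fc_g1_dim, spec$fc_g2_dim)
      params[["embed_xt.W"]] <- glorot_uniform(
        spec$vocab_size + 1L, spec$embed_dim,
        dims = c(spec$vocab_size + 1L, spec$embed_dim)
      )
      if (spec$family == "bigraph") {
        for (dir in c("fwd", "bwd")) {
          ini <- lstm_init(spec$embed_dim, spec$bilstm_hidden)
          params[[paste0("protein_core.", dir, ".Wx")]] <- ini$Wx
          params[[paste0("protein_core.", dir, ".Wh")]] <- ini$Wh
          params[[paste0("protein_core.", dir, ".b")]] <- ini$b
        }
      } else {
        kE <- spec$conv_kernel * spec$embed_dim
        params[["protein_core.conv1.W"]] <- glorot_uniform(kE, spec$conv_filters)
        params[["protein_core.conv1.b"]] <- numeric(spec$conv_filters)
        if (spec$extra_protein_conv) {
          kF <- spec$conv_kernel * spec$conv_filters
          params[["protein_core.conv2.W"]] <- glorot_uniform(kF, spec$conv_filters)
          params[["protein_core.conv2.b"]] <- numeric(spec$conv_filters)
        }
      }
      dense_init("fc1_xt", .protein_flat_dim(spec), spec$fc1_xt_dim)
      head_in <- spec$fc_g2_dim + spec$fc1_xt_dim
    } else {
      if (is.null(spec$smiles_vocab_size)) {
        stop_config("deepdta spec requires smiles_vocab_size")
      }
      params[["embed_xd.W"]] <- glorot_uniform(
        spec$smiles_vocab_size + 1L, spec$embed_dim,
        dims = c(spec$smiles_vocab_size + 1L, spec$embed_dim)
      )
      params[["embed_xt.W"]] <- glorot_uniform(
        spec$vocab_size + 1L, spec$embed_dim,
        dims = c(spec$vocab_size + 1L, spec$embed_dim)
      )
      f <- spec$conv_filters
      k <- spec$conv_kernel
      for (br in c("drug_core", "protein_core")) {
        dims <- c(spec$embed_dim, f, 2L * f, 3L * f)
        for (cl in 1:3) {
          params[[paste0(br, ".conv", cl, ".W")]] <-
            glorot_uniform(k * dims[cl], dims[cl + 1L])
          params[[paste0(br, ".conv", cl, ".b")]] <- numeric(dims[cl + 1L])
        }
      }
      head_in <- 2L * 3L * f
    }
    plan <- .head_plan(spec)
    for (layer in plan) {
      dense_init(layer$name, head_in, layer$dim)
      head_in <- layer$dim
    }
    dense_init("out", head_in, 1L)
  })
  groups <- sub("\\..*$", "", names(params))
  registry <- split(names(params), factor(groups, levels = unique(groups)))
  structure(
    list(
      spec = spec, params = params, registry = registry,
      head_plan = .head_plan(spec), seed = as.integer(seed), meta = meta
    ),
    class = "dta_model"
  )
}

#' Named-layer registry of a model
#'
#' @param model A [build_model()] result.
#' @return Named list mapping layer-group names (`gcn1`, `fc_g1`,
#'   `embed_xt`, `protein_core`, `fc1_xt`, `fc1`, `fc2`, `out`, ...) to
#'   the parameter names they own.
#' @export
layer_registry <- function(model) model$registry

#' Total trainable parameter count
#'
#' @param model A `dta_model`.
#' @return Integer parameter count (a pure function of the spec).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- batching ----------------------------------------------------------

# Ensure per-graph normalized adjacencies are cached on the featurized set.
.with_adjacency <- function(fz) {
  if (is.null(fz$adj)) {
    fz$adj <- lapply(fz$graphs, normalize_adjacency)
  }
  fz
}

# Assemble one mini-batch: block-diagonal sparse adjacency, stacked node
# features, node-to-graph index, token matrices, labels.
prepare_batch <- function(fz, idx) {
  B <- length(idx)
  graphs <- fz$graphs[idx]
  adjs <- fz$adj[idx]
  n_nodes <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offset <- c(0L, cumsum(n_nodes))
  ii <- vector("list", B)
  jj <- vector("list", B)
  xx <- vector("list", B)
  for (g in seq_len(B)) {
    a <- adjs[[g]]
    ii[[g]] <- c(a$edges[, 1] + 1L, seq_len(a$n)) + offset[g]
    jj[[g]] <- c(a$edges[, 2] + 1L, seq_len(a$n)) + offset[g]
    xx[[g]] <- c(a$edge_coef, a$self_coef)
  }
  total <- offset[B + 1L]
  A_hat <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(total, total)
  )
  H0 <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  tokens <- fz$tokens[idx, , drop = FALSE]
  list(
    B = B, A_hat = A_hat, H0 = H0,
    graph_index = rep(seq_len(B), times = n_nodes),
    tokens = tokens,
    lengths = pmax(1L, as.integer(rowSums(tokens > 0))),
    smiles_tokens = if (!is.null(fz$smiles_tokens)) {
      fz$smiles_tokens[idx, , drop = FALSE]
    },
    labels = fz$labels[idx]
  )
}

# Per-sample prefix reversal permutation for the masked last-hidden
# backward direction: positions 1..len are reversed, pads stay in place.
.prefix_reverse_perm <- function(lengths, B, L) {
  perm <- integer(L * B)
  for (b in seq_len(B)) {
    len <- min(lengths[b], L)
    src <- c(rev(seq_len(len)), if (len < L) (len + 1L):L)
    perm[(seq_len(L) - 1L) * B + b] <- (src - 1L) * B + b
  }
  perm
}

# ---- forward/backward: graph families ---------------------------------

.head_forward <- function(params, plan, X, rate, training) {
  caches <- vector("list", length(plan))
  for (k in seq_along(plan)) {
    nm <- plan[[k]]$name
    d <- dense_forward(X, params[[paste0(nm, ".W")]], params[[paste0(nm, ".b")]])
    r <- relu_forward(d$Y)
    dr <- dropout_forward(r$Y, if (plan[[k]]$dropout) rate else 0, training)
    caches[[k]] <- list(dense = d, relu = r, drop = dr)
    X <- dr$Y
  }
  o <- dense_forward(X, params[["out.W"]], params[["out.b"]])
  list(yhat = as.vector(o$Y), caches = caches, out = o)
}

.head_backward <- function(params, plan, cache, dy) {
  grads <- list()
  db <- dense_backward(cache$out, params[["out.W"]], matrix(dy, ncol = 1))
  grads[["out.W"]] <- db$dW
  grads[["out.b"]] <- db$db
  dX <- db$dX
  for (k in rev(seq_along(plan))) {
    nm <- plan[[k]]$name
    ck <- cache$caches[[k]]
    dX <- dropout_backward(ck$drop, dX)
    dX <- relu_backward(ck$relu, dX)
    db <- dense_backward(ck$dense, params[[paste0(nm, ".W")]], dX)
    grads[[paste0(nm, ".W")]] <- db$dW
    grads[[paste0(nm, ".b")]] <- db$db
    dX <- db$dX
  }
  list(grads = grads, dX = dX)
}

.forward_graph_family <- function(model, batch, training) {
  p <- model$params
  spec <- model$spec
  rate <- spec$dropout_rate
  B <- batch$B
  L <- spec$seq_len

  # drug branch: GCN stack -> pooled graph vector -> fc_g1 -> fc_g2
  H <- batch$H0
  gcn_caches <- vector("list", spec$n_gcn_layers)
  for (l in seq_len(spec$n_gcn_layers)) {
    gc <- gcn_layer_forward(
      batch$A_hat, H,
      p[[paste0("gcn", l, ".W")]], p[[paste0("gcn", l, ".b")]]
    )
    gcn_caches[[l]] <- gc
    H <- gc$Y
  }
  pool <- graph_max_pool_forward(H, batch$graph_index, B)
  dg1 <- dense_forward(pool$Y, p[["fc_g1.W"]], p[["fc_g1.b"]])
  rg1 <- relu_forward(dg1$Y)
  og1 <- dropout_forward(rg1$Y, rate, training)
  dg2 <- dense_forward(og1$Y, p[["fc_g2.W"]], p[["fc_g2.b"]])
  og2 <- dropout_forward(dg2$Y, rate, training)
  drug_vec <- og2$Y

  # protein branch
  emb <- embedding_forward(batch$tokens, p[["embed_xt.W"]])
  if (spec$family == "bigraph") {
    pp <- list(
      fwd.Wx = p[["protein_core.fwd.Wx"]], fwd.Wh = p[["protein_core.fwd.Wh"]],
      fwd.b = p[["protein_core.fwd.b"]],
      bwd.Wx = p[["protein_core.bwd.Wx"]], bwd.Wh = p[["protein_core.bwd.Wh"]],
      bwd.b = p[["protein_core.bwd.b"]]
    )
    if (spec$bilstm_mode == "flatten") {
      bl <- bilstm_flat_forward_cpp(
        emb$Y, pp$fwd.Wx, pp$fwd.Wh, pp$fwd.b,
        pp$bwd.Wx, pp$bwd.Wh, pp$bwd.b, B, L
      )
      prot_in <- bl$Y
      prot_cache <- list(mode = "flatten", ptr = bl$ptr, pp = pp)
    } else {
      fwd <- lstm_forward(emb$Y, pp$fwd.Wx, pp$fwd.Wh, pp$fwd.b, B, L)
      perm <- .prefix_reverse_perm(batch$lengths, B, L)
      Xrev <- emb$Y[perm, , drop = FALSE]
      bwd <- lstm_forward(Xrev, pp$bwd.Wx, pp$bwd.Wh, pp$bwd.b, B, L)
      gf <- gather_last_forward(fwd$Y, B, L, batch$lengths)
      gb <- gather_last_forward(bwd$Y, B, L, batch$lengths)
      prot_in <- cbind(gf$Y, gb$Y)
      prot_cache <- list(
        mode = "last_hidden", fwd = fwd, bwd = bwd,
        gf = gf, gb = gb, perm = perm, pp = pp
      )
    }
  } else {
    k <- spec$conv_kernel
    cv1 <- conv1d_forward(
      emb$Y, p[["protein_core.conv1.W"]], p[["protein_core.conv1.b"]],
      B, L, k
    )
    if (spec$extra_protein_conv) {
      rc <- relu_forward(cv1$Y)
      cv2 <- conv1d_forward(
        rc$Y, p[["protein_core.conv2.W"]], p[["protein_core.conv2.b"]],
        B, cv1$Lout, k
      )
      fl <- flatten_forward(cv2$Y, B, cv2$Lout)
      prot_cache <- list(mode = "conv2", cv1 = cv1, rc = rc, cv2 = cv2, fl = fl)
    } else {
      fl <- flatten_forward(cv1$Y, B, cv1$Lout)
      prot_cache <- list(mode = "conv", cv1 = cv1, fl = fl)
    }
    prot_in <- fl$Y
  }
  dxt <- dense_forward(prot_in, p[["fc1_xt.W"]], p[["fc1_xt.b"]])
  prot_vec <- dxt$Y

  hin <- cbind(drug_vec, prot_vec)
  head <- .head_forward(p, model$head_plan, hin, rate, training)
  list(
    yhat = head$yhat,
    cache = list(
      gcn = gcn_caches, pool = pool, dg1 = dg1, rg1 = rg1, og1 = og1,
      dg2 = dg2, og2 = og2, emb = emb, prot = prot_cache, dxt = dxt,
      hin = hin, head = head, drug_vec = drug_vec, prot_vec = prot_vec
    )
  )
}

.backward_graph_family <- function(model, batch, cache, dy) {
  p <- model$params
  spec <- model$spec
  hb <- .head_backward(p, model$head_plan, cache$head, dy)
  grads <- hb$grads
  g2d <- spec$fc_g2_dim
  d_drug <- hb$dX[, seq_len(g2d), drop = FALSE]
  d_prot <- hb$dX[, (g2d + 1L):ncol(hb$dX), drop = FALSE]

  # protein branch
  db <- dense_backward(cache$dxt, p[["fc1_xt.W"]], d_prot)
  grads[["fc1_xt.W"]] <- db$dW
  grads[["fc1_xt.b"]] <- db$db
  pc <- cache$prot
  if (pc$mode == "flatten") {
    blb <- bilstm_flat_backward_cpp(
      pc$ptr, pc$pp$fwd.Wx, pc$pp$fwd.Wh, pc$pp$bwd.Wx, pc$pp$bwd.Wh, db$dX
    )
    grads[["protein_core.fwd.Wx"]] <- blb$fwd.dWx
    grads[["protein_core.fwd.Wh"]] <- blb$fwd.dWh
    grads[["protein_core.fwd.b"]] <- blb$fwd.db
    grads[["protein_core.bwd.Wx"]] <- blb$bwd.dWx
    grads[["protein_core.bwd.Wh"]] <- blb$bwd.dWh
    grads[["protein_core.bwd.b"]] <- blb$bwd.db
    demb <- blb$dX
  } else if (pc$mode == "last_hidden") {
    H <- ncol(pc$gf$Y)
    dfwd_all <- gather_last_backward(pc$gf, db$dX[, seq_len(H), drop = FALSE])
    dbwd_all <- gather_last_backward(pc$gb, db$dX[, (H + 1L):(2L * H), drop = FALSE])
    fb <- lstm_backward(pc$fwd, pc$pp$fwd.Wx, pc$pp$fwd.Wh, dfwd_all)
    bb <- lstm_backward(pc$bwd, pc$pp$bwd.Wx, pc$pp$bwd.Wh, dbwd_all)
    grads[["protein_core.fwd.Wx"]] <- fb$dWx
    grads[["protein_core.fwd.Wh"]] <- fb$dWh
    grads[["protein_core.fwd.b"]] <- fb$db
    grads[["protein_core.bwd.Wx"]] <- bb$dWx
    grads[["protein_core.bwd.Wh"]] <- bb$dWh
    grads[["protein_core.bwd.b"]] <- bb$db
    demb <- fb$dX
    demb[pc$perm, ] <- demb[pc$perm, ] + bb$dX
  } else if (pc$mode == "conv2") {
    dcv2_in <- flatten_backward(pc$fl, db$dX)
    cb2 <- conv1d_backward(pc$cv2, p[["protein_core.conv2.W"]], dcv2_in)
    grads[["protein_core.conv2.W"]] <- cb2$dW
    grads[["protein_core.conv2.b"]] <- cb2$db
    dcv1_out <- relu_backward(pc$rc, cb2$dX)
    cb1 <- conv1d_backward(pc$cv1, p[["protein_core.conv1.W"]], dcv1_out)
    grads[["protein_core.conv1.W"]] <- cb1$dW
    grads[["protein_core.conv1.b"]] <- cb1$db
    demb <- cb1$dX
  } else {
    dcv1_out <- flatten_backward(pc$fl, db$dX)
    cb1 <- conv1d_backward(pc$cv1, p[["protein_core.conv1.W"]], dcv1_out)
    grads[["protein_core.conv1.W"]] <- cb1$dW
    grads[["protein_core.conv1.b"]] <- cb1$db
    demb <- cb1$dX
  }
  grads[["embed_xt.W"]] <- embedding_backward(cache$emb, demb)$dW

  # drug branch
  dY <- dropout_backward(cache$og2, d_drug)
  db <- dense_backward(cache$dg2, p[["fc_g2.W"]], dY)
  grads[["fc_g2.W"]] <- db$dW
  grads[["fc_g2.b"]] <- db$db
  dY <- dropout_backward(cache$og1, db$dX)
  dY <- relu_backward(cache$rg1, dY)
  db <- dense_backward(cache$dg1, p[["fc_g1.W"]], dY)
  grads[["fc_g1.W"]] <- db$dW
  grads[["fc_g1.b"]] <- db$db
  dH <- graph_max_pool_backward(cache$pool, db$dX)
  for (l in rev(seq_len(model$spec$n_gcn_layers))) {
    gb <- gcn_layer_backward(
      cache$gcn[[l]], batch$A_hat, p[[paste0("gcn", l, ".W")]], dH
    )
    grads[[paste0("gcn", l, ".W")]] <- gb$dW
    grads[[paste0("gcn", l, ".b")]] <- gb$db
    dH <- gb$dH
  }
  grads
}

# ---- forward/backward: deepdta ----------------------------------------

.convblock_forward <- function(params, prefix, tokens, B, L, k) {
  emb <- embedding_forward(tokens, params[[paste0(prefix, ".emb")]])
  caches <- list(emb = emb)
  X <- emb$Y
  Lc <- L
  for (cl in 1:3) {
    cv <- conv1d_forward(
      X,
      params[[paste0(prefix, ".core.conv", cl, ".W")]],
      params[[paste0(prefix, ".core.conv", cl, ".b")]],
      B, Lc, k
    )
    rl <- relu_forward(cv$Y)
    caches[[paste0("cv", cl)]] <- cv
    caches[[paste0("rl", cl)]] <- rl
    X <- rl$Y
    Lc <- cv$Lout
  }
  pool <- seq_max_pool_forward(X, B, Lc)
  caches$pool <- pool
  caches$Y <- pool$Y
  caches
}

.convblock_backward <- function(params, prefix, cache, dY) {
  grads <- list()
  dX <- seq_max_pool_backward(cache$pool, dY)
  for (cl in 3:1) {
    dX <- relu_backward(cache[[paste0("rl", cl)]], dX)
    cb <- conv1d_backward(
      cache[[paste0("cv", cl)]],
      params[[paste0(prefix, ".core.conv", cl, ".W")]], dX
    )
    grads[[paste0(prefix, ".core.conv", cl, ".W")]] <- cb$dW
    grads[[paste0(prefix, ".core.conv", cl, ".b")]] <- cb$db
    dX <- cb$dX
  }
  grads[[paste0(prefix, ".emb")]] <- embedding_backward(cache$emb, dX)$dW
  grads
}

.forward_deepdta <- function(model, batch, training) {
  p <- model$params
  spec <- model$spec
  if (is.null(batch$smiles_tokens)) {
    stop_invalid("deepdta batches require SMILES tokens; featurize with smiles_tokens = TRUE")
  }
  pmap <- list(
    drug.emb = p[["embed_xd.W"]], protein.emb = p[["embed_xt.W"]]
  )
  for (cl in 1:3) {
    pmap[[paste0("drug.core.conv", cl, ".W")]] <- p[[paste0("drug_core.conv", cl, ".W")]]
    pmap[[paste0("drug.core.conv", cl, ".b")]] <- p[[paste0("drug_core.conv", cl, ".b")]]
    pmap[[paste0("protein.core.conv", cl, ".W")]] <- p[[paste0("protein_core.conv", cl, ".W")]]
    pmap[[paste0("protein.core.conv", cl, ".b")]] <- p[[paste0("protein_core.conv", cl, ".b")]]
  }
  drug <- .convblock_forward(
    pmap, "drug", batch$smiles_tokens, batch$B, spec$smiles_len, spec$conv_kernel
  )
  prot <- .convblock_forward(
    pmap, "protein", batch$tokens, batch$B, spec$seq_len, spec$conv_kernel
  )
  hin <- cbind(drug$Y, prot$Y)
  head <- .head_forward(p, model$head_plan, hin, spec$dropout_rate, training)
  list(
    yhat = head$yhat,
    cache = list(drug = drug, prot = prot, hin = hin, head = head, pmap = pmap)
  )
}

.backward_deepdta <- function(model, batch, cache, dy) {
  p <- model$params
  hb <- .head_backward(p, model$head_plan, cache$head, dy)
  grads <- hb$grads
  half <- ncol(cache$drug$Y)
  gd <- .convblock_backward(
    cache$pmap, "drug", cache$drug, hb$dX[, seq_len(half), drop = FALSE]
  )
  gp <- .convblock_backward(
    cache$pmap, "protein", cache$prot,
    hb$dX[, (half + 1L):ncol(hb$dX), drop = FALSE]
  )
  grads[["embed_xd.W"]] <- gd[["drug.emb"]]
  grads[["embed_xt.W"]] <- gp[["protein.emb"]]
  for (cl in 1:3) {
    grads[[paste0("drug_core.conv", cl, ".W")]] <- gd[[paste0("drug.core.conv", cl, ".W")]]
    grads[[paste0("drug_core.conv", cl, ".b")]] <- gd[[paste0("drug.core.conv", cl, ".b")]]
    grads[[paste0("protein_core.conv", cl, ".W")]] <- gp[[paste0("protein.core.conv", cl, ".W")]]
    grads[[paste0("protein_core.conv", cl, ".b")]] <- gp[[paste0("protein.core.conv", cl, ".b")]]
  }
  grads
}

# ---- public forward interface -----------------------------------------

# One mini-batch forward pass; returns yhat and the cache for backward.
forward_batch <- function(model, batch, training = FALSE) {
  if (model$spec$family == "deepdta") {
    .forward_deepdta(model, batch, training)
  } else {
    .forward_graph_family(model, batch, training)
  }
}

backward_batch <- function(model, batch, cache, dy) {
  if (model$spec$family == "deepdta") {
    .backward_deepdta(model, batch, cache, dy)
  } else {
    .backward_graph_family(model, batch, cache, dy)
  }
}

#' Predict affinities for a featurized dataset
#'
#' Runs the model in evaluation mode (dropout disabled) over mini-batches.
#'
#' @param model A `dta_model`.
#' @param fz A [featurize_dataset()] result.
#' @param indices Record indices to predict (default all).
#' @param batch_size Mini-batch size.
#' @return Numeric vector of predicted pIC50 values.
#' @export
predict_affinity <- function(model, fz, indices = NULL, batch_size = 64L) {
  fz <- .with_adjacency(fz)
  indices <- indices %||% seq_along(fz$graphs)
  out <- numeric(length(indices))
  pos <- 1L
  for (chunk in split(indices, ceiling(seq_along(indices) / batch_size))) {
    batch <- prepare_batch(fz, chunk)
    fwd <- forward_batch(model, batch, training = FALSE)
    out[pos:(pos + length(chunk) - 1L)] <- fwd$yhat
    pos <- pos + length(chunk)
  }
  out
}

#' Extract fused drug/protein features
#'
#' Returns the concatenated pre-head representation (drug-branch output
#' alongside protein-branch output; 256-dimensional under the default
#' spec) for each record, in evaluation mode.  These are the learned
#' features consumed by the classical-regressor baselines.
#'
#' @inheritParams predict_affinity
#' @return Numeric matrix, one row per record.
#' @export
extract_drug_protein_features <- function(model, fz, indices = NULL,
                                          batch_size = 64L) {
  fz <- .with_adjacency(fz)
  indices <- indices %||% seq_along(fz$graphs)
  rows <- vector("list", 0)
  for (chunk in split(indices, ceiling(seq_along(indices) / batch_size))) {
    batch <- prepare_batch(fz, chunk)
    fwd <- forward_batch(model, batch, training = FALSE)
    rows <- c(rows, list(fwd$cache$hin))
  }
  do.call(rbind, rows)
}

# ---- checkpoints -------------------------------------------------------

#' Save a model checkpoint
#'
#' The checkpoint is self-describing: parameters, specification, seed, and
#' any featurization metadata travel together, and loading restores
#' bit-identical evaluation-mode forwards.
#'
#' @param model A `dta_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The restored `dta_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dta_model")) stop_config("not a model checkpoint")
  model
}

#' @export
print.dta_model <- function(x, ...) {
  cat(sprintf(
    "<dta_model> family=%s, %d parameter tensors, %d parameters\n",
    x$spec$family, length(x$params), n_parameters(x)
  ))
  cat("layer groups:", paste(names(x$registry), collapse = ", "), "\n")
  invisible(x)
}
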