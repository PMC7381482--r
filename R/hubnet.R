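#' Configuration for the hub-and-spoke auto-associator
#'
#' The network has 216 visible units (40 name, 64 visual, 112 verbal)
#' bidirectionally connected to a recurrent hidden "hub", with a fixed,
#' untrainable bias input of -2.0 to every unit.  Training presents every
#' pattern three times per epoch (name, verbal and visual block clamped in
#' turn) and backpropagates through the unrolled 2-clamped + 5-free
#' settling cycles, with targets applied to the visible units on the final
#' \code{target_cycles} cycles.
#'
#' @param n_hidden Hub size (default 64).
#' @param learning_rate,weight_decay Per-presentation learning rate and
#'   multiplicative weight-decay rate (both default 0.001).
#' @param epochs Training epochs (default 1000).
#' @param bias_value Fixed bias input (default -2.0; never trained,
#'   never lesioned).
#' @param settle_cycles_clamped,settle_cycles_free Settling protocol used
#'   for training and naming (defaults 2 and 5).
#' @param target_cycles Number of final unrolled cycles on which the
#'   visible targets are applied during training (default 5: targets apply
#'   on every cycle on which the visible units run free).
#' @param init_weight_scale Initial weights are uniform in
#'   \code{[-init_weight_scale, +init_weight_scale]} (default 0.5).
#' @param loss Training loss: "ce" (cross-entropy, default) or "sse".
#' @return A list of class \code{hub_config}.
#' @export
hub_config <- function(n_hidden = 64L, learning_rate = 0.001,
                       weight_decay = 0.001, epochs = 1000L,
                       bias_value = -2.0,
                       settle_cycles_clamped = 2L, settle_cycles_free = 5L,
                       target_cycles = 5L, init_weight_scale = 0.5,
                       loss = c("ce", "sse")) {
  loss <- match.arg(loss)
  if (n_hidden < 1L) stop("n_hidden must be positive")
  if (epochs < 0L) stop("epochs must be non-negative")
  if (settle_cycles_clamped < 0L || settle_cycles_free < 0L)
    stop("cycle counts must be non-negative")
  structure(list(
    n_name = N_NAME, n_visual = N_VISUAL, n_verbal = N_VERBAL,
    n_visible = N_UNITS, n_hidden = as.integer(n_hidden),
    learning_rate = learning_rate, weight_decay = weight_decay,
    epochs = as.integer(epochs), bias_value = bias_value,
    settle_cycles_clamped = as.integer(settle_cycles_clamped),
    settle_cycles_free = as.integer(settle_cycles_free),
    target_cycles = as.integer(target_cycles),
    init_weight_scale = init_weight_scale, loss = loss
  ), class = "hub_config")
}

#' Initialise a hub-and-spoke network
#'
#' Weights are drawn uniformly from
#' \code{[-init_weight_scale, +init_weight_scale]}; the bias input to every
#' unit is fixed at \code{bias_value} and is exempt from both training and
#' damage.
#'
#' @param config A \code{hub_config}.
#' @param seed Integer seed; the same config and seed give an identical
#'   network.
#' @return An object of class \code{hub_net} with weight matrices
#'   \code{W_vh} (visible to hidden), \code{W_hh} (hidden recurrent) and
#'   \code{W_hv} (hidden to visible).
#' @export
init_hub <- function(config = hub_config(), seed = 1L) {
  stopifnot(inherits(config, "hub_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  s <- config$init_weight_scale
  nv <- config$n_visible; nh <- config$n_hidden
  net <- list(
    W_vh = matrix(runif(nv * nh, -s, s), nv, nh),
    W_hh = matrix(runif(nh * nh, -s, s), nh, nh),
    W_hv = matrix(runif(nh * nv, -s, s), nh, nv),
    bias = config$bias_value,
    config = config, feedforward = FALSE, trained = FALSE, seed = as.integer(seed)
  )
  class(net) <- "hub_net"
  net
}

#' Feed-forward auto-associator variant
#'
#' A 216 input, 64 (by default) hidden, 216 output feed-forward
#' auto-associator with no hidden recurrence: processing is a single
#' forward pass through \code{W_vh} then \code{W_hv}.  Used as a
#' comparison architecture that lacks settling dynamics.
#'
#' @inheritParams init_hub
#' @return A \code{hub_net} with \code{feedforward = TRUE} and no
#'   \code{W_hh}.
#' @export
make_feedforward_variant <- function(config = hub_config(), seed = 1L) {
  net <- init_hub(config, seed)
  net$W_hh <- NULL
  net$feedforward <- TRUE
  net
}

#' Clamp specification for settling
#'
#' @param name,verbal,visual Optional binary vectors clamped onto the
#'   corresponding visible blocks (lengths 40, 112, 64); blocks left NULL
#'   run free.
#' @return A list of class \code{clamp_spec}.
#' @export
clamp_spec <- function(name = NULL, verbal = NULL, visual = NULL) {
  chk <- function(x, n, lab) {
    if (!is.null(x) && length(x) != n)
      stop(lab, " clamp must have length ", n)
    x
  }
  structure(list(name = chk(name, N_NAME, "name"),
                 verbal = chk(verbal, N_VERBAL, "verbal"),
                 visual = chk(visual, N_VISUAL, "visual")),
            class = "clamp_spec")
}

clamp_indices <- function(clamp) {
  idx <- integer(0); val <- numeric(0)
  if (!is.null(clamp$name)) { idx <- c(idx, name_cols()); val <- c(val, clamp$name) }
  if (!is.null(clamp$visual)) { idx <- c(idx, visual_cols()); val <- c(val, clamp$visual) }
  if (!is.null(clamp$verbal)) { idx <- c(idx, verbal_cols()); val <- c(val, clamp$verbal) }
  list(idx = idx, val = val)
}

#' Settle the network with a clamp
#'
#' Synchronous sigmoid updates: on every cycle the hidden units receive the
#' previous visible and hidden activations, and the visible units receive
#' the previous hidden activations, each plus the fixed bias.  Clamped
#' visible units are overwritten with their clamp values during the clamped
#' phase and run free afterwards.  All activations start at 0.
#'
#' @param net A \code{hub_net}.
#' @param clamp A \code{clamp_spec}.
#' @param cycles_clamped,cycles_free Cycle counts (defaults from the
#'   network's config: 2 and 5).
#' @return A list of class \code{settle_trace}: \code{visible} and
#'   \code{hidden} matrices of per-cycle activations (one row per cycle),
#'   and \code{final_visible}, \code{final_hidden}.
#' @export
settle <- function(net, clamp, cycles_clamped = net$config$settle_cycles_clamped,
                   cycles_free = net$config$settle_cycles_free) {
  stopifnot(inherits(net, "hub_net"), inherits(clamp, "clamp_spec"))
  if (cycles_clamped < 0 || cycles_free < 0) stop("cycle counts must be non-negative")
  ci <- clamp_indices(clamp)
  if (net$feedforward) {
    v_in <- numeric(net$config$n_visible)
    v_in[ci$idx] <- ci$val
    h <- plogis(net$bias + drop(v_in %*% net$W_vh))
    v <- plogis(net$bias + drop(h %*% net$W_hv))
    return(structure(list(visible = matrix(v, 1L), hidden = matrix(h, 1L),
                          final_visible = v, final_hidden = h),
                     class = "settle_trace"))
  }
  C <- cycles_clamped + cycles_free
  v <- numeric(net$config$n_visible); h <- numeric(net$config$n_hidden)
  v[ci$idx] <- ci$val
  V <- matrix(NA_real_, C, length(v)); H <- matrix(NA_real_, C, length(h))
  for (t in seq_len(C)) {
    hn <- plogis(net$bias + drop(v %*% net$W_vh) + drop(h %*% net$W_hh))
    vn <- plogis(net$bias + drop(h %*% net$W_hv))
    if (t <= cycles_clamped) vn[ci$idx] <- ci$val
    v <- vn; h <- hn
    V[t, ] <- v; H[t, ] <- h
  }
  structure(list(visible = V, hidden = H, final_visible = v, final_hidden = h),
            class = "settle_trace")
}

#' Train a hub network on a pattern set
#'
#' Backpropagation through time over the unrolled settling cycles.  Each
#' epoch presents every pattern three times (name, verbal, visual block
#' clamped in turn, in a fixed order), with weights updated after every
#' presentation and multiplicative weight decay applied at each update.
#' The bias input is untouched.
#'
#' @param net A \code{hub_net} (recurrent or feed-forward variant; the
#'   feed-forward variant is trained by ordinary backpropagation on the
#'   full 216-unit auto-association target).
#' @param ps A \code{pattern_set}.
#' @param epochs Override for the config's epoch count.
#' @return The trained \code{hub_net}, with a \code{loss_trace} element
#'   (per-epoch summed squared visible error at the final cycle).
#' @export
train_hub <- function(net, ps, epochs = NULL) {
  stopifnot(inherits(net, "hub_net"), inherits(ps, "pattern_set"))
  if (ncol(ps$units) != net$config$n_visible)
    stop("pattern width does not match network visible layer")
  cfg <- net$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (epochs == 0L) return(net)
  patterns <- ps$units
  storage.mode(patterns) <- "double"
  if (net$feedforward) return(train_feedforward(net, patterns, epochs))
  masks <- list(name_cols() - 1L, verbal_cols() - 1L, visual_cols() - 1L)
  fit <- hub_train_cpp(net$W_vh, net$W_hh, net$W_hv, patterns, masks,
                       as.integer(epochs), cfg$learning_rate,
                       cfg$weight_decay, cfg$bias_value,
                       cfg$settle_cycles_clamped, cfg$settle_cycles_free,
                       cfg$target_cycles, cfg$loss)
  net$W_vh <- fit$W_vh; net$W_hh <- fit$W_hh; net$W_hv <- fit$W_hv
  net$loss_trace <- c(net$loss_trace, as.numeric(fit$loss_trace))
  net$trained <- TRUE
  net
}

train_feedforward <- function(net, patterns, epochs) {
  cfg <- net$config
  lr <- cfg$learning_rate; decay <- cfg$weight_decay; b <- cfg$bias_value
  W1 <- net$W_vh; W2 <- net$W_hv
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    err_ep <- 0
    for (p in seq_len(nrow(patterns))) {
      x <- patterns[p, ]
      h <- plogis(b + drop(x %*% W1))
      o <- plogis(b + drop(h %*% W2))
      err <- o - x
      err_ep <- err_ep + sum(err^2)
      dpo <- if (cfg$loss == "ce") err else 2 * err * o * (1 - o)
      dph <- drop(W2 %*% dpo) * h * (1 - h)
      W2 <- W2 - lr * (outer(h, dpo) + decay * W2)
      W1 <- W1 - lr * (outer(x, dph) + decay * W1)
    }
    trace[ep] <- err_ep
  }
  net$W_vh <- W1; net$W_hv <- W2
  net$loss_trace <- c(net$loss_trace, trace)
  net$trained <- TRUE
  net
}

# Batched settling of many visual inputs through one network.
settle_visual_batch <- function(net, visual_matrix,
                                cycles_clamped = net$config$settle_cycles_clamped,
                                cycles_free = net$config$settle_cycles_free) {
  storage.mode(visual_matrix) <- "double"
  if (net$feedforward) {
    v_in <- matrix(0, nrow(visual_matrix), net$config$n_visible)
    v_in[, visual_cols()] <- visual_matrix
    h <- plogis(net$bias + v_in %*% net$W_vh)
    v <- plogis(net$bias + h %*% net$W_hv)
    return(list(visible = v, hidden = h))
  }
  hub_settle_cpp(net$W_vh, net$W_hh, net$W_hv, visual_matrix,
                 visual_cols() - 1L, net$bias, cycles_clamped, cycles_free)
}

#' Naming readout from a visual input
#'
#' Clamps the 64 visual units to \code{visual_vector} for 2 cycles, runs 5
#' free cycles, then reads the name block: the most active name unit above
#' 0.5 is the response; if none exceeds 0.5 the response is "no response"
#' (\code{NA}).  Ties break to the lowest unit index.
#'
#' @param net A \code{hub_net}.
#' @param visual_vector Binary vector of length 64.
#' @return Integer name-unit index, or \code{NA_integer_} for no response.
#' @export
name_response <- function(net, visual_vector) {
  if (length(visual_vector) != N_VISUAL)
    stop("visual_vector must have length ", N_VISUAL)
  out <- settle_visual_batch(net, matrix(visual_vector, 1L))
  name_act <- out$visible[1L, name_cols()]
  read_name(name_act)
}

read_name <- function(name_act) {
  m <- max(name_act)
  if (m <= 0.5) return(NA_integer_)
  which.max(name_act)  # lowest index on ties
}

#' Naming accuracy of a network over a pattern set
#'
#' Runs the naming protocol on every item's visual vector and scores the
#' response against the item's assigned name unit.
#'
#' @param net A \code{hub_net}.
#' @param ps A \code{pattern_set}.
#' @return Data frame with one row per item: id, category, domain,
#'   response (NA = no response), correct.
#' @export
name_accuracy <- function(net, ps) {
  out <- settle_visual_batch(net, ps$units[, visual_cols()])
  name_acts <- out$visible[, name_cols(), drop = FALSE]
  resp <- apply(name_acts, 1L, read_name)
  data.frame(ps$items[, c("id", "category", "domain")],
             response = resp,
             correct = !is.na(resp) & resp == ps$items$name_unit,
             stringsAsFactors = FALSE)
}

#' Maximum settling error over a pattern set
#'
#' Settles every item under the 2+5 naming protocol (visual clamp) and
#' returns the maximum absolute difference between the 216 visible
#' activations and the item's target vector, over all units and items.
#'
#' @param net A \code{hub_net}.
#' @param ps A \code{pattern_set}.
#' @return A single number.
#' @export
max_unit_error <- function(net, ps) {
  out <- settle_visual_batch(net, ps$units[, visual_cols()])
  max(abs(out$visible - ps$units))
}

#' Save / load a network checkpoint as JSON
#'
#' @param net A \code{hub_net} or \code{srn_net}.
#' @param path Output path.
#' @return \code{path} (write) or the network (read).
#' @export
write_checkpoint <- function(net, path) {
  strip <- function(x) {
    if (is.matrix(x)) return(list(matrix = TRUE, dim = dim(x), data = as.numeric(x)))
    if (is.list(x)) return(lapply(unclass(x), strip))
    unclass(x)
  }
  obj <- list(schema = "lesionette-checkpoint-1", class = class(net)[1],
              fields = lapply(unclass(net), strip))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "lesionette-checkpoint-1"))
    stop("not a lesionette checkpoint: ", path)
  fields <- lapply(obj$fields, function(x) {
    if (is.list(x) && isTRUE(x$matrix)) matrix(x$data, x$dim[1], x$dim[2])
    else x
  })
  cfg <- fields$config
  if (!is.null(cfg)) class(fields$config) <- paste0(sub("_net$", "", obj$class), "_config")
  structure(fields, class = obj$class)
}

#' @export
print.hub_net <- function(x, ...) {
  cat(sprintf("hub_net: %d visible / %d hidden%s%s (seed %d)\n",
              x$config$n_visible, x$config$n_hidden,
              if (x$feedforward) ", feed-forward" else ", recurrent",
              if (isTRUE(x$trained)) ", trained" else ", untrained", x$seed))
  invisible(x)
}
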